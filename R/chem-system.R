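# Polymer composition bookkeeping, hydration stoichiometry and cell sizing.

# IUPAC standard atomic masses (g/mol).
.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)
.WATER_MOLAR_MASS <- 18.015
.AVOGADRO <- 6.02214076e23

#' Create a mer (repeat unit) specification
#'
#' The molar mass is derived from the element counts using standard atomic
#' masses (H 1.008, C 12.011, N 14.007, O 15.999 g/mol).
#'
#' @param name short mer label, e.g. `"HEMA"`.
#' @param formula named numeric vector of element counts,
#'   e.g. `c(C = 6, H = 10, O = 3)`.
#' @return A [MerSpec-class].
#' @examples
#' merSpec("HEMA", c(C = 6, H = 10, O = 3))
#' @export
merSpec <- function(name, formula) {
  m <- .ATOMIC_MASS[names(formula)]
  if (anyNA(m))
    .stop_labeled("unknown_element", "no atomic mass for element(s): %s",
                  paste(names(formula)[is.na(m)], collapse = ", "))
  new("MerSpec", name = name, formula = formula,
      molarMass = sum(m * formula))
}

setMethod("show", "MerSpec", function(object) {
  cat(sprintf("MerSpec %s: %s, %.2f g/mol\n", object@name,
              paste0(names(object@formula), object@formula, collapse = ""),
              object@molarMass))
})

#' Built-in mer registry
#'
#' HEMA (2-hydroxyethyl methacrylate, C6H10O3, 130.1 g/mol) and VP
#' (N-vinylpyrrolidone, C6H9NO, 111.1 g/mol), the repeat units of
#' PHEMA / P(VP-co-HEMA) hydrogels.
#'
#' @param extra optional named list of additional [MerSpec-class] objects.
#' @return Named list of `MerSpec` objects keyed by mer label.
#' @export
defaultMerRegistry <- function(extra = NULL) {
  reg <- list(
    HEMA = merSpec("HEMA", c(C = 6, H = 10, O = 3)),
    VP   = merSpec("VP",   c(C = 6, H = 9, N = 1, O = 1))
  )
  if (!is.null(extra)) reg[names(extra)] <- extra
  reg
}

#' Build a chain composition from a mer sequence or counts
#'
#' @param sequence character vector of mer labels in chain order, or `NULL`
#'   to build an (order-less) composition from `counts`.
#' @param counts named integer mer counts, used when `sequence` is `NULL`.
#' @return A [ChainComposition-class].
#' @export
chainComposition <- function(sequence = NULL, counts = NULL) {
  if (is.null(sequence)) {
    if (is.null(counts)) .stop_labeled("bad_composition",
                                       "need a sequence or counts")
    sequence <- rep(names(counts), as.integer(counts))
  }
  tab <- table(sequence)
  new("ChainComposition", sequence = as.character(sequence),
      counts = stats::setNames(as.integer(tab), names(tab)))
}

#' @rdname chainComposition
#' @param x a `ChainComposition`.
#' @export
chainLength <- function(x) length(x@sequence)

#' @rdname chainComposition
#' @export
merCounts <- function(x) x@counts

setMethod("show", "ChainComposition", function(object) {
  cat(sprintf("ChainComposition: %d mers (%s)\n", length(object@sequence),
              paste(sprintf("%s x %d", names(object@counts), object@counts),
                    collapse = ", ")))
})

#' Named 50-mer polymers of the HEMA/VP hydrogel family
#'
#' `H50` is the PHEMA homopolymer; `B37`/`B13` are block copolymers with 37
#' and 13 HEMA mers; `R37`/`R13` their random-sequence counterparts (R37:
#' 37 HEMA + 13 VP, R13: 13 HEMA + 37 VP). Block sequences are literal
#' blocks; random sequences are drawn once per call from the stated counts
#' with a fixed internal seed, so the composition (which is what the
#' stoichiometry uses) is exact and reproducible.
#'
#' @param code one of `"H50"`, `"B37"`, `"B13"`, `"R37"`, `"R13"`.
#' @return A [ChainComposition-class] of length 50.
#' @export
namedPolymer <- function(code) {
  counts <- switch(code,
    H50 = c(HEMA = 50L, VP = 0L),
    B37 = ,
    R37 = c(HEMA = 37L, VP = 13L),
    B13 = ,
    R13 = c(HEMA = 13L, VP = 37L),
    .stop_labeled("unknown_polymer", "unknown polymer code: %s", code)
  )
  counts <- counts[counts > 0L]
  seqv <- switch(substr(code, 1, 1),
    H = rep("HEMA", 50L),
    B = c(rep("VP", counts[["VP"]]), rep("HEMA", counts[["HEMA"]])),
    R = .with_seed(match(code, c("R37", "R13")),
                   sample(rep(names(counts), counts)))
  )
  chainComposition(seqv)
}

#' Molar mass of a polymer chain
#'
#' Sum of mer molar masses; end groups are excluded by default and may be
#' supplied as an extra mass (e.g. ~18 g/mol for H/OH capping).
#'
#' @param composition a [ChainComposition-class].
#' @param registry mer registry, a named list of [MerSpec-class]; defaults
#'   to [defaultMerRegistry()].
#' @param end_group_mass additional chain-end mass in g/mol (default 0).
#' @return chain molar mass in g/mol.
#' @examples
#' chainMolarMass(namedPolymer("H50"))  # 6507.1
#' @export
chainMolarMass <- function(composition, registry = defaultMerRegistry(),
                           end_group_mass = 0) {
  if (chainLength(composition) == 0L) return(end_group_mass)
  unknown <- setdiff(names(composition@counts), names(registry))
  if (length(unknown))
    .stop_labeled("unknown_mer", "mer label(s) not in registry: %s",
                  paste(unknown, collapse = ", "))
  masses <- vapply(registry[names(composition@counts)],
                   function(m) m@molarMass, 0)
  sum(masses * composition@counts) + end_group_mass
}

#' Number of water molecules for a target mass fraction
#'
#' Rounds `n = (f / (1 - f)) * M_chain / m_water` (water molar mass
#' 18.015 g/mol) to the nearest integer, ties away from zero.
#'
#' @inheritParams chainMolarMass
#' @param mass_fraction target water mass fraction, in `[0, 1)`.
#' @return integer count of water molecules.
#' @examples
#' waterCount(namedPolymer("H50"), 0.10)  # 40
#' @export
waterCount <- function(composition, mass_fraction,
                       registry = defaultMerRegistry(), end_group_mass = 0) {
  if (mass_fraction < 0 || mass_fraction >= 1)
    .stop_labeled("bad_fraction", "mass_fraction must lie in [0, 1)")
  m_chain <- chainMolarMass(composition, registry, end_group_mass)
  n <- (mass_fraction / (1 - mass_fraction)) * m_chain / .WATER_MOLAR_MASS
  as.integer(floor(n + 0.5))  # nearest, ties away from zero (n >= 0)
}

#' Cubic cell edge for a total mass at a target density
#'
#' `edge = (total_mass / (N_A * density))^(1/3)` converted to Angstrom.
#'
#' @param total_mass total cell contents in g/mol (chain + waters).
#' @param density target density in g/cm^3.
#' @return cell edge in Angstrom.
#' @examples
#' cellEdge(6507.1, 1.1)  # ~21.42 A, the dry-PHEMA cell
#' @export
cellEdge <- function(total_mass, density) {
  if (total_mass <= 0 || density <= 0)
    .stop_labeled("bad_input", "total_mass and density must be positive")
  vol_cm3 <- total_mass / (.AVOGADRO * density)
  (vol_cm3 * 1e24)^(1 / 3)  # 1 cm^3 = 1e24 A^3
}

#' Hydration stoichiometry for one polymer cell
#'
#' Combines [waterCount()] and [cellEdge()] into a single-cell hydration
#' specification: one chain plus the rounded number of waters at the target
#' mass fraction, in a cubic cell sized to the target density.
#'
#' @inheritParams waterCount
#' @param density target density, g/cm^3 (default 1.1, typical of these
#'   hydrogel cells).
#' @return A [HydrationSpec-class].
#' @export
hydrationSpec <- function(composition, mass_fraction, density = 1.1,
                          registry = defaultMerRegistry(),
                          end_group_mass = 0) {
  n_w <- waterCount(composition, mass_fraction, registry, end_group_mass)
  m_chain <- chainMolarMass(composition, registry, end_group_mass)
  edge <- cellEdge(m_chain + n_w * .WATER_MOLAR_MASS, density)
  new("HydrationSpec", composition = composition,
      waterMassFraction = as.numeric(mass_fraction), nWater = n_w,
      density = as.numeric(density), cellEdge = edge)
}

#' @rdname hydrationSpec
#' @param x a `HydrationSpec`.
#' @export
nWater <- function(x) x@nWater

#' Achieved water mass fraction of a hydration spec
#'
#' @param x a [HydrationSpec-class].
#' @param registry,end_group_mass as in [chainMolarMass()].
#' @return achieved mass fraction `n m_w / (M_chain + n m_w)`.
#' @export
achievedMassFraction <- function(x, registry = defaultMerRegistry(),
                                 end_group_mass = 0) {
  m_chain <- chainMolarMass(x@composition, registry, end_group_mass)
  mw <- x@nWater * .WATER_MOLAR_MASS
  mw / (m_chain + mw)
}

setMethod("show", "HydrationSpec", function(object) {
  cat(sprintf(
    "HydrationSpec: %d-mer chain + %d waters (target %.0f%% water), %.3g g/cm^3, edge %.3f A\n",
    chainLength(object@composition), object@nWater,
    100 * object@waterMassFraction, object@density, object@cellEdge))
})

#' Hydration stoichiometry table for a named polymer
#'
#' Computes, for a set of water mass fractions, the water count and cubic
#' cell edge of a single-chain cell at the target density.
#'
#' @param code polymer code, see [namedPolymer()].
#' @param mass_fractions numeric vector of target water mass fractions.
#' @param density target density, g/cm^3.
#' @inheritParams chainMolarMass
#' @return data.frame with columns `polymer`, `water_pct`, `n_water`,
#'   `cell_edge`, `achieved_pct`.
#' @examples
#' hydrationTable("H50", c(0, 0.1, 0.2, 0.4))
#' @export
hydrationTable <- function(code, mass_fractions = c(0, 0.1, 0.2, 0.4, 0.6),
                           density = 1.1, registry = defaultMerRegistry(),
                           end_group_mass = 0) {
  comp <- namedPolymer(code)
  rows <- lapply(mass_fractions, function(f) {
    hs <- hydrationSpec(comp, f, density, registry, end_group_mass)
    data.frame(polymer = code, water_pct = 100 * f, n_water = hs@nWater,
               cell_edge = hs@cellEdge,
               achieved_pct = 100 * achievedMassFraction(hs, registry,
                                                         end_group_mass))
  })
  do.call(rbind, rows)
}
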