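#' @import methods
NULL

# Default van der Waals radii (Angstrom) used for polymer/water atoms.
.VDW_RADII <- c(C = 1.70, H = 1.20, O = 1.52, N = 1.55)

#' Single-frame particle configuration in a cubic periodic box
#'
#' Holds positions (Angstrom), an optional cubic box edge, per-particle
#' species labels, chemical elements, van der Waals radii and
#' hydrogen-bond roles. The box is cubic with the origin at a corner;
#' wrapped coordinates live in `[0, boxEdge)`.
#'
#' @slot positions numeric n x 3 matrix of coordinates in Angstrom.
#' @slot boxEdge cubic box edge in Angstrom (`NA_real_` for non-periodic).
#' @slot labels character species/site tag per particle.
#' @slot elements character chemical element per particle.
#' @slot vdwRadius numeric van der Waals radius per particle (Angstrom).
#' @slot hbondRole character, one of `"none"`, `"donor"`, `"hydrogen"`,
#'   `"acceptor"` per particle.
#' @exportClass Configuration
setClass("Configuration", representation(
  positions = "matrix",
  boxEdge = "numeric",
  labels = "character",
  elements = "character",
  vdwRadius = "numeric",
  hbondRole = "character"
))

setValidity("Configuration", function(object) {
  n <- nrow(object@positions)
  msgs <- character()
  if (ncol(object@positions) != 3L)
    msgs <- c(msgs, "positions must have 3 columns")
  if (!all(is.finite(object@positions)))
    msgs <- c(msgs, "positions must be finite")
  if (length(object@boxEdge) != 1L)
    msgs <- c(msgs, "boxEdge must be a scalar")
  else if (!is.na(object@boxEdge) && object@boxEdge <= 0)
    msgs <- c(msgs, "boxEdge must be positive")
  for (s in c("labels", "elements", "vdwRadius", "hbondRole"))
    if (length(slot(object, s)) != n)
      msgs <- c(msgs, sprintf("%s must have one entry per particle", s))
  bad <- setdiff(unique(object@hbondRole), c("none", "donor", "hydrogen", "acceptor"))
  if (length(bad))
    msgs <- c(msgs, sprintf("unknown hbondRole: %s", paste(bad, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Time-ordered particle trajectory
#'
#' Frames share particle count, ordering and annotations. Coordinates are
#' stored as an `n_frames x n_particles x 3` array in Angstrom with a fixed
#' frame spacing `dt` in picoseconds. The `wrapped` flag records whether
#' coordinates are folded into the periodic box; dynamic analyses (MSD,
#' van Hove) require unwrapped input.
#'
#' @slot coords numeric array, `n_frames x n_particles x 3`, Angstrom.
#' @slot dt frame spacing in ps.
#' @slot boxEdge cubic box edge in Angstrom (`NA_real_` if non-periodic).
#' @slot labels character species tag per particle.
#' @slot elements character element per particle.
#' @slot wrapped logical, `TRUE` if coordinates are wrapped into the box.
#' @exportClass Trajectory
setClass("Trajectory", representation(
  coords = "array",
  dt = "numeric",
  boxEdge = "numeric",
  labels = "character",
  elements = "character",
  wrapped = "logical"
))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  msgs <- character()
  if (length(d) != 3L || d[3] != 3L)
    msgs <- c(msgs, "coords must be an n_frames x n_particles x 3 array")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msgs <- c(msgs, "dt must be a positive scalar (ps)")
  if (length(d) == 3L) {
    if (length(object@labels) != d[2])
      msgs <- c(msgs, "labels must have one entry per particle")
    if (length(object@elements) != d[2])
      msgs <- c(msgs, "elements must have one entry per particle")
  }
  if (length(object@wrapped) != 1L)
    msgs <- c(msgs, "wrapped must be a scalar flag")
  if (length(msgs)) msgs else TRUE
})

#' Radial distribution function curve
#'
#' @slot binCenters bin centers in Angstrom.
#' @slot g dimensionless pair correlation per bin.
#' @slot pairLabels character(2): the two selections correlated.
#' @slot dr bin width in Angstrom.
#' @slot nFrames number of frames averaged.
#' @exportClass RDFCurve
setClass("RDFCurve", representation(
  binCenters = "numeric", g = "numeric", pairLabels = "character",
  dr = "numeric", nFrames = "integer"
))

setValidity("RDFCurve", function(object) {
  if (length(object@g) != length(object@binCenters))
    return("g and binCenters must have equal length")
  if (any(object@g < 0)) return("g must be non-negative")
  TRUE
})

#' Geometric hydrogen-bond acceptance criteria
#'
#' Defaults follow the common geometric definition for D-H...A bonds:
#' donor-acceptor distance of 3.5 Angstrom or shorter (inclusive),
#' hydrogen-acceptor distance strictly less than 2.5 Angstrom, and
#' deviation of the D-H...A angle from linearity of up to 30 degrees
#' (inclusive). `pairCutoff` is the covalent search radius used to
#' associate each hydrogen with its donor heavy atom.
#'
#' @slot maxDA donor-acceptor distance bound, Angstrom, inclusive.
#' @slot maxHA hydrogen-acceptor distance bound, Angstrom, exclusive.
#' @slot maxAngleDev deviation from linearity bound, degrees, inclusive.
#' @slot pairCutoff covalent donor-hydrogen pairing radius, Angstrom.
#' @exportClass HBondCriteria
setClass("HBondCriteria", representation(
  maxDA = "numeric", maxHA = "numeric", maxAngleDev = "numeric",
  pairCutoff = "numeric"
), prototype(maxDA = 3.5, maxHA = 2.5, maxAngleDev = 30, pairCutoff = 1.3))

setValidity("HBondCriteria", function(object) {
  if (object@maxDA <= 0 || object@maxHA <= 0 || object@maxAngleDev <= 0 ||
      object@pairCutoff <= 0)
    return("all criteria must be positive")
  if (object@maxHA >= object@maxDA)
    return("maxHA must be smaller than maxDA")
  TRUE
})

#' Detected hydrogen bonds
#'
#' @slot bonds data.frame with columns `donor`, `hydrogen`, `acceptor`
#'   (particle indices), `dDA`, `dHA` (Angstrom), `angleDev` (degrees).
#' @slot criteria the [HBondCriteria-class] used.
#' @slot classCounts named integer: bonds per acceptor/donor site class.
#' @exportClass HBondSet
setClass("HBondSet", representation(
  bonds = "data.frame", criteria = "HBondCriteria", classCounts = "integer"
))

#' Probe free-volume result
#'
#' @slot probeRadius probe sphere radius, Angstrom (0 = point probe).
#' @slot gridSpacing voxel grid spacing, Angstrom.
#' @slot ffv fractional free volume in percent of the box volume.
#' @slot freeVoxelCount number of free voxels.
#' @slot totalVoxelCount number of voxels in the grid.
#' @slot channelLabels integer vector, connected-component id per voxel
#'   (0 for occupied voxels), periodic 6-connectivity, column-major grid order.
#' @slot channelVolumes numeric, volume per channel in cubic Angstrom.
#' @slot gridDim integer(3) voxel counts per axis.
#' @exportClass FreeVolumeResult
setClass("FreeVolumeResult", representation(
  probeRadius = "numeric", gridSpacing = "numeric", ffv = "numeric",
  freeVoxelCount = "integer", totalVoxelCount = "integer",
  channelLabels = "integer", channelVolumes = "numeric", gridDim = "integer"
))

setValidity("FreeVolumeResult", function(object) {
  if (object@ffv < 0 || object@ffv > 100) return("ffv must be in [0, 100]")
  TRUE
})

#' Mean square displacement curve
#'
#' @slot lagTimes lag times in ps.
#' @slot msd mean square displacement in square Angstrom.
#' @slot nOrigins number of time origins averaged per lag.
#' @slot selection label of the particle selection analysed.
#' @exportClass MSDCurve
setClass("MSDCurve", representation(
  lagTimes = "numeric", msd = "numeric", nOrigins = "integer",
  selection = "character"
))

setValidity("MSDCurve", function(object) {
  if (length(object@msd) != length(object@lagTimes))
    return("msd and lagTimes must have equal length")
  if (any(object@msd < -1e-12)) return("msd must be non-negative")
  TRUE
})

#' Power-law fit of an MSD curve
#'
#' Parameters of the anomalous-diffusion law MSD(t) = K_alpha t^alpha,
#' obtained by least squares on the log-log scale.
#'
#' @slot alpha diffusive exponent (1 = normal diffusion).
#' @slot kAlpha generalized diffusion coefficient, Angstrom^2 / ps^alpha.
#' @slot window numeric(2) fit window in ps.
#' @slot rSquared coefficient of determination of the log-log fit.
#' @slot residualSD residual standard deviation on the log scale.
#' @exportClass PowerLawFit
setClass("PowerLawFit", representation(
  alpha = "numeric", kAlpha = "numeric", window = "numeric",
  rSquared = "numeric", residualSD = "numeric"
))

#' Einstein diffusion coefficient
#'
#' @slot d diffusion coefficient in cm^2/s.
#' @slot window numeric(2) fit window in ps.
#' @slot slopeSE standard error of the MSD slope, cm^2/s equivalent.
#' @slot nonlinearWarning TRUE if the window is outside the linear regime
#'   (local exponent outside 0.9-1.1).
#' @exportClass DiffusionResult
setClass("DiffusionResult", representation(
  d = "numeric", window = "numeric", slopeSE = "numeric",
  nonlinearWarning = "logical"
))

#' Van Hove self-correlation surfaces
#'
#' Radial distribution of single-particle displacement magnitudes per lag
#' time. `gs` is the probability density per unit volume, so that the shell
#' mass `4 pi r^2 gs dr` sums to one at each lag.
#'
#' @slot lagTimes lag times in ps.
#' @slot binCenters displacement bin centers in Angstrom.
#' @slot gs matrix `length(lagTimes) x length(binCenters)`, per-volume density.
#' @slot shellMass matrix of shell probabilities, rows summing to 1.
#' @slot dr bin width in Angstrom.
#' @exportClass VanHoveSelf
setClass("VanHoveSelf", representation(
  lagTimes = "numeric", binCenters = "numeric", gs = "matrix",
  shellMass = "matrix", dr = "numeric"
))

setValidity("VanHoveSelf", function(object) {
  if (any(object@gs < 0)) return("gs must be non-negative")
  if (nrow(object@gs) != length(object@lagTimes) ||
      ncol(object@gs) != length(object@binCenters))
    return("gs must be lag x bin")
  sums <- rowSums(object@shellMass)
  if (any(abs(sums - 1) > 1e-6))
    return("shell masses must sum to 1 per lag time")
  TRUE
})

#' Volume-temperature series
#'
#' @slot temperatures temperatures in K (any protocol order).
#' @slot volumes system volumes in cubic Angstrom.
#' @exportClass VTSeries
setClass("VTSeries", representation(
  temperatures = "numeric", volumes = "numeric"
))

setValidity("VTSeries", function(object) {
  if (length(object@temperatures) != length(object@volumes))
    return("temperatures and volumes must have equal length")
  if (length(object@temperatures) < 6L)
    return("need at least 6 points")
  if (anyDuplicated(object@temperatures))
    return("temperatures must be distinct")
  TRUE
})

#' Glass-transition (bilinear breakpoint) fit
#'
#' @slot tg breakpoint temperature in K.
#' @slot slopeBelow thermal expansion dV/dT below tg, cubic Angstrom per K.
#' @slot slopeAbove thermal expansion above tg.
#' @slot slopeBelowSE,slopeAboveSE standard errors of the slopes.
#' @slot sse residual sum of squares of the fit.
#' @slot tgSE bootstrap standard error of tg (NA when not requested).
#' @slot degenerate TRUE when the series is consistent with a single line.
#' @slot physical TRUE when slopeAbove >= slopeBelow (glass-forming order).
#' @exportClass TgFit
setClass("TgFit", representation(
  tg = "numeric", slopeBelow = "numeric", slopeAbove = "numeric",
  slopeBelowSE = "numeric", slopeAboveSE = "numeric",
  sse = "numeric", tgSE = "numeric", degenerate = "logical",
  physical = "logical"
))

#' Mer (repeat unit) specification
#'
#' @slot name short label, e.g. "HEMA".
#' @slot formula named numeric element counts, e.g. c(C = 6, H = 10, O = 3).
#' @slot molarMass g/mol, derived from the formula.
#' @exportClass MerSpec
setClass("MerSpec", representation(
  name = "character", formula = "numeric", molarMass = "numeric"
))

#' Polymer chain composition
#'
#' @slot sequence ordered character vector of mer labels along the chain.
#' @slot counts named integer mer counts, derived from the sequence.
#' @exportClass ChainComposition
setClass("ChainComposition", representation(
  sequence = "character", counts = "integer"
))

setValidity("ChainComposition", function(object) {
  if (!length(object@sequence) && !length(object@counts)) return(TRUE)
  tab <- table(object@sequence)
  cnt <- object@counts[order(names(object@counts))]
  tb <- as.integer(tab[order(names(tab))])
  if (length(cnt) != length(tab) || !all(cnt == tb) ||
      !identical(names(cnt), sort(names(tab))))
    return("counts inconsistent with sequence")
  TRUE
})

#' Hydration stoichiometry for one polymer cell
#'
#' @slot composition the polymer [ChainComposition-class].
#' @slot waterMassFraction target water mass fraction in [0, 1).
#' @slot nWater integer number of water molecules in the cell.
#' @slot density target density, g/cm^3.
#' @slot cellEdge cubic cell edge in Angstrom at the target density.
#' @exportClass HydrationSpec
setClass("HydrationSpec", representation(
  composition = "ChainComposition", waterMassFraction = "numeric",
  nWater = "integer", density = "numeric", cellEdge = "numeric"
))

setValidity("HydrationSpec", function(object) {
  if (object@nWater < 0L) return("nWater must be non-negative")
  if (object@cellEdge <= 0) return("cellEdge must be positive")
  if (object@waterMassFraction < 0 || object@waterMassFraction >= 1)
    return("waterMassFraction must lie in [0, 1)")
  TRUE
})
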