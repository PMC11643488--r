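#' Construct a Configuration
#'
#' @param positions n x 3 numeric matrix of coordinates in Angstrom.
#' @param boxEdge cubic box edge in Angstrom, or `NA` for a non-periodic
#'   configuration.
#' @param labels per-particle species/site tags; default taken from
#'   `elements`.
#' @param elements per-particle chemical elements; default `"C"`.
#' @param vdwRadius per-particle van der Waals radii in Angstrom; by default
#'   assigned from the element (C 1.70, H 1.20, O 1.52, N 1.55).
#' @param hbondRole per-particle hydrogen-bond role: `"none"`, `"donor"`,
#'   `"hydrogen"` or `"acceptor"`.
#' @return A [Configuration-class] object.
#' @examples
#' cfg <- configuration(matrix(runif(9, 0, 10), 3), boxEdge = 10,
#'                      elements = c("O", "H", "H"))
#' vdwRadius(cfg)
#' @export
configuration <- function(positions, boxEdge = NA_real_, labels = NULL,
                          elements = NULL, vdwRadius = NULL,
                          hbondRole = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  n <- nrow(positions)
  if (is.null(elements)) elements <- rep("C", n)
  if (is.null(labels)) labels <- elements
  if (is.null(vdwRadius)) vdwRadius <- defaultVdwRadius(elements)
  if (is.null(hbondRole)) hbondRole <- rep("none", n)
  new("Configuration", positions = positions, boxEdge = as.numeric(boxEdge),
      labels = as.character(labels), elements = as.character(elements),
      vdwRadius = as.numeric(vdwRadius), hbondRole = as.character(hbondRole))
}

#' Default van der Waals radius by element
#'
#' C 1.70, H 1.20, O 1.52 and N 1.55 Angstrom; other elements raise a
#' labeled error.
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
defaultVdwRadius <- function(elements) {
  r <- .VDW_RADII[elements]
  if (anyNA(r))
    .stop_labeled("unknown_element", "no default vdW radius for element(s): %s",
                  paste(unique(elements[is.na(r)]), collapse = ", "))
  unname(r)
}

#' @describeIn configuration particle count of a Configuration.
#' @param x a `Configuration`.
#' @export
nParticles <- function(x) {
  if (is(x, "Trajectory")) return(dim(x@coords)[2])
  nrow(x@positions)
}

#' Accessors for Configuration and Trajectory objects
#'
#' @param x a [Configuration-class] or [Trajectory-class].
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
positions <- function(x) x@positions

#' @rdname accessors
#' @export
boxEdge <- function(x) x@boxEdge

#' @rdname accessors
#' @export
particleLabels <- function(x) x@labels

#' @rdname accessors
#' @export
elements <- function(x) x@elements

#' @rdname accessors
#' @export
vdwRadius <- function(x) x@vdwRadius

#' @rdname accessors
#' @export
hbondRole <- function(x) x@hbondRole

setMethod("show", "Configuration", function(object) {
  cat(sprintf("Configuration: %d particles, box edge %s A\n",
              nrow(object@positions),
              if (is.na(object@boxEdge)) "none" else
                format(object@boxEdge, digits = 6)))
  tab <- table(object@labels)
  cat("  labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  roles <- table(object@hbondRole)
  if (length(roles) > 1L || names(roles)[1] != "none")
    cat("  h-bond roles:",
        paste(sprintf("%s (%d)", names(roles), roles), collapse = ", "), "\n")
})
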