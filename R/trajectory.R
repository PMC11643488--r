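#' Construct a Trajectory
#'
#' @param coords numeric array `n_frames x n_particles x 3` (Angstrom), or a
#'   list of `n x 3` matrices with constant particle count.
#' @param dt frame spacing in ps.
#' @param boxEdge cubic box edge in Angstrom (`NA` for non-periodic).
#' @param labels per-particle species tags.
#' @param elements per-particle elements.
#' @param wrapped logical; `TRUE` when coordinates are folded into the box.
#' @return A [Trajectory-class].
#' @export
trajectory <- function(coords, dt = 1, boxEdge = NA_real_, labels = NULL,
                       elements = NULL, wrapped = FALSE) {
  if (is.list(coords)) {
    ns <- vapply(coords, nrow, 1L)
    if (length(unique(ns)) != 1L)
      .stop_labeled("inconsistent_frames",
                    "frames have differing particle counts: %s",
                    paste(unique(ns), collapse = ", "))
    arr <- array(0, dim = c(length(coords), ns[1], 3L))
    for (i in seq_along(coords)) arr[i, , ] <- as.matrix(coords[[i]])
    coords <- arr
  }
  n <- dim(coords)[2]
  if (is.null(elements)) elements <- rep("C", n)
  if (is.null(labels)) labels <- elements
  new("Trajectory", coords = coords, dt = as.numeric(dt),
      boxEdge = as.numeric(boxEdge), labels = as.character(labels),
      elements = as.character(elements), wrapped = isTRUE(wrapped))
}

#' @rdname accessors
#' @export
nFrames <- function(x) dim(x@coords)[1]

#' @rdname accessors
#' @export
frameDt <- function(x) x@dt

#' @rdname accessors
#' @export
isWrapped <- function(x) x@wrapped

#' @rdname accessors
#' @export
coords <- function(x) x@coords

#' Extract one frame of a trajectory as a Configuration
#'
#' @param traj a [Trajectory-class].
#' @param i frame index (1-based).
#' @return A [Configuration-class] sharing the trajectory annotations.
#' @export
getFrame <- function(traj, i) {
  if (i < 1L || i > nFrames(traj))
    .stop_labeled("bad_frame", "frame %d outside 1..%d", i, nFrames(traj))
  pos <- traj@coords[i, , , drop = FALSE]
  dim(pos) <- dim(traj@coords)[2:3]
  configuration(pos, boxEdge = traj@boxEdge, labels = traj@labels,
                elements = traj@elements)
}

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf(
    "Trajectory: %d frames x %d particles, dt = %g ps, box edge %s A, %s\n",
    d[1], d[2], object@dt,
    if (is.na(object@boxEdge)) "none" else format(object@boxEdge, digits = 6),
    if (object@wrapped) "wrapped" else "unwrapped"))
})

#' Wrap a trajectory into its periodic box
#'
#' Folds all coordinates into `[0, boxEdge)`. Requires a periodic box.
#'
#' @param traj a [Trajectory-class] with a finite box edge.
#' @return A wrapped [Trajectory-class].
#' @seealso [unwrapTrajectory()]
#' @export
wrapTrajectory <- function(traj) {
  if (is.na(traj@boxEdge))
    .stop_labeled("missing_box", "cannot wrap without a box edge")
  out <- traj
  out@coords <- traj@coords %% traj@boxEdge
  out@wrapped <- TRUE
  out
}

#' Unwrap a periodic trajectory by minimum-image reconstruction
#'
#' Reconstructs continuous particle paths from wrapped coordinates by
#' accumulating minimum-image frame-to-frame displacements. Requires every
#' per-frame displacement to be resolvable, i.e. strictly smaller than half
#' the box edge; larger apparent jumps are ambiguous and raise a labeled
#' error. Already-unwrapped input is returned unchanged.
#'
#' @param traj a [Trajectory-class].
#' @param max_jump_fraction displacements at or above this fraction of the
#'   box edge are treated as unresolvable (default 0.5, the minimum-image
#'   limit).
#' @return An unwrapped [Trajectory-class]; re-wrapping recovers the input.
#' @export
unwrapTrajectory <- function(traj, max_jump_fraction = 0.5) {
  if (!traj@wrapped) return(traj)
  L <- traj@boxEdge
  if (is.na(L))
    .stop_labeled("missing_box", "cannot unwrap without a box edge")
  x <- traj@coords
  nf <- dim(x)[1]
  if (nf > 1L) {
    steps <- x[-1L, , , drop = FALSE] - x[-nf, , , drop = FALSE]
    steps <- steps - L * round(steps / L)
    if (max(abs(steps)) >= max_jump_fraction * L)
      .stop_labeled("ambiguous_unwrap",
                    "frame-to-frame displacement >= %.3g of the box edge; unwrap ambiguous",
                    max_jump_fraction)
    for (k in 1:3)
      x[, , k] <- rbind(x[1L, , k],
                        matrix(x[1L, , k], nf - 1L, dim(x)[2], byrow = TRUE) +
                          apply(steps[, , k, drop = FALSE], 2L, cumsum))
  }
  out <- traj
  out@coords <- x
  out@wrapped <- FALSE
  out
}
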