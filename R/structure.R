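# Static-structure analyses under the minimum-image convention:
# radial distribution functions, geometric hydrogen-bond detection,
# site classification, probe free volume and channel morphology.

#' Radial distribution function between two selections
#'
#' Histogram of minimum-image pair distances normalized by the ideal-gas
#' expectation `N_A * rho_B * 4 pi r^2 dr` per frame, averaged over frames.
#' Self-pairs are excluded when the selections overlap.
#'
#' @param frames a [Configuration-class], a list of them, or a
#'   [Trajectory-class] (all frames are used).
#' @param selection_a,selection_b particle selections: label character
#'   vectors, integer indices, logical masks, or `"all"`.
#' @param dr bin width, Angstrom.
#' @param r_max histogram range, Angstrom; must not exceed half the box
#'   edge (minimum-image validity).
#' @return An [RDFCurve-class].
#' @examples
#' cfg <- genPacking("poisson", 200, box = 15, seed = 1)
#' g <- rdf(cfg, "all", "all", dr = 0.25, r_max = 7)
#' @export
rdf <- function(frames, selection_a = "all", selection_b = "all",
                dr = 0.1, r_max = NULL) {
  if (is(frames, "Trajectory"))
    frames <- lapply(seq_len(nFrames(frames)), function(i) getFrame(frames, i))
  if (is(frames, "Configuration")) frames <- list(frames)
  box <- frames[[1]]@boxEdge
  if (is.na(box))
    .stop_labeled("missing_box", "RDF requires a periodic box")
  if (is.null(r_max)) r_max <- box / 2
  if (r_max > box / 2 + 1e-9)
    .stop_labeled("rmax_too_large",
                  "r_max = %.4g exceeds half the box edge %.4g", r_max, box / 2)
  breaks <- seq(0, r_max, by = dr)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  acc <- numeric(length(centers))
  norm <- 0
  lab_a <- lab_b <- NULL
  for (cfg in frames) {
    ia <- .match_selection(cfg@labels, selection_a)
    ib <- .match_selection(cfg@labels, selection_b)
    if (!length(ia) || !length(ib))
      .stop_labeled("empty_selection", "RDF selections must be non-empty")
    if (is.null(lab_a)) {
      lab_a <- if (is.character(selection_a)) paste(selection_a, collapse = "+") else "custom"
      lab_b <- if (is.character(selection_b)) paste(selection_b, collapse = "+") else "custom"
    }
    d2 <- .pair_dist2(cfg@positions[ia, , drop = FALSE],
                      cfg@positions[ib, , drop = FALSE], cfg@boxEdge)
    self <- outer(ia, ib, "==")
    d <- sqrt(d2[!self])
    d <- d[d < r_max]
    counts <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE),
                       nbins = length(centers))
    n_overlap <- sum(ia %in% ib)
    n_pairs <- length(ia) * length(ib) - n_overlap
    vol <- cfg@boxEdge^3
    shell <- 4 * pi * centers^2 * diff(breaks)
    acc <- acc + counts / (n_pairs / vol * shell)
    norm <- norm + 1
  }
  new("RDFCurve", binCenters = centers, g = acc / norm,
      pairLabels = c(lab_a, lab_b), dr = dr, nFrames = as.integer(norm))
}

setMethod("show", "RDFCurve", function(object) {
  cat(sprintf("RDFCurve %s-%s: %d bins (dr = %g A), %d frame(s)\n",
              object@pairLabels[1], object@pairLabels[2],
              length(object@g), object@dr, object@nFrames))
})

#' First peak position of an RDF curve
#'
#' Center of the first local maximum with `g >= min_height`; returns
#' `NA_real_` (a flagged "none" result, not an error) when no such peak
#' exists, e.g. for a flat ideal-gas curve.
#'
#' @param curve an [RDFCurve-class].
#' @param min_height minimum peak height (default 1.5, above the ideal-gas
#'   baseline of 1).
#' @return peak position in Angstrom, or `NA_real_`.
#' @export
firstPeak <- function(curve, min_height = 1.5) {
  g <- curve@g
  n <- length(g)
  if (n < 3L) return(NA_real_)
  for (i in 2:(n - 1L)) {
    if (g[i] >= min_height && g[i] >= g[i - 1L] && g[i] >= g[i + 1L] &&
        (g[i] > g[i - 1L] || g[i] > g[i + 1L]))
      return(curve@binCenters[i])
  }
  NA_real_
}

# Associate each hydrogen with its nearest donor within the pairing cutoff.
.pair_hydrogens <- function(cfg, cutoff) {
  hyd <- which(cfg@hbondRole == "hydrogen")
  don <- which(cfg@hbondRole == "donor")
  if (!length(hyd)) return(data.frame(hydrogen = integer(), donor = integer()))
  if (!length(don))
    .stop_labeled("unpaired_hydrogen", "hydrogens present but no donors")
  d2 <- .pair_dist2(cfg@positions[hyd, , drop = FALSE],
                    cfg@positions[don, , drop = FALSE], cfg@boxEdge)
  j <- apply(d2, 1L, which.min)
  dmin <- sqrt(d2[cbind(seq_along(hyd), j)])
  if (any(dmin > cutoff))
    .stop_labeled("unpaired_hydrogen",
                  "hydrogen(s) without a donor within %.3g A: %s", cutoff,
                  paste(hyd[dmin > cutoff], collapse = ", "))
  data.frame(hydrogen = hyd, donor = don[j])
}

#' Detect hydrogen bonds by geometric criteria
#'
#' A D-H...A triple is a hydrogen bond when, under minimum image, the
#' donor-acceptor distance is at most `maxDA` (inclusive), the
#' hydrogen-acceptor distance is strictly below `maxHA`, and the deviation
#' of the D-H...A angle from linearity (180 degrees) is at most
#' `maxAngleDev` (inclusive). Hydrogens are first associated with their
#' covalent donor (nearest donor within `criteria@pairCutoff`; a hydrogen
#' with no donor in range raises a labeled error).
#'
#' @param config a [Configuration-class] with `hbondRole` annotations.
#' @param criteria an [HBondCriteria-class] (defaults: 3.5 A, 2.5 A, 30
#'   degrees).
#' @return An [HBondSet-class]; `classCounts` tallies bonds per acceptor
#'   label class.
#' @examples
#' cfg <- genHbondFixture(data.frame(d_da = 2.9, d_ha = 1.9, angle_dev = 10))
#' nrow(hbonds(detectHbonds(cfg)))
#' @export
detectHbonds <- function(config, criteria = new("HBondCriteria")) {
  validObject(criteria)
  pairs <- .pair_hydrogens(config, criteria@pairCutoff)
  acc <- which(config@hbondRole == "acceptor")
  empty <- data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), dDA = numeric(), dHA = numeric(),
                      angleDev = numeric())
  if (!nrow(pairs) || !length(acc))
    return(new("HBondSet", bonds = empty, criteria = criteria,
               classCounts = integer(0)))
  pos <- config@positions
  box <- config@boxEdge
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    h <- pairs$hydrogen[i]; d <- pairs$donor[i]
    a_ok <- acc[acc != d]
    if (!length(a_ok)) next
    vHA <- .min_image(sweep(pos[a_ok, , drop = FALSE], 2L, pos[h, ]), box)
    dHA <- sqrt(rowSums(vHA^2))
    vDA <- .min_image(sweep(pos[a_ok, , drop = FALSE], 2L, pos[d, ]), box)
    dDA <- sqrt(rowSums(vDA^2))
    vHD <- .min_image(pos[d, ] - pos[h, ], box)
    nHD <- sqrt(sum(vHD^2))
    cosang <- (vHA %*% vHD) / (dHA * nHD)
    cosang <- pmin(1, pmax(-1, cosang))
    ang <- acos(cosang) * 180 / pi        # D-H...A angle at the hydrogen
    dev <- 180 - ang
    # boundary semantics: D...A and angle inclusive, H...A exclusive;
    # 1e-9 guards keep exact-threshold geometries on the intended side
    keep <- dDA <= criteria@maxDA + 1e-9 & dHA < criteria@maxHA - 1e-9 &
      dev <= criteria@maxAngleDev + 1e-9
    if (any(keep))
      rows[[i]] <- data.frame(donor = d, hydrogen = h, acceptor = a_ok[keep],
                              dDA = dDA[keep], dHA = dHA[keep],
                              angleDev = dev[keep])
  }
  bonds <- do.call(rbind, c(list(empty), rows))
  cls <- table(config@labels[bonds$acceptor])
  new("HBondSet", bonds = bonds, criteria = criteria,
      classCounts = stats::setNames(as.integer(cls), names(cls)))
}

#' @rdname detectHbonds
#' @param x an `HBondSet`.
#' @export
hbonds <- function(x) x@bonds

#' @rdname detectHbonds
#' @export
hbondClassCounts <- function(x) x@classCounts

setMethod("show", "HBondSet", function(object) {
  cat(sprintf("HBondSet: %d bond(s) (D...A <= %.2f A, H...A < %.2f A, dev <= %.0f deg)\n",
              nrow(object@bonds), object@criteria@maxDA,
              object@criteria@maxHA, object@criteria@maxAngleDev))
  if (length(object@classCounts))
    cat("  acceptor classes:",
        paste(sprintf("%s (%d)", names(object@classCounts),
                      object@classCounts), collapse = ", "), "\n")
})

#' Classify hydrogen-bonding sites by label tag
#'
#' Partitions particles into site classes (hydroxyl O, carbonyl O, ether O,
#' ring N, water O, water H, ...) from their label tags, for per-class
#' hydrogen-bond counting. Labels must come from the known tag set or be
#' declared via `extra_classes`; unknown tags raise a labeled error.
#'
#' @param config a [Configuration-class].
#' @param extra_classes optional named character vector mapping additional
#'   label tags to class names.
#' @return factor of length `nParticles(config)` with one class per
#'   particle.
#' @export
classifySites <- function(config, extra_classes = NULL) {
  map <- c(hydroxyl_O = "hydroxyl_O", carbonyl_O = "carbonyl_O",
           ether_O = "ether_O", ring_N = "ring_N", water_O = "water_O",
           water_H = "water_H", donor_O = "donor_O", donor_H = "donor_H",
           acceptor_O = "acceptor_O", backbone_C = "backbone_C")
  if (!is.null(extra_classes)) map <- c(map, extra_classes)
  cls <- map[config@labels]
  if (anyNA(cls))
    .stop_labeled("unknown_tag", "unknown site tag(s): %s",
                  paste(unique(config@labels[is.na(cls)]), collapse = ", "))
  factor(unname(cls), levels = unique(map))
}

# Periodic 6-connected components of free voxels; returns integer labels
# per voxel (0 = occupied) via frontier-based flood fill.
.label_channels <- function(free, dims) {
  n <- prod(dims)
  idx <- array(seq_len(n), dim = dims)
  shift <- function(a, k, by) {
    m <- dims[k]
    perm <- ((seq_len(m) - 1L + by) %% m) + 1L
    switch(k, a[perm, , , drop = FALSE], a[, perm, , drop = FALSE],
           a[, , perm, drop = FALSE])
  }
  nbrs <- cbind(as.vector(shift(idx, 1L, 1L)), as.vector(shift(idx, 1L, -1L)),
                as.vector(shift(idx, 2L, 1L)), as.vector(shift(idx, 2L, -1L)),
                as.vector(shift(idx, 3L, 1L)), as.vector(shift(idx, 3L, -1L)))
  labels <- integer(n)
  cur <- 0L
  todo <- which(free)
  seen <- !free
  for (start in todo) {
    if (seen[start]) next
    cur <- cur + 1L
    frontier <- start
    seen[start] <- TRUE
    labels[start] <- cur
    while (length(frontier)) {
      cand <- unique(as.vector(nbrs[frontier, , drop = FALSE]))
      cand <- cand[!seen[cand]]
      if (!length(cand)) break
      seen[cand] <- TRUE
      labels[cand] <- cur
      frontier <- cand
    }
  }
  labels
}

#' Probe free volume and diffusion channels
#'
#' Grid-probe estimate of the Connolly-style free volume: a voxel center is
#' free when it lies farther than `r_atom + probe_radius` from every atom
#' under minimum image. The fractional free volume (FFV) is the percentage
#' of free voxels; free voxels are grouped into channels by periodic
#' 6-connectivity.
#'
#' @param config a [Configuration-class] with a periodic box; an empty
#'   configuration gives FFV = 100.
#' @param probe_radius probe sphere radius in Angstrom (0 = point probe;
#'   1.4 approximates a water molecule).
#' @param grid_spacing voxel spacing in Angstrom; must be at most
#'   `probe_radius / 2`, or 0.5 A for a point probe (labeled error
#'   otherwise).
#' @return A [FreeVolumeResult-class].
#' @examples
#' cfg <- genPacking("poisson", 30, box = 12, seed = 2)
#' freeVolume(cfg, probe_radius = 1.4, grid_spacing = 0.5)@ffv
#' @export
freeVolume <- function(config, probe_radius = 1.4, grid_spacing = 0.25) {
  box <- config@boxEdge
  if (is.na(box))
    .stop_labeled("missing_box", "free volume requires a periodic box")
  max_sp <- if (probe_radius > 0) probe_radius / 2 else 0.5
  if (grid_spacing > max_sp + 1e-9)
    .stop_labeled("grid_too_coarse",
                  "grid_spacing %.3g too coarse (max %.3g A)", grid_spacing,
                  max_sp)
  m <- max(2L, as.integer(ceiling(box / grid_spacing)))
  h <- box / m
  centers1d <- (seq_len(m) - 0.5) * h
  n_vox <- m^3
  free <- rep(TRUE, n_vox)
  n_at <- nrow(config@positions)
  if (n_at > 0L) {
    for (i in seq_len(n_at)) {
      r_excl <- config@vdwRadius[i] + probe_radius
      dx <- .min_image(centers1d - config@positions[i, 1], box)
      dy <- .min_image(centers1d - config@positions[i, 2], box)
      dz <- .min_image(centers1d - config@positions[i, 3], box)
      d2i <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
      occupied <- d2i <= r_excl^2
      free[as.vector(occupied)] <- FALSE
    }
  }
  labels <- .label_channels(free, c(m, m, m))
  vols <- if (any(labels > 0L))
    as.numeric(tabulate(labels[labels > 0L])) * h^3 else numeric(0)
  new("FreeVolumeResult", probeRadius = as.numeric(probe_radius),
      gridSpacing = h, ffv = 100 * sum(free) / n_vox,
      freeVoxelCount = as.integer(sum(free)), totalVoxelCount = as.integer(n_vox),
      channelLabels = labels, channelVolumes = sort(vols, decreasing = TRUE),
      gridDim = rep(as.integer(m), 3L))
}

#' @rdname freeVolume
#' @param x a `FreeVolumeResult`.
#' @export
ffv <- function(x) x@ffv

#' @rdname freeVolume
#' @export
channelVolumes <- function(x) x@channelVolumes

setMethod("show", "FreeVolumeResult", function(object) {
  cat(sprintf(
    "FreeVolumeResult: probe %.2f A, grid %.3f A, FFV = %.2f%%, %d channel(s)\n",
    object@probeRadius, object@gridSpacing, object@ffv,
    length(object@channelVolumes)))
})

#' Remove a selection from a configuration
#'
#' Drops the selected particles while keeping the box unchanged, e.g. to
#' probe the water-accessible volume of a swollen polymer after removing
#' the water itself. Removing everything raises a labeled error; an empty
#' selection returns the input unchanged.
#'
#' @param config a [Configuration-class].
#' @param selection labels, indices or logical mask of particles to remove.
#' @return A [Configuration-class] without the selected particles.
#' @export
stripSelection <- function(config, selection) {
  drop_idx <- .match_selection(config@labels, selection)
  if (!length(drop_idx)) return(config)
  keep <- setdiff(seq_len(nrow(config@positions)), drop_idx)
  if (!length(keep))
    .stop_labeled("empty_remainder", "stripping would remove every particle")
  configuration(config@positions[keep, , drop = FALSE],
                boxEdge = config@boxEdge, labels = config@labels[keep],
                elements = config@elements[keep],
                vdwRadius = config@vdwRadius[keep],
                hbondRole = config@hbondRole[keep])
}
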