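# Time-dependent analyses: MSD, anomalous-exponent fitting, Einstein
# diffusion, van Hove self-correlation and hopping-mode detection.

# Resolve a lag grid (in frames) and origin indices for a trajectory.
.lag_frames <- function(traj, max_lag, lag_times = NULL,
                        points_per_decade = 20L) {
  nf <- nFrames(traj)
  if (!is.null(lag_times)) {
    lf <- as.integer(round(lag_times / traj@dt))
    if (any(lf < 1L) || any(lf > nf - 1L))
      .stop_labeled("invalid_lag", "lag times outside trajectory duration")
    return(sort(unique(lf)))
  }
  max_frames <- min(nf - 1L, as.integer(floor(max_lag / traj@dt)))
  if (max_frames < 1L)
    .stop_labeled("invalid_lag", "max_lag below one frame spacing")
  .log_lags(max_frames, points_per_decade)
}

# Squared displacements for one lag over sliding origins: returns the
# vector over (origins x particles).
.disp2_at_lag <- function(x, lag, origin_stride, cols) {
  nf <- dim(x)[1]
  origins <- seq(1L, nf - lag, by = origin_stride)
  d2 <- numeric(0)
  out <- vector("list", length(origins))
  for (oi in seq_along(origins)) {
    o <- origins[oi]
    d <- x[o + lag, cols, , drop = FALSE] - x[o, cols, , drop = FALSE]
    out[[oi]] <- rowSums(matrix(d, length(cols), 3L)^2)
  }
  list(d2 = unlist(out), n_origins = length(origins))
}

#' Mean square displacement over particles and time origins
#'
#' `MSD(t) = < |r_i(t0 + t) - r_i(t0)|^2 >` averaged over the selected
#' particles and sliding time origins. Requires an unwrapped trajectory;
#' wrapped input raises a labeled error. Lags are log-spaced by default
#' (~20 per decade of frames).
#'
#' @param traj an unwrapped [Trajectory-class].
#' @param selection particle selection (labels, indices, logical, or
#'   `"all"`).
#' @param max_lag maximum lag in ps (default: half the duration).
#' @param origin_stride frames between successive time origins (default 1,
#'   i.e. all overlapping origins).
#' @param lag_times explicit lag times in ps (overrides `max_lag`).
#' @param points_per_decade lag-grid density.
#' @return An [MSDCurve-class].
#' @examples
#' tr <- genBrownian(100, 500, diffusion = 1e-5, seed = 7)
#' m <- msd(tr, max_lag = 250)
#' @export
msd <- function(traj, selection = "all", max_lag = NULL, origin_stride = 1L,
                lag_times = NULL, points_per_decade = 20L) {
  if (traj@wrapped)
    .stop_labeled("wrapped_input", "MSD requires an unwrapped trajectory")
  cols <- .match_selection(traj@labels, selection)
  if (!length(cols)) .stop_labeled("empty_selection", "empty selection")
  if (is.null(max_lag)) max_lag <- (nFrames(traj) - 1L) * traj@dt / 2
  lags <- .lag_frames(traj, max_lag, lag_times, points_per_decade)
  msd_v <- numeric(length(lags))
  n_or <- integer(length(lags))
  for (li in seq_along(lags)) {
    r <- .disp2_at_lag(traj@coords, lags[li], origin_stride, cols)
    msd_v[li] <- mean(r$d2)
    n_or[li] <- r$n_origins
  }
  sel_label <- if (is.character(selection)) paste(selection, collapse = "+") else "custom"
  new("MSDCurve", lagTimes = lags * traj@dt, msd = msd_v, nOrigins = n_or,
      selection = sel_label)
}

setMethod("show", "MSDCurve", function(object) {
  cat(sprintf("MSDCurve [%s]: %d lags, %g..%g ps, MSD up to %.4g A^2\n",
              object@selection, length(object@lagTimes),
              min(object@lagTimes), max(object@lagTimes), max(object@msd)))
})

# Default window: one decade centered (log scale) inside the lag support.
.default_window <- function(lag_times) {
  lt <- range(lag_times[lag_times > 0])
  mid <- sqrt(lt[1] * lt[2])
  c(mid / sqrt(10), mid * sqrt(10))
}

#' Fit the anomalous-diffusion power law to an MSD curve
#'
#' Least squares of `log MSD` on `log t` inside an explicit window:
#' `MSD(t) = K_alpha t^alpha` with `alpha` the slope and `K_alpha` the
#' exponential of the intercept. The default window is one decade centered
#' (in log time) within the curve's support.
#'
#' @param curve an [MSDCurve-class].
#' @param window numeric(2) fit window `(t_min, t_max)` in ps.
#' @param min_points minimum lag points required in the window (default 5).
#' @return A [PowerLawFit-class].
#' @examples
#' curve <- new("MSDCurve", lagTimes = 1:100, msd = 2.5 * (1:100)^0.7,
#'              nOrigins = rep(1L, 100), selection = "exact")
#' fitPowerLaw(curve, window = c(1, 100))@alpha
#' @export
fitPowerLaw <- function(curve, window = NULL, min_points = 5L) {
  if (is.null(window)) window <- .default_window(curve@lagTimes)
  sel <- curve@lagTimes >= window[1] & curve@lagTimes <= window[2]
  if (sum(sel) < min_points)
    .stop_labeled("window_too_narrow",
                  "only %d lag points in window, need >= %d", sum(sel),
                  min_points)
  if (any(curve@msd[sel] <= 0))
    .stop_labeled("nonpositive_msd",
                  "non-positive MSD values in the fit window")
  lx <- log(curve@lagTimes[sel])
  ly <- log(curve@msd[sel])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  res <- fit$residuals
  alpha <- unname(fit$coefficients[2])
  r2 <- if (stats::var(ly) > 0) 1 - sum(res^2) / sum((ly - mean(ly))^2) else 1
  new("PowerLawFit", alpha = alpha,
      kAlpha = exp(unname(fit$coefficients[1])),
      window = as.numeric(window), rSquared = r2,
      residualSD = if (length(res) > 2L) stats::sd(res) else 0)
}

#' @rdname fitPowerLaw
#' @param x a `PowerLawFit`.
#' @export
alphaExponent <- function(x) x@alpha

#' @rdname fitPowerLaw
#' @export
kAlpha <- function(x) x@kAlpha

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf(
    "PowerLawFit: alpha = %.3f, K_alpha = %.4g A^2/ps^alpha, window %.3g..%.3g ps (R^2 = %.4f)\n",
    object@alpha, object@kAlpha, object@window[1], object@window[2],
    object@rSquared))
})

#' Einstein diffusion coefficient from an MSD curve
#'
#' `D = slope / 6` of the particle-averaged MSD versus lag time, fitted by
#' least squares inside the window and converted to cm^2/s. When the local
#' power-law exponent in the window falls outside 0.9-1.1 the window is
#' not in the linear regime and the result carries a warning flag.
#'
#' @param curve an [MSDCurve-class] (MSD in A^2, lags in ps).
#' @param window numeric(2) fit window in ps (default: upper half decade of
#'   the available lags).
#' @return A [DiffusionResult-class] with `d` in cm^2/s.
#' @export
diffusionCoefficient <- function(curve, window = NULL) {
  if (is.null(window)) {
    tmax <- max(curve@lagTimes)
    window <- c(tmax / sqrt(10), tmax)
  }
  sel <- curve@lagTimes >= window[1] & curve@lagTimes <= window[2]
  if (sum(sel) < 2L)
    .stop_labeled("window_too_narrow", "need >= 2 lag points in window")
  t <- curve@lagTimes[sel]
  y <- curve@msd[sel]
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2])
  if (slope < 0)
    .stop_labeled("negative_slope", "negative MSD slope in window")
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[2, 2]),
                 error = function(e) NA_real_)
  warn <- FALSE
  if (sum(sel) >= 5L && all(y > 0)) {
    a <- fitPowerLaw(curve, window, min_points = 5L)@alpha
    warn <- a < 0.9 || a > 1.1
  }
  new("DiffusionResult", d = slope / 6 * .A2PS_TO_CM2S,
      window = as.numeric(window), slopeSE = se / 6 * .A2PS_TO_CM2S,
      nonlinearWarning = warn)
}

#' @rdname diffusionCoefficient
#' @param x a `DiffusionResult`.
#' @export
diffusion <- function(x) x@d

setMethod("show", "DiffusionResult", function(object) {
  cat(sprintf("DiffusionResult: D = %.4g cm^2/s, window %.3g..%.3g ps%s\n",
              object@d, object@window[1], object@window[2],
              if (object@nonlinearWarning) " [non-linear regime warning]" else ""))
})

#' Van Hove self-correlation function
#'
#' Radial histogram of displacement magnitudes `|r_i(t0 + t) - r_i(t0)|`
#' over particles and sliding origins, per lag time. `gs` is normalized as
#' a probability density per unit volume so that the shell mass
#' `4 pi r^2 gs dr` sums to one at each lag; its second moment equals the
#' MSD at the same lag.
#'
#' @param traj an unwrapped [Trajectory-class].
#' @param selection particle selection.
#' @param lag_times lag times in ps.
#' @param dr radial bin width, Angstrom.
#' @param r_max histogram range, Angstrom; displacements beyond `r_max`
#'   raise a labeled error so no probability mass is silently lost.
#' @param origin_stride frames between time origins.
#' @return A [VanHoveSelf-class].
#' @export
vanHoveSelf <- function(traj, selection = "all", lag_times, dr = 0.1,
                        r_max = NULL, origin_stride = 1L) {
  if (traj@wrapped)
    .stop_labeled("wrapped_input", "van Hove requires an unwrapped trajectory")
  cols <- .match_selection(traj@labels, selection)
  if (!length(cols)) .stop_labeled("empty_selection", "empty selection")
  lags <- .lag_frames(traj, max_lag = NULL, lag_times = lag_times)
  if (is.null(r_max)) {
    r <- .disp2_at_lag(traj@coords, max(lags), origin_stride, cols)
    r_max <- max(sqrt(max(r$d2)) * 1.05, dr * 10)
  }
  breaks <- seq(0, r_max, by = dr)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nb <- length(centers)
  gs <- mass <- matrix(0, length(lags), nb)
  for (li in seq_along(lags)) {
    r <- .disp2_at_lag(traj@coords, lags[li], origin_stride, cols)
    d <- sqrt(r$d2)
    if (any(d >= r_max))
      .stop_labeled("rmax_exceeded",
                    "displacements up to %.3g A exceed r_max = %.3g", max(d),
                    r_max)
    counts <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE),
                       nbins = nb)
    p <- counts / sum(counts)
    mass[li, ] <- p
    gs[li, ] <- p / (4 * pi * centers^2 * diff(breaks))
  }
  new("VanHoveSelf", lagTimes = lags * traj@dt, binCenters = centers,
      gs = gs, shellMass = mass, dr = dr)
}

#' @rdname vanHoveSelf
#' @param x a `VanHoveSelf`.
#' @export
shellMass <- function(x) x@shellMass

#' Second moment of the van Hove self-part per lag
#'
#' `integral r^2 Gs(r, t) dr` evaluated on the binned distribution; equals
#' the MSD at each lag up to binning resolution.
#'
#' @param x a [VanHoveSelf-class].
#' @return numeric vector, one value per lag time (square Angstrom).
#' @export
vanHoveSecondMoment <- function(x) {
  as.numeric(x@shellMass %*% x@binCenters^2)
}

setMethod("show", "VanHoveSelf", function(object) {
  cat(sprintf("VanHoveSelf: %d lag(s) (%s ps), %d bins of %.3g A\n",
              length(object@lagTimes),
              paste(format(object@lagTimes, digits = 4), collapse = ", "),
              length(object@binCenters), object@dr))
})

#' Detect displacement modes (hopping signature) in a van Hove surface
#'
#' Finds local maxima of the smoothed shell mass `4 pi r^2 Gs dr` at one
#' lag time, keeping peaks whose prominence (height above the deeper of
#' the two flanking valleys) is at least `min_prominence` times the global
#' maximum. One mode is ordinary cage/diffusive motion; a second mode at
#' the jump length is the hopping signature. An empty result is a value,
#' not an error.
#'
#' @param vh a [VanHoveSelf-class].
#' @param lag lag time in ps; must be one of `vh@lagTimes`.
#' @param smooth_width moving-average width in bins (odd; default 3).
#' @param min_prominence relative prominence threshold (default 0.05).
#' @return numeric vector of mode radii (Angstrom), ordered by r.
#' @export
detectModes <- function(vh, lag, smooth_width = 3L, min_prominence = 0.05) {
  li <- which(abs(vh@lagTimes - lag) < 1e-9)
  if (!length(li))
    .stop_labeled("unknown_lag", "lag %.4g ps not present", lag)
  y <- vh@shellMass[li[1], ]
  if (smooth_width > 1L) {
    k <- rep(1 / smooth_width, smooth_width)
    y <- stats::filter(y, k, sides = 2)
    y[is.na(y)] <- vh@shellMass[li[1], ][is.na(y)]
    y <- as.numeric(y)
  }
  n <- length(y)
  peaks <- which(diff(sign(diff(c(-Inf, y, -Inf)))) == -2)
  if (!length(peaks)) return(numeric(0))
  ymax <- max(y)
  keep <- logical(length(peaks))
  for (pi in seq_along(peaks)) {
    p <- peaks[pi]
    # topographic prominence: drop to the key saddle toward the nearest
    # strictly higher point on each side (global max keeps full height)
    higher_l <- which(y[seq_len(p - 1L)] > y[p])
    left_saddle <- if (length(higher_l)) min(y[max(higher_l):(p - 1L)]) else -Inf
    higher_r <- if (p < n) p + which(y[(p + 1L):n] > y[p]) else integer(0)
    right_saddle <- if (length(higher_r)) min(y[(p + 1L):min(higher_r)]) else -Inf
    saddle <- max(left_saddle, right_saddle)
    prom <- if (is.finite(saddle)) y[p] - saddle else y[p]
    keep[pi] <- prom >= min_prominence * ymax
  }
  sort(vh@binCenters[peaks[keep]])
}
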