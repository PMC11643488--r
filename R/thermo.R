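# Glass-transition estimation: continuous bilinear (hinge) fit of a
# volume-temperature series; Tg is the segment intersection.

#' Construct a volume-temperature series
#'
#' @param temperatures temperatures in K (any order; the cooling protocol's
#'   descending order is fine).
#' @param volumes system volumes in cubic Angstrom.
#' @return A [VTSeries-class].
#' @export
vtSeries <- function(temperatures, volumes) {
  new("VTSeries", temperatures = as.numeric(temperatures),
      volumes = as.numeric(volumes))
}

setMethod("show", "VTSeries", function(object) {
  cat(sprintf("VTSeries: %d points, %g..%g K\n", length(object@temperatures),
              min(object@temperatures), max(object@temperatures)))
})

# SSE of the continuous hinge fit with the breakpoint at tb; returns the
# fit pieces too.
.hinge_fit <- function(temp, vol, tb) {
  x1 <- temp - tb
  x2 <- pmax(temp - tb, 0)
  X <- cbind(1, x1, x2)
  fit <- stats::lm.fit(X, vol)
  co <- fit$coefficients
  list(sse = sum(fit$residuals^2), v_break = unname(co[1]),
       slope_below = unname(co[2]), slope_above = unname(co[2] + co[3]),
       residuals = fit$residuals)
}

#' Fit a continuous bilinear model to locate the glass transition
#'
#' Fits `V(T)` as two straight lines constrained to intersect at a
#' breakpoint `Tg`, where the thermal expansion `(dV/dT)_P` changes. The
#' breakpoint is found by grid search over the interior data temperatures
#' (excluding `edge_margin` points at each end) refined by golden-section
#' minimization of the SSE between the neighbouring grid points. A series
#' indistinguishable from a single line is flagged `degenerate` (tg
#' unreliable); `physical` is `FALSE` when the high-temperature slope is
#' smaller than the low-temperature one.
#'
#' @param series a [VTSeries-class] (at least 6 points).
#' @param edge_margin number of points excluded at each temperature edge
#'   from the breakpoint grid (default 3, so each segment keeps >= 3
#'   points).
#' @param n_boot residual-bootstrap replicates for the breakpoint standard
#'   error (default 0 = skip; the point estimate is unaffected).
#' @param degeneracy_tol flag the fit degenerate when the bilinear SSE
#'   improves on the single-line SSE by less than this relative amount
#'   (default 0.05), or when the slopes are equal to within 1e-8.
#' @param seed RNG seed for the bootstrap.
#' @return A [TgFit-class].
#' @examples
#' s <- genBilinearVT(t_break = 425, noise_sd = 0)
#' fitBilinear(s)@tg
#' @export
fitBilinear <- function(series, edge_margin = 3L, n_boot = 0L,
                        degeneracy_tol = 0.05, seed = NULL) {
  ord <- order(series@temperatures)
  temp <- series@temperatures[ord]
  vol <- series@volumes[ord]
  n <- length(temp)
  if (n - 2L * edge_margin < 2L)
    .stop_labeled("too_few_points", "too few interior points for the grid")
  grid <- temp[(edge_margin + 1L):(n - edge_margin)]
  sses <- vapply(grid, function(tb) .hinge_fit(temp, vol, tb)$sse, 0)
  best <- which.min(sses)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  tb <- if (hi > lo) {
    stats::optimize(function(b) .hinge_fit(temp, vol, b)$sse,
                    interval = c(lo, hi))$minimum
  } else grid[best]
  # exact-on-noiseless polish: if the grid optimum itself is lower, keep it
  if (.hinge_fit(temp, vol, grid[best])$sse < .hinge_fit(temp, vol, tb)$sse)
    tb <- grid[best]
  h <- .hinge_fit(temp, vol, tb)
  line <- stats::lm.fit(cbind(1, temp), vol)
  sse_line <- sum(line$residuals^2)
  degenerate <- abs(h$slope_above - h$slope_below) < 1e-8 ||
    (sse_line > 0 && (sse_line - h$sse) / sse_line < degeneracy_tol) ||
    (sse_line <= .Machine$double.eps * sum(vol^2))
  # slope standard errors from the unconstrained per-segment residuals
  seg_se <- function(idx) {
    if (length(idx) < 3L) return(NA_real_)
    f <- stats::lm(vol[idx] ~ temp[idx])
    tryCatch(suppressWarnings(summary(f)$coefficients[2, 2]),
             error = function(e) NA_real_)
  }
  below <- which(temp <= tb)
  above <- which(temp >= tb)
  tg_se <- NA_real_
  if (n_boot > 0L) {
    fitted <- vol - h$residuals
    tg_se <- .with_seed(seed, {
      reps <- replicate(n_boot, {
        vb <- fitted + sample(h$residuals, n, replace = TRUE)
        s2 <- vapply(grid, function(b) .hinge_fit(temp, vb, b)$sse, 0)
        grid[which.min(s2)]
      })
      stats::sd(reps)
    })
  }
  new("TgFit", tg = tb, slopeBelow = h$slope_below,
      slopeAbove = h$slope_above, slopeBelowSE = seg_se(below),
      slopeAboveSE = seg_se(above), sse = h$sse, tgSE = tg_se,
      degenerate = degenerate,
      physical = h$slope_above >= h$slope_below - 1e-12)
}

#' @rdname fitBilinear
#' @param x a `TgFit`.
#' @export
tg <- function(x) x@tg

#' Thermal expansion slopes below and above the glass transition
#'
#' Returns the fitted `(dV/dT)_P` of the two segments with standard
#' errors; a `physical` flag of `FALSE` marks fits where the
#' high-temperature slope does not exceed the low-temperature one.
#'
#' @param series a [VTSeries-class] (used only for the standard errors; may
#'   be omitted).
#' @param fit a [TgFit-class] from [fitBilinear()].
#' @return data.frame with rows `below`/`above` and columns `slope`, `se`,
#'   plus attribute `"physical"`.
#' @export
thermalExpansion <- function(series = NULL, fit) {
  out <- data.frame(segment = c("below", "above"),
                    slope = c(fit@slopeBelow, fit@slopeAbove),
                    se = c(fit@slopeBelowSE, fit@slopeAboveSE))
  attr(out, "physical") <- fit@physical
  out
}

setMethod("show", "TgFit", function(object) {
  cat(sprintf(
    "TgFit: Tg = %.2f K%s, dV/dT = %.4g (below) / %.4g (above) A^3/K%s%s\n",
    object@tg,
    if (!is.na(object@tgSE)) sprintf(" +/- %.2f", object@tgSE) else "",
    object@slopeBelow, object@slopeAbove,
    if (object@degenerate) " [degenerate: single line]" else "",
    if (!object@physical) " [unphysical slope order]" else ""))
})
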