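# Internal helpers: units, seeding, periodic geometry, lag grids.

# 1 A^2/ps = 1e-4 cm^2/s
.A2PS_TO_CM2S <- 1e-4
.CM2S_TO_A2PS <- 1e4

.stop_labeled <- function(label, fmt, ...) {
  stop(structure(
    class = c(label, "gelkinetics_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# Evaluate expr with a fixed RNG seed without disturbing the caller's stream.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Minimum-image separation components for a cubic box (vectorized).
.min_image <- function(delta, box) {
  if (is.na(box)) return(delta)
  delta - box * round(delta / box)
}

# Squared minimum-image distances between rows of a (n x 3) and b (m x 3).
.pair_dist2 <- function(a, b, box) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  if (!is.na(box)) {
    dx <- dx - box * round(dx / box)
    dy <- dy - box * round(dy / box)
    dz <- dz - box * round(dz / box)
  }
  dx * dx + dy * dy + dz * dz
}

# Log-spaced integer frame lags, ~points_per_decade per decade, unique.
.log_lags <- function(max_lag_frames, points_per_decade = 20L) {
  if (max_lag_frames < 1L) .stop_labeled("invalid_lag", "max lag below one frame")
  n_dec <- log10(max_lag_frames)
  raw <- 10^seq(0, n_dec, length.out = max(2L, ceiling(n_dec * points_per_decade) + 1L))
  sort(unique(pmin(max_lag_frames, pmax(1L, as.integer(round(raw))))))
}

.match_selection <- function(labels, selection) {
  if (is.null(selection) || identical(selection, "all")) return(seq_along(labels))
  if (is.logical(selection)) return(which(selection))
  if (is.numeric(selection)) return(as.integer(selection))
  which(labels %in% selection)
}
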