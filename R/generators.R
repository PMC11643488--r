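# Stochastic trajectory and configuration generators with known ground
# truth. Internal units: Angstrom and ps; diffusion inputs in cm^2/s
# (1 A^2/ps = 1e-4 cm^2/s). Every generator is deterministic under a
# fixed seed and leaves the caller's RNG stream untouched.

#' Free Brownian walkers
#'
#' Independent 3-D random walks with i.i.d. Gaussian increments of
#' per-axis variance `2 D dt`, the alpha = 1 reference process of the
#' anomalous-diffusion law MSD(t) = K_alpha t^alpha.
#'
#' @param n_particles number of walkers.
#' @param n_steps number of steps (frames = `n_steps + 1`, starting at the
#'   origin).
#' @param dt frame spacing in ps.
#' @param diffusion diffusion coefficient in cm^2/s (must be >= 0; 0 gives
#'   static particles).
#' @param seed integer RNG seed, or `NULL` to use the current stream.
#' @return An unwrapped [Trajectory-class].
#' @examples
#' tr <- genBrownian(50, 200, diffusion = 1e-5, seed = 1)
#' @export
genBrownian <- function(n_particles = 500L, n_steps = 2000L, dt = 1,
                        diffusion = 1.5e-5, seed = NULL) {
  if (diffusion < 0)
    .stop_labeled("bad_diffusion", "diffusion must be non-negative")
  d_int <- diffusion * .CM2S_TO_A2PS
  sd_step <- sqrt(2 * d_int * dt)
  .with_seed(seed, {
    arr <- array(0, dim = c(n_steps + 1L, n_particles, 3L))
    for (k in 1:3) {
      inc <- matrix(stats::rnorm(n_steps * n_particles, sd = sd_step),
                    n_steps, n_particles)
      arr[, , k] <- rbind(0, apply(inc, 2L, cumsum))
    }
    trajectory(arr, dt = dt, labels = rep("W", n_particles),
               elements = rep("O", n_particles), wrapped = FALSE)
  })
}

# Exact fractional Gaussian noise by circulant embedding (Davies-Harte).
# Returns an n x n_paths matrix of increments with unit variance per step.
.fgn_circulant <- function(n, n_paths, hurst) {
  k <- 0:n
  gamma <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                    abs(k - 1)^(2 * hurst))
  m <- 2L * n
  circ <- c(gamma, gamma[n:2])  # gamma(0..n), gamma(n-1..1)
  lam <- Re(stats::fft(circ))
  lam[lam < 0 & lam > -1e-8] <- 0
  if (any(lam < 0))
    .stop_labeled("embedding_failure",
                  "circulant embedding produced negative eigenvalues")
  half <- m / 2L
  # Hermitian-symmetric complex Gaussian spectrum, batched over columns.
  U <- matrix(stats::rnorm(m * n_paths), m, n_paths)
  Y <- matrix(0i, m, n_paths)
  Y[1L, ] <- sqrt(lam[1L]) * U[1L, ]
  Y[half + 1L, ] <- sqrt(lam[half + 1L]) * U[half + 1L, ]
  j <- 2:half
  re <- U[j, , drop = FALSE]
  im <- U[m + 2L - j, , drop = FALSE]
  Y[j, ] <- sqrt(lam[j] / 2) * (re + 1i * im)
  Y[m + 2L - j, ] <- Conj(Y[j, ])
  X <- Re(stats::mvfft(Y)) / sqrt(m)
  X[seq_len(n), , drop = FALSE]
}

#' Fractional Brownian motion walkers
#'
#' Each coordinate axis is an independent fractional Brownian path built
#' from exact-covariance fractional Gaussian noise (circulant embedding),
#' so the ensemble MSD grows as `t^(2 H)`: the ground-truth diffusive
#' exponent is `alpha = 2 * hurst`.
#'
#' @inheritParams genBrownian
#' @param hurst Hurst exponent, strictly inside (0, 1).
#' @param step_sd per-axis increment standard deviation at lag one frame,
#'   Angstrom (default 1).
#' @return An unwrapped [Trajectory-class].
#' @export
genFbm <- function(n_particles = 500L, n_steps = 2000L, dt = 1, hurst,
                   step_sd = 1, seed = NULL) {
  if (hurst <= 0 || hurst >= 1)
    .stop_labeled("bad_hurst", "hurst must lie strictly inside (0, 1)")
  .with_seed(seed, {
    arr <- array(0, dim = c(n_steps + 1L, n_particles, 3L))
    for (k in 1:3) {
      inc <- step_sd * .fgn_circulant(n_steps, n_particles, hurst)
      arr[, , k] <- rbind(0, apply(inc, 2L, cumsum))
    }
    trajectory(arr, dt = dt, labels = rep("W", n_particles),
               elements = rep("O", n_particles), wrapped = FALSE)
  })
}

#' Continuous-time random walk (heavy-tailed waiting times)
#'
#' Renewal process with Pareto waiting times `w = dt * U^(-1/mu)` (tail
#' exponent `mu` in (0, 1)) and Gaussian jump displacements; the ensemble
#' MSD grows as `t^mu` at long times. `mu >= 1` (normal diffusion) is
#' outside this generator's contract and raises a labeled error.
#'
#' @inheritParams genBrownian
#' @param waiting_exponent Pareto tail exponent `mu`, strictly in (0, 1).
#' @param jump_length per-axis jump standard deviation in Angstrom.
#' @return An unwrapped [Trajectory-class].
#' @export
genCtrw <- function(n_particles = 500L, n_steps = 2000L, dt = 1,
                    waiting_exponent, jump_length = 1, seed = NULL) {
  mu <- waiting_exponent
  if (mu <= 0 || mu >= 1)
    .stop_labeled("bad_exponent",
                  "waiting_exponent must lie strictly inside (0, 1)")
  total <- n_steps * dt
  .with_seed(seed, {
    arr <- array(0, dim = c(n_steps + 1L, n_particles, 3L))
    frame_times <- (0:n_steps) * dt
    for (p in seq_len(n_particles)) {
      tsum <- 0; waits <- numeric()
      while (tsum < total) {
        w <- dt * stats::runif(256L)^(-1 / mu)
        waits <- c(waits, w)
        tsum <- tsum + sum(w)
      }
      ev <- cumsum(waits)
      ev <- ev[ev <= total]
      n_ev <- length(ev)
      k_f <- findInterval(frame_times, ev)
      if (n_ev > 0L) {
        jumps <- matrix(stats::rnorm(3L * n_ev, sd = jump_length), n_ev, 3L)
        walk <- rbind(0, apply(jumps, 2L, cumsum))
        if (n_ev == 1L) walk <- rbind(0, matrix(jumps, 1L, 3L))
        arr[, p, ] <- walk[k_f + 1L, ]
      }
    }
    trajectory(arr, dt = dt, labels = rep("W", n_particles),
               elements = rep("O", n_particles), wrapped = FALSE)
  })
}

#' Cage-hopping walkers
#'
#' Position = cage center + mean-reverting (AR(1) / discretized
#' Ornstein-Uhlenbeck) in-cage fluctuation of stationary scale
#' `cage_sigma`; the cage center performs jumps of fixed length
#' `jump_length` in uniformly random directions at Poisson times with rate
#' `hop_rate`. The displacement distribution at lags near `1/hop_rate` is
#' bimodal (cage mode + one-hop mode at `jump_length`), the signature of
#' hopping in the van Hove self-correlation function; the long-time MSD
#' slope gives jump diffusion `D = hop_rate * jump_length^2 / 6`.
#'
#' @inheritParams genBrownian
#' @param cage_sigma in-cage fluctuation scale, Angstrom.
#' @param jump_length hop distance, Angstrom.
#' @param hop_rate cage-escape rate, 1/ps; `hop_rate * dt > 0.5` is too
#'   coarse to resolve and raises a labeled error.
#' @param cage_tau in-cage relaxation time, ps (default 1).
#' @return An unwrapped [Trajectory-class].
#' @export
genCageHopper <- function(n_particles = 500L, n_steps = 2000L, dt = 1,
                          cage_sigma = 0.3, jump_length = 3, hop_rate = 0.01,
                          cage_tau = 1, seed = NULL) {
  if (cage_sigma < 0 || jump_length <= 0 || hop_rate < 0 || cage_tau <= 0)
    .stop_labeled("bad_params", "lengths, rates and times must be positive")
  if (hop_rate * dt > 0.5)
    .stop_labeled("coarse_resolution",
                  "hop_rate * dt = %.3g > 0.5: frame spacing too coarse",
                  hop_rate * dt)
  rho <- exp(-dt / cage_tau)
  innov_sd <- cage_sigma * sqrt(1 - rho^2)
  nf <- n_steps + 1L
  .with_seed(seed, {
    # cage-center hop displacements per (frame, particle)
    centers <- array(0, dim = c(nf, n_particles, 3L))
    counts <- matrix(stats::rpois(n_steps * n_particles, hop_rate * dt),
                     n_steps, n_particles)
    idx <- which(counts > 0L)
    if (length(idx)) {
      reps <- counts[idx]
      dirs <- matrix(stats::rnorm(3L * sum(reps)), ncol = 3L)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      g <- rep(seq_along(idx), reps)
      disp <- rowsum(dirs, g) * jump_length
      step_disp <- matrix(0, n_steps * n_particles, 3L)
      step_disp[idx, ] <- disp
      dim(step_disp) <- c(n_steps, n_particles, 3L)
      for (k in 1:3)
        centers[-1L, , k] <- apply(step_disp[, , k, drop = FALSE], 2L, cumsum)
    }
    # AR(1) in-cage fluctuation, stationary start
    fluct <- array(stats::rnorm(nf * n_particles * 3L),
                   dim = c(nf, n_particles, 3L))
    fluct[1L, , ] <- fluct[1L, , ] * cage_sigma
    for (f in 2:nf)
      fluct[f, , ] <- rho * fluct[f - 1L, , ] + innov_sd * fluct[f, , ]
    trajectory(centers + fluct, dt = dt, labels = rep("W", n_particles),
               elements = rep("O", n_particles), wrapped = FALSE)
  })
}

#' Ideal Rouse chains (overdamped bead-spring dynamics)
#'
#' Integrates `n_chains` phantom harmonic bead-spring chains without
#' excluded volume by Euler-Maruyama overdamped Langevin dynamics:
#' `dx_i = (k/zeta) (x_{i+1} - 2 x_i + x_{i-1}) dt + sqrt(2 kT dt / zeta) xi`
#' with free ends. Between the bond relaxation time (~ `zeta/(4 k)`) and the
#' Rouse time (`zeta n_beads^2 / (3 pi^2 k)`) the MSD of a middle bead grows
#' as `t^0.5`; a single bead (`n_beads = 1`) is a free Brownian particle.
#' All quantities are in reduced units (`kT = 1` by default); the trajectory
#' `dt` is `dt * record_stride`.
#'
#' @param n_beads beads per chain.
#' @param n_chains number of independent chains.
#' @param spring_constant harmonic spring constant, reduced units.
#' @param friction bead friction coefficient, reduced units.
#' @param dt integration step, reduced time; requires
#'   `dt * spring_constant / friction < 0.25` for stability.
#' @param n_steps number of integration steps.
#' @param record_stride record every this many steps.
#' @param record_beads integer bead indices to record (default all); labels
#'   are `"bead<i>"` so a single bead can be selected across chains.
#' @param kT thermal energy, reduced units.
#' @param seed integer RNG seed.
#' @return An unwrapped [Trajectory-class] with
#'   `n_chains * length(record_beads)` particles.
#' @export
genRouse <- function(n_beads = 64L, n_chains = 50L, spring_constant = 1,
                     friction = 1, dt = 0.05, n_steps = 2000L,
                     record_stride = 1L, record_beads = NULL, kT = 1,
                     seed = NULL) {
  if (dt * spring_constant / friction >= 0.25)
    .stop_labeled("unstable_dt",
                  "dt * spring/friction = %.3g >= 0.25: integration unstable",
                  dt * spring_constant / friction)
  if (is.null(record_beads)) record_beads <- seq_len(n_beads)
  a <- spring_constant / friction * dt
  noise_sd <- sqrt(2 * kT * dt / friction)
  n_rec <- floor(n_steps / record_stride) + 1L
  .with_seed(seed, {
    # equilibrium start: bond vectors ~ N(0, kT/k) per axis, chain COM at 0
    x <- array(0, dim = c(n_chains, n_beads, 3L))
    if (n_beads > 1L) {
      bonds <- array(stats::rnorm(n_chains * (n_beads - 1L) * 3L,
                                  sd = sqrt(kT / spring_constant)),
                     dim = c(n_chains, n_beads - 1L, 3L))
      for (k in 1:3)
        x[, -1L, k] <- t(apply(bonds[, , k, drop = FALSE], 1L, cumsum))
      x <- sweep(x, c(1, 3), apply(x, c(1, 3), mean))
    }
    out <- array(0, dim = c(n_rec, n_chains * length(record_beads), 3L))
    out[1L, , ] <- x[, record_beads, , drop = FALSE]
    rec <- 1L
    for (s in seq_len(n_steps)) {
      if (n_beads > 1L) {
        lap <- x
        lap[, 1L, ] <- x[, 2L, ] - x[, 1L, ]
        lap[, n_beads, ] <- x[, n_beads - 1L, ] - x[, n_beads, ]
        if (n_beads > 2L) {
          mid <- 2:(n_beads - 1L)
          lap[, mid, ] <- x[, mid + 1L, , drop = FALSE] +
            x[, mid - 1L, , drop = FALSE] - 2 * x[, mid, , drop = FALSE]
        }
        x <- x + a * lap +
          array(stats::rnorm(length(x), sd = noise_sd), dim = dim(x))
      } else {
        x <- x + array(stats::rnorm(length(x), sd = noise_sd), dim = dim(x))
      }
      if (s %% record_stride == 0L) {
        rec <- rec + 1L
        out[rec, , ] <- x[, record_beads, , drop = FALSE]
      }
    }
    labels <- rep(paste0("bead", record_beads), each = n_chains)
    trajectory(out[seq_len(rec), , , drop = FALSE], dt = dt * record_stride,
               labels = labels, elements = rep("C", dim(out)[2]),
               wrapped = FALSE)
  })
}

#' Random or lattice particle packings
#'
#' @param kind `"lattice"` (simple cubic) or `"poisson"` (uniform random).
#' @param n particle count; for `"lattice"` a perfect cube.
#' @param box cubic box edge in Angstrom; for `"lattice"` defaults to
#'   `n^(1/3) * spacing` (the consistent periodic lattice).
#' @param spacing lattice constant in Angstrom (lattice only).
#' @param labels species tags, recycled to `n`.
#' @param seed integer RNG seed (poisson only).
#' @return A [Configuration-class] in a periodic cubic box.
#' @export
genPacking <- function(kind = c("lattice", "poisson"), n, box = NULL,
                       spacing = 1, labels = "X", seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "lattice") {
    m <- round(n^(1 / 3))
    if (m^3 != n)
      .stop_labeled("bad_count", "lattice requires a perfect-cube count, got %d", n)
    if (is.null(box)) box <- m * spacing
    if (m * spacing > box + 1e-9)
      .stop_labeled("overfilled_box",
                    "lattice extent %.3g exceeds box %.3g", m * spacing, box)
    g <- (0:(m - 1L)) * spacing
    pos <- as.matrix(expand.grid(x = g, y = g, z = g))
  } else {
    if (is.null(box))
      .stop_labeled("missing_box", "poisson packing needs a box edge")
    pos <- .with_seed(seed, matrix(stats::runif(3L * n, 0, box), n, 3L))
  }
  configuration(pos, boxEdge = box, labels = rep_len(labels, n),
                elements = rep("C", n))
}

#' Hydrogen-bond geometry fixtures
#'
#' Places explicit donor / hydrogen / acceptor triples realizing requested
#' (D...A distance, H...A distance, deviation from linearity) geometries.
#' The covalent D-H distance follows from the law of cosines,
#' `d_DH = -d_HA cos(dev) + sqrt(d_DA^2 - d_HA^2 sin^2(dev))`, which must be
#' positive and real (requires `d_DA > d_HA`); unrealizable geometries raise
#' a labeled error. Triples are laid out on a widely spaced grid in a
#' periodic box so they do not interact. Donors and acceptors are oxygen.
#'
#' @param geometries data.frame (or list of length-3 vectors) with columns
#'   `d_da`, `d_ha` (Angstrom) and `angle_dev` (degrees).
#' @param class_labels optional character vector of site-class tags for the
#'   acceptor atoms (recycled), e.g. `"hydroxyl_O"`; defaults to
#'   `"acceptor_O"`.
#' @return A [Configuration-class] with `hbondRole` annotations (3 atoms
#'   per requested geometry; empty input gives an empty configuration).
#' @export
genHbondFixture <- function(geometries, class_labels = "acceptor_O") {
  if (is.list(geometries) && !is.data.frame(geometries))
    geometries <- do.call(rbind, lapply(geometries, function(g)
      data.frame(d_da = g[1], d_ha = g[2], angle_dev = g[3])))
  n <- nrow(geometries)
  if (is.null(n) || n == 0L)
    return(configuration(matrix(numeric(0), 0, 3), boxEdge = 50,
                         labels = character(0), elements = character(0)))
  spacing <- 10
  m <- ceiling(n^(1 / 3))
  box <- max(m * spacing, 20)
  cells <- as.matrix(expand.grid(0:(m - 1), 0:(m - 1), 0:(m - 1)))[seq_len(n), , drop = FALSE]
  base <- cells * spacing + spacing / 2
  pos <- matrix(0, 3L * n, 3L)
  for (i in seq_len(n)) {
    dda <- geometries$d_da[i]; dha <- geometries$d_ha[i]
    dev <- geometries$angle_dev[i] * pi / 180
    disc <- dda^2 - dha^2 * sin(dev)^2
    ddh <- -dha * cos(dev) + sqrt(pmax(disc, 0))
    if (disc < 0 || ddh <= 0)
      .stop_labeled("unrealizable_geometry",
                    "geometry %d (d_DA=%.3g, d_HA=%.3g, dev=%.3g deg) is not realizable",
                    i, dda, dha, geometries$angle_dev[i])
    phi <- pi - dev  # D-H...A angle at the hydrogen
    D <- base[i, ]
    H <- D + c(ddh, 0, 0)
    A <- H + dha * c(-cos(phi), sin(phi), 0)
    pos[3L * i - 2L, ] <- D
    pos[3L * i - 1L, ] <- H
    pos[3L * i, ] <- A
  }
  cls <- rep_len(class_labels, n)
  configuration(pos, boxEdge = box,
                labels = as.vector(rbind("donor_O", "donor_H", cls)),
                elements = rep(c("O", "H", "O"), n),
                hbondRole = rep(c("donor", "hydrogen", "acceptor"), n))
}

#' Bilinear volume-temperature series with known breakpoint
#'
#' Emulates the constant-pressure cooling protocol used for glass-transition
#' assessment: a continuous two-segment linear V(T) with a slope break at
#' `t_break` plus Gaussian noise. The default grid descends from 650 K to
#' 200 K in 25 K steps (19 points).
#'
#' @param t_break breakpoint temperature, K; must lie inside the grid.
#' @param slope_low thermal expansion below the break, A^3/K.
#' @param slope_high thermal expansion above the break; must exceed
#'   `slope_low` for a physical glass transition (equal slopes are allowed
#'   and produce a degenerate single line).
#' @param v_break volume at the breakpoint, A^3.
#' @param noise_sd Gaussian noise standard deviation, A^3.
#' @param t_grid temperature grid, K (any order).
#' @param seed integer RNG seed.
#' @return A [VTSeries-class] with attribute `"t_break"` holding the ground
#'   truth.
#' @export
genBilinearVT <- function(t_break = 425, slope_low = 0.5, slope_high = 1.2,
                          v_break = 10000, noise_sd = 0,
                          t_grid = seq(650, 200, by = -25), seed = NULL) {
  if (t_break <= min(t_grid) || t_break >= max(t_grid))
    .stop_labeled("break_outside_grid",
                  "t_break %.4g outside the temperature grid", t_break)
  if (slope_high < slope_low)
    .stop_labeled("bad_slopes", "slope_high must be >= slope_low")
  v <- v_break + slope_low * pmin(t_grid - t_break, 0) +
    slope_high * pmax(t_grid - t_break, 0)
  v <- .with_seed(seed, v + stats::rnorm(length(t_grid), sd = noise_sd))
  out <- new("VTSeries", temperatures = as.numeric(t_grid),
             volumes = as.numeric(v))
  attr(out, "t_break") <- t_break
  out
}
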