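# MSD, power-law fitting, diffusion, van Hove, mode detection.

test_that("MSD handles static, ballistic and Brownian motion", {
  # static particles
  arr <- array(2, dim = c(50, 4, 3))
  tr <- trajectory(arr, dt = 1)
  m <- msd(tr, max_lag = 25)
  expect_true(all(m@msd == 0))
  # ballistic x = v t: msd = v^2 t^2 exactly
  v <- 0.3
  arr <- array(0, dim = c(101, 2, 3))
  arr[, , 1] <- matrix((0:100) * v, 101, 2)
  m <- msd(trajectory(arr, dt = 1), max_lag = 50)
  expect_equal(m@msd, v^2 * m@lagTimes^2, tolerance = 1e-12)
  # Brownian: msd/(6t) -> D at large lag
  D <- 1e-5
  trb <- genBrownian(400, 1000, dt = 1, diffusion = D, seed = 1)
  mb <- msd(trb, max_lag = 500, origin_stride = 20)
  big <- mb@lagTimes > 100
  expect_equal(mean(mb@msd[big] / (6 * mb@lagTimes[big])) * 1e-4, D,
               tolerance = 0.05)
  # wrapped input refused
  trw <- trb; trw@wrapped <- TRUE
  expect_error(msd(trw), class = "wrapped_input")
})

test_that("power-law fit recovers exact and simulated exponents", {
  lag <- exp(seq(log(1), log(300), length.out = 40))
  exact <- new("MSDCurve", lagTimes = lag, msd = 2.5 * lag^0.7,
               nOrigins = rep(1L, 40), selection = "exact")
  f <- fitPowerLaw(exact, window = c(1, 300))
  expect_equal(f@alpha, 0.7, tolerance = 1e-12)
  expect_equal(f@kAlpha, 2.5, tolerance = 1e-10)
  expect_equal(f@rSquared, 1, tolerance = 1e-12)
  # simulated: Brownian alpha = 1, fBM(H = 0.35) alpha = 0.7
  a_b <- fit_alpha_of(genBrownian(500, 2000, diffusion = 1e-5, seed = 2),
                      c(10, 100))
  expect_lt(abs(a_b - 1.0), 0.05)
  a_f <- fit_alpha_of(genFbm(500, 2000, hurst = 0.35, seed = 3), c(5, 500))
  expect_lt(abs(a_f - 0.7), 0.05)
  # errors: narrow window, non-positive msd
  expect_error(fitPowerLaw(exact, window = c(1, 1.5)),
               class = "window_too_narrow")
  zero <- new("MSDCurve", lagTimes = 1:10, msd = c(0, 2:10),
              nOrigins = rep(1L, 10), selection = "z")
  expect_error(fitPowerLaw(zero, window = c(1, 10)),
               class = "nonpositive_msd")
})

test_that("exponent recovery holds across generators and seeds", {
  # alpha* in {0.3, 0.5, 0.7, 1.0} via fbm/ctrw/brownian, 10 seeds each
  cases <- list(
    list(alpha = 0.3, gen = function(s) genFbm(500, 1500, hurst = 0.15, seed = s),
         window = c(5, 500), single = FALSE),
    list(alpha = 0.5, gen = function(s) genFbm(500, 1500, hurst = 0.25, seed = s),
         window = c(5, 500), single = FALSE),
    list(alpha = 0.7, gen = function(s) genCtrw(500, 1500, waiting_exponent = 0.7,
                                                seed = s),
         window = c(10, 1000), single = TRUE),
    list(alpha = 1.0, gen = function(s) genBrownian(500, 1500, diffusion = 1e-5,
                                                    seed = s),
         window = c(5, 500), single = FALSE))
  for (cs in cases) {
    alphas <- vapply(1:10, function(s)
      fit_alpha_of(cs$gen(s), cs$window, single_origin = cs$single), 0)
    expect_lt(max(abs(alphas - cs$alpha)), 0.05)
    expect_lt(abs(mean(alphas) - cs$alpha), 0.02)
  }
})

test_that("diffusion coefficient implements D = slope/6 with unit conversion", {
  # exact line: msd = 6 D t with D = 1e-5 cm^2/s = 0.1 A^2/ps
  lag <- seq(1, 100)
  exact <- new("MSDCurve", lagTimes = lag, msd = 6 * 0.1 * lag,
               nOrigins = rep(1L, 100), selection = "exact")
  dres <- diffusionCoefficient(exact, window = c(1, 100))
  expect_equal(diffusion(dres), 1e-5, tolerance = 1e-12)
  expect_false(dres@nonlinearWarning)
  # Brownian recovery within 5% at 500 walkers
  trb <- genBrownian(500, 2000, dt = 1, diffusion = 1.5e-5, seed = 4)
  mb <- msd(trb, max_lag = 1000, origin_stride = 20)
  d <- diffusion(diffusionCoefficient(mb, window = c(100, 1000)))
  expect_equal(d, 1.5e-5, tolerance = 0.05)
  # subdiffusive curve flags the nonlinear regime
  sub <- new("MSDCurve", lagTimes = lag, msd = 2 * lag^0.7,
             nOrigins = rep(1L, 100), selection = "sub")
  expect_true(diffusionCoefficient(sub, window = c(1, 100))@nonlinearWarning)
  neg <- new("MSDCurve", lagTimes = 1:10, msd = 10:1,
             nOrigins = rep(1L, 10), selection = "neg")
  expect_error(diffusionCoefficient(neg, window = c(1, 10)),
               class = "negative_slope")
})

test_that("van Hove shell masses are normalized and Gaussian for Brownian", {
  # static particles: all mass in the first bin
  arr <- array(1, dim = c(20, 5, 3))
  vh0 <- vanHoveSelf(trajectory(arr, dt = 1), lag_times = 5, dr = 0.1,
                     r_max = 2)
  expect_equal(vh0@shellMass[1, 1], 1)
  expect_length(detectModes(vh0, 5), 1L)
  # Brownian: gs matches the Gaussian propagator within 3 s.e. per bin
  D <- 1e-5 * 1e4  # A^2/ps
  trb <- genBrownian(800, 400, dt = 1, diffusion = 1e-5, seed = 5)
  lag <- 100
  vh <- vanHoveSelf(trb, lag_times = lag, dr = 0.25, origin_stride = 25)
  r <- vh@binCenters
  p_theory <- (4 * pi * r^2 * 0.25) * (4 * pi * D * lag)^(-3 / 2) *
    exp(-r^2 / (4 * D * lag))
  n_samp <- 800 * length(seq(1, 400 - lag + 1, by = 25))
  se <- sqrt(pmax(p_theory, 1e-12) * (1 - p_theory) / n_samp)
  dev <- abs(vh@shellMass[1, ] - p_theory)
  expect_lt(mean(dev <= 3 * se + 0.002), 1.01)  # all bins within band
  expect_true(all(dev <= 4 * se + 0.002))
  expect_equal(rowSums(vh@shellMass), 1, tolerance = 1e-12)
  expect_length(detectModes(vh, lag), 1L)
})

test_that("van Hove second moment equals the MSD on every generator", {
  gens <- list(
    genBrownian(300, 400, diffusion = 1e-5, seed = 6),
    genFbm(300, 400, hurst = 0.35, seed = 7),
    genCtrw(300, 400, waiting_exponent = 0.7, seed = 8),
    genCageHopper(300, 400, hop_rate = 0.02, seed = 9))
  for (tr in gens) {
    lags <- c(20, 100)
    vh <- vanHoveSelf(tr, lag_times = lags, dr = 0.05, origin_stride = 10)
    m <- msd(tr, lag_times = lags, origin_stride = 10)
    expect_equal(vanHoveSecondMoment(vh), m@msd, tolerance = 0.01)
  }
})

test_that("overlapping and independent origins give consistent MSD", {
  tr <- genBrownian(300, 1000, diffusion = 1e-5, seed = 10)
  lag <- 100
  m_all <- msd(tr, lag_times = lag, origin_stride = 1)
  m_ind <- msd(tr, lag_times = lag, origin_stride = lag)
  # per-particle displacement^2 has relative sd sqrt(2/3) in 3-D; the
  # independent-origin mean over n_ind samples bounds the discrepancy
  n_ind <- 300 * length(seq(1, 1000 - lag, by = lag))
  se <- m_ind@msd * sqrt(2 / 3) / sqrt(n_ind)
  expect_lt(abs(m_all@msd - m_ind@msd), 2 * se)
})

test_that("hopping produces a second van Hove mode that fades with rate", {
  tr <- genCageHopper(500, 500, cage_sigma = 0.3, jump_length = 3,
                      hop_rate = 0.02, seed = 11)
  vh <- vanHoveSelf(tr, lag_times = 50, dr = 0.1, origin_stride = 10)
  modes <- detectModes(vh, 50)
  expect_length(modes, 2L)
  expect_lt(abs(modes[2] - 3.0), 0.5)
  # fast hopping at the same lag: displacement distribution is unimodal
  tr_fast <- genCageHopper(500, 500, cage_sigma = 0.3, jump_length = 3,
                           hop_rate = 0.4, seed = 12)
  vh_fast <- vanHoveSelf(tr_fast, lag_times = 50, dr = 0.25,
                         origin_stride = 5)
  expect_length(detectModes(vh_fast, 50), 1L)
  expect_error(detectModes(vh, 33), class = "unknown_lag")
})
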