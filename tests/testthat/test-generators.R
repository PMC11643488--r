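# Synthetic trajectory/configuration generators: ground-truth checks.

test_that("generators are deterministic under a fixed seed", {
  for (gen in list(function(s) genBrownian(10, 50, seed = s),
                   function(s) genFbm(10, 64, hurst = 0.4, seed = s),
                   function(s) genCtrw(10, 50, waiting_exponent = 0.6, seed = s),
                   function(s) genCageHopper(10, 50, hop_rate = 0.05, seed = s),
                   function(s) genRouse(8, 5, n_steps = 50, seed = s))) {
    a <- gen(7L); b <- gen(7L); c <- gen(8L)
    expect_identical(coords(a), coords(b))
    expect_false(identical(coords(a), coords(c)))
  }
  # seeding does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(genBrownian(5, 10, seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("Brownian walkers have the prescribed increment variance", {
  D <- 1e-5  # cm^2/s -> 0.1 A^2/ps
  dt <- 1
  tr <- genBrownian(200, 500, dt = dt, diffusion = D, seed = 1)
  x <- coords(tr)
  inc <- x[-1, , ] - x[-dim(x)[1], , ]
  v <- var(as.vector(inc))
  n <- length(inc)
  se <- sqrt(2 / (n - 1)) * v
  expect_lt(abs(v - 2 * (D * 1e4) * dt), 3 * se)
  # D = 0 gives static particles
  tr0 <- genBrownian(5, 20, diffusion = 0, seed = 1)
  expect_equal(max(abs(coords(tr0))), 0)
  expect_error(genBrownian(5, 20, diffusion = -1), class = "bad_diffusion")
})

test_that("fBM increments match the fractional Gaussian closed-form covariance", {
  H <- 0.35
  tr <- genFbm(400, 512, hurst = H, step_sd = 1, seed = 2)
  x <- coords(tr)[, , 1]
  inc <- x[-1, ] - x[-nrow(x), ]
  gamma_fgn <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                                    abs(k - 1)^(2 * H))
  n_eff <- length(inc)
  for (k in 1:10) {
    emp <- mean(inc[-(1:k), ] * inc[seq_len(nrow(inc) - k), ])
    se <- 3 / sqrt(n_eff)  # conservative s.e. for a lag covariance
    expect_lt(abs(emp - gamma_fgn(k)), se)
  }
  expect_error(genFbm(5, 20, hurst = 1.2), class = "bad_hurst")
})

test_that("fBM at H = 0.5 is Brownian and at H = 0.35 fits alpha = 0.7", {
  tr <- genFbm(200, 512, hurst = 0.5, seed = 3)
  inc <- apply(coords(tr)[, , 1], 2, diff)
  # increments are uncorrelated at lag 1 (Brownian limit)
  r1 <- cor(as.vector(inc[-1, ]), as.vector(inc[-nrow(inc), ]))
  expect_lt(abs(r1), 3 / sqrt(length(inc)))
  expect_gt(shapiro.test(as.vector(inc[1:100, 1:30]))$p.value, 1e-4)
  a <- fit_alpha_of(genFbm(500, 2000, hurst = 0.35, seed = 4), c(5, 500))
  expect_lt(abs(a - 0.70), 0.05)
})

test_that("CTRW walkers subdiffuse with the waiting-time exponent", {
  tr <- genCtrw(1000, 2000, waiting_exponent = 0.7, seed = 5)
  a <- fit_alpha_of(tr, c(10, 1000), single_origin = TRUE)
  expect_gte(a, 0.6); expect_lte(a, 0.8)
  # zero jump length moves nothing
  tr0 <- genCtrw(10, 100, waiting_exponent = 0.5, jump_length = 0, seed = 6)
  expect_equal(max(abs(coords(tr0))), 0)
  expect_error(genCtrw(5, 20, waiting_exponent = 1.0), class = "bad_exponent")
})

test_that("cage hopper produces pure-cage or jump-diffusion limits", {
  # no hops: displacement distribution unimodal at the cage scale
  tr <- genCageHopper(300, 300, cage_sigma = 0.3, hop_rate = 0, seed = 7)
  vh <- vanHoveSelf(tr, lag_times = 50, dr = 0.05, origin_stride = 10)
  modes <- detectModes(vh, 50)
  expect_length(modes, 1L)
  expect_lt(modes, 1.0)
  # long-time MSD slope ~ hop_rate * jump_length^2 (jump diffusion)
  tr2 <- genCageHopper(500, 1500, cage_sigma = 0.2, jump_length = 3,
                       hop_rate = 0.1, seed = 8)
  m <- msd(tr2, lag_times = c(500, 1000, 1500), origin_stride = 5000)
  slope <- coef(lm(m@msd ~ m@lagTimes))[2]
  expect_equal(unname(slope), 0.1 * 9, tolerance = 0.15)
  expect_error(genCageHopper(5, 20, hop_rate = 0.9, dt = 1),
               class = "coarse_resolution")
})

test_that("Rouse chains obey the single-bead and COM limits", {
  # single bead: free Brownian, alpha ~ 1
  tr1 <- genRouse(n_beads = 1, n_chains = 300, dt = 0.05, n_steps = 1000,
                  seed = 9)
  a1 <- fit_alpha_of(tr1, c(1, 25), origin_stride = 10)
  expect_lt(abs(a1 - 1.0), 0.05)
  # COM diffusion D = kT / (N zeta): halving N doubles D (within 15%)
  com_d <- function(nb, seed) {
    nc <- 150L
    tr <- genRouse(n_beads = nb, n_chains = nc, dt = 0.05, n_steps = 1500,
                   record_stride = 5, seed = seed)
    x <- coords(tr)  # particle order: bead-major, chain fastest
    com <- array(0, dim = c(dim(x)[1], nc, 3))
    for (b in seq_len(nb))
      com <- com + x[, ((b - 1L) * nc + 1L):(b * nc), , drop = FALSE]
    trc <- trajectory(com / nb, dt = frameDt(tr))
    m <- msd(trc, max_lag = 30, origin_stride = 20)
    diffusion(diffusionCoefficient(m, window = c(5, 30))) / 1e-4  # reduced
  }
  d16 <- com_d(16, 10); d32 <- com_d(32, 11)
  expect_equal(d16 / d32, 2, tolerance = 0.15)
  expect_equal(d16, 1 / 16 / 6 * 6, tolerance = 0.15)  # kT/(N zeta) = 1/N
  expect_error(genRouse(dt = 0.3), class = "unstable_dt")
})

test_that("packings realize their geometry", {
  lat <- genPacking("lattice", 27, spacing = 2)
  expect_equal(boxEdge(lat), 6)
  d2 <- as.matrix(dist(positions(lat)))^2
  expect_equal(sqrt(min(d2[d2 > 0])), 2)
  expect_error(genPacking("lattice", 10), class = "bad_count")
  poi <- genPacking("poisson", 100, box = 10, seed = 1)
  expect_true(all(positions(poi) >= 0 & positions(poi) < 10))
  expect_identical(positions(genPacking("poisson", 50, box = 5, seed = 2)),
                   positions(genPacking("poisson", 50, box = 5, seed = 2)))
})

test_that("h-bond fixtures realize the requested geometries", {
  g <- data.frame(d_da = c(2.9, 3.5), d_ha = c(1.9, 2.4),
                  angle_dev = c(0, 29))
  cfg <- genHbondFixture(g)
  expect_equal(nParticles(cfg), 6L)
  pos <- positions(cfg)
  for (i in 1:2) {
    D <- pos[3 * i - 2, ]; H <- pos[3 * i - 1, ]; A <- pos[3 * i, ]
    expect_equal(sqrt(sum((D - A)^2)), g$d_da[i], tolerance = 1e-9)
    expect_equal(sqrt(sum((H - A)^2)), g$d_ha[i], tolerance = 1e-9)
    ang <- acos(sum((D - H) * (A - H)) /
                  sqrt(sum((D - H)^2) * sum((A - H)^2))) * 180 / pi
    expect_equal(180 - ang, g$angle_dev[i], tolerance = 1e-9)
  }
  # collinear request: D, H, A lie on one line
  p <- positions(genHbondFixture(data.frame(d_da = 2.9, d_ha = 1.9,
                                            angle_dev = 0)))
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  expect_lt(max(abs(cross(p[2, ] - p[1, ], p[3, ] - p[1, ]))), 1e-9)
  expect_equal(nParticles(genHbondFixture(data.frame())), 0L)
  expect_error(genHbondFixture(data.frame(d_da = 2.0, d_ha = 2.4,
                                          angle_dev = 10)),
               class = "unrealizable_geometry")
})

test_that("bilinear V-T series encode the requested breakpoint", {
  s <- genBilinearVT(t_break = 425, slope_low = 0.5, slope_high = 1.2,
                     noise_sd = 0)
  expect_length(s@temperatures, 19L)  # 650 -> 200 K in 25 K steps
  expect_equal(attr(s, "t_break"), 425)
  # exactly bilinear: residuals of the hinge model vanish
  ft <- fitBilinear(s)
  expect_equal(ft@sse, 0, tolerance = 1e-16)
  expect_error(genBilinearVT(t_break = 100), class = "break_outside_grid")
})
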