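# RDF, hydrogen bonds, site classes, free volume.

test_that("RDF of a Poisson gas is flat at 1 beyond contact", {
  n <- 500L
  frames <- lapply(1:25, function(s) genPacking("poisson", n, box = 20,
                                                seed = s))
  g <- rdf(frames, dr = 0.5)
  far <- g@binCenters > 1
  expect_lt(max(abs(g@g[far] - 1)), 0.05)
  expect_lt(abs(mean(g@g[far]) - 1), 0.01)
  # density-weighted integral of g counts all ordered pairs (normalization)
  shell <- 4 * pi * g@binCenters^2 * 0.5
  n_pairs_seen <- sum(g@g[g@binCenters < 10] * shell[g@binCenters < 10]) *
    n * (n - 1) / 20^3
  expected <- n * (n - 1) * (4 / 3 * pi * 10^3) / 20^3  # pairs within L/2
  expect_equal(n_pairs_seen, expected, tolerance = 0.02)
})

test_that("RDF localizes constructed pair distances and lattice peaks", {
  # two particles 5 A apart -> a single occupied bin at 5 A
  cfg <- configuration(rbind(c(1, 1, 1), c(6, 1, 1)), boxEdge = 20)
  g <- rdf(cfg, dr = 0.1)
  occ <- which(g@g > 0)
  expect_length(occ, 1L)
  expect_lt(abs(g@binCenters[occ] - 5), 0.1)
  # simple cubic lattice: first peak at the lattice constant
  gl <- rdf(genPacking("lattice", 64, spacing = 2), dr = 0.1)
  expect_lt(abs(firstPeak(gl) - 2), 0.1)
  # flat curve has no peak; constructed double-peak returns the first
  flat <- new("RDFCurve", binCenters = seq(0.05, 9.95, 0.1),
              g = rep(1, 100), pairLabels = c("a", "b"), dr = 0.1,
              nFrames = 1L)
  expect_true(is.na(firstPeak(flat)))
  r <- seq(0.05, 9.95, 0.1)
  two <- new("RDFCurve", binCenters = r,
             g = 1 + 2 * exp(-(r - 3.1)^2 / 0.02) + 3 * exp(-(r - 5.2)^2 / 0.02),
             pairLabels = c("O_H2", "O_W"), dr = 0.1, nFrames = 1L)
  expect_lt(abs(firstPeak(two) - 3.1), 0.1)
  expect_error(rdf(cfg, r_max = 15), class = "rmax_too_large")
})

test_that("h-bond detection honors the boundary semantics exactly", {
  fx <- function(...) genHbondFixture(data.frame(...))
  expect_equal(nrow(hbonds(detectHbonds(fx(d_da = 2.9, d_ha = 1.9,
                                           angle_dev = 10)))), 1L)
  expect_equal(nrow(hbonds(detectHbonds(fx(d_da = 3.5, d_ha = 2.4,
                                           angle_dev = 30)))), 1L)
  expect_equal(nrow(hbonds(detectHbonds(fx(d_da = 3.51, d_ha = 2.4,
                                           angle_dev = 30)))), 0L)
  expect_equal(nrow(hbonds(detectHbonds(fx(d_da = 3.0, d_ha = 2.5,
                                           angle_dev = 0)))), 0L)
  expect_equal(nrow(hbonds(detectHbonds(fx(d_da = 3.5, d_ha = 2.4,
                                           angle_dev = 31)))), 0L)
})

test_that("h-bond detection matches the all-triples brute-force oracle", {
  for (seed in 1:50) {
    cfg <- random_hbond_config(n_donors = 60, n_acceptors = 80, box = 14,
                               seed = seed)
    got <- detectHbonds(cfg)@bonds
    got_m <- as.matrix(got[, c("donor", "hydrogen", "acceptor")])
    got_m <- got_m[order(got_m[, 2], got_m[, 3]), , drop = FALSE]
    ora <- oracle_hbonds(cfg)
    expect_equal(unname(got_m), unname(ora), info = sprintf("seed %d", seed))
  }
})

test_that("hydrogens without a covalent donor raise a labeled error", {
  cfg <- configuration(rbind(c(0, 0, 0), c(3, 0, 0), c(5, 0, 0)),
                       boxEdge = 20, elements = c("O", "H", "O"),
                       hbondRole = c("donor", "hydrogen", "acceptor"))
  expect_error(detectHbonds(cfg), class = "unpaired_hydrogen")
})

test_that("site classification partitions tagged atoms", {
  cfg <- configuration(matrix(runif(18, 0, 10), 6), boxEdge = 10,
                       labels = c("water_O", "water_O", "water_O",
                                  "hydroxyl_O", "carbonyl_O", "ring_N"),
                       elements = c("O", "O", "O", "O", "O", "N"))
  cls <- classifySites(cfg)
  expect_equal(sum(cls == "water_O"), 3L)
  expect_equal(sum(table(cls)), 6L)  # a partition
  bad <- configuration(matrix(0, 1, 3), boxEdge = 10, labels = "mystery",
                       elements = "C")
  expect_error(classifySites(bad), class = "unknown_tag")
})

test_that("per-class h-bond counts match hand enumeration", {
  cfg <- genHbondFixture(
    data.frame(d_da = c(2.9, 3.0, 3.4, 3.6), d_ha = c(1.9, 2.0, 2.3, 2.6),
               angle_dev = c(5, 10, 20, 10)),
    class_labels = c("hydroxyl_O", "carbonyl_O", "hydroxyl_O", "water_O"))
  hb <- detectHbonds(cfg)
  # the fourth geometry violates both distance bounds -> 3 bonds
  expect_equal(nrow(hbonds(hb)), 3L)
  expect_equal(hbondClassCounts(hb)[["hydroxyl_O"]], 2L)
  expect_equal(hbondClassCounts(hb)[["carbonyl_O"]], 1L)
  expect_false("water_O" %in% names(hbondClassCounts(hb)))
})

test_that("free volume matches the analytic sphere-in-box result", {
  cfg <- configuration(matrix(c(5, 5, 5), 1), boxEdge = 10,
                       elements = "C", vdwRadius = 2)
  fv0 <- freeVolume(cfg, probe_radius = 0, grid_spacing = 0.25)
  expect_lt(abs(ffv(fv0) - 100 * (1 - 4 * pi / 3 * 2^3 / 1000)), 0.1)
  fv1 <- freeVolume(cfg, probe_radius = 1.4, grid_spacing = 0.25)
  expect_lt(abs(ffv(fv1) - 100 * (1 - 4 * pi / 3 * 3.4^3 / 1000)), 0.2)
  # empty box
  empty <- configuration(matrix(numeric(0), 0, 3), boxEdge = 10,
                         labels = character(0), elements = character(0))
  expect_equal(ffv(freeVolume(empty, 1.4, 0.5)), 100)
  expect_error(freeVolume(cfg, probe_radius = 1.4, grid_spacing = 1),
               class = "grid_too_coarse")
})

test_that("free volume converges in grid spacing and decreases with probe", {
  cfg <- genPacking("poisson", 25, box = 12, seed = 3)
  f_half <- ffv(freeVolume(cfg, 1.0, 0.5))
  f_quarter <- ffv(freeVolume(cfg, 1.0, 0.25))
  expect_lt(abs(f_half - f_quarter), 0.3)
  probes <- c(0, 0.5, 1.0, 1.4, 2.0)
  ffvs <- vapply(probes, function(p) ffv(freeVolume(cfg, p, 0.25)), 0)
  expect_true(all(diff(ffvs) <= 0))
})

test_that("channel labelling respects periodic connectivity", {
  # a slab of atoms across the box leaves two y-slabs joined through the
  # periodic boundary -> a single channel
  xy <- expand.grid(x = seq(0.5, 9.5, 1), z = seq(0.5, 9.5, 1))
  pos <- cbind(xy$x, 5, xy$z)
  cfg <- configuration(pos, boxEdge = 10, elements = rep("C", nrow(pos)),
                       vdwRadius = rep(1.2, nrow(pos)))
  fv <- freeVolume(cfg, probe_radius = 0, grid_spacing = 0.5)
  expect_equal(length(channelVolumes(fv)), 1L)
  expect_equal(sum(channelVolumes(fv)),
               fv@freeVoxelCount * fv@gridSpacing^3, tolerance = 1e-9)
  # two parallel slabs cut the free space into two channels
  cfg2 <- configuration(rbind(pos, cbind(xy$x, 0.0, xy$z)), boxEdge = 10,
                        elements = rep("C", 2 * nrow(pos)),
                        vdwRadius = rep(1.2, 2 * nrow(pos)))
  fv2 <- freeVolume(cfg2, probe_radius = 0, grid_spacing = 0.5)
  expect_equal(length(channelVolumes(fv2)), 2L)
})

test_that("stripping a selection keeps the box and can only open volume", {
  poly <- genPacking("poisson", 40, box = 12, seed = 4, labels = "polymer")
  water <- genPacking("poisson", 30, box = 12, seed = 5, labels = "water_O")
  cfg <- configuration(rbind(positions(poly), positions(water)), boxEdge = 12,
                       labels = c(particleLabels(poly), particleLabels(water)),
                       elements = c(elements(poly), elements(water)))
  stripped <- stripSelection(cfg, "water_O")
  expect_identical(unique(particleLabels(stripped)), "polymer")
  expect_equal(boxEdge(stripped), 12)
  expect_identical(stripSelection(cfg, character(0)), cfg)
  expect_gte(ffv(freeVolume(stripped, 1.4, 0.5)),
             ffv(freeVolume(cfg, 1.4, 0.5)))
  expect_error(stripSelection(stripped, "polymer"), class = "empty_remainder")
})
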