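# Shared fixtures and independent oracles used across test files.

# Atomic-mass oracle, independent of the package's internal table.
oracle_mer_mass <- function(formula) {
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)
  sum(masses[names(formula)] * formula)
}

# Minimum-image distance between two points (scalar oracle).
oracle_mi_dist <- function(a, b, box) {
  d <- a - b
  d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

# Brute-force all-triples hydrogen-bond oracle: nearest-donor pairing,
# then exhaustive donor/hydrogen/acceptor triple enumeration with the
# geometric criteria evaluated from scratch.
oracle_hbonds <- function(cfg, max_da = 3.5, max_ha = 2.5, max_dev = 30,
                          pair_cutoff = 1.3) {
  pos <- positions(cfg)
  box <- boxEdge(cfg)
  role <- hbondRole(cfg)
  hyd <- which(role == "hydrogen")
  don <- which(role == "donor")
  acc <- which(role == "acceptor")
  out <- list()
  for (h in hyd) {
    dd <- vapply(don, function(d) oracle_mi_dist(pos[h, ], pos[d, ], box), 0)
    d <- don[which.min(dd)]
    if (min(dd) > pair_cutoff) stop("oracle: unpaired hydrogen")
    for (a in acc) {
      if (a == d) next
      dDA <- oracle_mi_dist(pos[d, ], pos[a, ], box)
      dHA <- oracle_mi_dist(pos[h, ], pos[a, ], box)
      vHD <- pos[d, ] - pos[h, ]; vHD <- vHD - box * round(vHD / box)
      vHA <- pos[a, ] - pos[h, ]; vHA <- vHA - box * round(vHA / box)
      ang <- acos(max(-1, min(1, sum(vHD * vHA) /
                                sqrt(sum(vHD^2) * sum(vHA^2))))) * 180 / pi
      dev <- 180 - ang
      if (dDA <= max_da + 1e-9 && dHA < max_ha - 1e-9 && dev <= max_dev + 1e-9)
        out[[length(out) + 1L]] <- c(d, h, a)
    }
  }
  if (!length(out)) return(matrix(integer(0), 0, 3))
  mat <- do.call(rbind, out)
  mat[order(mat[, 2], mat[, 3]), , drop = FALSE]
}

# Random configuration with donor/hydrogen/acceptor roles: donors and
# acceptors uniform in the box, each hydrogen placed ~1 A from its donor.
random_hbond_config <- function(n_donors, n_acceptors, box, seed) {
  set.seed(seed)
  don <- matrix(runif(3 * n_donors, 0, box), n_donors, 3)
  acc <- matrix(runif(3 * n_acceptors, 0, box), n_acceptors, 3)
  dirs <- matrix(rnorm(3 * n_donors), n_donors, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  hyd <- (don + dirs * runif(n_donors, 0.9, 1.1)) %% box
  configuration(
    rbind(don, hyd, acc), boxEdge = box,
    labels = c(rep("donor_O", n_donors), rep("donor_H", n_donors),
               rep("acceptor_O", n_acceptors)),
    elements = c(rep("O", n_donors), rep("H", n_donors),
                 rep("O", n_acceptors)),
    hbondRole = c(rep("donor", n_donors), rep("hydrogen", n_donors),
                  rep("acceptor", n_acceptors)))
}

# Fit the MSD exponent of a generated trajectory over a window, with
# origin averaging suitable for stationary-increment processes.
fit_alpha_of <- function(traj, window, origin_stride = 20L,
                         single_origin = FALSE) {
  stride <- if (single_origin) nFrames(traj) + 1L else origin_stride
  curve <- msd(traj, max_lag = max(window), origin_stride = stride)
  alphaExponent(fitPowerLaw(curve, window = window))
}
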