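test_that("the kernel density profile matches term-by-term hand summation
           and is normalised", {
  # 3 particles at z = 2.0, 2.5, 3.0; h = 0.3, dz = 0.5, Lz = 10
  box <- c(5, 5, 10)
  R <- cbind(1, 1, c(2.0, 2.5, 3.0))
  pr <- kde_density_profile(R, rep(1L, 3), box, n_b = 20, h = 0.3)
  ref <- oracle_kde(R[, 3], pr$z, box, 0.3)
  expect_equal(pr$rho[, 1], ref, tolerance = 1e-12)

  # single particle: symmetric profile peaked at the nearest bin center
  pr1 <- kde_density_profile(cbind(2, 2, 4.27), 1L, box, n_b = 20,
                             h = 0.4)
  expect_equal(which.max(pr1$rho[, 1]), 9) # center z = 4.25
  # normalisation: integral recovers the particle count
  s <- rand_system(n = 200, S = 2, box = c(4, 4, 6), seed = 21)
  pr2 <- kde_density_profile(s$R, s$sp, s$box, n_b = 30, h = 0.25)
  counts <- colSums(pr2$rho) * pr2$dz * s$box[1] * s$box[2]
  expect_equal(counts, tabulate(s$sp, 2), tolerance = 0.005)
})

test_that("the profile is translation-covariant and approaches the
           histogram for narrow kernels", {
  s <- rand_system(n = 100, S = 1, box = c(4, 4, 6), seed = 23)
  nb <- 12
  pr <- kde_density_profile(s$R, s$sp, s$box, n_b = nb, h = 0.3)
  # shift by two whole bins: cyclic permutation
  dz <- s$box[3] / nb
  R2 <- s$R
  R2[, 3] <- (R2[, 3] + 2 * dz) %% s$box[3]
  pr2 <- kde_density_profile(R2, s$sp, s$box, n_b = nb, h = 0.3)
  expect_equal(pr2$rho[((seq_len(nb) - 1 + 2) %% nb) + 1, 1], pr$rho[, 1],
               tolerance = 1e-9)

  # h -> 0: the kernel mass integrated over each bin recovers the
  # ordinary histogram counts (particles nudged off bin edges, where the
  # narrow kernel would legitimately split its mass)
  h <- dz / 20
  R3 <- s$R
  edge_dist <- abs(R3[, 3] / dz - round(R3[, 3] / dz)) * dz
  R3[edge_dist < 6 * h, 3] <- R3[edge_dist < 6 * h, 3] + 7 * h
  R3[, 3] <- R3[, 3] %% s$box[3]
  sub <- 40 # sub-points per bin for the quadrature
  fine <- kde_density_profile(R3, s$sp, s$box, n_b = nb * sub, h = h)
  mass <- fine$rho[, 1] * fine$dz * s$box[1] * s$box[2]
  kde_counts <- round(colSums(matrix(mass, sub)))
  hist_counts <- tabulate(floor(R3[, 3] / dz) + 1, nb)
  expect_equal(kde_counts, hist_counts)
})

test_that("area per lipid follows the leaflet formula", {
  expect_equal(area_per_lipid(c(5, 5, 8), 80), 0.625)
  expect_equal(area_per_lipid(c(10, 5, 8), 80),
               2 * area_per_lipid(c(5, 5, 8), 80))
  expect_error(area_per_lipid(c(5, 5, 8), 0), "undefined")
})

test_that("time averages are arithmetic means, and pooled-sample KDE
           equality holds only at constant box", {
  expect_equal(time_average(c(1, 2, 3)), 2)
  expect_equal(time_average(list(5, 5, 5)), 5)
  m <- matrix(1:4, 2)
  expect_equal(time_average(list(m, m + 2)), m + 1)

  # mean of per-frame profiles vs profile of pooled samples (same box)
  box <- c(4, 4, 6)
  set.seed(24)
  zs <- lapply(1:3, function(i) runif(40, 0, box[3]))
  profs <- lapply(zs, function(z)
    kde_density_profile(cbind(1, 1, z), rep(1L, 40), box, n_b = 12,
                        h = 0.3)$rho)
  pooled <- kde_density_profile(cbind(1, 1, unlist(zs)), rep(1L, 120),
                                box, n_b = 12, h = 0.3)$rho / 3
  expect_equal(time_average(profs), pooled, tolerance = 1e-12)
})

test_that("the lateral pressure profile vanishes for a homogeneous fluid
           and its slab sums reproduce the global tensor exactly", {
  fl <- make_homogeneous_fluid(448, c(4, 4, 4), seed = 25)
  fc <- field_config(grid = c(6, 6, 6), a = 7, order = 3)
  chi0 <- chi_matrix(fl$topo$species)
  rc <- run_config(n_equil = 0)
  res <- run_md(fl$state, fl$topo, chi0, fc, rc, n_steps = 60,
                stride = 10)
  pp <- lateral_pressure_profile(res$frames, fl$topo, chi0, fc,
                                 n_slabs = 8)
  # isotropy: mean profile within a few standard errors of zero
  se <- sd(pp$dP) / sqrt(length(pp$dP))
  expect_lt(abs(mean(pp$dP)), 4 * se + 1)

  # structured bilayer: per-term decomposition sums to the total and the
  # slab sum equals the global normal-lateral difference
  fx <- fixture_preset("toy-bilayer", seed = 26)
  eq <- run_md(fx$state, fx$topo, fx$chi, fx$field_cfg, fx$run_cfg,
               n_steps = 80)
  pp2 <- lateral_pressure_profile(eq$state, fx$topo, fx$chi,
                                  fx$field_cfg, n_slabs = 30)
  expect_equal(pp2$kinetic + pp2$bond + pp2$angle + pp2$field, pp2$dP,
               tolerance = 1e-12)
  P <- instantaneous_pressure(eq$state, fx$topo, fx$chi, fx$field_cfg)
  glob <- P[3, 3] - (P[1, 1] + P[2, 2]) / 2
  expect_equal(sum(pp2$dP * pp2$dz), eq$state$box[3] * glob,
               tolerance = 1e-6 * max(abs(eq$state$box[3] * glob), 1))
})
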