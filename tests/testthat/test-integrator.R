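test_that("free particles stream exactly and the RESPA splitting is inert
           without inner forces", {
  fl <- make_homogeneous_fluid(20, c(4, 4, 4), seed = 1)
  chi0 <- chi_matrix(fl$topo$species)
  rc <- run_config(temperature = NA)
  s1 <- respa_step(fl$state, fl$topo, chi0, NULL, rc, step = 0)
  expect_equal(s1$state$R, fl$state$R + fl$state$V * rc$dt_outer,
               tolerance = 1e-14)
  expect_identical(s1$state$V, fl$state$V)

  # with no bonded forces, n = 5 and n = 1 substeps give the same
  # trajectory up to the rounding of the split drift sums
  rc1 <- run_config(dt_inner = 0.1, dt_outer = 0.1, temperature = NA)
  r5 <- run_md(fl$state, fl$topo, chi0, NULL, rc, n_steps = 50)
  r1 <- run_md(fl$state, fl$topo, chi0, NULL, rc1, n_steps = 50)
  expect_equal(r5$state$R, r1$state$R, tolerance = 1e-12)
  expect_identical(r5$state$V, r1$state$V)
})

test_that("the velocity-rescaling thermostat has the decoupled limit,
           deterministic noise, and rejects zero kinetic energy", {
  fl <- make_homogeneous_fluid(50, c(4, 4, 4), seed = 2)
  V <- fl$state$V
  m <- fl$topo$masses

  # tau -> infinity: scaling factor -> 1
  r <- csvr_thermostat(V, m, 323, tau_t = 1e12, dt = 0.1, seed = 1,
                       counter = 0)
  expect_equal(r$alpha, 1, tolerance = 1e-6)
  expect_equal(r$velocities, V * r$alpha)

  # fixed counter: identical draw on repeated calls
  a <- csvr_thermostat(V, m, 323, 0.1, 0.1, seed = 9, counter = 4)
  b <- csvr_thermostat(V, m, 323, 0.1, 0.1, seed = 9, counter = 4)
  expect_identical(a$alpha, b$alpha)
  cdiff <- csvr_thermostat(V, m, 323, 0.1, 0.1, seed = 9, counter = 5)
  expect_false(identical(a$alpha, cdiff$alpha))

  expect_error(csvr_thermostat(matrix(0, 5, 3), rep(72, 5), 323, 0.1,
                               0.1), "zero kinetic energy")
})

test_that("the semi-isotropic Berendsen barostat follows the scaling
           formula", {
  fl <- make_homogeneous_fluid(10, c(4, 4, 5), seed = 3)
  P0 <- 1

  # P equal to the target: box unchanged
  P <- diag(c(P0, P0, P0))
  s <- berendsen_semiisotropic(fl$state, P, P0, tau_p = 0.1, dt = 0.1,
                               beta_c = 4.5e-5)
  expect_equal(s$box, fl$state$box, tolerance = 1e-14)

  # hand-evaluated mu for a given pressure imbalance
  P <- diag(c(300, 320, -50))
  s <- berendsen_semiisotropic(fl$state, P, P0, tau_p = 0.1, dt = 0.1,
                               beta_c = 4.5e-5)
  mu_l <- (1 - 0.1 / 0.1 * 4.5e-5 * (P0 - 310))^(1 / 3)
  mu_n <- (1 - 0.1 / 0.1 * 4.5e-5 * (P0 + 50))^(1 / 3)
  expect_equal(s$box, fl$state$box * c(mu_l, mu_l, mu_n),
               tolerance = 1e-12)
  # lateral pressure above target expands Lx, Ly
  expect_gt(s$box[1], fl$state$box[1])
  expect_equal(s$R, fl$state$R %*% diag(c(mu_l, mu_l, mu_n)),
               tolerance = 1e-12)

  # instability guard
  expect_error(berendsen_semiisotropic(fl$state, diag(rep(1e7, 3)), P0,
                                       0.1, 0.1, 4.5e-5), "unstable")
})

test_that("the pressure tensor reduces to the ideal-gas law without
           interactions and its field part matches a box-strain finite
           difference", {
  fl <- make_homogeneous_fluid(200, c(4, 4, 4), seed = 4)
  chi0 <- chi_matrix(fl$topo$species)
  P <- instantaneous_pressure(fl$state, fl$topo, chi0, NULL)
  Tk <- 2 * hhpf:::kinetic_energy(fl$state$V, fl$topo$masses) /
    (3 * 200 * hhpf:::KB)
  P_ideal <- 200 * hhpf:::KB * Tk / prod(fl$state$box) *
    hhpf:::PRESSURE_FACTOR
  expect_equal(mean(diag(P)), P_ideal, tolerance = 1e-10)

  # field virial vs +-1e-4 strain finite difference
  s <- rand_system(n = 60, S = 2, box = c(4, 4, 5), seed = 5)
  fc <- field_config(grid = c(8, 8, 8), a = 7)
  chi <- two_species_chi(15)
  fe <- hhpf:::field_eval(s$R, s$sp, s$box, chi, fc, forces = FALSE,
                          virial = TRUE)
  W_of <- function(R, box) interaction_energy(
    apply_filter(assign_density(R, s$sp, box, fc$grid, 2), fc$sigma),
    chi, fc)
  for (ax in 1:3) {
    eps <- 1e-4
    up <- rep(1, 3); up[ax] <- 1 + eps
    dn <- rep(1, 3); dn[ax] <- 1 - eps
    fd <- (W_of(s$R %*% diag(up), s$box * up) -
           W_of(s$R %*% diag(dn), s$box * dn)) / (2 * eps)
    expect_equal(fe$dWdeps[ax], fd, tolerance = 1e-6 * abs(fd))
  }
})

test_that("trajectories are bitwise reproducible and conserve momentum
           where the forces do", {
  fx <- fixture_preset("mini-bilayer", seed = 6)
  rc <- fx$run_cfg
  a <- run_md(fx$state, fx$topo, fx$chi, fx$field_cfg, rc, n_steps = 20)
  b <- run_md(fx$state, fx$topo, fx$chi, fx$field_cfg, rc, n_steps = 20)
  expect_identical(a$state$R, b$state$R)
  expect_identical(a$state$V, b$state$V)

  # bonded-only NVE conserves the zero net momentum exactly
  nve <- simulate_nve(fx$state, fx$topo, fx$chi, NULL, rc, 50)
  p <- colSums(fx$topo$masses * nve$state$V)
  expect_lt(max(abs(p)), 1e-9)
})

test_that("a short constant-energy segment of the toy bilayer stays on its
           shadow Hamiltonian", {
  fx <- fixture_preset("mini-bilayer", seed = 7)
  eq <- run_md(fx$state, fx$topo, fx$chi, fx$field_cfg, fx$run_cfg,
               n_steps = 100)
  nve <- simulate_nve(eq$state, fx$topo, fx$chi, fx$field_cfg, fx$run_cfg,
                      500)
  E <- nve$energy$total
  # total-energy excursions stay far below the potential-energy
  # fluctuation scale
  expect_lt(max(E) - min(E), 0.05 * sd(nve$energy$potential))
})

test_that("a ten-step rollout gradient with respect to chi matches central
           finite differences", {
  fx <- fixture_preset("mini-bilayer", seed = 8)
  res <- gradient_check("mini-bilayer", n_equil = 20, n_traced = 10,
                        seed = 8, delta = 0.01)
  expect_lt(max(res$rel_err), 1e-4)
})
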