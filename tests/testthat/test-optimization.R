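# Loss, gradients, replica averaging, the optimizer and the training loop.

make_flat_reference <- function(n_b, S, Lz, h) {
  structure(list(z = (seq_len(n_b) - 0.5) * Lz / n_b,
                 rho = matrix(0, n_b, S), dz = Lz / n_b, h = h),
            class = "hhpf_profile")
}

test_that("the replica loss reproduces hand-evaluated term values", {
  ref <- make_flat_reference(2, 1, 4, 1)
  chi <- matrix(0, 1, 1)
  lcfg <- loss_config(reference_profile = ref, reference_apl = NA,
                      w_t = 1, w_A = 100)
  # density residuals (0.1, -0.1): L = (0.01 + 0.01) / 2 = 0.01
  prof <- ref
  prof$rho <- matrix(c(0.1, -0.1), 2, 1)
  expect_equal(replica_loss(prof, NA, chi, lcfg), 0.01)

  # perfect match and chi inside the box: zero loss
  lcfg2 <- loss_config(reference_profile = ref, reference_apl = 0.625)
  expect_equal(replica_loss(ref, 0.625, chi, lcfg2), 0)

  # an experimental target such as the fluid-phase DPPC area per lipid
  # (0.633 nm^2 at 50 C) enters purely through the quadratic area term
  lcfg_dppc <- loss_config(reference_profile = ref, reference_apl = 0.633)
  expect_equal(replica_loss(ref, 0.65, chi, lcfg_dppc),
               100 * (0.65 - 0.633)^2, tolerance = 1e-12)

  # one chi entry at dchi_max + 2 adds 2^3 = 8
  chi2 <- matrix(302, 1, 1)
  lcfg3 <- loss_config(reference_profile = NULL, dchi_max = 300)
  expect_equal(replica_loss(ref, NA, chi2,
                            loss_config(reference_profile = ref,
                                        dchi_max = 300)) -
               replica_loss(ref, NA, matrix(0, 1, 1),
                            loss_config(reference_profile = ref,
                                        dchi_max = 300)), 8)

  # bin mismatch is an error, never silent interpolation
  prof_bad <- prof
  prof_bad$z <- prof_bad$z + 0.01
  expect_error(replica_loss(prof_bad, NA, chi, lcfg), "bins")
})

test_that("the cubic constraint gradient is 3 (|chi| - bound)^2 per free
           entry", {
  chi <- matrix(0, 2, 2)
  chi[1, 2] <- chi[2, 1] <- 302
  g <- hhpf:::chi_constraint_grad(chi, 300)
  expect_equal(g[1, 2], 12)
  expect_equal(g, t(g))
  expect_equal(g[1, 1], 0)
})

test_that("rollouts are pure functions of the seed and decompose into
           equilibration plus traced segment", {
  fx <- fixture_preset("mini-bilayer", seed = 31)
  prs <- prs_config(n_replicas = 1, n_equil = 15, n_traced = 5)
  ref <- make_reference_data(fx, fx$chi, fx$field_cfg, fx$run_cfg, prs,
                             seed = 3)
  lcfg <- loss_config(reference_profile = ref$profile,
                      reference_apl = ref$apl)
  a <- rollout_and_loss(fx, fx$chi, fx$field_cfg, fx$run_cfg, prs, lcfg,
                        seed = 5)
  b <- rollout_and_loss(fx, fx$chi, fx$field_cfg, fx$run_cfg, prs, lcfg,
                        seed = 5)
  expect_identical(a$loss, b$loss)

  # equilibrating outside and tracing from the evolved state gives the
  # same traced segment: gradients depend on the equilibration only
  # through the state it hands over
  rc <- fx$run_cfg
  rc$seed <- 5L
  eq <- run_md(fx$state, fx$topo, fx$chi, fx$field_cfg, rc, n_steps = 15,
               phase = 1L)
  fx2 <- fx
  fx2$state <- eq$state
  prs0 <- prs_config(n_replicas = 1, n_equil = 0, n_traced = 5)
  c2 <- rollout_and_loss(fx2, fx$chi, fx$field_cfg, fx$run_cfg, prs0,
                         lcfg, seed = 5)
  expect_identical(a$loss, c2$loss)

  # references generated at chi* with the same seed: loss is the
  # inactive-constraint minimum, below any perturbed chi
  ref_self <- rollout_and_loss(fx, fx$chi, fx$field_cfg, fx$run_cfg, prs,
                               lcfg, seed = 3)
  expect_lt(ref_self$loss, 1e-12)
  set.seed(32)
  for (rep in 1:3) {
    pert <- matrix(0, 3, 3)
    ij <- sample(1:3, 2)
    pert[ij[1], ij[2]] <- pert[ij[2], ij[1]] <- 10
    lp <- rollout_and_loss(fx, fx$chi + pert, fx$field_cfg, fx$run_cfg,
                           prs, lcfg, seed = 3)
    expect_gt(lp$loss, ref_self$loss)
  }
})

test_that("the loss gradient isolates the constraint term and ignores
           absent species", {
  # constraint-only regime: all observable weights zero, one entry beyond
  # the boundary
  fl <- make_homogeneous_fluid(60, c(3, 3, 3), seed = 33)
  # add a second, absent species to the table
  topo <- fl$topo
  topo$species <- species_table(c("W", "X"))
  sys <- list(state = fl$state, topo = topo)
  fc <- field_config(grid = c(6, 6, 6), a = 60 / 27, order = 3)
  rc <- run_config(n_equil = 0, n_traced = 1)
  prs <- prs_config(n_replicas = 1, n_equil = 0, n_traced = 1)
  ref <- make_flat_reference(10, 2, 3, 0.3)
  lcfg <- loss_config(reference_profile = ref, reference_apl = NA,
                      w_t = 0, w_A = 0, dchi_max = 300, center = FALSE)
  chi <- matrix(0, 2, 2)
  chi[1, 2] <- chi[2, 1] <- 302
  g <- loss_gradient(sys, chi, fc, rc, prs, lcfg, seed = 1)
  expect_equal(g[1, 2], 12, tolerance = 1e-9)

  # species X is absent: with the constraint inactive its gradient rows
  # vanish
  chi0 <- matrix(0, 2, 2)
  lcfg2 <- loss_config(reference_profile = ref, reference_apl = NA,
                       w_t = 1, w_A = 0, center = FALSE)
  g0 <- loss_gradient(sys, chi0, fc, rc, prs, lcfg2, seed = 1)
  expect_equal(g0[1, 2], 0, tolerance = 1e-12)
})

test_that("replica averaging is the arithmetic mean with a failure
           policy", {
  g1 <- matrix(1, 2, 2)
  r <- list(list(loss = 1, grad = g1, apl = 1),
            list(loss = 3, grad = 3 * g1, apl = 1))
  m <- prs_mean(r)
  expect_equal(m$loss, 2)
  expect_equal(m$grad, 2 * g1)

  # identical replicas: the mean is the single value
  m1 <- prs_mean(list(r[[1]], r[[1]]))
  expect_equal(m1$loss, 1)

  # a failed replica is dropped with a warning within the tolerance,
  # beyond it the bundle aborts
  rf <- c(r, list(simpleError("blew up")))
  expect_warning(mf <- prs_mean(rf, max_failures = 0.5), "failed")
  expect_equal(mf$loss, 2)
  expect_error(suppressWarnings(prs_mean(rf, max_failures = 0.1)),
               "replicas failed")
})

test_that("the multi-system mean couples shared parameters", {
  expect_equal(multi_system_mean(c(0.4, 0.8)), 0.6)
  expect_equal(multi_system_mean(1.7), 1.7)
})

test_that("the belief-style optimizer reproduces the hand-evaluated first
           step and preserves symmetry", {
  cfg <- optimizer_config(eta = 0.01, b1 = 0.1, b2 = 0.4)
  chi <- matrix(0, 1, 1)
  st <- adabelief_init(chi)

  # zero gradient from step one: fixed point
  up0 <- optimizer_update(chi, matrix(0, 1, 1), st, cfg)
  expect_equal(up0$chi, chi)

  # g = 1: m = 0.9, mhat = 1, s = 0.6 * 0.01, shat = 0.01,
  # update = -eta / 0.1 = -0.1
  up <- optimizer_update(chi, matrix(1, 1, 1), st, cfg)
  expect_equal(up$chi[1, 1], -0.1, tolerance = 1e-9)

  # symmetric gradients keep chi symmetric exactly
  chi2 <- chi_matrix(c("A", "B"))
  g <- matrix(c(0.3, 1.2, 1.2, -0.5), 2, 2)
  up2 <- optimizer_update(chi2, g, adabelief_init(chi2), cfg)
  expect_identical(up2$chi, t(up2$chi))
})

test_that("training runs deterministically and restarts bitwise from a
           checkpoint", {
  fx <- fixture_preset("mini-bilayer", seed = 35)
  prs <- prs_config(n_replicas = 2, n_equil = 10, n_traced = 5)
  ref <- make_reference_data(fx, fx$chi, fx$field_cfg, fx$run_cfg, prs,
                             seed = 2)
  lcfg <- loss_config(reference_profile = ref$profile,
                      reference_apl = ref$apl)
  sys <- list(state = fx$state, topo = fx$topo, loss_cfg = lcfg)
  ocfg <- optimizer_config(eta = 0.05, epochs = 4)
  free <- rbind(c(2, 3))

  # zero epochs: chi unchanged
  r0 <- train_chi(list(sys), fx$chi, fx$field_cfg, fx$run_cfg, prs, ocfg,
                  free_pairs = free, seed = 3, epochs = 0)
  expect_identical(r0$chi, fx$chi)

  full <- train_chi(list(sys), fx$chi, fx$field_cfg, fx$run_cfg, prs,
                    ocfg, free_pairs = free, seed = 3, epochs = 4)
  half <- train_chi(list(sys), fx$chi, fx$field_cfg, fx$run_cfg, prs,
                    ocfg, free_pairs = free, seed = 3, epochs = 2)
  resumed <- train_chi(list(sys), fx$chi, fx$field_cfg, fx$run_cfg, prs,
                       ocfg, free_pairs = free, seed = 3,
                       checkpoint = half$checkpoint, epochs = 2)
  expect_identical(resumed$chi, full$chi)
})
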