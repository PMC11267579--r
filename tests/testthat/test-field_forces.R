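# Particle-mesh density assignment, filtering, interaction functional,
# external potential, forces and electrostatics, checked against
# independent direct-space oracles and closed forms.

test_that("trilinear deposition places the expected corner weights", {
  box <- c(4, 4, 4)
  dims <- c(4, 4, 4)
  vcell <- prod(box) / prod(dims)

  # particle exactly on a node: full weight on that node
  d <- assign_density(rbind(c(1, 2, 3)), 1L, box, dims)
  expect_equal(sum(d$rho != 0), 1)
  expect_equal(max(d$rho), 1 / vcell)

  # cell centre: 1/8 per corner
  d <- assign_density(rbind(c(0.5, 0.5, 0.5)), 1L, box, dims)
  expect_equal(sort(unique(round(d$rho[d$rho != 0], 12))),
               round(1 / (8 * vcell), 12))
  expect_equal(sum(d$rho != 0), 8)

  # fractional offsets (0.25, 0.5, 0.75): weights are the products of the
  # per-axis linear factors
  d <- assign_density(rbind(c(0.25, 0.5, 0.75)), 1L, box, dims)
  got <- sort(d$rho[d$rho != 0])
  want <- sort(as.vector(outer(outer(c(0.75, 0.25), c(0.5, 0.5)),
                               c(0.25, 0.75))) / vcell)
  expect_equal(got, want, tolerance = 1e-14)
})

test_that("deposition conserves per-species particle number", {
  s <- rand_system(n = 100, S = 3, seed = 7)
  for (ord in c(2, 3)) {
    d <- assign_density(s$R, s$sp, s$box, c(6, 5, 7), 3, order = ord)
    expect_equal(colSums(d$rho) * d$cell_volume, tabulate(s$sp, 3),
                 tolerance = 1e-12)
    f <- apply_filter(d, 0.5)
    expect_equal(colSums(f$rho) * d$cell_volume, tabulate(s$sp, 3),
                 tolerance = 1e-10)
  }
})

test_that("the Gaussian filter is the identity at sigma 0 and matches the
           direct-space periodic Gaussian sum", {
  s <- rand_system(n = 5, S = 1, box = c(4, 4, 4), seed = 3)
  dims <- c(20, 20, 20) # fine enough that sampling aliasing is < 1e-9
  d <- assign_density(s$R, s$sp, s$box, dims)
  expect_equal(apply_filter(d, 0)$rho, d$rho, tolerance = 1e-10)

  f <- apply_filter(d, 0.5)
  ref <- oracle_filter(d$rho, s$box, dims, 0.5)
  expect_lt(max(abs(f$rho - ref)) / max(abs(ref)), 1e-8)
})

test_that("interaction energy matches closed forms and the cell-by-cell
           double-loop oracle", {
  fc <- field_config(grid = c(4, 4, 4), rho0 = 8.33, kappa = 0.05,
                     a = 9.21)
  box <- c(3, 3, 3)
  ncell <- 64
  vcell <- prod(box) / ncell

  # uniform one-species density phi: W = Vbox (phi - a)^2 / (2 rho0 kappa)
  phi <- 4.2
  dens <- structure(list(rho = matrix(phi, ncell, 1), dims = c(4L, 4L, 4L),
                         box = box, cell_volume = vcell, filtered = TRUE),
                    class = "hhpf_density")
  expect_equal(interaction_energy(dens, matrix(0, 1, 1), fc),
               prod(box) * (phi - fc$a)^2 / (2 * fc$rho0 * fc$kappa),
               tolerance = 1e-12)

  # uniform total density equal to a with chi = 0: W = 0
  dens2 <- dens
  dens2$rho <- matrix(fc$a / 2, ncell, 2)
  expect_equal(interaction_energy(dens2, matrix(0, 2, 2), fc), 0,
               tolerance = 1e-9)

  # random two-species grid vs the brute-force double loop
  set.seed(9)
  dens3 <- dens
  dens3$rho <- matrix(runif(ncell * 2, 0, 10), ncell, 2)
  chi <- two_species_chi(17)
  expect_equal(interaction_energy(dens3, chi, fc),
               oracle_energy(dens3$rho, chi, box, c(4, 4, 4), fc$rho0,
                             fc$kappa, fc$a),
               tolerance = 1e-12)
})

test_that("the external potential is the functional derivative of W", {
  s <- rand_system(n = 25, S = 2, box = c(4, 4, 4), seed = 5)
  dims <- c(6, 6, 6)
  fc <- field_config(grid = dims, a = 6)
  chi <- two_species_chi(10)
  d <- assign_density(s$R, s$sp, s$box, dims, 2)
  df <- apply_filter(d, fc$sigma)
  V <- external_potential(df, chi, fc)
  vcell <- d$cell_volume

  # chi = 0 and uniform total density a gives V = 0
  du <- d
  du$rho <- matrix(fc$a / 2, prod(dims), 2)
  expect_lt(max(abs(external_potential(du, matrix(0, 2, 2), fc))), 1e-10)

  # perturbing one unfiltered-density cell by eps changes W by
  # eps * Vcell * V(cell)
  W0 <- interaction_energy(df, chi, fc)
  for (cell in c(1, 57, 100)) {
    eps <- 1e-6
    dp <- d
    dp$rho[cell, 1] <- dp$rho[cell, 1] + eps
    Wp <- interaction_energy(apply_filter(dp, fc$sigma), chi, fc)
    dm <- d
    dm$rho[cell, 1] <- dm$rho[cell, 1] - eps
    Wm <- interaction_energy(apply_filter(dm, fc$sigma), chi, fc)
    expect_equal((Wp - Wm) / (2 * eps), vcell * V[cell, 1],
                 tolerance = 1e-5)
  }

  # V depends linearly on chi: doubling an off-diagonal entry doubles the
  # cross-species contribution
  V2 <- external_potential(df, 2 * chi, fc)
  V0 <- external_potential(df, 0 * chi, fc)
  expect_equal(V2 - V0, 2 * (V - V0), tolerance = 1e-10)
})

test_that("field forces are the exact gradient of W and vanish for a
           homogeneous commensurate lattice", {
  # one species on a lattice commensurate with the mesh, total density a
  dims <- c(4, 4, 4)
  box <- c(4, 4, 4)
  g <- as.matrix(expand.grid(x = (0:3) + 0.5, y = (0:3) + 0.5,
                             z = (0:3) + 0.5))
  fc <- field_config(grid = dims, a = nrow(g) / prod(box))
  ff <- field_forces(g, rep(1L, nrow(g)), box, matrix(0, 1, 1), fc)
  expect_lt(max(abs(ff$forces)), 1e-10)
  expect_lt(abs(ff$energy), 1e-8)

  # random system: forces match central finite differences of W
  s <- rand_system(n = 30, S = 2, seed = 11)
  dims <- c(8, 8, 8)
  fc <- field_config(grid = dims, a = 9.21)
  chi <- two_species_chi(12)
  ff <- field_forces(s$R, s$sp, s$box, chi, fc)
  h <- 1e-4
  W_of <- function(R) interaction_energy(
    apply_filter(assign_density(R, s$sp, s$box, dims, 2), fc$sigma),
    chi, fc)
  for (i in c(1, 13)) for (ax in 1:3) {
    Rp <- s$R; Rp[i, ax] <- Rp[i, ax] + h
    Rm <- s$R; Rm[i, ax] <- Rm[i, ax] - h
    fd <- -(W_of(Rp) - W_of(Rm)) / (2 * h)
    expect_equal(ff$forces[i, ax], fd,
                 tolerance = 1e-5 * max(1, abs(fd)))
  }
})

test_that("tangent-mode derivatives of W equal minus force times
           displacement", {
  # the engine's own consistency between its gradient (tangent of W) and
  # its returned forces
  s <- rand_system(n = 20, S = 2, seed = 13)
  fc <- field_config(grid = c(6, 6, 6), a = 7)
  chi <- two_species_chi(8)
  set.seed(14)
  dR <- matrix(rnorm(60), 20, 3)
  fe <- hhpf:::field_eval(s$R, s$sp, s$box, chi, fc,
                          tans = list(list(R = dR)))
  expect_equal(fe$dW, -sum(fe$forces * dR),
               tolerance = 1e-10 * abs(fe$dW))
})

test_that("translation by a lattice vector leaves W unchanged and the net
           force is a small fraction of the force scale", {
  s <- rand_system(n = 40, S = 2, seed = 17)
  dims <- c(6, 6, 6)
  fc <- field_config(grid = dims, a = 7, order = 3)
  chi <- two_species_chi(20)
  W_of <- function(R) interaction_energy(
    apply_filter(assign_density(wrap_positions(
      system_state(R, box = s$box))$R, s$sp, s$box, dims, 2, order = 3),
      fc$sigma), chi, fc)
  W0 <- W_of(s$R)
  # shifting by whole cells permutes the deposited density exactly
  shift <- s$box / dims * c(2, 1, 3)
  expect_equal(W_of(sweep(s$R, 2, shift, "+")), W0,
               tolerance = 1e-12)
  # generic shifts change W only through deposition-window aliasing, so
  # the net force is not exactly zero; it decays with the window's
  # spectral tail as the mesh refines (the energy/momentum trade-off of
  # exact-gradient particle-mesh forces)
  ff6 <- field_forces(s$R, s$sp, s$box, chi, fc)
  fc20 <- field_config(grid = c(20, 20, 20), a = 7, order = 3)
  ff20 <- field_forces(s$R, s$sp, s$box, chi, fc20)
  rel6 <- max(abs(colSums(ff6$forces))) / max(abs(ff6$forces))
  rel20 <- max(abs(colSums(ff20$forces))) / max(abs(ff20$forces))
  expect_lt(rel20, rel6 / 3)
  expect_lt(rel20, 0.1)
})

test_that("W and forces match the brute-force direct-space oracle", {
  # deposition by explicit per-particle loops, filtering by direct-space
  # periodic Gaussian convolution, energy by a cell double loop, forces by
  # explicit weight-derivative contraction -- no FFT, no shared kernels.
  s <- rand_system(n = 30, S = 2, box = c(4, 4, 4), seed = 19)
  dims <- c(20, 20, 20)
  fc <- field_config(grid = dims, a = 9.21)
  chi <- two_species_chi(12)

  rho <- oracle_deposit(s$R, s$sp, s$box, dims, 2)
  phit <- oracle_filter(rho, s$box, dims, fc$sigma)
  W_ref <- oracle_energy(phit, chi, s$box, dims, fc$rho0, fc$kappa, fc$a)
  psi <- oracle_potential(phit, chi, s$box, dims, fc$rho0, fc$kappa, fc$a)
  V_ref <- oracle_filter(psi, s$box, dims, fc$sigma)
  F_ref <- oracle_forces(s$R, s$sp, V_ref, s$box, dims)

  ff <- field_forces(s$R, s$sp, s$box, chi, fc)
  expect_lt(abs(ff$energy - W_ref) / abs(W_ref), 1e-8)
  expect_lt(max(abs(ff$forces - F_ref)) / max(abs(F_ref)), 1e-8)
})

test_that("electrostatics: zero charges, pair symmetry, and the smeared
           pair-energy law", {
  box <- c(6, 6, 6)
  dims <- c(24, 24, 24)
  R <- rbind(c(1.13, 3.21, 3.12), c(3.13, 3.21, 3.12))

  z <- electrostatic_forces(R, c(0, 0), box, c(12, 12, 12), 0.5, 15)
  expect_equal(z$energy, 0)
  expect_equal(z$forces, matrix(0, 2, 3))

  pm <- electrostatic_forces(R, c(1, -1), box, dims, 0.5, 15, order = 3)
  # mutual attraction along x; equal and opposite up to the deposition
  # aliasing residual
  expect_gt(pm$forces[1, 1], 0)
  expect_lt(max(abs(pm$forces[1, ] + pm$forces[2, ])),
            0.01 * max(abs(pm$forces)))

  # net charge warns about the neutralising background
  expect_warning(electrostatic_forces(R, c(1, 0), box, dims, 0.5, 15),
                 "net charge")
})

test_that("the energy difference of a displaced charge pair follows the
           smeared-Coulomb erf law", {
  # neutral pair in a 20 nm box: self energies and backgrounds cancel in
  # the difference between separations, periodic-image corrections are
  # negligible, and the fine mesh keeps window smearing below 1%
  box <- c(20, 20, 20)
  dims <- c(128, 128, 128)
  sg <- 0.5
  epsr <- 15
  E_at <- function(r) {
    p1 <- c(5.013, 10.071, 10.113)
    electrostatic_forces(rbind(p1, p1 + c(r, 0, 0)), c(1, -1), box, dims,
                         sg, epsr)$energy
  }
  ana <- function(r) -hhpf:::COULOMB_K / epsr * 2 / sqrt(pi) *
    stats::integrate(function(t) exp(-t^2), 0, r / (2 * sg))$value / r
  d_num <- E_at(1) - E_at(2)
  d_ana <- ana(1) - ana(2)
  expect_lt(abs(d_num - d_ana) / abs(d_ana), 0.01)
})
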