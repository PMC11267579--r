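# Shared data structures: species, topology, system state, mixing-parameter
# matrix, and the field / run configurations, plus their validation.
#
# Conventions: orthorhombic right-handed box with the membrane normal along
# z; particle and species indices are 1-based (species occupy 1..S with no
# gaps); units are nm / ps / kJ mol^-1 / u / e / K / bar throughout.

#' Construct a species table
#'
#' @param name character vector of unique short labels.
#' @param charge per-species charge in elementary units (default 0).
#' @return data.frame with columns `name`, `index`, `charge`.
#' @export
species_table <- function(name, charge = 0) {
  stopifnot(!anyDuplicated(name))
  data.frame(name = as.character(name),
             index = seq_along(name),
             charge = rep_len(as.numeric(charge), length(name)),
             stringsAsFactors = FALSE)
}

#' Construct a topology
#'
#' Bonds are harmonic, `U = 1/2 k (r - r0)^2` with `r0` in nm and `k` in
#' kJ mol^-1 nm^-2.  Angles default to the cosine-harmonic form
#' `U = 1/2 k (cos(theta) - cos(theta0))^2` with `theta0` in degrees and
#' `k` in kJ mol^-1; set `angle_form = "harmonic"` for a plain harmonic in
#' theta.
#'
#' @param species data.frame from [species_table()].
#' @param particle_species integer vector, species index per particle.
#' @param particle_mol integer vector, molecule index per particle.
#' @param masses per-particle mass in u.
#' @param charges per-particle charge in e (defaults to the species charge).
#' @param bonds data.frame with columns `i`, `j`, `r0`, `k` (may be empty).
#' @param angles data.frame with columns `i`, `j`, `k`, `theta0`, `fc`
#'   where `j` is the apex particle (may be empty).
#' @param n_lipids number of molecules flagged as lipids (for the area per
#'   lipid); 0 when the system carries no membrane.
#' @param lipid_mols integer vector of molecule indices that are lipids.
#' @param angle_form `"cosharm"` or `"harmonic"`.
#' @return list of class `hhpf_topology`.
#' @export
topology <- function(species, particle_species, particle_mol, masses,
                     charges = NULL, bonds = NULL, angles = NULL,
                     n_lipids = 0L, lipid_mols = integer(),
                     angle_form = c("cosharm", "harmonic")) {
  angle_form <- match.arg(angle_form)
  n <- length(particle_species)
  if (is.null(charges)) charges <- species$charge[particle_species]
  if (is.null(bonds))
    bonds <- data.frame(i = integer(), j = integer(), r0 = numeric(),
                        k = numeric())
  if (is.null(angles))
    angles <- data.frame(i = integer(), j = integer(), k = integer(),
                         theta0 = numeric(), fc = numeric())
  topo <- structure(list(
    species = species,
    particle_species = as.integer(particle_species),
    particle_mol = as.integer(particle_mol),
    masses = rep_len(as.numeric(masses), n),
    charges = rep_len(as.numeric(charges), n),
    bonds = bonds,
    angles = angles,
    n_lipids = as.integer(n_lipids),
    lipid_mols = as.integer(lipid_mols),
    angle_form = angle_form
  ), class = "hhpf_topology")
  topo
}

#' Construct a system state
#'
#' @param positions N x 3 matrix, nm.
#' @param velocities N x 3 matrix, nm/ps (defaults to zero).
#' @param box lengths `c(Lx, Ly, Lz)`, nm.
#' @param time simulation time, ps.
#' @return list of class `hhpf_state`.
#' @export
system_state <- function(positions, velocities = NULL, box, time = 0) {
  positions <- as.matrix(positions)
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  stopifnot(ncol(positions) == 3, all(dim(velocities) == dim(positions)),
            length(box) == 3, all(box > 0))
  structure(list(R = unname(positions), V = unname(as.matrix(velocities)),
                 box = as.numeric(box), time = as.numeric(time)),
            class = "hhpf_state")
}

#' Construct a symmetric mixing-parameter matrix
#'
#' The chi matrix holds the species-pair mixing energies (kJ/mol) of the
#' density-field interaction functional.  Entries are symmetrised from the
#' upper triangle; the diagonal defaults to zero.
#'
#' @param species data.frame from [species_table()], or a character vector
#'   of names.
#' @param pairs optional data.frame with columns `a`, `b` (species names)
#'   and `chi` used to fill entries.
#' @return S x S symmetric matrix with species names as dimnames.
#' @export
chi_matrix <- function(species, pairs = NULL) {
  nm <- if (is.data.frame(species)) species$name else as.character(species)
  S <- length(nm)
  chi <- matrix(0, S, S, dimnames = list(nm, nm))
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      chi[pairs$a[r], pairs$b[r]] <- pairs$chi[r]
      chi[pairs$b[r], pairs$a[r]] <- pairs$chi[r]
    }
  }
  chi
}

#' Field (particle-mesh) configuration
#'
#' Defaults mirror the engine's documented simulation protocol: a Gaussian
#' filter spread of 0.5 nm, compressibility kappa = 0.05 kJ^-1 mol,
#' rho0 = 8.33 nm^-3 and a = 9.21 nm^-3.
#'
#' @param grid mesh dimensions `c(nx, ny, nz)`, each >= 4.
#' @param rho0 coarse-grained particle density, nm^-3.
#' @param kappa compressibility, kJ^-1 mol.
#' @param a target total density, nm^-3.
#' @param sigma filter spread, nm.
#' @param epsr relative permittivity for the smeared-charge electrostatics.
#' @param coulomb logical, enable electrostatics.
#' @param order assignment window order: 2 = cloud-in-cell (trilinear),
#'   3 = quadratic spline.  The quadratic window makes the exact-gradient
#'   field forces continuous across cell faces, which long constant-energy
#'   runs require.
#' @return list of class `hhpf_field_config`.
#' @export
field_config <- function(grid = c(20, 20, 30), rho0 = 8.33, kappa = 0.05,
                         a = 9.21, sigma = 0.5, epsr = 15, coulomb = FALSE,
                         order = 2L) {
  stopifnot(length(grid) == 3, all(grid >= 4), kappa > 0, sigma >= 0,
            rho0 > 0, epsr > 0, order %in% c(2L, 3L))
  structure(list(grid = as.integer(grid), rho0 = rho0, kappa = kappa, a = a,
                 sigma = sigma, epsr = epsr, coulomb = isTRUE(coulomb),
                 order = as.integer(order)),
            class = "hhpf_field_config")
}

#' Run (integrator) configuration
#'
#' The rRESPA splitting uses `dt_inner` for the bonded forces and
#' `dt_outer` for the field and electrostatic forces; `dt_outer` must be an
#' integer multiple of `dt_inner`.  Defaults follow the engine's standard
#' protocol (0.02 / 0.1 ps, tau = 0.1 ps).
#'
#' @param dt_inner inner (bonded) time step, ps.
#' @param dt_outer outer (field) time step, ps.
#' @param temperature thermostat target, K; `NA` disables the thermostat.
#' @param tau_t thermostat coupling time, ps.
#' @param pressure barostat target, bar.
#' @param tau_p barostat coupling time, ps.
#' @param barostat `"off"` or `"semiisotropic"`.
#' @param beta_c isothermal compressibility used by the barostat, bar^-1.
#' @param n_equil equilibration (untraced) outer steps.
#' @param n_traced traced (sampled) outer steps.
#' @param stride frame stride for observable accumulation in the traced
#'   segment.
#' @param seed integer random seed.
#' @return list of class `hhpf_run_config`.
#' @export
run_config <- function(dt_inner = 0.02, dt_outer = 0.1, temperature = 323,
                       tau_t = 0.1, pressure = 1, tau_p = 0.1,
                       barostat = c("off", "semiisotropic"),
                       beta_c = 4.5e-5, n_equil = 2000, n_traced = 200,
                       stride = 1L, seed = 1L) {
  barostat <- match.arg(barostat)
  ratio <- dt_outer / dt_inner
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("dt_outer must be an integer multiple of dt_inner")
  stopifnot(tau_t > 0, tau_p > 0, dt_inner > 0)
  structure(list(dt_inner = dt_inner, dt_outer = dt_outer,
                 n_inner = as.integer(round(ratio)),
                 temperature = temperature, tau_t = tau_t,
                 pressure = pressure, tau_p = tau_p, barostat = barostat,
                 beta_c = beta_c, n_equil = as.integer(n_equil),
                 n_traced = as.integer(n_traced),
                 stride = as.integer(stride), seed = as.integer(seed)),
            class = "hhpf_run_config")
}

#' Validate a system
#'
#' Report-based validation: returns a character vector of violations (empty
#' when the system is consistent).  Checks particle/bond/angle index ranges,
#' mass positivity, chi symmetry and finiteness, box positivity, and that
#' bonded pairs stay within one molecule; the net charge is reported as a
#' violation only when electrostatics is off and the system is charged.
#'
#' @param topo topology.
#' @param state system state.
#' @param field_cfg field configuration.
#' @param chi optional mixing matrix to check for symmetry.
#' @return character vector of violations; `character(0)` means valid.
#' @export
validate_system <- function(topo, state, field_cfg, chi = NULL) {
  bad <- character()
  n <- length(topo$particle_species)
  S <- nrow(topo$species)
  if (!identical(topo$species$index, seq_len(S)))
    bad <- c(bad, "species indices are not 1..S without gaps")
  if (anyDuplicated(topo$species$name))
    bad <- c(bad, "species names are not unique")
  if (nrow(state$R) != n)
    bad <- c(bad, sprintf("state has %d particles, topology %d",
                          nrow(state$R), n))
  if (any(topo$particle_species < 1 | topo$particle_species > S))
    bad <- c(bad, "particle species index out of range")
  if (any(topo$masses <= 0))
    bad <- c(bad, "non-positive particle mass")
  if (any(state$box <= 0))
    bad <- c(bad, "non-positive box length")
  bnd <- topo$bonds
  if (nrow(bnd)) {
    out <- which(bnd$i < 1 | bnd$i > n | bnd$j < 1 | bnd$j > n)
    for (b in out)
      bad <- c(bad, sprintf("bond %d references a particle out of range", b))
    ok <- bnd$i >= 1 & bnd$i <= n & bnd$j >= 1 & bnd$j <= n
    cross <- which(ok &
      topo$particle_mol[pmin(bnd$i, n)] != topo$particle_mol[pmin(bnd$j, n)])
    for (b in cross)
      bad <- c(bad, sprintf("bond %d joins two different molecules", b))
  }
  ang <- topo$angles
  if (nrow(ang)) {
    out <- which(ang$i < 1 | ang$i > n | ang$j < 1 | ang$j > n |
                 ang$k < 1 | ang$k > n)
    for (q in out)
      bad <- c(bad, sprintf("angle %d references a particle out of range", q))
  }
  if (!is.null(chi)) {
    if (!isTRUE(all.equal(chi, t(chi), tolerance = 0)) ||
        !identical(chi, t(chi)))
      bad <- c(bad, "chi not symmetric")
    if (any(!is.finite(chi)))
      bad <- c(bad, "chi has non-finite entries")
    if (nrow(chi) != S)
      bad <- c(bad, "chi dimension does not match species count")
  }
  qtot <- sum(topo$charges)
  if (abs(qtot) > 1e-9 && !field_cfg$coulomb)
    bad <- c(bad, sprintf("net charge %.3f with electrostatics disabled",
                          qtot))
  bad
}

#' Wrap positions into the primary box
#'
#' Each coordinate is mapped into `[0, L)` by subtracting an integer number
#' of box lengths.  Idempotent; velocities and box are untouched.
#'
#' @param state system state.
#' @return state with wrapped positions.
#' @export
wrap_positions <- function(state) {
  R <- state$R
  for (a in 1:3) {
    L <- state$box[a]
    R[, a] <- R[, a] - floor(R[, a] / L) * L
    # floor(x/L)*L can round x == L back to itself; enforce [0, L)
    R[R[, a] >= L, a] <- 0
  }
  state$R <- R
  state
}
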