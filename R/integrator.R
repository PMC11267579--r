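# Time evolution: rRESPA multiple-time-step integration (bonded forces on
# the inner step, field + electrostatic forces on the outer step), a
# canonical-sampling velocity-rescaling thermostat and a semi-isotropic
# Berendsen barostat.  The step is a pure function of (state, parameters,
# step counter): stochastic terms are drawn from counter-based streams
# keyed on (seed, phase, step), so trajectories are bitwise reproducible
# and tangent propagation can treat the noise as fixed (reparametrised).

# counter-based seed stream; all factors keep products well below 2^53
rng_stream_seed <- function(seed, phase, step) {
  (as.numeric(seed) * 69069 + phase * 1234567 + step * 362437) %%
    2147483563 + 1
}

kinetic_energy <- function(V, masses) {
  0.5 * sum(masses * rowSums(V^2))
}

# ---- thermostat -----------------------------------------------------------

# core of the stochastic velocity rescaling: given the current kinetic
# energy K, target Kbar, ndf degrees of freedom, coupling c = exp(-dt/tau)
# and the noise pair (r1, s2 ~ chi^2_{ndf-1}), returns alpha^2 and its
# derivative with respect to K (noise held fixed).
csvr_alpha2 <- function(K, Kbar, ndf, cc, r1, s2) {
  A <- (1 - cc) * Kbar * (r1^2 + s2) / ndf
  B <- 2 * r1 * sqrt(cc * (1 - cc) * Kbar / ndf)
  a2 <- cc + A / K + B / sqrt(K)
  da2dK <- -A / K^2 - 0.5 * B / K^1.5
  list(a2 = a2, da2dK = da2dK)
}

#' Canonical-sampling velocity-rescaling thermostat
#'
#' Rescales all velocities by a single stochastic factor that relaxes the
#' kinetic energy towards the canonical distribution at the target
#' temperature over the coupling time `tau_t`.  The noise is drawn from a
#' counter-based stream keyed on `(seed, counter)`, so repeated calls with
#' the same counter return bitwise identical results.
#'
#' @param velocities N x 3 matrix, nm/ps.
#' @param masses per-particle masses, u.
#' @param temperature target temperature, K.
#' @param tau_t coupling time, ps.
#' @param dt time step, ps.
#' @param seed,counter integers keying the noise stream.
#' @param ndf number of degrees of freedom (default `3N - 3`, accounting
#'   for conserved zero net momentum).
#' @return list with `velocities` and the applied scaling factor `alpha`.
#' @export
csvr_thermostat <- function(velocities, masses, temperature, tau_t, dt,
                            seed = 1L, counter = 0L, ndf = NULL) {
  N <- nrow(velocities)
  if (is.null(ndf)) ndf <- 3 * N - 3
  K <- kinetic_energy(velocities, masses)
  if (K <= 0) stop("zero kinetic energy: velocity rescaling undefined")
  Kbar <- 0.5 * ndf * KB * temperature
  cc <- exp(-dt / tau_t)
  set.seed(rng_stream_seed(seed, 3, counter))
  r1 <- rnorm(1)
  s2 <- rchisq(1, df = ndf - 1)
  al <- csvr_alpha2(K, Kbar, ndf, cc, r1, s2)
  alpha <- sqrt(al$a2)
  list(velocities = velocities * alpha, alpha = alpha)
}

# ---- barostat -------------------------------------------------------------

#' Semi-isotropic Berendsen barostat step
#'
#' Scales the lateral (x, y, common factor) and normal (z) box lengths by
#' `mu = (1 - (dt / tau_p) * beta * (P0 - P))^(1/3)` using the respective
#' components of the pressure tensor, and scales particle coordinates
#' affinely.  Velocities are untouched.
#'
#' @param state system state.
#' @param pressure 3 x 3 instantaneous pressure tensor, bar.
#' @param target target pressure, bar (applied in both directions).
#' @param tau_p coupling time, ps.
#' @param dt time step, ps.
#' @param beta_c isothermal compressibility, bar^-1.
#' @return state with scaled box and positions.
#' @export
berendsen_semiisotropic <- function(state, pressure, target, tau_p, dt,
                                    beta_c = 4.5e-5) {
  pl <- (pressure[1, 1] + pressure[2, 2]) / 2
  pn <- pressure[3, 3]
  mu_l <- (1 - (dt / tau_p) * beta_c * (target - pl))^(1 / 3)
  mu_n <- (1 - (dt / tau_p) * beta_c * (target - pn))^(1 / 3)
  if (mu_l < 0.9 || mu_l > 1.1 || mu_n < 0.9 || mu_n > 1.1)
    stop(sprintf("barostat scaling unstable (mu_l = %.4f, mu_n = %.4f)",
                 mu_l, mu_n))
  mu <- c(mu_l, mu_l, mu_n)
  state$box <- state$box * mu
  state$R <- state$R %*% diag(mu)
  state
}

# ---- combined outer (field + electrostatic) force evaluation -------------

outer_eval <- function(R, topo, box, chi, field_cfg, tans = NULL,
                       virial = FALSE, percell = FALSE) {
  if (is.null(field_cfg)) {
    # free (ideal-gas) outer forces
    nt <- length(tans)
    z <- matrix(0, nrow(R), 3)
    return(list(F = z, U = 0,
                dWdeps = if (virial) c(0, 0, 0),
                stress_cells = NULL,
                dF = if (nt) rep(list(z), nt),
                dU = if (nt) numeric(nt),
                ddWdeps = if (nt && virial) rep(list(c(0, 0, 0)), nt)))
  }
  fe <- field_eval(R, topo$particle_species, box, chi, field_cfg,
                   forces = TRUE, virial = virial, percell = percell,
                   tans = tans)
  out <- list(F = fe$forces, U = fe$W, dWdeps = fe$dWdeps,
              stress_cells = fe$stress_cells,
              dF = fe$dF, dU = fe$dW, ddWdeps = fe$ddWdeps)
  if (field_cfg$coulomb && any(topo$charges != 0)) {
    ee <- elec_eval(R, topo$charges, box, field_cfg$grid, field_cfg$sigma,
                    field_cfg$epsr, field_cfg$order %||% 2L,
                    forces = TRUE, virial = virial,
                    percell = percell, tans = tans)
    out$F <- out$F + ee$forces
    out$U <- out$U + ee$E
    if (virial) {
      out$dWdeps <- out$dWdeps + ee$dEdeps
      if (percell) out$stress_cells <- out$stress_cells + ee$stress_cells
    }
    if (!is.null(tans)) {
      out$dU <- out$dU + ee$dE
      for (t in seq_along(tans)) {
        out$dF[[t]] <- out$dF[[t]] + ee$dF[[t]]
        if (virial) out$ddWdeps[[t]] <- out$ddWdeps[[t]] + ee$ddEdeps[[t]]
      }
    }
  }
  out
}

# ---- pressure -------------------------------------------------------------

# internal pressure from cached force evaluations; returns the tensor in
# bar and, per tangent, its directional derivative.
pressure_from_parts <- function(V, masses, box, be, oe, tans = NULL,
                                dV = NULL) {
  vol <- prod(box)
  kin <- crossprod(V * masses, V) # sum_i m v v^T
  X <- kin + be$virial
  X[1, 1] <- X[1, 1] - oe$dWdeps[1]
  X[2, 2] <- X[2, 2] - oe$dWdeps[2]
  X[3, 3] <- X[3, 3] - oe$dWdeps[3]
  P <- X / vol * PRESSURE_FACTOR
  out <- list(P = P)
  if (!is.null(tans)) {
    out$dP <- vector("list", length(tans))
    for (t in seq_along(tans)) {
      tn <- tans[[t]]
      dVol <- if (is.null(tn$box)) 0 else vol * sum(tn$box / box)
      dVt <- dV[[t]]
      dkin <- crossprod(dVt * masses, V) + crossprod(V * masses, dVt)
      dX <- dkin + be$dvir[[t]]
      dX[1, 1] <- dX[1, 1] - oe$ddWdeps[[t]][1]
      dX[2, 2] <- dX[2, 2] - oe$ddWdeps[[t]][2]
      dX[3, 3] <- dX[3, 3] - oe$ddWdeps[[t]][3]
      out$dP[[t]] <- (dX / vol - P / PRESSURE_FACTOR * dVol / vol) *
        PRESSURE_FACTOR
    }
  }
  out
}

#' Instantaneous pressure tensor
#'
#' Kinetic term plus bonded Clausius virial plus the field (and, when
#' enabled, electrostatic) contribution obtained as the analytic derivative
#' of the discretised interaction functional with respect to anisotropic
#' box scaling at fixed fractional coordinates.
#'
#' @param state system state.
#' @param topo topology.
#' @param chi mixing matrix.
#' @param field_cfg field configuration.
#' @return 3 x 3 pressure tensor, bar.
#' @export
instantaneous_pressure <- function(state, topo, chi, field_cfg) {
  be <- bonded_eval(state$R, state$box, topo)
  oe <- outer_eval(state$R, topo, state$box, chi, field_cfg, virial = TRUE)
  pressure_from_parts(state$V, topo$masses, state$box, be, oe)$P
}

# ---- the rRESPA step ------------------------------------------------------

# Internal simulation container: state plus cached outer/bonded force
# evaluations and, optionally, tangent states.  tans is a list of
# list(R, V, box, chi): the evolving tangent of positions/velocities/box
# for a fixed chi direction.
sim_init <- function(state, topo, chi, field_cfg, run_cfg, tans = NULL) {
  need_vir <- run_cfg$barostat != "off"
  ftans <- sim_field_tans(tans)
  be <- bonded_eval(state$R, state$box, topo, tans = ftans)
  oe <- outer_eval(state$R, topo, state$box, chi, field_cfg, tans = ftans,
                   virial = need_vir)
  list(state = state, tans = tans, be = be, oe = oe)
}

# restrict evolving tangents to the directions the force kernels need
sim_field_tans <- function(tans) {
  if (is.null(tans)) return(NULL)
  lapply(tans, function(tn) list(R = tn$R, box = tn$box, chi = tn$chi))
}

step_core <- function(sim, topo, chi, field_cfg, run_cfg, phase, istep) {
  st <- sim$state
  tans <- sim$tans
  nt <- length(tans)
  m <- topo$masses
  dto <- run_cfg$dt_outer
  dti <- run_cfg$dt_inner
  need_vir <- run_cfg$barostat != "off"

  kick <- function(V, F, dt) V + F * (dt / m)

  # outer half kick
  st$V <- kick(st$V, sim$oe$F, dto / 2)
  if (nt) for (t in seq_len(nt))
    tans[[t]]$V <- tans[[t]]$V + sim$oe$dF[[t]] * (dto / (2 * m))

  # inner velocity-Verlet loop with bonded forces
  be <- sim$be
  for (j in seq_len(run_cfg$n_inner)) {
    st$V <- kick(st$V, be$forces, dti / 2)
    if (nt) for (t in seq_len(nt))
      tans[[t]]$V <- tans[[t]]$V + be$dF[[t]] * (dti / (2 * m))
    st$R <- st$R + st$V * dti
    if (nt) for (t in seq_len(nt))
      tans[[t]]$R <- tans[[t]]$R + tans[[t]]$V * dti
    be <- bonded_eval(st$R, st$box, topo, tans = sim_field_tans(tans))
    st$V <- kick(st$V, be$forces, dti / 2)
    if (nt) for (t in seq_len(nt))
      tans[[t]]$V <- tans[[t]]$V + be$dF[[t]] * (dti / (2 * m))
  }

  # outer forces at the new positions, then the closing half kick
  oe <- outer_eval(st$R, topo, st$box, chi, field_cfg,
                   tans = sim_field_tans(tans), virial = need_vir)
  st$V <- kick(st$V, oe$F, dto / 2)
  if (nt) for (t in seq_len(nt))
    tans[[t]]$V <- tans[[t]]$V + oe$dF[[t]] * (dto / (2 * m))

  # thermostat: global stochastic rescaling, noise keyed on (seed, phase,
  # step) and held fixed along the tangents
  if (is.finite(run_cfg$temperature)) {
    N <- nrow(st$V)
    ndf <- 3 * N - 3
    K <- kinetic_energy(st$V, m)
    if (K <= 0) stop("zero kinetic energy in thermostat at step ", istep)
    Kbar <- 0.5 * ndf * KB * run_cfg$temperature
    cc <- exp(-dto / run_cfg$tau_t)
    set.seed(rng_stream_seed(run_cfg$seed, phase, istep))
    r1 <- rnorm(1)
    s2 <- rchisq(1, df = ndf - 1)
    al <- csvr_alpha2(K, Kbar, ndf, cc, r1, s2)
    alpha <- sqrt(al$a2)
    if (nt) for (t in seq_len(nt)) {
      dK <- sum(m * rowSums(st$V * tans[[t]]$V))
      dalpha <- al$da2dK * dK / (2 * alpha)
      tans[[t]]$V <- alpha * tans[[t]]$V + dalpha * st$V
    }
    st$V <- st$V * alpha
  }

  # barostat: semi-isotropic Berendsen on the instantaneous tensor
  if (need_vir) {
    pr <- pressure_from_parts(st$V, m, st$box, be, oe,
                              tans = tans,
                              dV = if (nt) lapply(tans, `[[`, "V"))
    P <- pr$P
    pl <- (P[1, 1] + P[2, 2]) / 2
    pn <- P[3, 3]
    fac <- (run_cfg$dt_outer / run_cfg$tau_p) * run_cfg$beta_c
    xl <- 1 - fac * (run_cfg$pressure - pl)
    xn <- 1 - fac * (run_cfg$pressure - pn)
    mu_l <- xl^(1 / 3)
    mu_n <- xn^(1 / 3)
    if (mu_l < 0.9 || mu_l > 1.1 || mu_n < 0.9 || mu_n > 1.1)
      stop(sprintf(
        "barostat scaling unstable at step %d (mu_l = %.4f, mu_n = %.4f)",
        istep, mu_l, mu_n))
    mu <- c(mu_l, mu_l, mu_n)
    if (nt) for (t in seq_len(nt)) {
      dP <- pr$dP[[t]]
      dpl <- (dP[1, 1] + dP[2, 2]) / 2
      dpn <- dP[3, 3]
      dmu_l <- xl^(-2 / 3) / 3 * fac * dpl
      dmu_n <- xn^(-2 / 3) / 3 * fac * dpn
      dmu <- c(dmu_l, dmu_l, dmu_n)
      tans[[t]]$box <- mu * (if (is.null(tans[[t]]$box)) 0 else
                             tans[[t]]$box) + dmu * st$box
      tans[[t]]$R <- sweep(tans[[t]]$R, 2, mu, "*") +
        sweep(st$R, 2, dmu, "*")
    }
    st$box <- st$box * mu
    st$R <- sweep(st$R, 2, mu, "*")
    # forces cached for the next step were computed in the unscaled box;
    # re-evaluate so the next half kick is consistent
    oe <- outer_eval(st$R, topo, st$box, chi, field_cfg,
                     tans = sim_field_tans(tans), virial = need_vir)
    be <- bonded_eval(st$R, st$box, topo, tans = sim_field_tans(tans))
  }

  st$time <- st$time + dto
  list(state = st, tans = tans, be = be, oe = oe)
}

#' Advance the system by one rRESPA outer step
#'
#' One outer step: half kick with the field (and electrostatic) forces,
#' `n = dt_outer / dt_inner` velocity-Verlet inner steps with the bonded
#' forces, a closing half kick, then the thermostat and (optionally) the
#' barostat.  Passing the returned `cache` back in avoids recomputing the
#' forces at the start of the next step.
#'
#' @param state system state.
#' @param topo topology.
#' @param chi mixing matrix.
#' @param field_cfg field configuration.
#' @param run_cfg run configuration (uses `temperature`, couplings,
#'   `barostat`, `seed`).
#' @param step step counter keying the thermostat noise stream.
#' @param cache value returned by a previous call, or `NULL`.
#' @return list with `state` and `cache`.
#' @export
respa_step <- function(state, topo, chi, field_cfg, run_cfg, step = 0L,
                       cache = NULL) {
  sim <- if (is.null(cache)) {
    sim_init(state, topo, chi, field_cfg, run_cfg)
  } else {
    cache$state <- state
    cache
  }
  sim <- step_core(sim, topo, chi, field_cfg, run_cfg, phase = 1L,
                   istep = as.integer(step))
  list(state = sim$state, cache = sim)
}

#' Run a molecular dynamics trajectory
#'
#' Drives [respa_step()] for `n_steps` outer steps, recording every
#' `stride`-th frame.
#'
#' @param state initial state.
#' @param topo topology.
#' @param chi mixing matrix.
#' @param field_cfg field configuration.
#' @param run_cfg run configuration.
#' @param n_steps number of outer steps (default `run_cfg$n_equil`).
#' @param stride frame stride for the returned trajectory.
#' @param phase integer stream label separating noise used here from other
#'   phases of a protocol.
#' @return list with final `state` and `frames` (list of recorded states).
#' @export
run_md <- function(state, topo, chi, field_cfg, run_cfg,
                   n_steps = run_cfg$n_equil, stride = 0L, phase = 1L) {
  sim <- sim_init(state, topo, chi, field_cfg, run_cfg)
  frames <- list()
  for (i in seq_len(n_steps)) {
    sim <- step_core(sim, topo, chi, field_cfg, run_cfg, phase = phase,
                     istep = i - 1L)
    if (stride > 0 && i %% stride == 0)
      frames[[length(frames) + 1]] <- sim$state
  }
  list(state = sim$state, frames = frames)
}

#' Run a constant-energy (NVE) trajectory and track the energy
#'
#' Convenience wrapper with thermostat and barostat disabled; returns the
#' kinetic, potential and total energy per outer step for conservation
#' checks.
#'
#' @inheritParams run_md
#' @return list with `state` and a data.frame `energy` (columns `time`,
#'   `kinetic`, `potential`, `total`).
#' @export
simulate_nve <- function(state, topo, chi, field_cfg, run_cfg, n_steps) {
  run_cfg$temperature <- NA
  run_cfg$barostat <- "off"
  sim <- sim_init(state, topo, chi, field_cfg, run_cfg)
  kin <- pot <- tim <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    sim <- step_core(sim, topo, chi, field_cfg, run_cfg, phase = 1L,
                     istep = i - 1L)
    kin[i] <- kinetic_energy(sim$state$V, topo$masses)
    pot[i] <- sim$oe$U + sim$be$energy
    tim[i] <- sim$state$time
  }
  list(state = sim$state,
       energy = data.frame(time = tim, kinetic = kin, potential = pot,
                           total = kin + pot))
}
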