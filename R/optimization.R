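# Gradient-based learning of the chi mixing matrix: per-replica losses
# built from time-averaged density profiles and area per lipid, exact
# tangent-mode gradients through the traced sampling segment, parallel
# replica (PRS) averaging, multi-system mean losses, and the adaptive
# "belief"-style optimizer driving the training loop.

#' Loss configuration
#'
#' The replica loss is
#' `L = sum_t (w_t / n_b) sum_b (rho_t(z_b) - rho_t_ref(z_b))^2 +
#'  w_A (A_L - A_L_ref)^2 + sum_{l <= m} relu(|chi_lm| - dchi_max)^3`
#' with the density term in nm^-6 weighted by `w_t` (nm^6), the area term
#' weighted by `w_A` (nm^-4), and a cubic penalty confining every mixing
#' parameter to `[-dchi_max, dchi_max]`.
#'
#' @param reference_profile `hhpf_profile` with the target per-species
#'   densities at fixed bin centers.
#' @param reference_apl target area per lipid, nm^2 (NA disables the term).
#' @param w_t per-species density weight, nm^6 (scalar or vector).
#' @param w_A area-per-lipid weight, nm^-4.
#' @param dchi_max cubic-constraint boundary, kJ/mol.
#' @param h profile bandwidth, nm (defaults to the reference bin width).
#' @param center logical: center profiles on the lipid midplane before
#'   comparison.
#' @return list of class `hhpf_loss_config`.
#' @export
loss_config <- function(reference_profile = NULL, reference_apl = NA,
                        w_t = 1, w_A = 100, dchi_max = 300, h = NULL,
                        center = TRUE) {
  stopifnot(all(w_t >= 0), w_A >= 0, dchi_max > 0)
  structure(list(reference_profile = reference_profile,
                 reference_apl = reference_apl, w_t = w_t, w_A = w_A,
                 dchi_max = dchi_max, h = h, center = isTRUE(center)),
            class = "hhpf_loss_config")
}

#' Parallel-replica configuration
#'
#' @param n_replicas number of independent replicas per loss evaluation.
#' @param n_equil untraced equilibration outer steps per replica.
#' @param n_traced traced (differentiable) outer steps per replica.
#' @param stride frame stride for observable accumulation.
#' @param max_failures maximum fraction of failed replicas tolerated per
#'   evaluation before aborting.
#' @return list of class `hhpf_prs_config`.
#' @export
prs_config <- function(n_replicas = 40, n_equil = 2000, n_traced = 200,
                       stride = 1L, max_failures = 0.1) {
  stopifnot(n_replicas >= 1, n_traced >= 1)
  structure(list(n_replicas = as.integer(n_replicas),
                 n_equil = as.integer(n_equil),
                 n_traced = as.integer(n_traced),
                 stride = as.integer(stride), max_failures = max_failures),
            class = "hhpf_prs_config")
}

#' Optimizer configuration (adaptive "belief"-style update)
#'
#' @param eta learning rate.
#' @param b1,b2 first/second moment decay rates in (0, 1).
#' @param epochs number of training epochs.
#' @param eps numerical floor in the denominator.
#' @return list of class `hhpf_optimizer_config`.
#' @export
optimizer_config <- function(eta = 0.01, b1 = 0.1, b2 = 0.4, epochs = 600,
                             eps = 1e-12) {
  stopifnot(eta > 0, b1 > 0, b1 < 1, b2 > 0, b2 < 1)
  structure(list(eta = eta, b1 = b1, b2 = b2,
                 epochs = as.integer(epochs), eps = eps),
            class = "hhpf_optimizer_config")
}

# cubic confinement penalty over the upper triangle (including diagonal)
chi_constraint <- function(chi, dchi_max) {
  ut <- chi[upper.tri(chi, diag = TRUE)]
  ex <- pmax(abs(ut) - dchi_max, 0)
  sum(ex^3)
}

chi_constraint_grad <- function(chi, dchi_max) {
  g <- matrix(0, nrow(chi), ncol(chi))
  ex <- pmax(abs(chi) - dchi_max, 0)
  gu <- 3 * ex^2 * sign(chi)
  g[upper.tri(g, diag = TRUE)] <- gu[upper.tri(g, diag = TRUE)]
  # each unordered pair is one parameter counted once; mirror the value so
  # the returned matrix is symmetric
  g[lower.tri(g)] <- t(g)[lower.tri(g)]
  g
}

#' Replica loss
#'
#' Three-term loss of a single replica: mean squared density-profile error
#' per bin, squared area-per-lipid error, and the cubic chi confinement
#' penalty (see [loss_config()]).
#'
#' @param profile `hhpf_profile`, the time-averaged simulated profile on
#'   the reference bins.
#' @param apl time-averaged area per lipid, nm^2.
#' @param chi mixing matrix.
#' @param loss_cfg loss configuration.
#' @return scalar loss.
#' @export
replica_loss <- function(profile, apl, chi, loss_cfg) {
  L <- chi_constraint(chi, loss_cfg$dchi_max)
  ref <- loss_cfg$reference_profile
  if (!is.null(ref)) {
    if (length(profile$z) != length(ref$z) ||
        max(abs(profile$z - ref$z)) > 1e-9)
      stop("profile bins do not match the reference bins")
    nb <- length(ref$z)
    wt <- rep_len(loss_cfg$w_t, ncol(ref$rho))
    for (s in seq_len(ncol(ref$rho)))
      L <- L + (wt[s] / nb) * sum((profile$rho[, s] - ref$rho[, s])^2)
  }
  if (is.finite(loss_cfg$reference_apl) && loss_cfg$w_A > 0)
    L <- L + loss_cfg$w_A * (apl - loss_cfg$reference_apl)^2
  L
}

# loss + tangents given per-frame averaged observables and their tangents
replica_loss_jvp <- function(profile, apl, chi, loss_cfg, drho, dapl,
                             dchi) {
  dL <- sum(chi_constraint_grad(chi, loss_cfg$dchi_max) *
            dchi * upper_weight(chi))
  ref <- loss_cfg$reference_profile
  if (!is.null(ref)) {
    nb <- length(ref$z)
    wt <- rep_len(loss_cfg$w_t, ncol(ref$rho))
    for (s in seq_len(ncol(ref$rho)))
      dL <- dL + (wt[s] / nb) *
        sum(2 * (profile$rho[, s] - ref$rho[, s]) * drho[, s])
  }
  if (is.finite(loss_cfg$reference_apl) && loss_cfg$w_A > 0)
    dL <- dL + loss_cfg$w_A * 2 * (apl - loss_cfg$reference_apl) * dapl
  dL
}

# weight matrix turning a symmetric dchi direction into a sum over the
# upper triangle once per parameter
upper_weight <- function(chi) {
  w <- matrix(0, nrow(chi), ncol(chi))
  w[upper.tri(w, diag = TRUE)] <- 1
  w
}

#' Run one replica: equilibrate, trace, and evaluate the loss
#'
#' Runs `n_equil` untraced outer steps followed by `n_traced` steps with
#' tangent propagation (when gradients are requested), accumulating the
#' kernel density profile on the reference bins and the area per lipid at
#' every `stride`-th traced step, then applies the time average and the
#' replica loss.  A pure function of its inputs and `seed`: the same seed
#' yields a bitwise identical loss.
#'
#' @param system list with `state`, `topo` (from the fixture generators or
#'   file readers).
#' @param chi mixing matrix.
#' @param field_cfg,run_cfg,prs_cfg,loss_cfg configurations; `run_cfg`
#'   supplies the integrator and thermostat/barostat settings.
#' @param seed replica seed.
#' @param gradient logical: propagate tangents for the free chi entries
#'   and return the loss gradient.
#' @param free_pairs 2-column matrix of species index pairs (upper
#'   triangle) treated as free parameters; default all off-diagonal pairs.
#' @return list with `loss`, `grad` (S x S symmetric, zero outside the
#'   free pairs; NULL when `gradient = FALSE`), `profile`, `apl`, `state`.
#' @export
rollout_and_loss <- function(system, chi, field_cfg, run_cfg, prs_cfg,
                             loss_cfg, seed, gradient = FALSE,
                             free_pairs = NULL) {
  topo <- system$topo
  state <- system$state
  S <- nrow(chi)
  run_cfg$seed <- as.integer(seed)

  # untraced equilibration (phase 1)
  if (prs_cfg$n_equil > 0) {
    sim <- sim_init(state, topo, chi, field_cfg, run_cfg)
    for (i in seq_len(prs_cfg$n_equil)) {
      sim <- step_core(sim, topo, chi, field_cfg, run_cfg, phase = 1L,
                       istep = i - 1L)
      if (any(!is.finite(sim$state$R)))
        stop("non-finite positions at equilibration step ", i)
    }
    state <- sim$state
  }

  # tangent directions: one per free upper-triangle pair
  tans <- NULL
  if (gradient) {
    if (is.null(free_pairs)) free_pairs <- default_free_pairs(S)
    N <- nrow(state$R)
    tans <- lapply(seq_len(nrow(free_pairs)), function(p) {
      dchi <- matrix(0, S, S)
      dchi[free_pairs[p, 1], free_pairs[p, 2]] <- 1
      dchi[free_pairs[p, 2], free_pairs[p, 1]] <- 1
      list(R = matrix(0, N, 3), V = matrix(0, N, 3), box = c(0, 0, 0),
           chi = dchi)
    })
  }

  ref <- loss_cfg$reference_profile
  nb <- if (!is.null(ref)) length(ref$z) else 30L
  centers <- if (!is.null(ref)) ref$z else NULL
  h <- if (!is.null(loss_cfg$h)) loss_cfg$h else
    if (!is.null(ref)) ref$h else state$box[3] / nb

  sim <- sim_init(state, topo, chi, field_cfg, run_cfg, tans = tans)
  nt <- length(tans)
  prof_acc <- NULL
  dprof_acc <- NULL
  apl_acc <- 0
  dapl_acc <- numeric(max(nt, 1))
  nfr <- 0
  for (i in seq_len(prs_cfg$n_traced)) {
    sim <- step_core(sim, topo, chi, field_cfg, run_cfg, phase = 2L,
                     istep = i - 1L)
    st <- sim$state
    if (any(!is.finite(st$R)))
      stop("non-finite positions at traced step ", i)
    if (i %% prs_cfg$stride == 0) {
      nfr <- nfr + 1
      shift <- if (loss_cfg$center) lipid_midplane(st$R, topo) else 0
      ctr <- if (is.null(centers)) (seq_len(nb) - 0.5) * st$box[3] / nb
             else centers
      pr <- kde_profile_core(st$R[, 3] - shift, topo$particle_species,
                             st$box, ctr, h, S)
      prof_acc <- if (is.null(prof_acc)) pr else prof_acc + pr
      apl_acc <- apl_acc + if (topo$n_lipids >= 1)
        area_per_lipid(st$box, topo$n_lipids) else NA_real_
      if (nt) {
        sel <- topo$particle_mol %in% topo$lipid_mols
        msel <- topo$masses[sel]
        for (t in seq_len(nt)) {
          tn <- sim$tans[[t]]
          dshift <- if (loss_cfg$center && any(sel))
            sum(msel * tn$R[sel, 3]) / sum(msel) else 0
          dpr <- kde_profile_jvp(st$R[, 3] - shift, topo$particle_species,
                                 st$box, ctr, h, S, tn$R[, 3], tn$box,
                                 dshift)
          if (is.null(dprof_acc))
            dprof_acc <- vector("list", nt)
          dprof_acc[[t]] <- if (is.null(dprof_acc[[t]])) dpr
                            else dprof_acc[[t]] + dpr
          if (topo$n_lipids >= 1)
            dapl_acc[t] <- dapl_acc[t] +
              (tn$box[1] * st$box[2] + st$box[1] * tn$box[2]) /
                (topo$n_lipids / 2)
        }
      }
    }
  }
  if (nfr == 0) stop("no frames accumulated; check n_traced and stride")
  profile <- structure(list(
    z = if (is.null(centers)) (seq_len(nb) - 0.5) * sim$state$box[3] / nb
        else centers,
    rho = prof_acc / nfr, dz = if (!is.null(ref)) ref$dz else
      sim$state$box[3] / nb, h = h), class = "hhpf_profile")
  apl <- apl_acc / nfr

  loss <- replica_loss(profile, apl, chi, loss_cfg)
  grad <- NULL
  if (gradient) {
    grad <- matrix(0, S, S)
    for (t in seq_len(nt)) {
      dL <- replica_loss_jvp(profile, apl, chi, loss_cfg,
                             dprof_acc[[t]] / nfr, dapl_acc[t] / nfr,
                             tans[[t]]$chi)
      if (!is.finite(dL))
        stop("non-finite gradient for chi entry (",
             free_pairs[t, 1], ", ", free_pairs[t, 2], ")")
      grad[free_pairs[t, 1], free_pairs[t, 2]] <- dL
      grad[free_pairs[t, 2], free_pairs[t, 1]] <- dL
    }
  }
  list(loss = loss, grad = grad, profile = profile, apl = apl,
       state = sim$state)
}

default_free_pairs <- function(S) {
  p <- which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)
  unname(as.matrix(p[, c(1, 2), drop = FALSE]))
}

#' Gradient of the replica loss with respect to chi
#'
#' Tangent-mode derivative of [rollout_and_loss()] with respect to every
#' requested chi entry; the returned matrix is symmetric, each off-diagonal
#' slot holding the derivative with respect to the single shared parameter
#' `chi_lm = chi_ml`.
#'
#' @inheritParams rollout_and_loss
#' @param include_diagonal also differentiate the diagonal entries.
#' @return S x S symmetric gradient matrix.
#' @export
loss_gradient <- function(system, chi, field_cfg, run_cfg, prs_cfg,
                          loss_cfg, seed, free_pairs = NULL,
                          include_diagonal = FALSE) {
  S <- nrow(chi)
  if (is.null(free_pairs)) {
    free_pairs <- default_free_pairs(S)
    if (include_diagonal)
      free_pairs <- rbind(free_pairs, cbind(seq_len(S), seq_len(S)))
  }
  rollout_and_loss(system, chi, field_cfg, run_cfg, prs_cfg, loss_cfg,
                   seed, gradient = TRUE, free_pairs = free_pairs)$grad
}

#' Average replica losses and gradients
#'
#' Arithmetic means over a set of independent replicas.  Failed replicas
#' (entries that are `NULL` or carry a `condition`) are dropped with a
#' warning up to `max_failures`; beyond that the bundle evaluation aborts.
#'
#' @param results list of [rollout_and_loss()] results (possibly including
#'   failures).
#' @param max_failures tolerated failure fraction.
#' @return list with `loss` (mean), `grad` (mean matrix or NULL),
#'   `losses`, `grads`, `n_failed`.
#' @export
prs_mean <- function(results, max_failures = 0.1) {
  ok <- !vapply(results, function(r)
    is.null(r) || inherits(r, "condition"), logical(1))
  n_failed <- sum(!ok)
  if (n_failed > max_failures * length(results))
    stop(n_failed, " of ", length(results), " replicas failed")
  if (n_failed > 0)
    warning(n_failed, " replica(s) failed; averaging over the rest")
  results <- results[ok]
  losses <- vapply(results, `[[`, numeric(1), "loss")
  grads <- lapply(results, `[[`, "grad")
  grad <- if (!is.null(grads[[1]]))
    Reduce(`+`, grads) / length(grads) else NULL
  list(loss = mean(losses), grad = grad, losses = losses, grads = grads,
       n_failed = n_failed)
}

#' Mean loss over several systems
#'
#' @param losses numeric vector of per-system PRS losses.
#' @return scalar mean.
#' @export
multi_system_mean <- function(losses) mean(losses)

# ---- optimizer ------------------------------------------------------------

#' Initialise the optimizer state
#'
#' @param chi mixing matrix (shape template).
#' @return optimizer state (first/second moment matrices and step count).
#' @export
adabelief_init <- function(chi) {
  list(m = matrix(0, nrow(chi), ncol(chi)),
       s = matrix(0, nrow(chi), ncol(chi)), step = 0L)
}

#' Adaptive "belief"-style optimizer update
#'
#' First moment of the gradient, second moment of the gradient's deviation
#' from the first moment, both bias-corrected:
#' `m <- b1 m + (1 - b1) g`, `s <- b2 s + (1 - b2) (g - m)^2`,
#' `theta <- theta - eta * mhat / (sqrt(shat) + eps)`.
#' Symmetry of chi is preserved exactly for symmetric gradients.
#'
#' @param chi current mixing matrix.
#' @param grad symmetric gradient matrix.
#' @param opt_state state from [adabelief_init()] or a previous call.
#' @param optimizer_cfg configuration.
#' @return list with updated `chi` and `opt_state`.
#' @export
optimizer_update <- function(chi, grad, opt_state, optimizer_cfg) {
  b1 <- optimizer_cfg$b1
  b2 <- optimizer_cfg$b2
  opt_state$step <- opt_state$step + 1L
  opt_state$m <- b1 * opt_state$m + (1 - b1) * grad
  opt_state$s <- b2 * opt_state$s + (1 - b2) * (grad - opt_state$m)^2
  mhat <- opt_state$m / (1 - b1^opt_state$step)
  shat <- opt_state$s / (1 - b2^opt_state$step)
  chi <- chi - optimizer_cfg$eta * mhat /
    (sqrt(shat) + optimizer_cfg$eps)
  list(chi = chi, opt_state = opt_state)
}

# ---- training driver ------------------------------------------------------

#' Train the chi matrix against reference data
#'
#' Per epoch and per system, `n_replicas` independent replicas are spawned
#' from the system's initial structure with distinct counter-derived
#' seeds; each runs an untraced equilibration followed by a traced
#' sampling segment, and returns its loss and chi gradient.  Replica
#' results are averaged (PRS), system means are averaged again, and a
#' single optimizer update is applied to the shared chi.
#'
#' @param systems list of systems; each a list with `state`, `topo`,
#'   `loss_cfg` (per-system references) and optionally `run_cfg`.
#' @param chi initial mixing matrix.
#' @param field_cfg field configuration.
#' @param run_cfg default run configuration.
#' @param prs_cfg replica configuration.
#' @param optimizer_cfg optimizer configuration.
#' @param free_pairs free chi entries (upper-triangle index pairs);
#'   default all off-diagonal pairs.
#' @param seed master seed; replica seeds are derived from
#'   (seed, epoch, system, replica).
#' @param checkpoint optional resume state from a previous run's
#'   `checkpoint` element.
#' @param epochs number of epochs (default from `optimizer_cfg`).
#' @param verbose print per-epoch loss lines.
#' @return list with `chi`, `history` (data.frame epoch/system/loss/apl),
#'   `checkpoint` (chi, optimizer state, epoch).
#' @export
train_chi <- function(systems, chi, field_cfg, run_cfg, prs_cfg,
                      optimizer_cfg, free_pairs = NULL, seed = 1L,
                      checkpoint = NULL, epochs = optimizer_cfg$epochs,
                      verbose = FALSE) {
  S <- nrow(chi)
  if (is.null(free_pairs)) free_pairs <- default_free_pairs(S)
  opt_state <- adabelief_init(chi)
  epoch0 <- 0L
  if (!is.null(checkpoint)) {
    chi <- checkpoint$chi
    opt_state <- checkpoint$opt_state
    epoch0 <- checkpoint$epoch
  }
  hist <- list()
  for (ep in seq_len(epochs)) {
    epoch <- epoch0 + ep
    sys_loss <- numeric(length(systems))
    sys_apl <- numeric(length(systems))
    grads <- vector("list", length(systems))
    for (sy in seq_along(systems)) {
      system <- systems[[sy]]
      rc <- if (!is.null(system$run_cfg)) system$run_cfg else run_cfg
      res <- lapply(seq_len(prs_cfg$n_replicas), function(r) {
        sd <- rng_stream_seed(seed, 7L,
                              (epoch - 1L) * 1000L + sy * 100L + r)
        tryCatch(
          rollout_and_loss(system, chi, field_cfg, rc, prs_cfg,
                           system$loss_cfg, seed = sd, gradient = TRUE,
                           free_pairs = free_pairs),
          error = function(e) e)
      })
      bundle <- prs_mean(res, prs_cfg$max_failures)
      sys_loss[sy] <- bundle$loss
      grads[[sy]] <- bundle$grad
      ok <- !vapply(res, inherits, logical(1), "condition")
      sys_apl[sy] <- mean(vapply(res[ok], `[[`, numeric(1), "apl"))
    }
    mean_grad <- Reduce(`+`, grads) / length(grads)
    if (any(!is.finite(mean_grad)))
      stop("non-finite mean gradient at epoch ", epoch)
    up <- optimizer_update(chi, mean_grad, opt_state, optimizer_cfg)
    chi <- up$chi
    opt_state <- up$opt_state
    hist[[ep]] <- data.frame(epoch = epoch,
                             system = seq_along(systems),
                             loss = sys_loss, apl = sys_apl,
                             mean_loss = multi_system_mean(sys_loss))
    if (verbose)
      message(sprintf("epoch %d  mean loss %.6g", epoch,
                      multi_system_mean(sys_loss)))
  }
  history <- if (length(hist)) do.call(rbind, hist) else
    data.frame(epoch = integer(), system = integer(), loss = numeric(),
               apl = numeric(), mean_loss = numeric())
  list(chi = chi, history = history,
       checkpoint = list(chi = chi, opt_state = opt_state,
                         epoch = epoch0 + epochs))
}
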