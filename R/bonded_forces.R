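# Intramolecular bonded terms: harmonic bonds and (cosine-)harmonic
# angles.  Distances use the minimum-image convention, so molecules are
# never unwrapped; forces are the exact gradients of the energies and the
# Clausius virial is accumulated alongside.

#' Harmonic bond energy and forces
#'
#' `U = sum_b 1/2 k_b (r_b - r0_b)^2` over minimum-image bond vectors.
#'
#' @param state system state.
#' @param topo topology (uses `topo$bonds`).
#' @return list with `energy` (kJ/mol), `forces` (N x 3) and `virial`
#'   (3 x 3, kJ/mol).
#' @export
bond_energy_forces <- function(state, topo) {
  b <- topo$bonds
  if (!nrow(b)) {
    n <- nrow(state$R)
    return(list(energy = 0, forces = matrix(0, n, 3),
                virial = matrix(0, 3, 3)))
  }
  bond_ef_cpp(state$R, state$box, as.integer(b$i), as.integer(b$j),
              as.numeric(b$r0), as.numeric(b$k))
}

#' Angle energy and forces
#'
#' Cosine-harmonic by default, `U = sum 1/2 k (cos(theta) -
#' cos(theta0))^2`; the plain harmonic-in-theta form is selected by
#' `topo$angle_form == "harmonic"`.  Per-angle force triplets sum to zero.
#'
#' @param state system state.
#' @param topo topology (uses `topo$angles`; `theta0` in degrees).
#' @return list with `energy`, `forces`, `virial`.
#' @export
angle_energy_forces <- function(state, topo) {
  a <- topo$angles
  if (!nrow(a)) {
    n <- nrow(state$R)
    return(list(energy = 0, forces = matrix(0, n, 3),
                virial = matrix(0, 3, 3)))
  }
  th <- a$theta0 * pi / 180
  if (topo$angle_form == "cosharm") {
    angle_ef_cpp(state$R, state$box, as.integer(a$i), as.integer(a$j),
                 as.integer(a$k), cos(th), as.numeric(a$fc), 1L)
  } else {
    angle_ef_cpp(state$R, state$box, as.integer(a$i), as.integer(a$j),
                 as.integer(a$k), th, as.numeric(a$fc), 2L)
  }
}

# Combined bonded evaluation with optional tangents.  tans: list of
# tangents (R, box); returns energy/forces/virial and their directional
# derivatives.  Only the cosine-harmonic angle form is differentiable.
bonded_eval <- function(R, box, topo, tans = NULL) {
  n <- nrow(R)
  b <- topo$bonds
  a <- topo$angles
  U <- 0
  F <- matrix(0, n, 3)
  vir <- matrix(0, 3, 3)
  if (nrow(b)) {
    be <- bond_ef_cpp(R, box, as.integer(b$i), as.integer(b$j),
                      as.numeric(b$r0), as.numeric(b$k))
    U <- U + be$energy; F <- F + be$forces; vir <- vir + be$virial
  }
  Ub <- U
  virb <- vir
  if (nrow(a)) {
    th <- a$theta0 * pi / 180
    form <- if (topo$angle_form == "cosharm") 1L else 2L
    t0 <- if (form == 1L) cos(th) else th
    ae <- angle_ef_cpp(R, box, as.integer(a$i), as.integer(a$j),
                       as.integer(a$k), t0, as.numeric(a$fc), form)
    U <- U + ae$energy; F <- F + ae$forces; vir <- vir + ae$virial
  }
  out <- list(energy = U, forces = F, virial = vir,
              bond_energy = Ub, bond_virial = virb,
              angle_virial = vir - virb)
  if (!is.null(tans)) {
    if (nrow(a) && topo$angle_form != "cosharm")
      stop("tangent propagation requires the cosine-harmonic angle form")
    nt <- length(tans)
    out$dU <- numeric(nt)
    out$dF <- vector("list", nt)
    out$dvir <- vector("list", nt)
    for (t in seq_len(nt)) {
      tn <- tans[[t]]
      dR <- if (is.null(tn$R)) zero_tan_matrix else tn$R
      dbox <- if (is.null(tn$box)) c(0, 0, 0) else tn$box
      dU <- 0
      dF <- matrix(0, n, 3)
      dvir <- matrix(0, 3, 3)
      if (nrow(b)) {
        je <- bond_ef_jvp_cpp(R, dR, box, dbox, as.integer(b$i),
                              as.integer(b$j), as.numeric(b$r0),
                              as.numeric(b$k))
        dU <- dU + je$energy; dF <- dF + je$forces; dvir <- dvir + je$virial
      }
      if (nrow(a)) {
        th <- a$theta0 * pi / 180
        ja <- angle_ef_jvp_cpp(R, dR, box, dbox, as.integer(a$i),
                               as.integer(a$j), as.integer(a$k), cos(th),
                               as.numeric(a$fc))
        dU <- dU + ja$energy; dF <- dF + ja$forces; dvir <- dvir + ja$virial
      }
      out$dU[t] <- dU
      out$dF[[t]] <- dF
      out$dvir[[t]] <- dvir
    }
  }
  out
}
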