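# Observables: differentiable Gaussian-kernel lateral density profiles,
# area per lipid, trajectory time averages, and slab-resolved lateral
# pressure profiles.

#' Gaussian-kernel lateral density profile
#'
#' Differentiable replacement for the z-histogram: each particle
#' contributes a Gaussian of bandwidth `h` (wrapped periodically along z),
#' and the per-species profile is evaluated at the bin centers
#' `z_b`:
#' `rho_T(z_b) = 1/(Lx Ly) sum_{i in T} sum_n N(z_b; z_i + n Lz, h)`.
#' The normalisation `sum_b rho_T(z_b) dz * Lx * Ly ~= N_T` holds to the
#' kernel-tail truncation (images within 5h are included).
#'
#' @param positions N x 3 matrix, nm.
#' @param species_idx species index per particle.
#' @param box box lengths, nm.
#' @param n_b number of bins (>= 2).
#' @param h Gaussian bandwidth, nm.
#' @param centers optional bin centers, nm; defaults to the `n_b` cell
#'   midpoints of `[0, Lz)`.  Supplying reference centers keeps profiles
#'   comparable when the box fluctuates.
#' @param nspecies number of species.
#' @param shift subtracted from all z before binning (e.g. the bilayer
#'   midplane), nm.
#' @return object of class `hhpf_profile`: list with `z` (bin centers),
#'   `rho` (n_b x S matrix, nm^-3), `dz`, `h`.
#' @export
kde_density_profile <- function(positions, species_idx, box, n_b = 30,
                                h = NULL, centers = NULL,
                                nspecies = max(species_idx), shift = 0) {
  stopifnot(n_b >= 2)
  Lz <- box[3]
  dz <- Lz / n_b
  if (is.null(h)) h <- dz
  stopifnot(h > 0)
  if (is.null(centers)) centers <- (seq_len(n_b) - 0.5) * dz
  pr <- kde_profile_core(positions[, 3] - shift, species_idx, box, centers,
                         h, nspecies)
  structure(list(z = centers, rho = pr, dz = dz, h = h),
            class = "hhpf_profile")
}

# value core: z (length N), returns n_b x S matrix
kde_profile_core <- function(z, species_idx, box, centers, h, nspecies) {
  nb <- length(centers)
  area <- box[1] * box[2]
  Lz <- box[3]
  nimg <- ceiling(5 * h / Lz)
  imgs <- (-nimg):nimg
  norm <- 1 / (sqrt(2 * pi) * h * area)
  rho <- matrix(0, nb, nspecies)
  for (s in seq_len(nspecies)) {
    zs <- z[species_idx == s]
    if (!length(zs)) next
    acc <- numeric(nb)
    for (n in imgs) {
      d <- outer(centers, zs + n * Lz, "-")
      # wrap the difference itself into [-Lz/2, Lz/2) before imaging is
      # wrong for kernels wider than the box; plain imaging is exact
      acc <- acc + rowSums(exp(-d^2 / (2 * h^2)))
    }
    rho[, s] <- norm * acc
  }
  rho
}

# value + tangents; tangent inputs: dz_part (per-particle z tangent, may be
# NULL), dbox (length 3 or NULL), dshift scalar.  Centers are treated as
# fixed reference bins.
kde_profile_jvp <- function(z, species_idx, box, centers, h, nspecies,
                            dz_part, dbox, dshift = 0) {
  nb <- length(centers)
  area <- box[1] * box[2]
  Lz <- box[3]
  nimg <- ceiling(5 * h / Lz)
  imgs <- (-nimg):nimg
  norm <- 1 / (sqrt(2 * pi) * h * area)
  if (is.null(dbox)) dbox <- c(0, 0, 0)
  darea_rel <- dbox[1] / box[1] + dbox[2] / box[2]
  drho <- matrix(0, nb, nspecies)
  for (s in seq_len(nspecies)) {
    sel <- species_idx == s
    zs <- z[sel]
    if (!length(zs)) next
    dzs <- if (is.null(dz_part)) rep(0, length(zs)) else dz_part[sel]
    dzs <- dzs - dshift
    acc <- numeric(nb)
    accv <- numeric(nb)
    for (n in imgs) {
      d <- outer(centers, zs + n * Lz, "-")
      e <- exp(-d^2 / (2 * h^2))
      acc <- acc + rowSums(e)
      # d(arg)/dtheta = -(dzs + n dLz); d e = e * (-d/h^2) * d(arg)
      accv <- accv + (e * (-d / h^2)) %*% (-(dzs + n * dbox[3]))
    }
    drho[, s] <- norm * accv - norm * acc * darea_rel
  }
  drho
}

#' Area per lipid
#'
#' `A_L = Lx * Ly / (N_lipids / 2)`, assuming the lipids are evenly split
#' between the two leaflets.
#'
#' @param box box lengths, nm.
#' @param n_lipids total number of lipid molecules (>= 2, even).
#' @return scalar area, nm^2.
#' @export
area_per_lipid <- function(box, n_lipids) {
  if (n_lipids < 1) stop("area per lipid undefined without lipids")
  box[1] * box[2] / (n_lipids / 2)
}

#' Time average over trajectory frames
#'
#' Arithmetic mean of per-frame observable values (scalars, vectors or
#' matrices of a common shape).
#'
#' @param values list of per-frame values, or a numeric vector.
#' @return the mean value.
#' @export
time_average <- function(values) {
  if (is.numeric(values)) return(mean(values))
  stopifnot(length(values) >= 1)
  Reduce(`+`, values) / length(values)
}

# bilayer midplane: mass-weighted mean z of lipid-molecule particles
lipid_midplane <- function(R, topo) {
  sel <- topo$particle_mol %in% topo$lipid_mols
  if (!any(sel)) return(0)
  sum(topo$masses[sel] * R[sel, 3]) / sum(topo$masses[sel])
}

# ---- lateral pressure profile --------------------------------------------

# Spread a per-bond virial contribution uniformly over the slabs traversed
# by the minimum-image segment between z1 and z2 (Harasima-style equal
# split).  Returns a length-n_slabs weight vector summing to 1.
harasima_weights <- function(z1, z2, Lz, n_slabs) {
  dz <- z2 - z1
  dz <- dz - round(dz / Lz) * Lz
  zlo <- z1
  zhi <- z1 + dz
  if (zlo > zhi) { tmp <- zlo; zlo <- zhi; zhi <- tmp }
  w <- numeric(n_slabs)
  hs <- Lz / n_slabs
  if (zhi - zlo < 1e-12) {
    i <- floor((zlo %% Lz) / hs) %% n_slabs
    w[i + 1] <- 1
    return(w)
  }
  # walk the slab boundaries crossed by [zlo, zhi] (may wrap)
  span <- zhi - zlo
  i0 <- floor(zlo / hs)
  i1 <- floor(zhi / hs)
  for (i in i0:i1) {
    lo <- max(zlo, i * hs)
    hi <- min(zhi, (i + 1) * hs)
    if (hi > lo) {
      idx <- (i %% n_slabs + n_slabs) %% n_slabs
      w[idx + 1] <- w[idx + 1] + (hi - lo) / span
    }
  }
  w
}

#' Lateral pressure profile
#'
#' Slab-resolved difference between the normal and lateral pressure,
#' `dP(z) = P_N(z) - P_L(z)`, time-averaged over a trajectory segment.
#' The kinetic term is binned by particle position; bond and angle virials
#' are split equally over the slabs traversed by the minimum-image segment
#' between the interacting particles (Harasima convention; the apex-to-end
#' vectors for angles); the field term uses the per-cell decomposition of
#' the box-strain derivative of the interaction functional, accumulated
#' into the slab containing each cell center.  Slab sums reproduce the
#' global pressure tensor difference by construction.
#'
#' @param frames list of states (a trajectory segment, all with the same
#'   box), or a single state.
#' @param topo topology.
#' @param chi mixing matrix.
#' @param field_cfg field configuration.
#' @param n_slabs number of z slabs (>= 4).
#' @return object of class `hhpf_pressure_profile`: list with `z` (slab
#'   centers), `dP` (bar), and per-term columns `field`, `bond`, `angle`,
#'   `kinetic` summing to `dP`.
#' @export
lateral_pressure_profile <- function(frames, topo, chi, field_cfg,
                                     n_slabs = 30) {
  stopifnot(n_slabs >= 4)
  if (inherits(frames, "hhpf_state")) frames <- list(frames)
  nf <- length(frames)
  box <- frames[[1]]$box
  Lz <- box[3]
  hs <- Lz / n_slabs
  vol_slab <- box[1] * box[2] * hs
  terms <- c("kinetic", "bond", "angle", "field")
  acc <- sapply(terms, function(t) matrix(0, n_slabs, 2),
                simplify = FALSE) # [, 1] lateral sum-xx+yy/2, [, 2] normal
  for (fr in frames) {
    R <- fr$R
    V <- fr$V
    # kinetic
    zi <- (floor((R[, 3] %% Lz) / hs) %% n_slabs) + 1
    kxx <- topo$masses * V[, 1]^2
    kyy <- topo$masses * V[, 2]^2
    kzz <- topo$masses * V[, 3]^2
    for (i in seq_along(zi)) {
      acc$kinetic[zi[i], 1] <- acc$kinetic[zi[i], 1] + (kxx[i] + kyy[i]) / 2
      acc$kinetic[zi[i], 2] <- acc$kinetic[zi[i], 2] + kzz[i]
    }
    # bonds
    b <- topo$bonds
    if (nrow(b)) {
      for (q in seq_len(nrow(b))) {
        i <- b$i[q]; j <- b$j[q]
        d <- R[i, ] - R[j, ]
        d <- d - round(d / box) * box
        r <- sqrt(sum(d^2))
        A <- -b$k[q] * (r - b$r0[q]) / r
        fi <- A * d
        w <- harasima_weights(R[j, 3], R[j, 3] + d[3], Lz, n_slabs)
        lat <- (fi[1] * d[1] + fi[2] * d[2]) / 2
        nor <- fi[3] * d[3]
        acc$bond[, 1] <- acc$bond[, 1] + w * lat
        acc$bond[, 2] <- acc$bond[, 2] + w * nor
      }
    }
    # angles: virial fi (x) u + fk (x) v, each spread along its own leg
    a <- topo$angles
    if (nrow(a)) {
      th <- a$theta0 * pi / 180
      form <- if (topo$angle_form == "cosharm") 1L else 2L
      t0 <- if (form == 1L) cos(th) else th
      for (q in seq_len(nrow(a))) {
        i <- a$i[q]; j <- a$j[q]; k <- a$k[q]
        u <- R[i, ] - R[j, ]; u <- u - round(u / box) * box
        v <- R[k, ] - R[j, ]; v <- v - round(v / box) * box
        nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
        cth <- sum(u * v) / (nu * nv)
        pref <- if (form == 1L) a$fc[q] * (cth - t0[q]) else {
          s <- sqrt(max(1 - cth^2, 1e-12)); -a$fc[q] * (acos(cth) - t0[q]) / s
        }
        fi <- -pref * (v / (nu * nv) - cth * u / nu^2)
        fk <- -pref * (u / (nu * nv) - cth * v / nv^2)
        wu <- harasima_weights(R[j, 3], R[j, 3] + u[3], Lz, n_slabs)
        wv <- harasima_weights(R[j, 3], R[j, 3] + v[3], Lz, n_slabs)
        acc$angle[, 1] <- acc$angle[, 1] +
          wu * (fi[1] * u[1] + fi[2] * u[2]) / 2 +
          wv * (fk[1] * v[1] + fk[2] * v[2]) / 2
        acc$angle[, 2] <- acc$angle[, 2] + wu * fi[3] * u[3] +
          wv * fk[3] * v[3]
      }
    }
    # field: per-cell stress decomposition of -dW/deps
    fe <- field_eval(R, topo$particle_species, box, chi, field_cfg,
                     forces = FALSE, virial = TRUE, percell = TRUE)
    sc <- fe$stress_cells
    if (field_cfg$coulomb && any(topo$charges != 0)) {
      ee <- elec_eval(R, topo$charges, box, field_cfg$grid,
                      field_cfg$sigma, field_cfg$epsr,
                      field_cfg$order %||% 2L, forces = FALSE,
                      virial = TRUE, percell = TRUE)
      sc <- sc + ee$stress_cells
    }
    dims <- field_cfg$grid
    zcell <- (rep(seq_len(dims[3]), each = dims[1] * dims[2]) - 0.5) *
      Lz / dims[3]
    slab_of_cell <- (floor(zcell / hs) %% n_slabs) + 1
    for (sl in seq_len(n_slabs)) {
      sel <- slab_of_cell == sl
      lat <- -(sum(sc[sel, 1]) + sum(sc[sel, 2])) / 2
      nor <- -sum(sc[sel, 3])
      acc$field[sl, 1] <- acc$field[sl, 1] + lat
      acc$field[sl, 2] <- acc$field[sl, 2] + nor
    }
  }
  to_bar <- PRESSURE_FACTOR / (vol_slab * nf)
  per_term <- sapply(terms, function(t)
    (acc[[t]][, 2] - acc[[t]][, 1]) * to_bar)
  dP <- rowSums(per_term)
  structure(list(z = (seq_len(n_slabs) - 0.5) * hs, dP = dP,
                 kinetic = per_term[, "kinetic"],
                 bond = per_term[, "bond"], angle = per_term[, "angle"],
                 field = per_term[, "field"], dz = hs),
            class = "hhpf_pressure_profile")
}
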