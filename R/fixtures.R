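# Programmatic toy systems and self-consistent reference data.  The toy
# lipid is a deliberate minimal caricature -- a 4-bead head/tail chain with
# generic bonded constants -- built to exercise the particle-field
# machinery, not to reproduce any published coarse-grained mapping.  Toy
# bead densities are chosen commensurate with the field calibration
# density `a`, so that constant-pressure runs are mechanically stable.

#' Build a toy lipid bilayer
#'
#' A 4-bead model lipid (1 head bead H, 3 tail beads T; bonds H-T, T-T,
#' T-T at r0 = 0.47 nm, k = 1250 kJ mol^-1 nm^-2; two straight angles at
#' k = 25 kJ/mol) arranged in two opposing leaflets on a lattice around
#' the box midplane, with water beads W filling the remaining volume.  The
#' charged variant gives heads charge -1 and adds one +1 counterion bead
#' per lipid (net charge zero).  All beads have mass 72 u.  Deterministic
#' given the seed.
#'
#' @param n_lipids even number of lipids (split over two leaflets).
#' @param n_water number of water beads.
#' @param box box lengths, nm.
#' @param seed integer seed for jitter and velocities.
#' @param charged logical, charged-head variant.
#' @param temperature Maxwell-Boltzmann velocity temperature, K.
#' @return list with `topo` and `state`.
#' @export
make_toy_lipid_bilayer <- function(n_lipids = 40, n_water = 400,
                                   box = c(4, 4, 5), seed = 1,
                                   charged = FALSE, temperature = 323) {
  if (n_lipids %% 2 != 0) stop("n_lipids must be even")
  nl2 <- n_lipids / 2
  nxy <- ceiling(sqrt(nl2))
  if (nxy * 0.6 > min(box[1], box[2]))
    stop("box too small for the requested lipid count")
  r0 <- 0.47
  zmid <- box[3] / 2
  set.seed(seed)

  sp_names <- c("H", "T", "W")
  sp_charge <- c(0, 0, 0)
  if (charged) {
    sp_names <- c(sp_names, "ION")
    sp_charge <- c(-1, 0, 0, 1)
  }
  species <- species_table(sp_names, sp_charge)

  pos <- list()
  spec <- integer()
  mol <- integer()
  bonds <- list()
  angles <- list()
  ax <- box[1] / nxy
  ay <- box[2] / ceiling(nl2 / nxy)
  idx <- 0
  for (leaf in 0:1) {
    sgn <- if (leaf == 0) -1 else 1
    for (l in seq_len(nl2)) {
      gx <- (l - 1) %% nxy
      gy <- (l - 1) %/% nxy
      x <- (gx + 0.5) * ax + rnorm(1, 0, 0.05)
      y <- (gy + 0.5) * ay + rnorm(1, 0, 0.05)
      # head farthest from the midplane, tails reaching toward it
      z0 <- zmid + sgn * (0.25 + 3 * r0)
      zs <- z0 - sgn * r0 * (0:3)
      p <- cbind(x + rnorm(4, 0, 0.02), y + rnorm(4, 0, 0.02), zs)
      pos[[length(pos) + 1]] <- p
      spec <- c(spec, c(1L, 2L, 2L, 2L))
      molid <- leaf * nl2 + l
      mol <- c(mol, rep(molid, 4))
      bonds[[length(bonds) + 1]] <-
        data.frame(i = idx + 1:3, j = idx + 2:4, r0 = r0, k = 1250)
      angles[[length(angles) + 1]] <-
        data.frame(i = idx + c(1, 2), j = idx + c(2, 3), k = idx + c(3, 4),
                   theta0 = 180, fc = 25)
      idx <- idx + 4
    }
  }
  # waters: uniform outside the tail core |z - zmid| < 1.2 nm
  wz <- numeric(0)
  while (length(wz) < n_water) {
    cand <- runif(2 * n_water, 0, box[3])
    cand <- cand[abs(cand - zmid) > 1.2]
    wz <- c(wz, cand)
  }
  wz <- wz[seq_len(n_water)]
  wpos <- cbind(runif(n_water, 0, box[1]), runif(n_water, 0, box[2]), wz)
  pos[[length(pos) + 1]] <- wpos
  spec <- c(spec, rep(3L, n_water))
  mol <- c(mol, n_lipids + seq_len(n_water))
  n_ion <- 0
  if (charged) {
    n_ion <- n_lipids
    iz <- numeric(0)
    while (length(iz) < n_ion) {
      cand <- runif(2 * n_ion, 0, box[3])
      cand <- cand[abs(cand - zmid) > 1.2]
      iz <- c(iz, cand)
    }
    iz <- iz[seq_len(n_ion)]
    pos[[length(pos) + 1]] <- cbind(runif(n_ion, 0, box[1]),
                                    runif(n_ion, 0, box[2]), iz)
    spec <- c(spec, rep(4L, n_ion))
    mol <- c(mol, n_lipids + n_water + seq_len(n_ion))
  }
  R <- do.call(rbind, pos)
  N <- nrow(R)
  topo <- topology(species, spec, mol, masses = 72,
                   bonds = do.call(rbind, bonds),
                   angles = do.call(rbind, angles),
                   n_lipids = n_lipids, lipid_mols = seq_len(n_lipids))
  V <- matrix(rnorm(N * 3, 0, sqrt(KB * temperature / 72)), N, 3)
  V <- sweep(V, 2, colMeans(V)) # zero net momentum
  state <- wrap_positions(system_state(R, V, box))
  list(topo = topo, state = state)
}

#' Build a homogeneous single-species fluid
#'
#' Unbonded beads of one species on uniform random positions with
#' Maxwell-Boltzmann velocities; used for thermostat and pressure checks.
#'
#' @param n number of beads.
#' @param box box lengths, nm.
#' @param seed integer seed.
#' @param temperature velocity temperature, K.
#' @param mass bead mass, u.
#' @return list with `topo` and `state`.
#' @export
make_homogeneous_fluid <- function(n = 100, box = c(4, 4, 4), seed = 1,
                                   temperature = 323, mass = 72) {
  set.seed(seed)
  R <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
  V <- matrix(rnorm(n * 3, 0, sqrt(KB * temperature / mass)), n, 3)
  V <- sweep(V, 2, colMeans(V))
  topo <- topology(species_table("W"), rep(1L, n), seq_len(n),
                   masses = mass)
  list(topo = topo, state = system_state(R, V, box))
}

#' Named fixture presets
#'
#' Bundles a toy system with matched field/run configurations and a
#' stable starting chi matrix.  The field calibration density `a` is set
#' to the fixture's actual bead density so that the incompressibility term
#' is balanced at the starting volume.
#'
#' All presets use the quadratic assignment window (`order = 3`), whose
#' exact-gradient forces are continuous and keep long constant-energy
#' segments drift-free.
#'
#' Presets: `"toy-bilayer"` (40 lipids + 400 waters, 4 x 4 x 5 nm, 6^3
#' grid), `"toy-bilayer-charged"` (anionic heads + counterions),
#' `"mini-bilayer"` (20 lipids + 204 waters, 3 x 3 x 4.5 nm; the
#' parameter-recovery workhorse) and `"fluid"` (homogeneous single
#' species).
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return list with `topo`, `state`, `field_cfg`, `run_cfg`, `chi`.
#' @export
fixture_preset <- function(name = c("toy-bilayer", "toy-bilayer-charged",
                                    "mini-bilayer", "fluid"), seed = 1) {
  name <- match.arg(name)
  chi_pairs <- data.frame(a = c("H", "H", "T"), b = c("T", "W", "W"),
                          chi = c(10, -5, 30))
  if (name == "fluid") {
    fx <- make_homogeneous_fluid(448, box = c(4, 4, 4), seed = seed)
    fcfg <- field_config(grid = c(6, 6, 6), a = 7, coulomb = FALSE,
                         order = 3)
    chi <- chi_matrix(fx$topo$species)
  } else if (name == "mini-bilayer") {
    fx <- make_toy_lipid_bilayer(20, 204, box = c(3, 3, 4.5), seed = seed)
    fcfg <- field_config(grid = c(6, 6, 6), a = 7, coulomb = FALSE,
                         order = 3)
    chi <- chi_matrix(fx$topo$species, chi_pairs)
  } else {
    charged <- name == "toy-bilayer-charged"
    fx <- make_toy_lipid_bilayer(40, 400, box = c(4, 4, 5), seed = seed,
                                 charged = charged)
    n <- length(fx$topo$particle_species)
    fcfg <- field_config(grid = c(6, 6, 6),
                         a = round(n / prod(fx$state$box), 2),
                         coulomb = charged, order = 3)
    chi <- chi_matrix(fx$topo$species, chi_pairs)
  }
  rcfg <- run_config(n_equil = 200, n_traced = 50, seed = seed)
  list(name = name, topo = fx$topo, state = fx$state, field_cfg = fcfg,
       run_cfg = rcfg, chi = chi)
}

#' Generate self-consistent reference data
#'
#' Runs a forward simulation at a known chi, accumulates the time-averaged
#' kernel density profile and area per lipid over the sampled segment, and
#' optionally writes the profile in the tab-separated reference format.
#' Feeding these references back to the optimizer yields a closed-loop
#' parameter-recovery task whose solution is the generating chi.
#'
#' @param system list with `state`, `topo`.
#' @param chi_star generating mixing matrix.
#' @param field_cfg,run_cfg,prs_cfg configurations (`prs_cfg` supplies the
#'   equilibration/sampling lengths).
#' @param n_b number of profile bins.
#' @param h profile bandwidth, nm.
#' @param seed replica seed.
#' @param path optional TSV output path for the profile.
#' @param center center profiles on the lipid midplane.
#' @return list with `profile` (`hhpf_profile`), `apl`, and the final
#'   `state`.
#' @export
make_reference_data <- function(system, chi_star, field_cfg, run_cfg,
                                prs_cfg, n_b = 30, h = NULL, seed = 1,
                                path = NULL, center = TRUE) {
  Lz <- system$state$box[3]
  dz <- Lz / n_b
  if (is.null(h)) h <- dz
  centers <- (seq_len(n_b) - 0.5) * dz
  template <- structure(list(z = centers,
                             rho = matrix(0, n_b,
                                          nrow(system$topo$species)),
                             dz = dz, h = h), class = "hhpf_profile")
  lcfg <- loss_config(reference_profile = template, reference_apl = NA,
                      h = h, center = center)
  res <- rollout_and_loss(system, chi_star, field_cfg, run_cfg, prs_cfg,
                          lcfg, seed = seed, gradient = FALSE)
  prof <- res$profile
  if (!is.null(path))
    write_profile_tsv(prof, path, system$topo$species$name)
  list(profile = prof, apl = res$apl, state = res$state)
}
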