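# Shared test fixtures and independent oracle implementations.  The
# oracles deliberately re-derive every quantity from the defining formulas
# in plain R, sharing no code with the engine's kernels.

# small random multi-species gas
rand_system <- function(n = 30, S = 2, box = c(4, 5, 6), seed = 42) {
  set.seed(seed)
  list(R = cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
                 runif(n, 0, box[3])),
       sp = sample(seq_len(S), n, replace = TRUE), box = box, S = S)
}

two_species_chi <- function(c01 = 12) {
  matrix(c(0, c01, c01, 0), 2, 2)
}

# ---- direct-space oracles -------------------------------------------------

# per-axis B-spline weights evaluated from the closed forms
oracle_axis_weights <- function(u, order) {
  if (order == 2) {
    i0 <- floor(u)
    f <- u - i0
    list(idx = i0 + 0:1, w = c(1 - f, f), dwdu = c(-1, 1))
  } else {
    n0 <- floor(u + 0.5)
    d <- u - n0
    list(idx = n0 + (-1):1,
         w = c(0.5 * (0.5 - d)^2, 0.75 - d^2, 0.5 * (0.5 + d)^2),
         dwdu = c(-(0.5 - d), -2 * d, 0.5 + d))
  }
}

# explicit per-particle deposition, returning an ncell x S matrix of
# number densities
oracle_deposit <- function(R, sp, box, dims, S, order = 2) {
  ncell <- prod(dims)
  vcell <- prod(box) / ncell
  rho <- matrix(0, ncell, S)
  for (i in seq_len(nrow(R))) {
    ax <- lapply(1:3, function(a)
      oracle_axis_weights(R[i, a] * dims[a] / box[a], order))
    for (cx in seq_along(ax[[1]]$idx))
      for (cy in seq_along(ax[[2]]$idx))
        for (cz in seq_along(ax[[3]]$idx)) {
          ix <- ax[[1]]$idx[cx] %% dims[1]
          iy <- ax[[2]]$idx[cy] %% dims[2]
          iz <- ax[[3]]$idx[cz] %% dims[3]
          cell <- 1 + ix + dims[1] * (iy + dims[2] * iz)
          rho[cell, sp[i]] <- rho[cell, sp[i]] +
            ax[[1]]$w[cx] * ax[[2]]$w[cy] * ax[[3]]$w[cz] / vcell
        }
  }
  rho
}

# direct-space periodic Gaussian filter: separable per-axis circular
# convolution with the periodically summed normalised Gaussian
oracle_filter <- function(rho, box, dims, sigma) {
  out <- rho
  for (a in 1:3) {
    n <- dims[a]
    h <- box[a] / n
    x <- (0:(n - 1)) * h
    K <- matrix(0, n, n)
    for (img in -6:6) {
      d <- outer(x, x, "-") + img * box[a]
      K <- K + exp(-d^2 / (2 * sigma^2))
    }
    K <- K * h / (sqrt(2 * pi) * sigma)
    perm <- c(a, setdiff(1:3, a))
    for (s in seq_len(ncol(out))) {
      arr <- aperm(array(out[, s], dims), perm)
      arr <- array(K %*% matrix(arr, dims[a]), dims[perm])
      out[, s] <- as.vector(aperm(arr, order(perm)))
    }
  }
  out
}

# cell-by-cell double loop over species pairs
oracle_energy <- function(phit, chi, box, dims, rho0, kappa, a) {
  vcell <- prod(box) / prod(dims)
  S <- ncol(phit)
  W <- 0
  for (cell in seq_len(nrow(phit))) {
    mix <- 0
    for (l in seq_len(S)) for (m in seq_len(S)) if (l != m)
      mix <- mix + chi[l, m] * phit[cell, l] * phit[cell, m]
    W <- W + (vcell / (2 * rho0)) *
      (mix + (sum(phit[cell, ]) - a)^2 / kappa)
  }
  W
}

# external potential by direct-space filtering of the pre-filter potential
oracle_potential <- function(phit, chi, box, dims, rho0, kappa, a) {
  S <- ncol(phit)
  tot <- rowSums(phit)
  psi <- matrix(0, nrow(phit), S)
  for (l in seq_len(S)) {
    acc <- (tot - a) / kappa
    for (m in seq_len(S)) if (m != l) acc <- acc + chi[l, m] * phit[, m]
    psi[, l] <- acc / rho0
  }
  psi
}

# force on each particle: -sum_cells V(cell) dw/dr
oracle_forces <- function(R, sp, V, box, dims, order = 2) {
  F <- matrix(0, nrow(R), 3)
  for (i in seq_len(nrow(R))) {
    ax <- lapply(1:3, function(a)
      oracle_axis_weights(R[i, a] * dims[a] / box[a], order))
    for (cx in seq_along(ax[[1]]$idx))
      for (cy in seq_along(ax[[2]]$idx))
        for (cz in seq_along(ax[[3]]$idx)) {
          ix <- ax[[1]]$idx[cx] %% dims[1]
          iy <- ax[[2]]$idx[cy] %% dims[2]
          iz <- ax[[3]]$idx[cz] %% dims[3]
          cell <- 1 + ix + dims[1] * (iy + dims[2] * iz)
          v <- V[cell, sp[i]]
          w <- c(ax[[1]]$w[cx], ax[[2]]$w[cy], ax[[3]]$w[cz])
          dw <- c(ax[[1]]$dwdu[cx], ax[[2]]$dwdu[cy], ax[[3]]$dwdu[cz])
          for (a in 1:3) {
            others <- prod(w[-a])
            F[i, a] <- F[i, a] - v * dw[a] * (dims[a] / box[a]) * others
          }
        }
  }
  F
}

# Gaussian-kernel profile by naive term-by-term summation
oracle_kde <- function(z, centers, box, h, nimg = 3) {
  acc <- numeric(length(centers))
  for (b in seq_along(centers))
    for (zi in z)
      for (n in -nimg:nimg)
        acc[b] <- acc[b] +
          exp(-(centers[b] - zi - n * box[3])^2 / (2 * h^2))
  acc / (sqrt(2 * pi) * h * box[1] * box[2])
}
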