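# Independent oracles used to freeze expected values.  These deliberately
# avoid the package's own implementations: brute-force sums, quadrature,
# and finite differences only.

# Shape factor of an arbitrary bead set by direct summation over the
# definition (end-to-end over gyration, single configuration).
oracle_shape_factor <- function(pos) {
  re2 <- sum((pos[nrow(pos), ] - pos[1, ])^2)
  cm <- colMeans(pos)
  rg2 <- mean(rowSums(sweep(pos, 2, cm)^2))
  re2 / rg2
}

# Gyration-tensor eigenvalues via the covariance route (population
# covariance, eigen on the explicit sum).
oracle_gyration_eigen <- function(pos) {
  cm <- colMeans(pos)
  d <- sweep(pos, 2, cm)
  G <- matrix(0, 3, 3)
  for (i in seq_len(nrow(d)))
    G <- G + tcrossprod(d[i, ])
  sort(eigen(G / nrow(pos), symmetric = TRUE)$values, decreasing = TRUE)
}

# Central-difference gradient of the energy surface exposed by
# compute_forces(), bead by bead.
oracle_fd_forces <- function(state, cfg, h = 3e-5, E = cfg$E,
                             gate_on = TRUE) {
  mob <- which(state$mobile)
  F <- matrix(0, length(mob), 3)
  for (ii in seq_along(mob)) {
    for (a in 1:3) {
      sp <- state; sp$pos[mob[ii], a] <- sp$pos[mob[ii], a] + h
      sm <- state; sm$pos[mob[ii], a] <- sm$pos[mob[ii], a] - h
      up <- compute_forces(sp, cfg, E = E, gate_on = gate_on)$energy
      um <- compute_forces(sm, cfg, E = E, gate_on = gate_on)$energy
      F[ii, a] <- -(up - um) / (2 * h)
    }
  }
  F
}

# Boltzmann statistics of a bond in the implemented model (harmonic spring
# plus the WCA core that also acts between bonded neighbors), with the r^2
# Jacobian, by quadrature.
.oracle_bond_dens <- function(k, l0, kBT, sigma, eps) {
  function(r) {
    u_wca <- ifelse(r < 2^(1 / 6) * sigma,
                    4 * eps * ((sigma / r)^12 - (sigma / r)^6) + eps, 0)
    r^2 * exp(-(k * (r - l0)^2 / 2 + u_wca) / kBT)
  }
}

oracle_bond_moment <- function(k, l0 = 1, kBT = 1, moment = 1,
                               sigma = 1, eps = 1.2) {
  dens <- .oracle_bond_dens(k, l0, kBT, sigma, eps)
  hi <- l0 + 10 / sqrt(k)
  Z <- stats::integrate(dens, 1e-3, hi)$value
  stats::integrate(function(r) r^moment * dens(r), 1e-3, hi)$value / Z
}

# CDF of the bond Boltzmann length distribution.
oracle_bond_cdf <- function(k, l0 = 1, kBT = 1, sigma = 1, eps = 1.2) {
  dens <- .oracle_bond_dens(k, l0, kBT, sigma, eps)
  hi <- l0 + 10 / sqrt(k)
  Z <- stats::integrate(dens, 1e-3, hi)$value
  function(q) vapply(q, function(qq)
    stats::integrate(dens, 1e-3, min(qq, hi))$value / Z, 0)
}

# Waiting-time bookkeeping by direct accumulation on a toy path.
oracle_waiting <- function(s, time, N) {
  w <- setNames(numeric(N - 1), seq_len(N - 1))
  i <- 1
  while (s[i] < N) {
    if (s[i] >= 1 && s[i] <= N - 1)
      w[as.character(s[i])] <- w[as.character(s[i])] + time[i + 1] - time[i]
    i <- i + 1
  }
  w
}

# A free chain (no wall, no field) as a particle_state, for conservation
# checks.
free_chain_state <- function(N, cfg, vel_scale = 0, seed = 1) {
  set.seed(seed)
  pos <- matrix(0, N, 3)
  for (i in 2:N) {
    repeat {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- pos[i - 1, ] + cfg$l0 * u
      d2 <- rowSums(sweep(pos[seq_len(i - 1), , drop = FALSE], 2, cand)^2)
      d2[i - 1] <- Inf
      if (all(d2 > 0.81)) { pos[i, ] <- cand; break }
    }
  }
  pos[, 3] <- pos[, 3] + cfg$box[3] / 4   # far from the wall plane
  structure(list(pos = pos, vel = matrix(stats::rnorm(3 * N, 0, vel_scale),
                                         N, 3),
                 charge = rep(cfg$monomer_charge, N),
                 species = rep("monomer", N), mobile = rep(TRUE, N),
                 bonds = cbind(seq_len(N - 1), seq_len(N - 1) + 1L),
                 n_mono = N, cfg = cfg),
            class = "particle_state")
}

total_energy <- function(state, cfg, ...) {
  pe <- compute_forces(state, cfg, ...)$energy
  ke <- 0.5 * sum(state$vel[state$mobile, ]^2)
  pe + ke
}
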