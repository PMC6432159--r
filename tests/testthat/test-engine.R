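# Force-field primitives, integrator physics, and the translocation driver.

test_that("WCA pair potential: cutoff, contact value, repulsive core", {
  w <- pair_wca(2^(1 / 6) * 1.3, sigma = 1.3, eps = 2.5)
  expect_equal(w$energy, 0)
  expect_equal(w$force, 0)
  expect_equal(pair_wca(1, 1, 1.2)$energy, 1.2)      # r = sigma: +eps
  expect_equal(pair_wca(2, 1, 1.2)$energy, 0)        # beyond cutoff
  expect_equal(pair_wca(2, 1, 1.2)$force, 0)
  expect_gt(pair_wca(0.9, 1, 1.2)$force, 0)
  expect_error(pair_wca(0), "singular")
})

test_that("harmonic bond energy and signed tension", {
  b <- bond_harmonic(1.0)
  expect_equal(b$energy, 0)
  expect_equal(b$tension, 0)
  expect_equal(bond_harmonic(1.1)$tension, 60, tolerance = 1e-12)
  expect_equal(bond_harmonic(0.9)$tension, -60, tolerance = 1e-12)
  expect_equal(bond_harmonic(1.1)$energy, bond_harmonic(0.9)$energy)
})

test_that("Coulomb pair: Bjerrum-length normalization and screening", {
  expect_equal(pair_coulomb(3, 1, -1, lambda_B = 3)$energy, -1)
  expect_equal(pair_coulomb(3, 1, 1, lambda_B = 3)$energy, 1)
  s <- pair_coulomb(3, 1, 1, lambda_B = 3, mode = "screened",
                    screening_length = 3)
  expect_equal(s$energy, exp(-1))
  # truncated-shifted energy is continuous at the cutoff
  eps <- 1e-9
  e_in <- pair_coulomb(10 - eps, 1, 1, 3, cutoff = 10)$energy
  expect_lt(abs(e_in), 1e-6)
  expect_equal(pair_coulomb(10.5, 1, 1, 3, cutoff = 10)$energy, 0)
  expect_error(pair_coulomb(1e-9, 1, 1), "singular")
})

test_that("external forces: field region and sign algebra", {
  cfg <- system_config(N = 4, E = 8, electrostatics = "none")
  st <- build_system(cfg)
  st$pos[1, ] <- c(0, 0, 20)       # head far on the trans side, gate inactive
  st$pos[2, ] <- c(0, 0, 0)        # in the pore slab
  st$pos[3, ] <- c(0, 0, 10)       # outside region II
  st$pos[4, ] <- c(1, 0, 2.25)     # boundary: closed interval, inside
  F <- external_forces(st, cfg)
  expect_equal(F[2, 3], +8)        # charge -1 in field -E z^
  expect_equal(F[3, 3], 0)
  expect_equal(F[4, 3], +8)
  # a positive charge in the slab is driven the other way
  st$charge[2] <- +1
  expect_equal(external_forces(st, cfg)[2, 3], -8)
})

test_that("forces are the exact gradient of the energy (finite differences)", {
  for (mode in c("direct", "screened")) {
    cfg <- system_config(N = 12, E = 3, electrostatics = mode, n_salt = 0,
                         explicit_ions = FALSE, coulomb_cutoff = 10)
    st <- build_system(cfg)
    set.seed(42)
    st <- equilibrate_initial(st, cfg, steps = 500L)
    # place the head inside the smooth part of the gate ramp (the WCA
    # cutoff is only C1, so finite differences must not straddle it) and
    # keep beads off the slab boundary where the field force steps
    wh <- cfg$wall_thickness / 2
    st$pos[1, 3] <- wh + 0.8
    z <- st$pos[st$mobile, 3]
    expect_true(all(abs(abs(z) - wh) > 5e-4))
    F <- compute_forces(st, cfg)$forces
    Ffd <- oracle_fd_forces(st, cfg)
    scale <- pmax(abs(Ffd), 1)
    expect_lt(max(abs(F - Ffd) / scale), 1e-6)
  }
})

test_that("pair forces obey Newton's third law and conserve momentum", {
  cfg <- system_config(N = 10, E = 0, electrostatics = "direct", n_salt = 0,
                       explicit_ions = FALSE, coulomb_cutoff = Inf)
  st <- free_chain_state(10, cfg, vel_scale = 0.2, seed = 5)
  st$pos <- st$pos + matrix(rnorm(30, 0, 0.05), 10, 3)
  F <- compute_forces(st, cfg, E = 0, gate_on = FALSE)$forces
  expect_lt(max(abs(colSums(F))), 1e-10)
  # isolated, unthermostatted, field-free: total momentum conserved
  cfg0 <- cfg; cfg0$zeta <- 0
  p0 <- colSums(st$vel)
  st2 <- run_dynamics(st, cfg0, steps = 1000L, E = 0, gate_on = FALSE)
  expect_lt(max(abs(colSums(st2$vel) - p0)), 1e-8)
})

test_that("zero-friction integration conserves energy (velocity Verlet limit)", {
  cfg <- system_config(N = 8, E = 0, electrostatics = "none", n_salt = 0,
                       explicit_ions = FALSE)
  cfg$zeta <- 0
  st <- free_chain_state(8, cfg, vel_scale = 0.15, seed = 2)
  # start bonds at the minimum of the combined harmonic + WCA bond
  # potential so the conserved energy is dominated by gentle motion
  fwca <- function(r) pair_wca(r, cfg$sigma_bb, cfg$eps_bb)$force
  rstar <- stats::uniroot(function(r) cfg$k * (r - cfg$l0) - fwca(r),
                          c(1, 1.2))$root
  for (i in 2:8) {
    dir <- st$pos[i, ] - st$pos[i - 1, ]
    st$pos[i, ] <- st$pos[i - 1, ] + dir / sqrt(sum(dir^2)) * rstar
  }
  e0 <- total_energy(st, cfg, E = 0, gate_on = FALSE)
  drift <- 0
  for (chunk in 1:10) {
    st <- run_dynamics(st, cfg, steps = 1000L, E = 0, gate_on = FALSE)
    drift <- max(drift, abs(total_energy(st, cfg, E = 0, gate_on = FALSE) - e0))
  }
  expect_lt(drift / 8, 1e-3)    # kBT per bead over 1e4 steps
})

test_that("thermostat satisfies equipartition for a free bead", {
  cfg <- system_config(N = 2, E = 0, electrostatics = "none")
  st <- free_chain_state(2, cfg, vel_scale = 1, seed = 3)
  st$bonds <- st$bonds[0, , drop = FALSE]   # unbonded free beads
  set.seed(10)
  v2 <- c()
  for (chunk in 1:200) {
    st <- run_dynamics(st, cfg, steps = 200L, E = 0, gate_on = FALSE)
    v2 <- c(v2, sum(st$vel[1, ]^2))
  }
  se <- sqrt(stats::var(v2) / length(v2))
  expect_lt(abs(mean(v2) - 3), 3 * se)
})

test_that("bond-length distribution matches the Boltzmann weight (KS)", {
  cfg <- system_config(N = 41, E = 0, electrostatics = "none", n_salt = 0)
  st <- free_chain_state(41, cfg, vel_scale = 1, seed = 6)
  set.seed(11)
  st <- run_dynamics(st, cfg, steps = 3000L, E = 0, gate_on = FALSE)
  lens <- c()
  for (chunk in 1:250) {
    st <- run_dynamics(st, cfg, steps = 400L, E = 0, gate_on = FALSE)
    p <- st$pos
    lens <- c(lens, sqrt(rowSums((p[-1, ] - p[-41, ])^2)))
  }
  ks <- suppressWarnings(stats::ks.test(lens, oracle_bond_cdf(cfg$k)))
  expect_gt(ks$p.value, 0.01)
})

test_that("same seed reproduces a run bit-identically; budgets are flagged", {
  cfg <- system_config(N = 16, E = 32, electrostatics = "screened",
                       equilibration_steps = 2000L)
  r1 <- run_translocation(cfg, seed = 21)
  r2 <- run_translocation(cfg, seed = 21)
  expect_identical(r1$record$s, r2$record$s)
  expect_identical(r1$trajectory$frames, r2$trajectory$frames)
  r3 <- run_translocation(cfg, seed = 22)
  expect_false(identical(r1$record$s, r3$record$s))
  # exhausted step budget is reported, not silently truncated
  cfg_short <- cfg; cfg_short$max_steps <- 10L
  r4 <- run_translocation(cfg_short, seed = 21)
  expect_false(r4$record$completed)
  expect_true(is.na(r4$record$tau))
})

test_that("a driven run completes with s = N and the gate holds the head", {
  cfg <- system_config(N = 16, E = 32, electrostatics = "screened",
                       n_salt = 0, equilibration_steps = 2000L,
                       frame_stride = 5L)
  res <- run_translocation(cfg, seed = 31)
  expect_true(res$record$completed)
  expect_equal(res$record$s[length(res$record$s)], 16)
  expect_equal(sum(res$record$w), res$record$tau)
  head_z <- vapply(res$trajectory$frames, function(f) f[1, 3], 0)
  expect_true(all(head_z > cfg$wall_thickness / 2))
})

test_that("stronger fields translocate faster on average", {
  taus <- sapply(c(4, 32), function(E) {
    cfg <- system_config(N = 16, E = E, electrostatics = "screened",
                         equilibration_steps = 2000L, frame_stride = 0L,
                         seed = 77L)
    st <- build_system(cfg)
    set.seed(77)
    st <- equilibrate_initial(st, cfg)
    mean(sapply(1:10, function(k)
      run_translocation(cfg, seed = 100 + k, state = st)$record$tau))
  })
  expect_gt(taus[1], taus[2])
})
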