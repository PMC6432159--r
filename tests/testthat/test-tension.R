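# Bond tension profiles, pore distances, straightened section, front.

test_that("tension from prescribed bond lengths follows Hooke's law", {
  # uniform stretch
  fx <- make_ramp_fixture(rep(1.05, 15))
  pr <- bond_tension_profile(fx, taus = 1, n_bins = 1)
  expect_equal(unname(pr$f[1, ]), rep(30, 15), tolerance = 1e-10)
  # rest length everywhere: zero tension
  fx0 <- make_ramp_fixture(rep(1.0, 15))
  pr0 <- bond_tension_profile(fx0, taus = 1, n_bins = 1)
  expect_equal(unname(pr0$f[1, ]), rep(0, 15))
  # linear length ramp maps affinely to a linear tension ramp
  ramp <- seq(1.0, 1.1, length.out = 15)
  prr <- bond_tension_profile(make_ramp_fixture(ramp), taus = 1, n_bins = 1)
  expect_equal(unname(prr$f[1, ]), 600 * (ramp - 1), tolerance = 1e-10)
})

test_that("tension of the mean length equals the mean of per-frame tensions", {
  # two frames with different uniform stretches: Hooke is affine
  f1 <- make_ramp_fixture(rep(1.02, 7), time = 0.2)
  f2 <- make_ramp_fixture(rep(1.08, 7), time = 0.2)
  traj <- f1; traj$frames <- c(f1$frames, f2$frames); traj$times <- c(0.2, 0.2)
  pr <- bond_tension_profile(traj, taus = 1, n_bins = 1)
  expect_equal(unname(pr$f[1, ]), rep(600 * 0.05, 7), tolerance = 1e-10)
})

test_that("pore distances: collinear chain has D = Lambda, zero inside pore", {
  cfg <- system_config(N = 12, electrostatics = "none")
  z <- seq(5.5, -5.5, by = -1)
  pd <- pore_distances(cbind(0, 0, z), cfg)
  expect_false(attr(pd, "flagged"))
  in_pore <- pd$region == "II"
  expect_true(any(in_pore))
  expect_equal(pd$D[in_pore], rep(0, sum(in_pore)))
  expect_equal(pd$Lambda[in_pore], rep(0, sum(in_pore)))
  expect_equal(pd$D[!in_pore], pd$Lambda[!in_pore], tolerance = 1e-10)
  # a monomer 5 unit bonds beyond the last pre-pore monomer: Lambda grows by 5
  cis <- which(z < -2.25)
  expect_equal(pd$Lambda[cis[1] + 2] - pd$Lambda[cis[1]], 2, tolerance = 1e-10)
})

test_that("coiled chains satisfy the strict triangle inequality D < Lambda", {
  cfg <- system_config(N = 40, electrostatics = "none")
  set.seed(15)
  # random coil threaded through the pore region
  z0 <- seq(3, -3, length.out = 7)
  pos <- cbind(0, 0, z0)
  for (i in 8:40) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    cand <- pos[i - 1, ] + u
    while (cand[3] > -2.5) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2)); cand <- pos[i - 1, ] + u
    }
    pos <- rbind(pos, cand)
  }
  pd <- pore_distances(pos, cfg)
  out <- pd$region != "II"
  expect_true(all(pd$Lambda[out] >= pd$D[out] - 1e-12))
  # far, non-adjacent monomers of a coil are strictly closer than the contour
  deep <- which(out & pd$Lambda > 3)
  expect_true(all(pd$D[deep] < pd$Lambda[deep]))
})

test_that("no-pore-monomer configurations are flagged, not errored", {
  cfg <- system_config(N = 6, electrostatics = "none")
  pos <- cbind(0, 0, seq(-10, -15))
  pd <- pore_distances(pos, cfg)
  expect_true(attr(pd, "flagged"))
  expect_true(all(pd$Lambda >= pd$D - 1e-12))
})

test_that("straightened-section boundary follows the ratio threshold", {
  # fully straight: the entire profile qualifies
  expect_equal(straightened_section(1:10, 1:10), 10)
  # first crossing below 0.9 cuts the section at the 3rd monomer
  L <- rep(1, 5)
  D <- c(1.0, 0.95, 0.91, 0.6, 0.99)
  expect_equal(straightened_section(D, L), 3)
  # first monomer failing gives 0
  expect_equal(straightened_section(c(0.5, 1, 1), rep(1, 3)), 0)
  # threshold 1 on any thermal profile is (almost surely) 0
  set.seed(16)
  expect_equal(straightened_section(runif(10, 0.8, 0.999), rep(1, 10),
                                    threshold = 1), 0)
})

test_that("tension front: absent on uniform profiles, located on steps", {
  set.seed(17)
  flat <- rnorm(50, 2, 0.01)
  fr <- tension_front(flat, background = 2, threshold = 0.5)
  expect_false(fr$found)
  # step profile: high tension for n-tilde < 0.4, background beyond
  N <- 100
  f <- ifelse(seq_len(N - 1) / N <= 0.4, 50, 2)
  fr2 <- tension_front(f, background = 2, threshold = 1, N = N)
  expect_true(fr2$found)
  expect_equal(fr2$n_tilde, 0.4)
  # automatic trans-plateau background: surge sits between the pore
  # (s-tilde = 0.1) and 0.4, trans bonds have relaxed to background
  nn <- seq_len(N - 1) / N
  f2 <- ifelse(nn > 0.1 & nn <= 0.4, 50, 2) + rnorm(N - 1, 0, 0.01)
  fr3 <- tension_front(f2, s_tilde = 0.1, N = N)
  expect_true(fr3$found)
  expect_equal(fr3$n_tilde, 0.4)
})

test_that("zero-field equilibrium tensions show no trend along the chain", {
  cfg <- system_config(N = 24, E = 0, electrostatics = "none", n_salt = 0,
                       seed = 19L)
  st <- build_system(cfg)
  set.seed(19)
  st <- equilibrate_initial(st, cfg, 4000L)
  frames <- list(); times <- c()
  set.seed(20)
  for (i in 1:60) {
    st <- run_dynamics(st, cfg, steps = 200L, E = 0, gate_on = FALSE)
    frames[[i]] <- st$pos[st$mobile, , drop = FALSE]
    times[i] <- i
  }
  traj <- structure(list(frames = frames, times = times, n_mono = 24,
                         species = rep("monomer", 24),
                         charge = rep(-1, 24), cfg = cfg),
                    class = "trajectory")
  pr <- bond_tension_profile(traj, taus = max(times) + 1, n_bins = 1)
  fit <- summary(lm(pr$f[1, ] ~ seq_len(23)))
  expect_gt(fit$coefficients[2, 4], 0.01)   # slope not significant at 1%
})

test_that("strong-field front propagates monotonically toward the tail", {
  ens <- reduced_ensemble(32)
  taus <- vapply(ens$records, `[[`, 0, "tau")
  pr <- bond_tension_profile(ens$trajectories, taus, n_bins = 10)
  fronts <- rep(NA_real_, 10)
  for (b in 1:10) {
    if (pr$n_frames[b] == 0 || !is.finite(pr$s_tilde[b])) next
    if (pr$s_tilde[b] * pr$N < 5) next   # too few trans bonds for background
    fr <- tension_front(pr$f[b, ], s_tilde = pr$s_tilde[b], N = pr$N)
    if (fr$found) fronts[b] <- fr$n_front
  }
  found <- which(!is.na(fronts))
  expect_gt(length(found), 2)
  # non-decreasing within a 2-bond noise allowance, and the front reaches
  # the free chain end under this strong a drive
  runs <- fronts[found]
  expect_true(all(diff(runs) >= -2))
  expect_gte(max(runs), pr$N - 2)
})
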