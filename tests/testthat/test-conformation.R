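# Shape factor, gyration tensor, asphericity/prolateness, principal angles.

test_that("shape factor: rods, dimers, and the discrete-rod formula", {
  expect_equal(shape_factor(cbind(0, 0, 0:2)), 6)        # 3-bead rod
  expect_equal(shape_factor(cbind(0, 0, 0:1)), 4)        # dimer
  rod101 <- cbind(0, 0, seq(0, 100))
  expect_equal(shape_factor(rod101), 12 * 100 / 102, tolerance = 1e-12)
  expect_equal(shape_factor(rod101), oracle_shape_factor(rod101))
  expect_error(shape_factor(matrix(1, 4, 3)), "coincident")
})

test_that("gyration tensor: trace identity and known eigenvalues", {
  expect_equal(gyration_tensor(matrix(c(1, 2, 3), 1))$eigenvalues,
               rep(0, 3))
  a <- 2.5
  sq <- cbind(c(0, a, a, 0), c(0, 0, a, a), 0)
  ev <- gyration_tensor(sq)$eigenvalues
  expect_equal(ev, c(a^2 / 4, a^2 / 4, 0))
  set.seed(4)
  cloud <- matrix(rnorm(600), 200, 3) %*% diag(c(3, 1, 0.2))
  g <- gyration_tensor(cloud)
  expect_equal(g$eigenvalues, oracle_gyration_eigen(cloud),
               tolerance = 1e-10)
  expect_equal(sum(g$eigenvalues),
               mean(rowSums(sweep(cloud, 2, colMeans(cloud))^2)))
})

test_that("asphericity and prolateness at the canonical shapes", {
  expect_equal(asphericity_prolateness(1, 1, 1), list(A = 0, P = 0))
  expect_equal(asphericity_prolateness(1, 0, 0), list(A = 1, P = 2))
  expect_equal(asphericity_prolateness(1, 1, 0), list(A = 0.25, P = -0.25))
  expect_error(asphericity_prolateness(0, 0, 0), "undefined")
  expect_error(asphericity_prolateness(1, 2, 0), "l1 >= l2")
})

test_that("A and P stay in their intervals for random eigenvalue triples", {
  set.seed(12)
  ap <- vapply(seq_len(10000), function(i) {
    ev <- sort(rexp(3), decreasing = TRUE)
    unlist(asphericity_prolateness(ev[1], ev[2], ev[3]))
  }, c(A = 0, P = 0))
  expect_true(all(ap["A", ] >= 0 & ap["A", ] <= 1))
  expect_true(all(ap["P", ] >= -0.25 & ap["P", ] <= 2))
})

test_that("principal angles resolve quadrant and fix the z-sign", {
  rod_z <- cbind(0, 0, seq(-3, 3))
  an <- principal_angles(rod_z)
  expect_equal(an$theta_deg, 0)
  rod_x <- cbind(seq(-3, 3), 0, 0)
  an_x <- principal_angles(rod_x)
  expect_equal(an_x$theta_deg, 90)
  expect_equal(abs(an_x$phi_deg) %% 180, 0)
  # axis (1,1,sqrt(2))/2: theta = 45, phi = 45
  ax <- c(1, 1, sqrt(2)) / 2
  rod <- outer(seq(-3, 3), ax)
  an_d <- principal_angles(rod)
  expect_equal(an_d$theta_deg, 45, tolerance = 1e-8)
  expect_equal(an_d$phi_deg, 45, tolerance = 1e-8)
  # degenerate axis is flagged
  disk <- rbind(cbind(cos(seq(0, 2 * pi, length.out = 41)[-41]),
                      sin(seq(0, 2 * pi, length.out = 41)[-41]), 0))
  expect_true(principal_angles(disk)$degenerate)
})

test_that("descriptors are invariant under rotation and translation", {
  set.seed(13)
  p <- matrix(rnorm(90), 30, 3) %*% diag(c(2, 1, 0.5))
  qr_rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_rot) < 0) qr_rot[, 1] <- -qr_rot[, 1]
  p2 <- p %*% qr_rot + matrix(rep(c(5, -3, 11), each = 30), 30)
  expect_equal(shape_factor(p2), shape_factor(p), tolerance = 1e-10)
  ev1 <- gyration_tensor(p)$eigenvalues
  ev2 <- gyration_tensor(p2)$eigenvalues
  expect_equal(ev1, ev2, tolerance = 1e-10)
  ap1 <- asphericity_prolateness(ev1)
  ap2 <- asphericity_prolateness(ev2)
  expect_equal(ap1$A, ap2$A, tolerance = 1e-10)
  expect_equal(ap1$P, ap2$P, tolerance = 1e-10)
})

test_that("coil and globule ensembles reach their limiting shape factors", {
  set.seed(14)
  coils <- make_coil_ensemble(N = 512, n_configs = 600)
  expect_equal(shape_factor(coils), 6, tolerance = 0.2 / 6)
  balls <- make_ball_ensemble(N = 128, n_configs = 1500)
  expect_equal(shape_factor(balls), 2, tolerance = 0.1 / 2)
})

test_that("scaled-time descriptor series recovers rod geometry exactly", {
  fx <- make_rod_fixture(N = 24, speed = 1, frame_dt = 0.25)
  n_bins <- 8
  tab <- conformation_timeseries(list(fx$trajectory), taus = fx$record$tau,
                                 region = "I", n_bins = n_bins)
  wh <- fx$trajectory$cfg$wall_thickness / 2
  # oracle: recompute each bin's ratio-of-means directly from the frames
  breaks <- seq(0, 1, length.out = n_bins + 1)
  tt <- fx$trajectory$times / fx$record$tau
  bin_of <- cut(pmin(tt, 1), breaks, include.lowest = TRUE, labels = FALSE)
  for (b in which(tab$n_samples > 0)) {
    fr <- which(bin_of == b)
    sub <- lapply(fr, function(fi) {
      p <- fx$trajectory$frames[[fi]]
      p[p[, 3] < -wh, , drop = FALSE]
    })
    sub <- sub[vapply(sub, nrow, 0L) >= 2]
    eta_oracle <- mean(vapply(sub, function(p)
      sum((p[nrow(p), ] - p[1, ])^2), 0)) /
      mean(vapply(sub, function(p) {
        cm <- colMeans(p); mean(rowSums(sweep(p, 2, cm)^2))
      }, 0))
    expect_equal(tab$eta[b], eta_oracle, tolerance = 1e-10)
    # a bin whose frames all share one cis bead count obeys the rod formula
    ns <- unique(vapply(sub, nrow, 0L))
    if (length(ns) == 1 && ns >= 2)
      expect_equal(tab$eta[b], 12 * (ns - 1) / (ns + 1), tolerance = 1e-10)
  }
  # rod on the axis: polar angle 0 throughout
  expect_true(all(abs(tab$theta_deg[tab$n_samples > 0]) < 1e-6))
})

test_that("azimuthal symmetry: ensemble phi fluctuates about zero", {
  # independently initialized runs: the transverse directions carry no
  # preferred azimuth, so the pooled cis-side phi is centered on zero
  phis <- c()
  for (k in 1:12) {
    cfg <- system_config(N = 16, E = 8, electrostatics = "screened",
                         equilibration_steps = 20000L, frame_stride = 20L,
                         seed = 300L + k)
    res <- run_translocation(cfg, seed = 400 + k)
    wh <- cfg$wall_thickness / 2
    phis <- c(phis, vapply(res$trajectory$frames, function(f) {
      sub <- f[seq_len(16), , drop = FALSE]
      sub <- sub[sub[, 3] < -wh, , drop = FALSE]
      if (nrow(sub) < 3) return(NA_real_)
      principal_angles(sub)$phi_deg
    }, 0))
  }
  phis <- phis[is.finite(phis)]
  expect_gt(length(phis), 50)
  se <- sd(phis) / sqrt(12)   # frames within a run strongly correlate
  expect_lt(abs(mean(phis)), 3 * se)
})
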