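# Synthetic fixtures with closed-form ground truth.  They exercise every
# analysis module without running dynamics: a rigid rod translocating at
# constant speed, random-coil and uniform-ball ensembles, log-normal
# passage-time samples, and a chain with prescribed bond lengths.

#' Build a synthetic fixture
#'
#' Dispatches on `kind`:
#' * `"rod"` — an N-bead straight chain advanced through the pore at
#'   constant speed; `s(t)` is known exactly, `w(s) = 1/speed` for every
#'   state, the cis sub-chain is perfectly collinear
#'   (`eta = 12 (n-1)/(n+1)`, `D = Lambda`).
#' * `"coil"` — an ensemble of ideal chains (fixed bond length, uniformly
#'   random bond directions); `eta -> 6` for long chains.
#' * `"ball"` — an ensemble of compact globules: beads uniform in a
#'   sphere, chain ends at random positions inside; `eta -> 2`.
#' * `"lognormal"` — first-passage samples from a stated log-normal.
#' * `"ramp"` — a straight chain with prescribed bond lengths (tension
#'   ramp), as a one-frame trajectory.
#'
#' @param kind Fixture kind.
#' @param ... Parameters passed to the specific generator.
#' @return The fixture object (see the individual generators).
#' @export
make_fixture <- function(kind = c("rod", "coil", "ball", "lognormal", "ramp"),
                         ...) {
  kind <- match.arg(kind)
  switch(kind,
         rod = make_rod_fixture(...),
         coil = make_coil_ensemble(...),
         ball = make_ball_ensemble(...),
         lognormal = make_lognormal_samples(...),
         ramp = make_ramp_fixture(...))
}

#' Rigid-rod translocation fixture
#'
#' A straight N-bead chain on the pore axis, bond length `l0`, advanced
#' toward +z at `speed` states per tau_u.  At `t = 0` exactly one bead is
#' past the pore exit (s = 1); bead `i` crosses at
#' `t = (i - 1) / speed`.
#'
#' @param N Beads.
#' @param speed States per tau_u.
#' @param frame_dt Frame spacing (tau_u).
#' @param cfg Geometry ([system_config()]); only wall/pore/bond fields are
#'   used.
#' @return List with `trajectory`, `record` (exact `s` jump series and
#'   waiting times), and `truth` (`w`, `tau`, `speed`).
#' @export
make_rod_fixture <- function(N = 16, speed = 1.0, frame_dt = 0.1,
                             cfg = system_config(N = N, E = 0,
                                                 electrostatics = "none")) {
  wh <- cfg$wall_thickness / 2
  eps <- 1e-6
  z_of <- function(i, t) (wh + eps) + speed * t * cfg$l0 - (i - 1) * cfg$l0
  tau <- (N - 1) / speed
  times <- seq(0, tau, by = frame_dt)
  if (times[length(times)] < tau) times <- c(times, tau)
  frames <- lapply(times, function(t)
    cbind(0, 0, z_of(seq_len(N), t)))
  traj <- structure(list(frames = frames, times = times, n_mono = N,
                         species = rep("monomer", N),
                         charge = rep(cfg$monomer_charge, N), cfg = cfg),
                    class = "trajectory")
  jump_times <- c(0, seq_len(N - 1) / speed)   # s = 1..N at these times
  s_series <- seq_len(N)
  w <- waiting_times(s_series, jump_times, N = N)
  rec <- structure(list(run_id = 1L, seed = NA_integer_, s = s_series,
                        time = jump_times, tau = tau, w = w, N = N,
                        completed = TRUE),
                   class = "translocation_record")
  list(trajectory = traj, record = rec,
       truth = list(w = rep(1 / speed, N - 1), tau = tau, speed = speed))
}

#' Ideal-chain (random-walk) ensemble
#'
#' @param N Beads per chain.
#' @param n_configs Number of configurations.
#' @param l0 Bond length.
#' @return List of N x 3 position matrices.
#' @export
make_coil_ensemble <- function(N = 512, n_configs = 2000, l0 = 1.0) {
  lapply(seq_len(n_configs), function(i) {
    u <- matrix(stats::rnorm(3 * (N - 1)), N - 1, 3)
    u <- u / sqrt(rowSums(u^2)) * l0
    apply(rbind(c(0, 0, 0), u), 2, cumsum)
  })
}

#' Uniform-ball ensemble with random chain ends
#'
#' Beads independently uniform in a sphere of radius `R`; the chain ends
#' are simply the first and last beads, i.e. random interior points.
#'
#' @param N Beads per globule.
#' @param n_configs Number of configurations.
#' @param R Sphere radius.
#' @return List of N x 3 position matrices.
#' @export
make_ball_ensemble <- function(N = 256, n_configs = 2000, R = 5.0) {
  lapply(seq_len(n_configs), function(i) {
    p <- matrix(stats::rnorm(3 * N), N, 3)
    p <- p / sqrt(rowSums(p^2))
    r <- R * stats::runif(N)^(1 / 3)
    p * r
  })
}

#' Log-normal passage-time samples
#'
#' @param sigma,mu Log-normal parameters (`mu` is the median, tau_u).
#' @param n Sample count.
#' @return Numeric samples.
#' @export
make_lognormal_samples <- function(sigma = 0.3, mu = 50, n = 10000) {
  stats::rlnorm(n, meanlog = log(mu), sdlog = sigma)
}

#' Straight chain with prescribed bond lengths
#'
#' Beads on the z-axis with the stated bond lengths, tail-to-head toward
#' +z, as a one-frame trajectory whose tension profile is known exactly:
#' `f_n = k (lengths[n] - l0)`.
#'
#' @param lengths Bond lengths (sigma), length N-1.
#' @param cfg Geometry and bond parameters.
#' @param time Frame time stamp.
#' @return A `trajectory` with one frame.
#' @export
make_ramp_fixture <- function(lengths,
                              cfg = system_config(N = length(lengths) + 1,
                                                  E = 0,
                                                  electrostatics = "none"),
                              time = 0) {
  N <- length(lengths) + 1L
  z <- cfg$wall_thickness / 2 + 1 - c(0, cumsum(lengths))
  structure(list(frames = list(cbind(0, 0, z)), times = time, n_mono = N,
                 species = rep("monomer", N),
                 charge = rep(cfg$monomer_charge, N), cfg = cfg),
            class = "trajectory")
}
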