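# Force-field primitives, integrator wrappers, and the translocation driver.

#' WCA (purely repulsive Lennard-Jones) pair interaction
#'
#' `U(r) = 4 eps [(sig/r)^12 - (sig/r)^6] + eps` for `r < 2^(1/6) sig`,
#' zero beyond; the energy shift makes both energy and force continuous at
#' the cutoff.
#'
#' @param r Pair separation (sigma), > 0.
#' @param sigma,eps WCA size and strength parameters.
#' @return List with `energy` (kBT) and `force` (kBT/sigma, positive =
#'   repulsive), vectorized over `r`.
#' @examples
#' pair_wca(2^(1/6), 1, 1.2)  # exactly (0, 0) at the cutoff
#' @export
pair_wca <- function(r, sigma = 1.0, eps = 1.2) {
  if (any(r <= 0)) stop("WCA is singular at r = 0; r must be positive")
  rc <- 2^(1 / 6) * sigma
  s6 <- (sigma / r)^6
  energy <- ifelse(r < rc, 4 * eps * (s6^2 - s6) + eps, 0)
  force <- ifelse(r < rc, 24 * eps * (2 * s6^2 - s6) / r, 0)
  list(energy = energy, force = force)
}

#' Harmonic bond energy and tension
#'
#' `U = (k/2)(l - l0)^2`; the tension `k (l - l0)` is positive for a
#' stretched bond.
#'
#' @param l Bond length (sigma).
#' @param k Spring constant (kBT/sigma^2).
#' @param l0 Rest length (sigma).
#' @return List with `energy` (kBT) and `tension` (kBT/sigma), vectorized.
#' @export
bond_harmonic <- function(l, k = 600.0, l0 = 1.0) {
  if (any(l < 0)) stop("bond length must be non-negative")
  list(energy = 0.5 * k * (l - l0)^2, tension = k * (l - l0))
}

#' Coulomb pair interaction (direct or Debye-Hueckel screened)
#'
#' In direct mode the pair energy is `lambda_B * kBT * qi * qj / r`
#' (shifted to zero at a finite cutoff); by construction two unit charges
#' at `r = lambda_B` interact with exactly +/- 1 kBT when untruncated.
#' Screened mode multiplies by `exp(-r / screening_length)`.
#'
#' @param r Separation (sigma).
#' @param qi,qj Charges (e).
#' @param lambda_B Bjerrum length (sigma).
#' @param mode `"direct"` or `"screened"`.
#' @param cutoff Cutoff radius; `Inf` for no truncation (no shift).
#' @param screening_length Debye length (sigma), screened mode only.
#' @return List with `energy` and `force` (positive = repulsive),
#'   vectorized over `r`.
#' @examples
#' pair_coulomb(3, +1, -1, lambda_B = 3)$energy  # -1 kBT
#' @export
pair_coulomb <- function(r, qi, qj, lambda_B = 3.0,
                         mode = c("direct", "screened"), cutoff = Inf,
                         screening_length = 1.0) {
  mode <- match.arg(mode)
  if (any(r < 1e-6)) stop("overlapping charges (r < 1e-6): Coulomb singular")
  pref <- lambda_B * qi * qj
  if (mode == "direct") {
    shift <- if (is.finite(cutoff)) pref / cutoff else 0
    energy <- ifelse(r < cutoff, pref / r - shift, 0)
    force <- ifelse(r < cutoff, pref / r^2, 0)
  } else {
    shift <- if (is.finite(cutoff))
      pref * exp(-cutoff / screening_length) / cutoff else 0
    ex <- exp(-r / screening_length)
    energy <- ifelse(r < cutoff, pref * ex / r - shift, 0)
    force <- ifelse(r < cutoff,
                    pref * ex * (1 / r^2 + 1 / (r * screening_length)), 0)
  }
  list(energy = energy, force = force)
}

#' External (field and gate) forces on every bead
#'
#' Each charged bead whose z-coordinate lies inside the pore slab
#' (`|z| <= wall_thickness/2`, closed interval) receives the driving force
#' `q * (-E) z^`; the head monomer additionally feels the short-ranged WCA
#' gate that prevents re-entry past the pore exit.  All other beads get
#' zero.
#'
#' @param state A `particle_state`.
#' @param cfg A [system_config()].
#' @return n x 3 matrix of forces (kBT/sigma).
#' @export
external_forces <- function(state, cfg = state$cfg) {
  n <- nrow(state$pos)
  F <- matrix(0, n, 3)
  z <- state$pos[, 3]
  in_pore <- abs(z) <= cfg$wall_thickness / 2
  F[, 3] <- ifelse(in_pore, state$charge * (-cfg$E), 0)
  d <- z[1] - cfg$wall_thickness / 2
  if (d < 2^(1 / 6) * .gate_sigma) {
    w <- pair_wca(max(d, 1e-9), .gate_sigma, cfg$eps_bw)
    F[1, 3] <- F[1, 3] + w$force
  }
  F
}

#' Total potential energy and per-bead forces of a state
#'
#' Evaluates the full implemented force field (WCA, bonds, electrostatics,
#' driving field, gate) through the compiled kernel.  Forces are the exact
#' negative gradient of the returned energy.
#'
#' @param state A `particle_state`.
#' @param cfg A [system_config()].
#' @param E Field strength override (default `cfg$E`).
#' @param gate_on Whether the pore-exit gate is active.
#' @return List with `energy` (kBT) and `forces` (mobile beads x 3).
#' @export
compute_forces <- function(state, cfg = state$cfg, E = cfg$E,
                           gate_on = TRUE) {
  mob <- state$mobile
  cpp_forces(state$pos[mob, , drop = FALSE], state$charge[mob], state$bonds,
             state$pos[!mob, , drop = FALSE],
             .par_list(cfg, E = E, gate_on = gate_on), state$n_mono)
}

#' Advance a state by Langevin dynamics
#'
#' BAOAB-split underdamped Langevin integration of all mobile beads; wall
#' beads are never integrated.  With `zeta = 0` the scheme is exactly
#' velocity Verlet.  Uses R's RNG stream, so `set.seed()` makes runs
#' bit-reproducible.
#'
#' @param state A `particle_state`.
#' @param cfg A [system_config()].
#' @param steps Number of steps (default 1, i.e. a single Langevin step).
#' @param E Field strength (default `cfg$E`).
#' @param gate_on Whether the pore-exit gate acts on the head monomer.
#' @param record_s Record the translocation coordinate after every step.
#' @param stride Frame-recording stride in steps (0 = no frames).
#' @param stop_at_completion Stop as soon as `s == N`.
#' @return The advanced `particle_state`; attributes `s_series`,
#'   `frames`, `frame_times`, `steps_done`, `completed` carry the run
#'   record when requested.
#' @export
run_dynamics <- function(state, cfg = state$cfg, steps = 1L, E = cfg$E,
                         gate_on = TRUE, record_s = FALSE, stride = 0L,
                         stop_at_completion = FALSE) {
  stopifnot(inherits(state, "particle_state"))
  mob <- state$mobile
  res <- cpp_run(state$pos[mob, , drop = FALSE],
                 state$vel[mob, , drop = FALSE],
                 state$charge[mob], state$bonds,
                 state$pos[!mob, , drop = FALSE],
                 .par_list(cfg, E = E, gate_on = gate_on),
                 state$n_mono, as.integer(steps), as.integer(stride),
                 constrain_head = FALSE,
                 stop_at_completion = stop_at_completion,
                 record_s = record_s)
  state$pos[mob, ] <- res$pos
  state$vel[mob, ] <- res$vel
  attr(state, "s_series") <- res$s
  attr(state, "frames") <- res$frames
  attr(state, "frame_times") <- res$frame_steps * cfg$dt
  attr(state, "steps_done") <- res$steps_done
  attr(state, "completed") <- res$completed
  state
}

#' Single Langevin step
#'
#' Convenience wrapper over [run_dynamics()] with `steps = 1`.
#'
#' @inheritParams run_dynamics
#' @export
langevin_step <- function(state, cfg = state$cfg, E = cfg$E,
                          gate_on = TRUE) {
  run_dynamics(state, cfg, steps = 1L, E = E, gate_on = gate_on)
}

#' Run one driven translocation from release to completion
#'
#' Builds and equilibrates the system (unless a prepared state is given),
#' releases the head constraint, switches on the driving field and the
#' pore-exit gate, and integrates until all `N` monomers are in the trans
#' region or the step budget is exhausted.  The translocation coordinate is
#' recorded every integrator step, so waiting times are dt-resolution
#' exact; full frames are stored at `cfg$frame_stride`.
#'
#' @param cfg A [system_config()].
#' @param seed Seed for the run (initial build uses `cfg$seed`).
#' @param state Optional pre-built, pre-equilibrated `particle_state`.
#' @return List with `trajectory` (class `trajectory`: frames of mobile
#'   bead positions, times, `n_mono`) and `record` (class
#'   `translocation_record`: `s` series with times, waiting times `w`,
#'   translocation time `tau`, `completed` flag).
#' @export
run_translocation <- function(cfg, seed = cfg$seed, state = NULL) {
  stopifnot(inherits(cfg, "system_config"))
  if (is.null(state)) {
    state <- build_system(cfg)
    set.seed(seed)
    state <- equilibrate_initial(state, cfg)
  }
  set.seed(seed)
  s0 <- translocation_coordinate(state)
  out <- run_dynamics(state, cfg, steps = cfg$max_steps, E = cfg$E,
                      gate_on = TRUE, record_s = TRUE,
                      stride = cfg$frame_stride, stop_at_completion = TRUE)
  steps <- attr(out, "steps_done")
  s_series <- c(s0, attr(out, "s_series"))
  times <- seq(0, by = cfg$dt, length.out = length(s_series))
  completed <- isTRUE(attr(out, "completed"))
  frames <- attr(out, "frames")
  traj <- structure(list(frames = frames,
                         times = attr(out, "frame_times"),
                         n_mono = cfg$N, species = state$species[state$mobile],
                         charge = state$charge[state$mobile],
                         cfg = cfg),
                    class = "trajectory")
  rec <- structure(list(run_id = NA_integer_, seed = seed,
                        s = s_series, time = times,
                        tau = if (completed) steps * cfg$dt else NA_real_,
                        w = if (completed)
                          waiting_times(s_series, times, N = cfg$N) else NULL,
                        N = cfg$N, completed = completed),
                   class = "translocation_record")
  list(trajectory = traj, record = rec)
}

#' Run a seeded ensemble of translocations
#'
#' The system is built and equilibrated once (seeded by `seed`), and the
#' `M` runs all start from that common initial configuration with
#' independent noise seeds `seed + 1 .. seed + M`, so the variance of the
#' translocation coordinate is exactly zero at `t = 0`.
#'
#' @param cfg A [system_config()].
#' @param M Number of runs.
#' @param seed Base seed.
#' @param keep_frames Keep full trajectories (needed for conformation and
#'   tension analyses); records alone are much lighter.
#' @return List with `records` (list of `translocation_record`),
#'   `trajectories` (list of `trajectory` or `NULL`), `cfg`, `M`, `seed`.
#' @export
run_ensemble <- function(cfg, M = 32L, seed = cfg$seed, keep_frames = TRUE) {
  state <- build_system(cfg)
  set.seed(seed)
  state <- equilibrate_initial(state, cfg)
  records <- vector("list", M)
  trajectories <- if (keep_frames) vector("list", M) else NULL
  for (kk in seq_len(M)) {
    res <- run_translocation(cfg, seed = seed + kk, state = state)
    res$record$run_id <- kk
    records[[kk]] <- res$record
    if (keep_frames) trajectories[[kk]] <- res$trajectory
  }
  list(records = records, trajectories = trajectories, cfg = cfg,
       M = as.integer(M), seed = as.integer(seed))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %d beads (%d monomers), t = %g .. %g tau_u\n",
              length(x$frames), if (length(x$frames)) nrow(x$frames[[1]]) else 0,
              x$n_mono,
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  invisible(x)
}

#' @export
print.translocation_record <- function(x, ...) {
  cat(sprintf("Translocation record: N = %d, %s, tau = %s tau_u (seed %d)\n",
              x$N, if (x$completed) "completed" else "incomplete",
              format(x$tau), x$seed))
  invisible(x)
}

#' Append a line-oriented run log entry
#'
#' @param path Log file path.
#' @param cfg A [system_config()].
#' @param seed Run seed.
#' @param status Completion status string.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, cfg, seed, status = "completed") {
  line <- sprintf("config=%s seed=%d N=%d E=%g integrator=BAOAB electrostatics=%s status=%s",
                  config_hash(cfg), seed, cfg$N, cfg$E, cfg$electrostatics,
                  status)
  cat(line, "\n", file = path, append = TRUE, sep = "")
  invisible(path)
}
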