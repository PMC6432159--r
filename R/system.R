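# System construction: wall lattice with pore, threaded chain, ions.
#
# Coordinate frame (package-wide): pore axis = z, wall centered at z = 0,
# trans side = +z.  x, y in [-box/2, box/2), periodic.

.gate_sigma <- 1.0  # WCA range of the pore-exit gate (sigma)

#' Build the particle system for a translocation run
#'
#' Constructs the membrane wall (two square-lattice layers of immobile
#' beads at the wall faces, cleared within `pore_radius` of the z-axis),
#' threads the chain head section through the pore with the head monomer
#' held one WCA contact distance above the pore exit, grows the remaining
#' monomers as a cis-side self-avoiding walk, and (for explicit-ion
#' configurations) scatters `N` counterions and `n_salt` salt pairs in the
#' fluid volume with no hard overlaps.  Net charge is zero by construction
#' in explicit-ion mode.
#'
#' Building is deterministic given `cfg$seed`.
#'
#' @param cfg A [system_config()].
#' @return An object of class `particle_state`: list with `pos`, `vel`
#'   (n x 3), `charge`, `species` (monomer/counterion/coion/wall), `mobile`,
#'   `bonds` (chain connectivity, consecutive monomers), `n_mono`, `cfg`.
#' @export
build_system <- function(cfg) {
  stopifnot(inherits(cfg, "system_config"))
  set.seed(cfg$seed)
  wall <- .wall_lattice(cfg)
  chain <- .place_chain(cfg, wall)
  n_ion <- if (cfg$explicit_ions) cfg$N + 2L * cfg$n_salt else 0L
  ion_pos <- if (n_ion > 0) .place_ions(cfg, n_ion, chain, wall) else
    matrix(0, 0, 3)
  ion_charge <- if (n_ion > 0)
    c(rep(1, cfg$N), rep(c(1, -1), length.out = 2L * cfg$n_salt)) else numeric(0)
  ion_species <- if (n_ion > 0)
    c(rep("counterion", cfg$N),
      rep(c("counterion", "coion"), length.out = 2L * cfg$n_salt)) else
    character(0)
  # salt cations are chemically counterion-species too; keep salt labels
  if (cfg$n_salt > 0 && n_ion > 0)
    ion_species[(cfg$N + 1):n_ion] <- rep(c("counterion", "coion"),
                                          length.out = 2L * cfg$n_salt)

  pos <- rbind(chain, ion_pos, wall)
  n <- nrow(pos)
  n_mobile <- cfg$N + n_ion
  state <- list(
    pos = pos,
    vel = matrix(0, n, 3),
    charge = c(rep(cfg$monomer_charge, cfg$N), ion_charge,
               rep(0, nrow(wall))),
    species = c(rep("monomer", cfg$N), ion_species,
                rep("wall", nrow(wall))),
    mobile = c(rep(TRUE, n_mobile), rep(FALSE, nrow(wall))),
    bonds = cbind(seq_len(cfg$N - 1L), seq_len(cfg$N - 1L) + 1L),
    n_mono = cfg$N,
    cfg = cfg
  )
  class(state) <- "particle_state"
  state
}

# Two square-lattice layers of immobile beads at z = +/- wall_thickness/2,
# spacing ~wall_spacing (snapped to tile the periodic box), beads within
# pore_radius of the axis removed.
.wall_lattice <- function(cfg) {
  nx <- max(1L, round(cfg$box[1] / cfg$wall_spacing))
  ny <- max(1L, round(cfg$box[2] / cfg$wall_spacing))
  xs <- (seq_len(nx) - 1) * cfg$box[1] / nx - cfg$box[1] / 2
  ys <- (seq_len(ny) - 1) * cfg$box[2] / ny - cfg$box[2] / 2
  g <- expand.grid(x = xs, y = ys)
  keep <- sqrt(g$x^2 + g$y^2) >= cfg$pore_radius
  g <- g[keep, , drop = FALSE]
  zh <- cfg$wall_thickness / 2
  rbind(cbind(g$x, g$y, rep(-zh, nrow(g))),
        cbind(g$x, g$y, rep(+zh, nrow(g))))
}

# Clearance check against the (immobile) wall beads: TRUE when the point
# keeps a near-contact WCA distance from every wall bead.
.clear_of_wall <- function(p, wall, cfg) {
  dz <- abs(wall[, 3] - p[3])
  rc <- 0.95 * cfg$sigma_bw
  near <- dz < rc
  if (!any(near)) return(TRUE)
  w <- wall[near, , drop = FALSE]
  d2 <- (w[, 1] - p[1])^2 + (w[, 2] - p[2])^2 + (w[, 3] - p[3])^2
  all(d2 >= rc^2)
}

# Head section collinear along the pore axis, head one WCA contact distance
# above the exit plane; remainder grown as a cis-side self-avoiding walk.
.place_chain <- function(cfg, wall) {
  zh <- cfg$wall_thickness / 2
  z_head <- zh + 2^(1 / 6) * .gate_sigma
  pos <- matrix(NA_real_, cfg$N, 3)
  i <- 1L
  z <- z_head
  while (i <= cfg$N && z >= -(zh + cfg$l0)) {
    pos[i, ] <- c(0, 0, z)
    z <- z - cfg$l0
    i <- i + 1L
  }
  min2 <- (0.9 * cfg$sigma_bb)^2
  while (i <= cfg$N) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- pos[i - 1L, ] + cfg$l0 * u
      if (cand[3] > -zh) next                       # stay on the cis side
      if (abs(cand[1]) > cfg$box[1] / 2 - 1 ||
          abs(cand[2]) > cfg$box[2] / 2 - 1 ||
          cand[3] < -cfg$box[3] / 2 + 1) next
      if (!.clear_of_wall(cand, wall, cfg)) next
      prev <- pos[seq_len(i - 1L), , drop = FALSE]
      d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
        (prev[, 3] - cand[3])^2
      d2[i - 1L] <- Inf                             # bonded neighbor exempt
      if (any(d2 < min2)) next
      pos[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed)
      stop("cannot place monomer ", i, " without overlap near the cis side ",
           "of the pore; the region is too crowded")
    i <- i + 1L
  }
  pos
}

# Ions uniform in the fluid volume, hard-core rejection against everything
# already placed.
.place_ions <- function(cfg, n_ion, chain, wall) {
  zh <- cfg$wall_thickness / 2
  min2 <- (0.9 * cfg$sigma_bb)^2
  out <- matrix(NA_real_, n_ion, 3)
  all_pos <- chain
  for (i in seq_len(n_ion)) {
    placed <- FALSE
    for (try in seq_len(5000L)) {
      x <- stats::runif(1, -cfg$box[1] / 2, cfg$box[1] / 2)
      y <- stats::runif(1, -cfg$box[2] / 2, cfg$box[2] / 2)
      z <- stats::runif(1, -cfg$box[3] / 2 + 1, cfg$box[3] / 2 - 1)
      if (abs(z) < zh + 0.95 * cfg$sigma_bw) next   # keep clear of the wall
      d2 <- (all_pos[, 1] - x)^2 + (all_pos[, 2] - y)^2 + (all_pos[, 3] - z)^2
      if (any(d2 < min2)) next
      if (!.clear_of_wall(c(x, y, z), wall, cfg)) next
      out[i, ] <- c(x, y, z)
      all_pos <- rbind(all_pos, out[i, ])
      placed <- TRUE
      break
    }
    if (!placed)
      stop("cannot place ion ", i, " without overlap in the fluid volume; ",
           "the box is too crowded")
  }
  out
}

#' @export
print.particle_state <- function(x, ...) {
  cat(sprintf("Particle state: %d beads (%d monomers, %d ions, %d wall)\n",
              nrow(x$pos), x$n_mono,
              sum(x$species %in% c("counterion", "coion")),
              sum(x$species == "wall")))
  cat(sprintf("  net charge %g e, s = %d\n", sum(x$charge),
              translocation_coordinate(x)))
  invisible(x)
}

# Assemble the C++ parameter list from a config.
.par_list <- function(cfg, E = cfg$E, gate_on = TRUE) {
  mode <- switch(cfg$electrostatics, none = 0L, direct = 1L, screened = 2L)
  list(box_x = cfg$box[1], box_y = cfg$box[2], box_z = cfg$box[3],
       periodic_z = cfg$periodic_z, wall_half = cfg$wall_thickness / 2,
       k = cfg$k, l0 = cfg$l0,
       sigma_bb = cfg$sigma_bb, eps_bb = cfg$eps_bb,
       sigma_bw = cfg$sigma_bw, eps_bw = cfg$eps_bw,
       lambda_B = cfg$lambda_B, coul_mode = mode,
       r_cut = cfg$coulomb_cutoff, screen_len = cfg$screening_length,
       E = E, gate_on = gate_on, gate_z = cfg$wall_thickness / 2,
       gate_sigma = .gate_sigma, gate_eps = cfg$eps_bw,
       head = 0L, dt = cfg$dt, zeta = cfg$zeta, mass = 1.0, kBT = 1.0)
}

#' Constrained pre-release equilibration
#'
#' Runs Langevin dynamics with the head monomer held fixed at its
#' constraint point above the pore exit and the driving field off, relaxing
#' the threaded chain (and ions, if explicit) before release.
#'
#' @param state A built [build_system()] state.
#' @param cfg The matching [system_config()].
#' @param steps Number of integration steps (default
#'   `cfg$equilibration_steps`); `0` returns the state unchanged.
#' @return The relaxed `particle_state`, with attribute `pre_release_s`
#'   holding the translocation coordinate at release.
#' @export
equilibrate_initial <- function(state, cfg = state$cfg,
                                steps = cfg$equilibration_steps) {
  stopifnot(inherits(state, "particle_state"), steps >= 0)
  if (steps == 0) {
    attr(state, "pre_release_s") <- translocation_coordinate(state)
    return(state)
  }
  mob <- state$mobile
  res <- cpp_run(state$pos[mob, , drop = FALSE],
                 state$vel[mob, , drop = FALSE],
                 state$charge[mob], state$bonds,
                 state$pos[!mob, , drop = FALSE],
                 .par_list(cfg, E = 0, gate_on = FALSE),
                 state$n_mono, as.integer(steps), 0L,
                 constrain_head = TRUE, stop_at_completion = FALSE,
                 record_s = FALSE)
  state$pos[mob, ] <- res$pos
  state$vel[mob, ] <- res$vel
  s0 <- translocation_coordinate(state)
  if (s0 < 1)
    stop("equilibration violated the head constraint: the chain retracted ",
         "fully to the cis side")
  attr(state, "pre_release_s") <- s0
  state
}
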