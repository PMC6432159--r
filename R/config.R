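# System configuration: every physical and numerical parameter of one run.

#' Configure a translocation simulation
#'
#' Collects all physical and numerical parameters of the driven-translocation
#' system: a charged bead-spring chain of `N` monomers (charge -1 e each)
#' threaded through a cylindrical pore in an immobile-bead membrane wall,
#' driven by an electric field of strength `E` applied inside the pore.
#'
#' Interaction defaults follow the standard parameterization of this model:
#' WCA excluded volume with `sigma_bb = 1`, `eps_bb = 1.2` between mobile
#' beads and `sigma_bw = 1.5`, `eps_bw = 2.5` against wall beads; harmonic
#' bonds with `k = 600`, `l0 = 1`; Bjerrum length `lambda_B = 3`.  All in
#' reduced units (sigma, kBT, e, m, tau_u).
#'
#' @param N Number of chain monomers (>= 2).
#' @param E Driving field strength in kBT/(e sigma), applied inside the pore.
#' @param box Box dimensions in sigma (x, y periodic; z closed by default).
#' @param wall_thickness Wall slab thickness (sigma); the pore region is
#'   `|z| <= wall_thickness/2`.
#' @param pore_radius Pore channel radius (sigma).
#' @param k,l0 Harmonic bond spring constant (kBT/sigma^2) and rest length.
#' @param sigma_bb,eps_bb WCA parameters between mobile beads.
#' @param sigma_bw,eps_bw WCA parameters between mobile and wall beads.
#' @param lambda_B Bjerrum length (sigma).
#' @param n_salt Added salt molecules (pairs) for explicit-ion builds.
#' @param monomer_charge Charge per monomer in e (default -1).
#' @param zeta Langevin friction coefficient (m/tau_u).
#' @param dt Integration time step (tau_u).
#' @param seed Base random seed.
#' @param electrostatics One of `"screened"` (Debye-Hückel, implicit ions),
#'   `"direct"` (truncated-shifted Coulomb, minimum image, explicit ions),
#'   or `"none"`.
#' @param explicit_ions Whether counterions and salt are explicit beads.
#'   Defaults to `TRUE` for `"direct"` electrostatics and `FALSE` for the
#'   implicit-salt `"screened"` mode.
#' @param coulomb_cutoff Electrostatic cutoff (sigma).
#' @param screening_length Debye length for `"screened"` mode (sigma);
#'   `NULL` derives it from `n_salt` via [osf_persistence_length()] inputs.
#' @param equilibration_steps Pre-release constrained equilibration steps.
#' @param max_steps Step budget for one translocation run.
#' @param frame_stride Steps between stored trajectory frames.
#' @param wall_spacing Lattice spacing of the wall beads (sigma).
#' @param periodic_z Use full 3D periodicity instead of a z-closed box.
#' @return An object of class `system_config`.
#' @export
system_config <- function(N = 32, E = 1.0,
                          box = c(48.0, 49.36, 200.0),
                          wall_thickness = 4.5, pore_radius = 2.25,
                          k = 600.0, l0 = 1.0,
                          sigma_bb = 1.0, eps_bb = 1.2,
                          sigma_bw = 1.5, eps_bw = 2.5,
                          lambda_B = 3.0, n_salt = 256,
                          monomer_charge = -1, zeta = 1.0, dt = 0.005,
                          seed = 1L,
                          electrostatics = c("screened", "direct", "none"),
                          explicit_ions = NULL,
                          coulomb_cutoff = 10.0, screening_length = NULL,
                          equilibration_steps = 50000L,
                          max_steps = 2000000L, frame_stride = 200L,
                          wall_spacing = 1.5, periodic_z = FALSE) {
  electrostatics <- match.arg(electrostatics)
  if (N < 2) stop("N must be at least 2")
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths")
  if (pore_radius >= min(box[1], box[2]) / 2)
    stop("pore_radius must be smaller than half the box cross-section")
  if (wall_thickness >= box[3]) stop("wall_thickness must be below box_z")
  pos_pars <- c(k = k, l0 = l0, sigma_bb = sigma_bb, eps_bb = eps_bb,
                sigma_bw = sigma_bw, eps_bw = eps_bw, lambda_B = lambda_B,
                zeta = zeta, dt = dt, wall_spacing = wall_spacing)
  bad <- names(pos_pars)[pos_pars <= 0]
  if (length(bad)) stop("parameters must be positive: ",
                        paste(bad, collapse = ", "))
  if (is.null(explicit_ions)) explicit_ions <- (electrostatics == "direct")
  if (is.null(screening_length)) {
    sc <- salt_concentration(salt_spec(n_salt = max(n_salt, 1), box = box,
                                       wall_thickness = wall_thickness))
    screening_length <- 1 / sqrt(8 * pi * lambda_B * sc$sigma3)
  }
  cfg <- list(N = as.integer(N), E = E, box = box,
              wall_thickness = wall_thickness, pore_radius = pore_radius,
              k = k, l0 = l0, sigma_bb = sigma_bb, eps_bb = eps_bb,
              sigma_bw = sigma_bw, eps_bw = eps_bw, lambda_B = lambda_B,
              n_salt = as.integer(n_salt), monomer_charge = monomer_charge,
              zeta = zeta, dt = dt, seed = as.integer(seed),
              electrostatics = electrostatics,
              explicit_ions = isTRUE(explicit_ions),
              coulomb_cutoff = coulomb_cutoff,
              screening_length = screening_length,
              equilibration_steps = as.integer(equilibration_steps),
              max_steps = as.integer(max_steps),
              frame_stride = as.integer(frame_stride),
              wall_spacing = wall_spacing, periodic_z = isTRUE(periodic_z))
  class(cfg) <- "system_config"
  cfg
}

#' @export
print.system_config <- function(x, ...) {
  cat(sprintf("Translocation config: N = %d, E = %g kBT/(e sigma), %s electrostatics (%s ions)\n",
              x$N, x$E, x$electrostatics,
              if (x$explicit_ions) "explicit" else "implicit"))
  cat(sprintf("  box %g x %g x %g sigma, wall %g sigma, pore radius %g sigma\n",
              x$box[1], x$box[2], x$box[3], x$wall_thickness, x$pore_radius))
  cat(sprintf("  k = %g, l0 = %g, lambda_B = %g, zeta = %g, dt = %g\n",
              x$k, x$l0, x$lambda_B, x$zeta, x$dt))
  invisible(x)
}

#' Read or write a configuration as sectioned key/value text
#'
#' The on-disk format is line-oriented `key = value` pairs; `[section]`
#' headers and `#` comments are allowed and ignored on read.  Vector values
#' (the box) are comma-separated.
#'
#' @param path File path.
#' @param cfg A [system_config()].
#' @return `read_config` returns a `system_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  if (!all(grepl("=", lines, fixed = TRUE)))
    stop("malformed config line (missing '='): ",
         lines[!grepl("=", lines, fixed = TRUE)][1])
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  known <- names(formals(system_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  args <- lapply(seq_along(keys), function(i) {
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num
    else if (vals[i] %in% c("TRUE", "FALSE")) as.logical(vals[i])
    else vals[i]
  })
  names(args) <- keys
  do.call(system_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "system_config"))
  fmt <- function(v) paste(vapply(v, format, "", digits = 15), collapse = ",")
  lines <- c("[system]",
             vapply(names(cfg), function(k) sprintf("%s = %s", k, fmt(cfg[[k]])),
                    ""))
  writeLines(lines, path)
  invisible(path)
}

#' Hash a configuration for run logs
#'
#' A short deterministic digest of the flattened key/value representation,
#' used to tag run logs and outputs.  Not cryptographic.
#'
#' @param cfg A [system_config()].
#' @return A character scalar.
#' @export
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v, digits = 15),
                                                       collapse = ","), ""),
             sep = "=", collapse = ";")
  bytes <- utf8ToInt(s)
  h <- c(5381, 52711)
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x%08x", h[1], h[2])
}
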