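# Simulation (sigma, m, kBT, e) unit system and its mapping to real units.
#
# All dynamics and analysis in this package work in reduced units: length in
# sigma, energy in kBT, charge in e, mass in m, time in tau_u =
# sigma*sqrt(m/kBT).  This file maps those to laboratory units and computes
# the Odijk-Skolnick-Fixman (OSF) persistence length of the charged chain.

# Physical constants.  kB*T is kept at the rounded 4.14e-21 J (T = 300 K)
# because the canonical aqueous mapping of this model was computed with that
# rounded value; using kB*300 exactly would shift the printed table in the
# third digit.
.kB <- 1.380649e-23   # J/K
.NA_mol <- 6.02214e23 # 1/mol
.kBT_300K <- 4.14e-21 # J

#' Define a simulation-to-real unit system
#'
#' The reduced-unit system is anchored by four base quantities: the length
#' unit `sigma` (in Angstrom), the bead mass `m` (g/mol), the thermal energy
#' `kBT` (J), and the elementary charge `e` (C).  The time unit
#' `tau_u = sigma * sqrt(m / kBT)` is derived.  The default values give the
#' aqueous mapping of the model: the Bjerrum length of water (7.14 Angstrom)
#' is identified with its reduced value of 3 sigma, so sigma = 2.38 Angstrom.
#'
#' @param length_A Angstrom per sigma.
#' @param mass_gmol g/mol per bead mass unit m.
#' @param energy_J J per kBT.
#' @param charge_C C per unit charge e.
#' @param bjerrum_sigma Bjerrum length in sigma.
#' @return An object of class `unit_system` with fields `length_unit_A`,
#'   `mass_unit_gmol`, `thermal_energy_J`, `charge_unit_C`, `time_unit_ps`
#'   (derived), and `bjerrum_sigma`.
#' @examples
#' u <- unit_system()
#' u$time_unit_ps  # 2.13 ps
#' @export
unit_system <- function(length_A = 2.38, mass_gmol = 200,
                        energy_J = .kBT_300K, charge_C = 1.602e-19,
                        bjerrum_sigma = 3.0) {
  vals <- c(length_A, mass_gmol, energy_J, charge_C, bjerrum_sigma)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all unit-system quantities must be finite and strictly positive")
  mass_kg <- mass_gmol * 1e-3 / .NA_mol
  time_s <- (length_A * 1e-10) * sqrt(mass_kg / energy_J)
  structure(list(
    length_unit_A = length_A,
    mass_unit_gmol = mass_gmol,
    thermal_energy_J = energy_J,
    charge_unit_C = charge_C,
    time_unit_ps = time_s * 1e12,
    bjerrum_sigma = bjerrum_sigma
  ), class = "unit_system")
}

#' Length unit fixed by matching the Bjerrum length
#'
#' The solvent's Bjerrum length (7.14 Angstrom in water at room temperature)
#' is identified with its value in reduced units, which fixes the length
#' unit: `sigma = bjerrum_real_A / bjerrum_sigma`.
#'
#' @param bjerrum_real_A Real Bjerrum length in Angstrom.
#' @param bjerrum_sigma Reduced Bjerrum length in sigma.
#' @return Angstrom per sigma.
#' @examples
#' length_unit_from_bjerrum(7.14, 3.0)  # 2.38
#' @export
length_unit_from_bjerrum <- function(bjerrum_real_A, bjerrum_sigma) {
  if (!is.finite(bjerrum_real_A) || !is.finite(bjerrum_sigma) ||
      bjerrum_real_A <= 0 || bjerrum_sigma <= 0)
    stop("Bjerrum lengths must be finite and strictly positive")
  bjerrum_real_A / bjerrum_sigma
}

#' Table of derived real units
#'
#' Converts the base units to the derived units used throughout: time
#' (ps per tau_u), force (pN per kBT/sigma), electric field (V/m per
#' kBT/(e sigma)), concentration (mol/L per sigma^-3), and energy (J per
#' kBT).
#'
#' @param u A [unit_system()].
#' @return A data.frame with columns `quantity`, `sim_unit`, `value`,
#'   `real_unit`.
#' @examples
#' real_unit_table(unit_system())
#' @export
real_unit_table <- function(u) {
  stopifnot(inherits(u, "unit_system"))
  length_m <- u$length_unit_A * 1e-10
  force_N <- u$thermal_energy_J / length_m
  field_Vm <- force_N / u$charge_unit_C
  conc_molL <- 1 / (.NA_mol * (u$length_unit_A * 1e-9)^3) # sigma^3 in dm^3
  data.frame(
    quantity = c("time", "force", "field", "concentration", "energy"),
    sim_unit = c("tau_u", "kBT/sigma", "kBT/(e sigma)", "1/sigma^3", "kBT"),
    value = c(u$time_unit_ps, force_N * 1e12, field_Vm, conc_molL,
              u$thermal_energy_J),
    real_unit = c("ps", "pN", "V/m", "mol/L", "J"),
    stringsAsFactors = FALSE
  )
}

#' Convert a quantity between simulation and real units
#'
#' @param x Numeric value(s).
#' @param quantity One of `"length"`, `"time"`, `"force"`, `"field"`,
#'   `"concentration"`, `"energy"`.
#' @param u A [unit_system()].
#' @return Converted value(s).  `to_real` maps sim -> real (Angstrom, ps,
#'   pN, V/m, mol/L, J); `to_sim` is its exact inverse.
#' @export
to_real <- function(x, quantity, u = unit_system()) {
  x * .unit_factor(quantity, u)
}

#' @rdname to_real
#' @export
to_sim <- function(x, quantity, u = unit_system()) {
  x / .unit_factor(quantity, u)
}

.unit_factor <- function(quantity, u) {
  tab <- real_unit_table(u)
  if (quantity == "length") return(u$length_unit_A)
  i <- match(quantity, tab$quantity)
  if (is.na(i)) stop("unknown quantity '", quantity, "'")
  tab$value[i]
}

#' Describe the salt content of a simulation box
#'
#' The ionic strength is the salt number density in the fluid volume, i.e.
#' the box volume with the wall slab excluded:
#' `I = n_salt / (box_x * box_y * (box_z - wall_thickness))`.
#'
#' @param n_salt Number of added salt molecules (monovalent pairs).
#' @param box Box dimensions `c(x, y, z)` in sigma.
#' @param wall_thickness Membrane wall thickness in sigma.
#' @param charge_spacing Distance between charges along the backbone
#'   (sigma).
#' @param intrinsic_persistence Intrinsic persistence length (sigma).
#' @return An object of class `salt_spec`.
#' @export
salt_spec <- function(n_salt = 256, box = c(48.0, 49.36, 200.0),
                      wall_thickness = 4.5, charge_spacing = 1.0,
                      intrinsic_persistence = 1.0) {
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths")
  if (box[3] <= wall_thickness)
    stop("box_z must exceed the wall thickness (no fluid volume left)")
  if (n_salt < 0) stop("n_salt must be non-negative")
  structure(list(
    n_salt = n_salt, box = box, wall_thickness = wall_thickness,
    charge_spacing = charge_spacing,
    intrinsic_persistence = intrinsic_persistence
  ), class = "salt_spec")
}

#' Salt concentration in reduced and molar units
#'
#' @param spec A [salt_spec()].
#' @param u A [unit_system()].
#' @return List with `sigma3` (number density in sigma^-3) and `mol_L`.
#' @examples
#' salt_concentration(salt_spec())$mol_L  # 0.068
#' @export
salt_concentration <- function(spec, u = unit_system()) {
  stopifnot(inherits(spec, "salt_spec"))
  vol <- spec$box[1] * spec$box[2] * (spec$box[3] - spec$wall_thickness)
  cs <- spec$n_salt / vol
  list(sigma3 = cs, mol_L = cs * .unit_factor("concentration", u))
}

#' Odijk-Skolnick-Fixman persistence length
#'
#' Electrostatic stiffening of a charged chain screened by salt:
#' `kappa = sqrt(8 * pi * lambda_B * I)` is the inverse Debye length and
#' `lp_e = lambda_B / (4 * (kappa * l_c)^2)` the electrostatic persistence
#' length, added to the intrinsic `lp_0`.  The ionic strength is taken equal
#' to the (monovalent) salt concentration.
#'
#' @param spec A [salt_spec()].
#' @param u A [unit_system()] (supplies `lambda_B` in sigma and the length
#'   unit).
#' @return List with `lpe_sigma`, `lp_sigma`, `lp_A`, plus `kappa_sigma_inv`
#'   and `debye_length_sigma`.
#' @examples
#' osf_persistence_length(salt_spec())  # lp_e = 18.0 sigma, lp = 45.2 A
#' @export
osf_persistence_length <- function(spec, u = unit_system()) {
  stopifnot(inherits(spec, "salt_spec"), inherits(u, "unit_system"))
  I <- salt_concentration(spec, u)$sigma3
  if (I <= 0)
    stop("ionic strength is zero: the electrostatic persistence length ",
         "diverges (unscreened limit); no finite value is returned")
  kappa <- sqrt(8 * pi * u$bjerrum_sigma * I)
  lpe <- u$bjerrum_sigma / (4 * (kappa * spec$charge_spacing)^2)
  lp <- spec$intrinsic_persistence + lpe
  list(lpe_sigma = lpe, lp_sigma = lp, lp_A = lp * u$length_unit_A,
       kappa_sigma_inv = kappa, debye_length_sigma = 1 / kappa)
}

#' Print method for unit systems
#' @param x A `unit_system`.
#' @param ... Unused.
#' @export
print.unit_system <- function(x, ...) {
  cat(sprintf("Unit system: sigma = %.4g A, m = %.4g g/mol, kBT = %.4g J, e = %.4g C\n",
              x$length_unit_A, x$mass_unit_gmol, x$thermal_energy_J,
              x$charge_unit_C))
  tab <- real_unit_table(x)
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  1 %-13s = %.4g %s\n", tab$sim_unit[i], tab$value[i],
                tab$real_unit[i]))
  invisible(x)
}

#' Write a unit table as a flat key-value text file
#' @param u A [unit_system()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_unit_table <- function(u, path) {
  tab <- real_unit_table(u)
  lines <- c(
    sprintf("length_A = %.15g", u$length_unit_A),
    sprintf("mass_gmol = %.15g", u$mass_unit_gmol),
    sprintf("energy_J = %.15g", u$thermal_energy_J),
    sprintf("charge_C = %.15g", u$charge_unit_C),
    sprintf("%s_%s = %.15g", tab$quantity, gsub("/", "_per_", tab$real_unit),
            tab$value))
  writeLines(lines, path)
  invisible(path)
}
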