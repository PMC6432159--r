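---
title: "Driven polyelectrolyte translocation: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driven polyelectrolyte translocation: model, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical model

`poretrans` simulates a charged bead-spring chain pulled through a
nanopore by an electric field confined to the pore channel, the standard
coarse-grained picture of voltage-driven DNA translocation. A membrane
wall of thickness 4.5 σ, centered at z = 0, separates the cis (z < 0)
and trans (z > 0) half-spaces; a cylindrical channel of radius 2.25 σ
along the z-axis connects them. Each monomer carries charge −1 e; in
explicit-ion mode every monomer dissociates a monovalent counterion and
an adjustable number of salt pairs is added, so the net charge is zero.

All quantities are in reduced units: length σ, energy kBT, charge e,
bead mass m, time τᵤ = σ√(m/kBT). The aqueous mapping anchors σ to the
Bjerrum length of water (7.14 Å = 3 σ, so σ = 2.38 Å); with
m = 200 g/mol (roughly one nucleobase) and kBT = 4.14×10⁻²¹ J (300 K,
kept at this rounded value so the printed unit table is reproducible),
the derived units are 2.13 ps, 17.4 pN, 1.08×10⁸ V/m and 123.2 mol/L.

Interactions:

* **WCA excluded volume** between all mobile pairs
  (σ_bb = 1, ε_bb = 1.2) and between mobile and wall beads
  (σ_bw = 1.5, ε_bw = 2.5); energy-shifted so energy and force vanish
  continuously at the 2^(1/6) σᵢⱼ cutoff.
* **Harmonic bonds**, k = 600 kBT/σ², ℓ0 = 1 σ. The WCA core also acts
  between bonded neighbors, so the equilibrium bond length sits slightly
  above ℓ0 — the test oracles integrate the combined Boltzmann weight.
* **Electrostatics** with λB = 3 σ. The default desk mode is
  Debye–Hückel screened Coulomb (minimum image, truncated-shifted at
  10 σ) with the Debye length κ⁻¹ = (8π λB I)^(−1/2) computed from the
  salt concentration; ions are then implicit. Direct truncated-shifted
  Coulomb with explicit ions is available (`electrostatics = "direct"`),
  and both modes are exact gradients of the stated energy, which the
  tests verify by central differences. A full Ewald treatment is an
  extension point, not included.
* **Driving field** −E ẑ acting on every charge inside the pore slab
  |z| ≤ 2.25 σ (closed interval; membership uses z only, since only
  channel beads can occupy that slab).
* **Exit gate**: a half-space WCA ramp, felt only by the head monomer,
  diverging at the pore-exit plane. It guarantees threading success, so
  failed-translocation statistics are out of scope by construction.

The wall is hollow: two square-lattice layers of immobile beads
(spacing ≈ 1.5 σ, snapped to tile the periodic cross-section) at the
two wall faces z = ±2.25 σ, with beads within the pore radius of the
axis removed. The σ_bw = 1.5 WCA closes the lattice gaps (the barrier at
a lattice-cell center is several hundred kBT), and the effective open
pore radius is ≈ 1 σ — single-file threading, as intended.

## Integration and initialization

Dynamics is underdamped Langevin, integrated with the BAOAB splitting at
dt = 0.005 τᵤ and friction ζ = 1 m/τᵤ (typical values for this
bead-spring class; both configurable). With ζ = 0 the O-step is the
identity and the scheme reduces exactly to velocity Verlet, so the
zero-friction energy-conservation test exercises the production code
path. Random numbers come from R's RNG: `set.seed()` makes builds, runs
and whole ensembles bit-reproducible.

Initialization threads the head section collinearly along the pore axis
with the head monomer one WCA contact distance (2^(1/6) σ) above the
exit plane — the gate potential diverges *at* the plane, so the head can
sit at the exit but never re-enter; the remaining monomers grow as a
cis-side self-avoiding walk that also keeps a near-contact clearance
from the wall beads. The system is then equilibrated for 5×10⁴ steps
(250 τᵤ, several Rouse times of the short confined sections at desk
scale) with the head position-constrained and the field off. A
translocation starts by releasing the constraint and switching on the
field, and ends when all N monomers are in the trans region; exhausted
step budgets are flagged, never silently truncated.

Ensembles (`run_ensemble`) share one equilibrated initial configuration
across the M runs, with independent noise seeds afterwards. This makes
the variance of the translocation coordinate exactly zero at t = 0,
which is the property the drift-diffusion analysis pins at both ends of
the process. The cost is that ensemble averages are conditioned on one
initial conformation; with runs much longer than the conformational
relaxation time (weak fields) this washes out, while for strong fields
it suppresses the run-to-run spread that independent coils would add —
see the scale limitations below.

## Analysis conventions

* **Waiting times** are accumulated at integrator-step resolution (not
  frame resolution), because at strong fields a state's dwell time is
  only a few dt. The terminal state s = N is excluded (the chain dwells
  there forever), giving Σₛ w_k(s) = τ_k exactly.
* **Scaled time** uses each run's own τ_k, so every run spans
  t̃ ∈ [0, 1] (a global-⟨τ⟩ mode is provided). The per-run choice keeps
  end-of-process features aligned across runs.
* **Sub-chain membership** for cis/trans descriptors is by monomer z;
  pore monomers belong to neither sub-chain. Sub-chains with fewer than
  two beads are flagged and skipped, not averaged. η within a time bin
  is the ratio of the binned means of Re² and Rg², matching its
  ensemble definition.
* **Angles**: the principal axis is sign-fixed to e₁z > 0; θ and φ use
  full-quadrant arctangents, θ ∈ [0°, 180°], φ ∈ (−180°, 180°]; a
  λ1 = λ2 degeneracy is reported as a flag, not a number.
* **Pore distances**: D_n is measured to the intersection of the pore
  axis with the wall face on the monomer's own side; Λ_n follows the
  backbone from monomer n to the last monomer before region II and then
  adds that monomer's direct distance. With this convention
  D_n ≤ Λ_n is a theorem (triangle inequality along the path), and both
  vanish identically for pore monomers. Configurations with no pore
  monomer (pre-release, post-completion) are computed toward the
  nearest pore mouth and flagged.
* **Straightened section**: the largest contour depth from the pore
  outward over which ⟨D⟩/⟨Λ⟩ ≥ 0.9 holds monomer by monomer (0 if the
  first monomer fails).
* **Tension front**: scanning from the free end toward the pore, the
  deepest bond whose mean tension exceeds the trans-plateau background
  by 3 standard deviations of the plateau tensions. The plateau scatter
  is the per-bond noise floor of the averaged profile, so a
  noise-band (SD) rule is used rather than a standard-error rule — an
  SE band sits below single-bond noise and would flag a false front on
  essentially every flat profile. Both the background estimator and the
  threshold are explicit arguments.
* **Hump position** s̃*: argmax of w̃ inside an interior window,
  [0.05, 0.95] by default, excluding the field-switch-on peak near 0
  and the crowding overshoot near 1. At desk-scale N the switch-on peak
  reaches farther into the interior (it sits at s̃ ≈ s₀/N), so the
  desk analyses use a window starting at 0.2.
* **Log-normal fits** of the first-passage density hold the amplitude
  A_s fixed at its waiting-time value w(s)/⟨τ⟩ and fit (σ_s, μ_s) by
  Levenberg–Marquardt (minpack.lm) on a log-spaced histogram; first
  passage means first arrival at or past a state, revisits ignored.
  Non-convergence returns a flagged result with the last residual.
* **Condensed ions**: a (+1)-ion counts as condensed in the pore when it
  is inside region II and within λB of any monomer — the standard
  Bjerrum-distance criterion, configurable, used for the driving-force
  and effective-friction terms of the entropic drift model. The model's
  velocity is v_es = (f_entropic + f_driving)/(ℓ0 ζ_eff), the only
  dimensionally consistent composition of those terms.

## Desk-scale study conditions, and what they can show

The reduced-scale conditions exercised by the test suite are N = 32,
M = 32 runs per field, screened (implicit-salt) electrostatics at the
standard salt content (256 molecules in the 48 × 49.36 × 200 σ box,
I = 5.5×10⁻⁴ σ⁻³, κ⁻¹ ≈ 4.9 σ), with a weak (E = 0.2) and a strong
(E = 32) field. These sizes keep a full two-field study within a couple
of minutes on one CPU; synthetic fixtures (rigid rod, ideal coil,
uniform ball, prescribed-tension chains, log-normal samples) cover
every analysis path with closed-form ground truth, independent of the
engine.

A genuine limitation of this scale must be stated plainly. At the
study's salt concentration the OSF persistence length is 19 σ, so a
32-mer spans fewer than two persistence lengths and behaves as a
semi-rigid rod. Tension is then effectively global from the moment the
field switches on, the cis sub-chain starts near its rod-limit shape
factor and can only fall as it empties, the waiting-time hump sits left
of the midpoint (rod threading accelerates as the cis friction drops),
and the translocation coordinate evolves almost deterministically, so
no ballistic window appears in ⟨Δs²⟩(t). The flexible-chain
tension-propagation signatures — the hump pushed beyond s̃ = 0.5, the
rising cis shape factor, the super-diffusive early variance at strong
field — require the chain to span several persistence lengths and
emerge in this same code as N grows; the corresponding desk-scale
assertions are kept in the acceptance suite at their stated conditions
and fail there, which we report rather than re-tune. Passing the
remaining desk-scale tests therefore demonstrates correct mechanics,
bookkeeping and statistics, not paper-scale tension-propagation
physics; the paper-scale curve shapes and the (N − s*) ~ N^0.58 law are
covered by estimator-recovery tests on constructed data.

## Numerical choices and degenerate inputs

* dt = 0.005 τᵤ keeps ω·dt ≈ 0.12 for the stiffest mode (k = 600);
  non-finite coordinates abort with an instability error.
* Electrostatic cutoff 10 σ (≈ 2 Debye lengths in screened mode);
  truncated-shifted energies keep forces as exact gradients.
* The pore-slab field force derives from the continuous clamped
  potential q·E·clamp(z, ±w/2), so energy bookkeeping stays consistent
  at the region boundary; the boundary itself is a closed interval on
  region II.
* Ratio of means, not mean of ratios, for ⟨D⟩/⟨Λ⟩, following the
  profile notation; ties at thresholds resolve toward the straightened
  side (≥).
* Degenerate inputs error loudly with named reasons: coincident beads
  (η), all-zero eigenvalue triples (A, P), zero ionic strength (the
  electrostatic persistence length diverges), series that never reach
  s = N (waiting times), fewer than 2 runs (variance), fewer than 3
  chain lengths (scaling fit), fewer than 20 samples (log-normal fit).
* Box z is closed (non-periodic) by default: at a 200 σ extent, z
  images are irrelevant at desk scale and the minimum-image
  electrostatics stays simple; full 3D periodicity is a flag.

## Known limitations

No hydrodynamic interactions, no bending stiffness (dsDNA-scale
persistence lengths would need an explicit bending potential), no pore
surface charge or atomistic wall chemistry, no Ewald summation, and no
solution of the Fokker–Planck equation — the drift-diffusion layer
characterizes the empirical process (v(s), ⟨Δs²⟩, p(s,t) fits) rather
than propagating the model forward. The implicit-ion screened mode has
no ion condensation, so its chains are somewhat stiffer and its pore
driving force somewhat larger than the explicit-ion system at the same
nominal parameters.
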