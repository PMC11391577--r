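---
title: "Methods: coarse-grained ion model parameterization at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained ion model parameterization at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cgionfit)
```

# Scope and model

`cgionfit` implements, end to end and at desk scale, the workflow by
which coarse-grained (CG) sodium/chloride ion models are parameterized
top-down against concentration-resolved bulk properties: a CG molecular
dynamics engine with SPICA-style interactions, the full set of
observable estimators (density, Kirkwood-Irving surface and interfacial
tension, virtual-wall osmotic pressure, bilayer structure), and a
two-condition fitting loop (Bayesian optimization of Lennard-Jones pair
parameters against density/surface-tension curves, then targeted tuning
of the sodium-chloride cross interaction against an osmotic-pressure
value).

Beads represent three water molecules (`W`), ions with (`solvated`) or
without (`bare`) their grouped waters, short alkane fragments, and the
fragments of a 4-bead toy amphiphile. Nonbonded interactions are
Lennard-Jones in the two forms of the SPICA family,

$$U_{9\text{-}6}(r) = \frac{27}{4}\,\epsilon\left[\left(\frac{\sigma}{r}\right)^{9} -
\left(\frac{\sigma}{r}\right)^{6}\right],\qquad
U_{12\text{-}4}(r) = \frac{3\sqrt3}{2}\,\epsilon\left[\left(\frac{\sigma}{r}\right)^{12} -
\left(\frac{\sigma}{r}\right)^{4}\right],$$

both with zero crossing exactly at $\sigma$ and well depth exactly
$-\epsilon$. The 12-4 form is used for water-water and water-ion pairs,
9-6 for everything else; the form is an explicit per-pair field, so
either convention can be overridden pair by pair. Charges ($\pm 1\,e$ on
ions and on the toy head beads) interact through a uniform relative
permittivity $\epsilon_r = 80$ — the screened-charge convention of the
parent force-field family — with either a full Ewald treatment
(real-space $\mathrm{erfc}$ within the 15 Å cutoff plus a reciprocal-space
sum) or an energy-shifted cutoff for fast tests. Bonded terms are
harmonic with the no-half convention, $U = k\,(x - x_0)^2$; a
`bond_prefactor` option switches to the $\tfrac12 k$ convention, so the
choice is testable rather than implicit. Angles may carry a repulsive
1-3 LJ term that guards against angle collapse.

There are deliberately **no mixing rules** at evaluation time: every
co-occurring pair must have an explicit table entry, because cross terms
are the objects being optimized and a silent Lorentz-Berthelot fallback
would corrupt fits. (The fallback exists but warns on every use.) The
cross-interaction *scaling* rule
$\epsilon' = \kappa_\epsilon\,\epsilon$, $\sigma' = \kappa_\sigma\,\sigma$
is available for ion-alkane pairs via `apply_scaling()`, with
$\kappa = 1$ defaults since no published values ship with the package.

## Units and key constants

Internally: Å, fs, amu, kcal/mol. Conversions are centralized in
`cg_units` and unit-tested: the Coulomb prefactor
332.0637 kcal Å/(mol e²), 1 kcal/mol/Å³ = 69 477 bar,
1 amu/Å³ = 1660.54 kg/m³, 1 bar·Å = 0.01 mN/m.

# The engine

Propagation is velocity Verlet. Temperature control is a Nosé-Hoover
chain of length 3 (time constant default $100\,dt$); pressure control is
an MTK-style Nosé-Hoover barostat (default $1000\,dt$) whose cell
variable carries its own thermostat chain. Barostat coupling groups
implement the three ensembles the workflow needs: isotropic NPT for
bulk boxes, N$P_z$AT (z only, lateral box fixed) for biphasic stacks,
and semi-isotropic x y / z for bilayers. The production time step is
10 fs (the CG convention); validation runs use 1–8 fs. Nonbonded forces
go through a Verlet neighbor list (skin 2 Å) that is provably identical
to the direct $O(N^2)$ double loop — the test suite asserts equality
configuration by configuration, and the list is rebuilt on a
displacement trigger or a >0.3 % box rescale.

Within the engine the LJ energy is shifted to vanish at the cutoff
(`lj_shift = TRUE`), which removes the truncation discontinuity and is
what makes the $10^4$-step NVE drift criterion ($<10^{-4}$ relative at
1 fs) achievable; the bare `pair_energy_force()` functions report the
unshifted values, whose zero crossing and well depth are part of the
documented contract.

Semipermeable **virtual walls** are one-sided repulsive planes that act
only on listed bead types (ions), with force constant
$k = 20$ kcal/mol/Å³. The default force law is the indenter form
$F = k\,\Delta x^2$ for penetration $\Delta x$ — dimensionally consistent
with the printed unit of $k$ — while a half-harmonic linear law
$F = k\,\Delta x$ (with $k$ then in kcal/mol/Å²) is retained as an
option, since the osmotic-pressure methodology this apparatus follows
originally used a linear restraint. Both are covered by tests; the time
average of the wall force per area equals the confined solute's pressure
for either law, so the estimator itself is law-agnostic. Wall forces are
recorded per wall per sample and excluded from the internal virial.

## Pressure tensor

$P_{ab} = (\sum_i m_i v_{ia} v_{ib} + W_{ab})/V$ with $W$ the pair
virial (LJ + Coulomb real and reciprocal space + bonded). The kinetic
term uses instantaneous velocities with no thermostat-aware correction —
at CG desk scale the difference is far below sampling error. Validated
against the ideal-gas law, a hand-computed two-body virial, and the
barostat setpoint.

# Estimators

All scalar estimators analyze a configurable window (default: the final
25 % of the run, mirroring the last-5-ns-of-20-ns production
convention; fitting budgets use 50 %) and report a block-averaged
standard error with 5 blocks — an implementation choice, since reported
uncertainties of the order "±1 kg/m³, ±0.7–1 mN/m" in this literature
rarely state their method.

* **Density**: $\langle M/V\rangle$ over NPT frames, kg/m³.
* **Surface tension** (Kirkwood-Irving):
  $\gamma = \frac{L_z}{2}\langle P_{zz} - \tfrac12(P_{xx}+P_{yy})\rangle$
  on an NVT slab; the $\tfrac12$ accounts for the slab's two interfaces.
  The same estimator with $\langle L_z\rangle$ for the fluctuating box
  gives the interfacial tension of an N$P_z$AT biphasic stack.
* **Osmotic pressure**: frame-average of the total ion force on each
  wall, divided by the wall area $L_y L_z$, averaged over the two walls,
  in bar.
* **Bilayer**: APL $= \langle L_x\rangle\langle L_y\rangle/N_{lpl}$;
  $D_{HH}$ as the distance between leaflet head-bead centers of mass
  (leaflet membership fixed at the window start by the sign of $z$
  relative to the head COM — flip-flop is not tracked, which is safe at
  these scales and durations); order parameters
  $S = \tfrac12(3\langle(\hat b\cdot\hat n)^2\rangle - 1)$ per bond
  position, with exact limits $1$, $-0.5$, $0$ for parallel,
  perpendicular and isotropic bond sets.

A subtlety worth recording: a *collisionless* solute (the ideal-gas
validation of the osmometer) cannot re-thermalize under a global
Nosé-Hoover chain — the chain rescales all velocities by a common
factor, so per-particle velocity ratios are frozen at their initial
draw and the wall-force average inherits that draw's bias.
`simulate_osmotic(n_segments = k)` therefore re-draws velocities from
the Maxwell-Boltzmann distribution between segments (a massive Andersen
resampling step, which is canonically exact) and reports the standard
error over segment means. The acceptance checks run the 12-segment
ideal-solute cell against the van 't Hoff pressure
$\Pi = c_{tot} R T$ at 0.1 M total solute. Interacting (real-solution)
runs default to a single continuous NVT segment.

# Synthetic data: what it emulates and what it does not

The generator builds every geometry the workflow needs, deterministic
per seed: bulk boxes sized to land in the 1000–1200-bead range used for
bulk property runs (tests use smaller budgets), z-tripled slabs,
three-compartment osmotic cells (pure-water pads of twice the cutoff on
each side along x, walls at the compartment boundaries), biphasic
decane-like/water stacks at roughly a tenth of the production counts
(the production counts sit behind a `full_scale` flag), and a toy
bilayer of 4-bead zwitterionic amphiphiles on a lateral grid.
Rejection packing with bounded retries replaces an external packing
binary; at CG bead densities (packing fractions ≲ 0.25 at the default
3.4 Å separation) it converges quickly, and a capped steepest-descent
minimizer removes residual strain before dynamics.

Target curves come in three provenances. `synthetic_parametric` curves
are smooth monotone stand-ins with the *shape* of the corresponding
experimental data — density $998 + 40c$ kg/m³, surface tension
$72.8 + 1.7c$ mN/m, osmotic pressure $2cRT\,\phi(c)$ with
$\phi(c) = 0.93 + 0.006c + 0.006c^2$ — chosen once as physically
plausible values (the density intercept and slope, the pure-water
surface tension at 20 °C, and an osmotic coefficient near 0.93 rising
above 1 at high molality are all textbook magnitudes for NaCl
solutions). They are documented stand-ins, **not** measured tables;
`user_table` mode ingests real measurements with the same CSV layout.
`ground_truth_sim` runs the engine itself with a known table, which is
what closed-loop recovery testing uses.

The toy force-field defaults were likewise fixed once: the water bead
(12-4, $\epsilon = 0.90$ kcal/mol, $\sigma = 4.38$ Å) gives a liquid
within about 1 % of water's density at 293 K / 1 bar and a cohesive
slab with positive surface tension (both recomputed by the acceptance
script) — water-like in the properties this workflow fits, with no claim
to reproduce any published CG water parameter set. What the synthetic
systems do *not* emulate: real lipid topologies and their parameters,
triolein's ester polarity, experimental noise structure, or
production-scale system sizes. Passing tests therefore demonstrate the
correctness of estimators, engine and fitting logic — not transferability
of the toy parameters to real systems.

# The fitting pipeline

**Condition 1.** The objective is a weighted sum of squared relative
deviations of simulated density (bulk NPT) and surface tension (slab
NVT) from their target curves over the concentration grid, with weights
`w_density`, `w_gamma` and one seed per concentration. Simulation
blow-ups return a large finite penalty ($10^6$) rather than throwing, so
optimization continues. The optimizer is a hand-rolled but standard
Bayesian optimization: Matérn-5/2 Gaussian process on inputs scaled to
$[0,1]^d$, maximum-likelihood hyperparameters, expected improvement (a
lower-confidence-bound acquisition is available), seeded with a Latin
hypercube design. Two numerical choices matter and are worth their
rationale:

* The GP is fit to $\sqrt{y}$ — for a sum-of-squares objective this is
  the RMS relative deviation, which compresses a 4-decade dynamic range
  into one the stationary kernel can model, and turns the optimum's
  quadratic funnel into a cone. Without it the surrogate systematically
  under-explores the funnel.
* Acquisition maximization uses 700 uniform candidates plus 300 local
  candidates around the incumbent, followed by an L-BFGS-B polish.

**Common random numbers.** Candidate evaluations and ground-truth
targets share seeds, initial configurations and velocity draws. Two
consequences: the generating parameters give an objective of exactly
zero (asserted in tests), and — because trajectories at nearby
parameters stay correlated over short horizons — the objective is a
*smooth* function of the parameters at short production lengths, while
long horizons decorrelate chaotically and turn the landscape into
deterministic noise. The recovery tests therefore use short budgets
(200 + 800 steps at 10 fs, ~300 beads), where the chaotic floor sits
orders of magnitude below the parameter signals. Density alone leaves
$(\epsilon, \sigma)$ of a pair nearly degenerate along a compensation
valley (attraction down, size down); adding the surface-tension curve —
exactly the two-property design of the original condition 1 — breaks
it, and the closed-loop acceptance test requires both ion-water
parameters back within 10 % in 50 evaluations.

**Condition 2.** `condition2_tune()` adjusts only
$\epsilon_{\mathrm{CLA-SOD}}$ and $\sigma_{\mathrm{CLA-SOD}}$ — bitwise
identity elsewhere is asserted — by a bounded Nelder-Mead search on the
squared relative mismatch of the simulated osmotic pressure at the
reference molarity, preceded by a coarse $\epsilon$ line scan that
exploits the monotone response of $\Pi$ to the cross attraction (more
ion pairing, lower osmotic pressure). Tolerance is 5 % relative; an
unreachable target raises an error carrying the closest achieved value.
The directionality the literature reports (raise $\epsilon$ for solvated
models; raise $\sigma$, lower $\epsilon$ for bare models) is probed as a
sign test on toy systems, not hard-coded. Model selection is data, not
logic: the solvated lineage keeps its condition-1 parameters, the bare
lineage its condition-1+2 parameters.

# Problem sizes and determinism

All tests and the acceptance script run at desk scale, chosen as the
smallest sizes at which each check is statistically meaningful: 100–500
beads and 10⁴ steps for engine validation, a 500-bead slab for the
tension estimator, ~100 ions in an 82 Å compartment for the van 't Hoff
check, 32 lipids per leaflet for bilayer observables, ~300-bead budgets
for the fitting loops. Production-style windows (2 ns equilibration,
20 ns production, last 5 ns analyzed, 1000+ beads) are plain
configuration changes (`fit_budget`, `full_scale`), not code paths.
Every stochastic stage is seed-derived; trajectories are bitwise
reproducible for identical inputs on one platform, and each analysis
stage writes a manifest (config hash, seeds, file checksums) sufficient
to regenerate its outputs.

# Known limitations

* No constraint algorithms, triclinic boxes, or parallelism; the engine
  is a correctness-first reference implementation, not a production code.
* The Ewald implementation is a classic (non-mesh) sum over reciprocal
  vectors of the charged subset — fine for tens to hundreds of charges,
  not for production electrolytes at scale.
* The barostat's MTK factors are implemented to second order; averages
  (the quantity fitted) are correct, while fluctuation spectra in NPT
  are not guaranteed to machine precision.
* The toy amphiphile is an architectural stand-in: its APL, $D_{HH}$ and
  order parameters exercise the estimators but do not approximate any
  real lipid's values.
* Parameter recovery relies on common random numbers; recovering
  parameters from *noisy external* targets (the real experimental
  setting) needs longer per-evaluation budgets than the test suite's.
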