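---
title: "Methods: analysing coarse-grained DES mixture simulations with desmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing coarse-grained DES mixture simulations with desmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desmix)
```

## Scope

`desmix` implements the analysis layer of a coarse-grained molecular
dynamics study of a hydrophobic deep eutectic solvent (DES) — hexanoic acid
(HexA, the hydrogen-bond donor) mixed with imidazole (IMID, the acceptor)
plus a small fixed amount of water — and of its reaction toward an
imidazolium hexanoate ionic liquid. The package does not attempt to
reproduce a production force field. Instead it provides

* composition algebra on the HexA/IMID/water simplex, including
  reaction-extent bookkeeping and the solvent-regeneration mass balance;
* a campaign planner that enumerates composition × temperature × size ×
  replica grids with deterministic per-cell seeds;
* contact-based miscibility scoring and its three-band classification;
* Einstein-relation diffusion with finite-size extrapolation and a
  survivor-bias-free per-phase variant;
* thermal expansion from density series and shear viscosity via the
  periodic perturbation method;
* partial density profiles, radial distribution functions and
  phase-partition (pollutant) quantification;
* a toy Langevin soft-sphere simulator and direct stochastic generators
  that produce data with *known* ground truth, so that every analysis
  stage is testable at desk scale.

All quantities use the nm / ps / amu / kJ mol⁻¹ / K unit system common in
coarse-grained simulation, so cutoffs (0.6 nm), radii (1.2 nm) and
acceleration rates (nm/ps²) read directly in their conventional values.

## Composition algebra

A composition is a point on the mole-fraction simplex of the solvent
species; the water fraction is fixed at χ(H₂O) = 0.1 by default and the
HexA fraction is the balance 1 − χ(IMID) − χ(H₂O). Oil (oleic or linoleic
acid) attaches on a mass basis (g oil per g solvent) and deliberately does
*not* enter the solvent simplex: when χ(IMID) is varied the oil mass stays
fixed, so including it in the denominator would make the fractions of every
other species depend on the oil conversion convention.

The DES → IL reaction is a proton transfer, HexA + IMID → HexA⁻ + IMID⁺,
modelled as a mole-for-mole identity swap (in a coarse-grained picture the
beads change type, not number). At extent ξ the number of reacted pairs is
min(ξ·n(IMID), n(HexA)): conversion is capped by the available donor.
With χ(H₂O) = 0.1 the donor runs out exactly when
χ(IMID) = (1 − 0.1)/2 = 0.45, so mixtures at or below that composition
react completely while richer mixtures keep an unreacted IMID excess of
χ(IMID) − (0.9 − χ(IMID)). Tests verify this against brute-force mole
counting.

The regeneration mass balance answers "how much HexA must be added to
dilute a separated χ(IMID) = 0.60 mixture back to 0.30, and what does that
do to the solvent mass?" With n initial solvent moles and x added HexA
moles, χ·n/(n + x) = target gives x = n(χ/target − 1). Two mass tables are
provided because the convention genuinely matters: atomistic molar masses
(116.16 / 68.08 / 18.02 g/mol for HexA / IMID / water) give a mass factor
of ≈ 2.50 for the 0.60 → 0.30 dilution with oil excluded, while a
coarse-grained bead-mass table (one 72 amu bead = four waters, 108 amu for
IMID, 126 amu for HexA) gives ≈ 2.15. Both conventions, and the oil
inclusion switch, are explicit arguments; neither is silently preferred.

```{r}
reg <- regeneration_mass_balance(make_composition(0.60, 0.10), 0.30)
reg$mass_factor
```

## Campaign planning

`sim_plan()` defaults to the property-scan protocol: 7 compositions
(χ(IMID) = 0.10–0.50), 270–330 K in 10 K steps, three system sizes (10⁴,
20⁴, 30⁴ particles) and 4 replicas of 300 ns, i.e. 588 runs and 176.4 μs
of combined simulated time. `viscosity_plan()` swaps the size grid for 7
cosine acceleration rates (0.002–0.008 nm/ps²), giving 1372 runs of 3 ns
in 1:1:3 elongated boxes. Each cell receives a seed from a stable integer
hash of the base seed and the cell's grid indices, so campaign manifests
are reproducible and cells are independently seeded.

## The contact-based miscibility metric

Two molecules are "in contact" when any bead of one is within 0.6 nm of
any bead of the other under the minimum-image convention, counted once per
unordered molecule pair. The mixing percentage is

$$ 100\% \times \frac{N_{\mathrm{HexA-IMID}}}
   {N_{\mathrm{HexA-IMID}} + N_{\mathrm{IMID-IMID}}} $$

— cross contacts relative to all contacts involving the acceptor. In a
well-mixed system the percentage is high; when IMID self-associates it
collapses. For an ideal random equimolar mixture of N single-bead
molecules per species the expectation has the closed form
100·2N/(2N + N − 1) ≈ 66.9% at N = 100 (the per-pair contact probability
cancels between numerator and denominator), which the test suite verifies
by simulation.

Classification uses three bands: above 50% "mixed", 30–45% "partially
mixed", below 30% "almost biphasic". The band definitions leave (45, 50]
unassigned; rather than silently snapping to a neighbour, the classifier
emits an explicit `intermediate` label there. Percentages outside [0, 100]
are errors, and a zero contact denominator yields `NA` (an undefined
metric), deliberately distinct from 0%.

Both a linked-cell and an all-pairs contact search are implemented; they
are required to agree exactly (integer equality) on randomized fixtures,
and a pure-R oracle double-checks both. Whether contacts should be counted
per molecule pair or per bead pair is ambiguous in common tooling; both
modes exist and molecule-pair is the default.

Time series are analysed at stored-frame resolution with the first 20% of
frames discarded as equilibration by default — a pragmatic default, since
equilibration in practice is confirmed by property plateaus rather than a
fixed rule.

## Diffusion

The Einstein relation MSD(t) → 6Dt is fitted over a lag window of 10–50%
of the maximum lag, avoiding the short-time ballistic/cage regime and the
poorly averaged tail. Any affine offset is absorbed by the intercept. Two
error conventions are relevant:

* points of one averaged MSD curve are strongly correlated, so the naive
  fit standard error is optimistic;
* `compute_msd()` therefore retains per-walker curves, and the reported SE
  is the spread of per-walker slopes (SEM across walkers), which the test
  suite shows gives near-nominal (~95%) coverage of the ±2 SE interval
  over independent Brownian ensembles.

Finite-size effects are handled empirically: D is measured at several
system sizes N and regressed against N^(−1/3); the intercept estimates the
infinite-system value. The fit is exact on noise-free linear inputs and
unbiased under Gaussian noise (Monte-Carlo tested). No analytic
hydrodynamic correction is applied — the empirical extrapolation *is* the
method.

### Per-phase diffusion without survivor bias

In a nanostructured liquid one wants diffusion coefficients per phase, but
following only molecules that *remain* in a phase selects slow movers and
biases D low. The unbiased estimator groups each molecule by the phase it
occupied at each time origin and credits its full subsequent displacement
to that phase, regardless of later exchanges. By construction, the
pair-count-weighted average of the per-phase MSDs reconstructs the
whole-population MSD exactly at every lag — an identity the tests assert
to 10 significant digits. The biased "survivors only" variant is kept,
switched off by default, purely to demonstrate the artefact: on a
fast-exchange fixture it underestimates D severely while the default
estimator matches the population average, mirroring the physically
expected result that rapidly exchanging nanodomains behave as one
dynamically homogeneous fluid.

Phase labels come either from generator ground truth or from
`classify_local_phase()`: molecules are labelled by the majority species
group among molecule centres within a 1.2 nm radius. The majority rule
details are not uniquely determined by common practice, so the package
makes its choices explicit and records them in the output: water is
excluded from the vote by default (the phases of interest are HexA-rich
vs IMID-rich), a strict majority above threshold 0.5 is required, and
ties or empty neighbourhoods are labelled `interfacial` rather than
force-assigned.

## Thermal expansion and viscosity

The thermal expansion coefficient is α = −(∂ ln ρ/∂T)ₚ, estimated as minus
the slope of a weighted linear fit of ln ρ against T; it is exact on
exponential density series, which is also precisely what the paired
generator produces (ρ(T) = ρ₀e^(−αT), optionally with relative Gaussian
noise).

The periodic perturbation method drives the fluid with an external
acceleration field a_x(z) = A cos(2πz/L_z). The steady Navier–Stokes
solution is a cosine velocity profile of amplitude V = ρA/(ηk²) with
k = 2π/L_z, so each run yields

$$ \eta = \frac{\rho A}{V k^2}. $$

The profile amplitude is measured by mass-weighted least squares on the
basis {1, cos(kz)}; the constant term makes the estimate exactly invariant
under a uniform (Galilean) velocity offset, and the cos(2kz) mode is
orthogonal to the fitted one. Internally η is in amu nm⁻¹ ps⁻¹ and is
reported in mPa·s (1 amu nm⁻¹ ps⁻¹ = 1.66054 × 10⁻³ mPa·s); the
single-run unit conversion is pinned by a dimensional-analysis test to
10⁻¹⁰ relative precision. Several acceleration rates are averaged (with
the straight-line R² of V vs A reported as a linearity diagnostic) rather
than extrapolated to zero rate; extrapolation is available implicitly
through the per-run table if wanted.

When the toy simulator runs with a cosine field, the Langevin thermostat
is applied to *peculiar* velocities — the instantaneous cosine mode is
subtracted before the friction/noise step and added back — so the
thermostat does not artificially damp the very mode being measured.

## Structural analyses

Partial density profiles are per-species number-density histograms along
one axis (default bin 0.1 nm, half-open bins), time-averaged; binned
counts are exactly conserved. Because a periodic slab drifts, profiles can
be re-centred per frame on the circular mean of a reference species along
the axis — the standard drift correction; the tests build a deliberately
drifting slab and show the aligned profile keeps its contrast while the
raw one washes out. Peak-normalised variants are provided for plotting;
quantitation always uses raw counts.

RDFs are computed between molecule centres by default (bead–bead
optional) with bin width 0.02 nm and range capped at half the shortest box
edge (complete bins only); normalisation is by ideal-gas shell counts, so
g(r) → 1 for homogeneous fluids and the integral of ρg(r)4πr²dr recovers
N − 1, both asserted in tests.

The pollutant fraction — the percentage of a species' molecules outside
its majority phase — supports two phase definitions: an axis interval
(slab ground truth, or the contiguous bins where the species' density
exceeds half its peak) and local-composition labels. On sharp-interface
fixtures the definitions agree within a few percentage points; on weakly
separated systems the value genuinely depends on the boundary convention,
which is why the convention is always recorded in the result object.

## The toy simulator: what it emulates, and what it does not

The simulator integrates soft spheres with a harmonic repulsive core
(radius σ = 0.47 nm, stiffness 200 kJ/mol) and a finite quartic attractive
well (depth ε = 3 kJ/mol, cut at 1.1 nm with continuous forces), using the
BAOAB splitting of Langevin dynamics (velocity Verlet when the thermostat
is off) at dt = 0.02 ps, friction γ = 2 ps⁻¹ and bead mass 72 amu. The
form was chosen over Lennard-Jones for stability at large time steps
while still driving demixing. Unlike-species well depths are scaled by a
cross-interaction factor κ ≤ 1; lowering κ penalises unlike contacts, the
toy analogue of lowering the cross-affinity between bead types. A default
number density of 4.5 nm⁻³ with insertion distance 0.35 nm gives a dense
liquid that equilibrates in a few thousand steps at 150–300 particles.

Under these conditions a 50/50 binary mixture sweeps cleanly through the
classification bands as κ decreases (κ = 1 → ≈ 67–69%, "mixed"; κ = 0.2 →
≈ 12–17%, "almost biphasic"), monotonically across seeds — the toy
counterpart of the mixed → biphasic progression with increasing acceptor
content. Energy conservation (NVE drift < 10⁻³ relative over 10⁴ steps),
equipartition (⟨T⟩ within 2%), the free-particle Langevin limit
D = k_BT/(mγ) (within 5%) and bit-exact seed determinism are all tested.

The direct stochastic generators sidestep dynamics entirely where ground
truth matters: Gaussian walkers with exact per-species D (optionally in
exchanging compartments with Poisson swap rates), steady cosine flow
fields with known amplitude, and exponential density series with known α.

What the toy data do **not** emulate: real chemistry (no electrostatics,
no bonded topology, no hydrogen-bond directionality), Martini-level bead
typing, or μs-scale phase kinetics. Passing tests therefore demonstrate
the *analysis machinery* is correct and the *trends* are reproduced on
controlled fixtures — they do not validate force-field-level absolute
densities, viscosities or diffusion coefficients, which require the real
coarse-grained model at production scale. For the same reason the measured
toy viscosity's temperature dependence is too seed-noisy at desk scale
(hundreds of particles, a few ns) for a meaningful trend assertion; only
positivity, linear response in A and cross-rate consistency are asserted.

## Numerical conventions and degenerate inputs

* Coordinates in nm, wrapped to [0, L); half-open bins [lo, hi); 1-based
  molecule ids; exact unwrapped coordinates carried by the simulator,
  minimum-image reconstruction for externally read trajectories (valid
  while per-frame displacements stay below half a box edge).
* Contact cutoffs and RDF ranges beyond half the shortest box edge are
  errors (minimum-image ambiguity), not warnings.
* Zero contact denominators, all-discarded frame sets, single-size
  finite-size fits, phases with no members and profiles without density
  contrast all raise explicit conditions rather than returning silent
  zeros.
* Campaign cell seeds come from a multiplicative hash folded into
  [1, 2³¹ − 2]; all arithmetic stays below 2⁵³ so the hash is platform
  stable.

## Problem sizes used in the shipped tests

The test and acceptance workloads were sized for a single CPU: Brownian
ensembles of 400–1000 walkers × 150–300 steps, Langevin mixtures of
125–300 particles × 2000–10⁴ steps, κ sweeps of 3 seeds × 5 values, 50
randomized contact fixtures, and 10⁴-particle flow snapshots. These sizes
keep every statistical tolerance (5% on D, 1% on the flow amplitude, 10%
on per-phase D) comfortably met while completing in a few minutes.
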