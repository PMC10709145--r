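---
title: "Model and methods: chiral self-propelled worm-like chains in 2D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: chiral self-propelled worm-like chains in 2D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`activewlc` simulates membrane-bound treadmilling cytoskeletal filaments —
FtsZ is the motivating system — as two-dimensional, overdamped,
self-propelled, chiral, semiflexible worm-like chains, and quantifies the
collective states they form: rotating chiral rings at low and intermediate
density, polar bands, and a nematic phase with half-integer topological
defects at high density. This vignette is the package's own account of the
model, its conventions, the numerical choices, and the limits of what the
bundled desk-scale studies can show.

## The model

A filament is `N + 1` beads of radius `r0` joined by `N` harmonic bonds of
rest length `r0`; overlapping beads give a smooth chain of effective
diameter `d = 2*sqrt(2)*r0`, the reduced length unit. Energies are in units
of the thermal energy `kBT` and times in units of `tau`, the rotation
period of a single isolated wild-type filament (physically 78.5 s, the
period of a 1 um ring treadmilling at 0.04 um/s; `1 d = 50 nm`).

The overdamped equation of motion for bead `i` is

    gamma dr_i/dt = -grad_i V + F_p^i + F_noise^i

with `V = V_bond + V_bend + V_pair`:

* `V_bond = (k_bond/2) * sum (|b_j| - r0)^2` over bonds `b_j`;
* `V_bend = (k_bend/(2 d)) * sum (phi_j + dtheta)^2` over interior joints,
  where `phi_j` is the *signed* turn angle between consecutive bonds
  traversed head to tail. A nonzero `dtheta` makes the rest shape a chiral
  arc of geometric curvature `dtheta/r0`; the handedness is encoded in the
  sign. This signed (asymmetric) potential is what distinguishes a chiral
  filament from a merely curved one;
* `V_pair`: a soft (4,2) Lennard-Jones potential
  `4*eps*[(sigma/r)^4 - (sigma/r)^2]` with `sigma = 2*r0`, excluding
  nearest and next-nearest chain neighbours, linearly shifted so that both
  the potential and its derivative vanish at the cutoff. In repulsive-only
  mode the cutoff sits at the minimum `sqrt(2)*sigma` and the shift reduces
  to `+eps`. With attraction the default cutoff is `2.5*sigma`; note that
  for this long-ranged potential the linear shift substantially shallows
  the effective well (to roughly a tenth of the nominal `eps` at
  `2.5*sigma`), so `eps = 0.1 kBT` describes adhesion well below thermal
  energy — consistent with the loose lateral contacts the model is meant
  to capture.

Treadmilling is modelled as a tangential "follow the head" force: every
bead except the two ends is pushed with magnitude `gamma*v0` along the bond
towards its predecessor, and the head bead is pushed along its first bond
vector plus a unit vector rotated by `dtheta` (the frame-covariant reading
of the chiral steering term), which keeps the filament circling with its
intrinsic handedness. Because the tail bead carries no propulsion, a free
straight filament translates at `v0*N/(N+1)` — 4% below `v0` for `N = 23` —
which the tests assert exactly.

Thermal noise is white with per-component variance `2*kBT*gamma/dt`
(two-dimensional total `4*kBT*gamma/dt`), reproducing `D = kBT/gamma`.

## Dimensionless groups and presets

Two groups govern the dynamics: the Peclet number `Pe = f_p*Lf^2/kBT` and
the flexure number `F = f_p*Lf^3/k_bend`, with `f_p` the propulsion force
per unit length. The package books `f_p = gamma*v0/d`, i.e. numerically
`gamma*v0` in reduced units. This choice — rather than dividing the bead
force by the bond length `r0` — is what makes the printed working timestep
stable for both bundled presets (the stiffest bending mode sets
`dt < 2*gamma/k_max` with `k_max = 16*k_bend/(d*r0^2)`; under the per-`r0`
bookkeeping the implied friction would be `2*sqrt(2)` times smaller and
both presets would sit beyond the Euler stability limit). The group
formulas use the nominal filament length (8 d, 16 d), while bond-count
rounding makes the realised contour up to 2% longer; the realised geometry
is what is simulated.

Bundled presets:

* **wild type** (`params_wt()`): `Lf = 8 d` (`N = 23`), flexure number 40,
  `eps = 0.1 kBT` with attraction, intrinsic curvature 3.48 rad/um
  (`dtheta = 0.0615` rad, rest rotation diameter ~575 nm), `Pe = 900` and
  `v0 = 29 d/tau`. The last two are fixed by the mutant set below being
  three times lower in Pe and eight times lower in `v0`; the reported Pe
  range for the wild type is ~700-1300, and the alternative physical
  reading of the speed (0.04 um/s = 62.8 d/tau) is exposed through the
  unit layer but deliberately not used to re-derive `gamma` — the two
  printed constraints are mutually inconsistent at the 2x level and the
  package keeps the preset self-consistent instead of splitting the
  difference.
* **L169R mutant** (`params_l169r()`): the printed set `v0 = 3.625 d/tau`,
  `Pe = 300`, flexure number 20, `dtheta = 0`, `Lf = 16 d` (`N = 46`,
  twice the wild-type bond count), giving `k_bend = 240 kBT d`.
* `k_bond = 2000 kBT/d^2` throughout: bond-length fluctuations ~6% of
  `r0`, "large enough to keep bonds constant" without dominating the
  stability limit.

## Two contour measures, and the persistence-length identity

Two distinct contour measures coexist in this model, and the package keeps
both deliberately:

* the **geometric** measure (`delta_s = r0`, the bond length) is used for
  shape observables: `local_curvatures()` reports `kappa = turn/r0`, so the
  chiral rest arc has curvature `dtheta/r0 = 0.174 rad/d = 3.48 rad/um`,
  matching the rotation-diameter calibration;
* the **energy** measure (`delta_s = d`, one length unit per joint) is the
  measure in which the bending energy is written (`k_bend/d` per squared
  radian per joint). Under it the continuum bending modulus is `k_bend`
  itself, so thermal equipartition gives the exact identity
  `Lp = 1/(sigma^2*delta_s) = k_bend/kBT`, where `sigma` is the Gaussian
  width of the local-curvature distribution. `sim_persistence_length()`
  uses this measure; it is the convention under which the calibrated
  mutant persistence length (`240 d = 12,000 nm` at equipartition; the
  interacting active system measures slightly lower) is stated, and the
  package's equilibrium tests verify the identity directly against
  single-filament simulations. The two measures differ by the fixed factor
  `d/r0 = 2*sqrt(2)`; confusing them is the single easiest way to
  mis-state a persistence length for this model, which is why every
  estimator in the package carries its `delta_s` explicitly.

The second, independent estimator fits the 2D worm-like-chain
mean-squared end-to-end relation
`y^2 = 4*Lp*(x - 2*Lp*(1 - exp(-x/(2*Lp))))` to pooled pairwise
separations; on synthetic discrete chains (joint-angle variance
`delta_s/Lp`) the two estimators agree within 15% across `Lp` from 20 d to
500 d, and the tangent-correlation e-folding length is `2*Lp` (the 2D
convention).

## Numerical integration

Euler-Maruyama with timestep `dt = 1.8e-5 tau` by default. The scheme's
stationary variance for a stiff harmonic mode with stability factor
`a = dt*k/gamma` is inflated by `1/(1 - a/2)`; at the default timestep the
mutant preset sits at `a = 1.71` for its stiffest (zigzag) bending mode,
which inflates the *measured* joint-angle variance appreciably (a factor
2.4 in single-filament checks) without affecting stability or the
collective phenomenology. Analyses that depend quantitatively on the
curvature variance — the persistence-length study — therefore sample in a
refined window at `dt = 4.5e-6 tau`, where the inflation measured against
the analytic equipartition value is below 8%. This calibration is made
against the closed-form single-filament answer, never against any target
number.

Pair interactions use a cell list plus Verlet neighbour list with a 0.4 d
skin, rebuilt whenever the accumulated maximum single-bead displacement
exceeds half the skin — a conservative criterion that guarantees no
interacting pair is missed. Candidate partners are processed in ascending
index order, which makes the neighbour-list and brute-force paths agree
*bit for bit*; the test suite asserts byte-identical trajectories.
Thermal noise uses a 128-layer ziggurat over `mt19937_64`, so trajectories
are bit-reproducible given `(state, parameters, seed)` on a given build.
Beads closer than `1e-3*sigma` abort the run with a diagnostic (the soft
potential makes this unreachable at sane timesteps); non-finite or runaway
displacements abort with the offending bead and step.

## Initial conditions

`lattice_nematic_init()` places straight filaments on a rectangular
lattice with fair left/right coin flips (a nematic, polarity-balanced
start, used for all active runs) and a sub-gap axial jitter that breaks
columnar register without ever creating overlaps. Dense or passive systems
that must start well mixed use `stepwise_compression()`: lattice start at
packing fraction 0.25 in an enlarged box, a mixing run under strong
thermal noise (mixing Peclet 100; for passive systems the temperature is
raised tenfold instead, since Pe is undefined at `v0 = 0`), then 5% affine
box shrinks each followed by a 0.2 tau relaxation until the target packing
fraction, with a bounded-retry overlap guard. The shrink magnitude and
per-stage relaxation are engineering choices (they are not prescribed by
the physics); both are configurable.

## Analyses

* **Curvature**: per-joint signed curvature, head to tail; per-filament
  means, then snapshot means, pooled over frames.
* **Density fluctuations**: the box is tiled by non-overlapping square
  sub-boxes over eight log-spaced sizes from 2 d to L/3; the exponent is
  the least-squares slope of `log sd(N)` vs `log mean(N)` pooled over
  tiles and frames. The ladder stops at L/3 so every size is tiled by at
  least nine sub-boxes: at fixed total bead count, a partition into only
  four tiles measures a conserved quantity whose variance is suppressed
  far below the grand-canonical fluctuation the exponent refers to, at
  any run length. Poisson gives 1/2 (the package's fixture measures it
  within 0.05 with a fixed-count caveat that biases slightly low);
  perfectly latticed points tiled commensurately give zero variance,
  reported as complete suppression. Counting beads (rather than
  filaments) makes the variance-to-mean ratio rise across tile sizes
  comparable to the filament length, which places the measured passive
  exponent slightly above 1/2 and is part of what the active exponent
  rides on.
* **Rings**: per-filament rotation centres by Taubin circle fit (straight
  filaments flagged and excluded, not errors); single-linkage clustering
  at the density-derived cutoff `L/(2*sqrt(Nf))`; four acceptance filters
  in order — more than ten members, normalised radius (gyration
  radius/size) below 0.1 d, normalised polarity (|sum of member
  orientations|/size) below 0.25, centre packing fraction below 0.5 within
  2 d. The polarity and radius thresholds are applied as the printed
  numbers; the polarity quantity is dimensionless, and the package treats
  the printed "0.25 d" as the number 0.25. Ring tracks are spatial
  single-linkage clusters of detections over time (cutoff 3 d; stable
  rings barely translate), tracks shorter than three detections are
  discarded, and lifetime is last minus first detection. Ring diameter is
  twice the mean distance of member beads from the centre; density is
  accepted detections per frame per area.
* **Nematic defects**: bond orientations are averaged per grid cell
  (pitch ~4.7 d; the cell count per side is forced even so the 3x3 loops
  on the even sublattice tile the torus, which makes total-charge
  neutrality an exact identity on fully occupied grids). Winding numbers
  accumulate nematic angle differences wrapped to `(-pi/2, pi/2]` — the
  only wrap under which half-integer charges are well defined — around
  anticlockwise 3x3 loops; windings snap to `{-2pi, -pi, pi, 2pi}` within
  0.3 rad (charges -1, -1/2, +1/2, +1), frames with nonzero total charge
  or unsnapped loops are flagged invalid, and empty cells can be
  in-painted from their nearest occupied neighbour for loop completion
  (flagged). Tracking is per-charge nearest-neighbour linking gated at
  three grid cells, bridging single missing frames, dropping tracks below
  three frames.
* **Polarity**: bead pairs on distinct filaments within the pair cutoff
  are classified parallel below 90 degrees and antiparallel above; exact
  ties count antiparallel (a measure-zero deterministic rule).
* **Local density**: beads within 2 d of each filament's central bead
  (probe excluded), converted to a packing fraction with the per-bead
  coverage `d*r0`. The conversion factor is chosen for consistency with
  the global packing-fraction definition `phi = N*Nf*d*r0/L^2`.

## The synthetic fixtures and what passing means

Every analysis has a seeded generator with exact ground truth: defect
textures `angle = sum_k q_k*atan2(y-y_k, x-x_k) + const` (all four
charges, neutrality enforced on periodic grids), discrete worm-like-chain
ensembles with known `Lp`, Poisson and lattice point sets, and ring scenes
(tangentially closed, polarity-balanced arcs plus clutter; an open-arc
variant that must be rejected by the polarity filter). These validate the
*detectors* exactly — precision and recall 1, charges exact — but they are
idealised: fixture rings are noiseless and perfectly circular, fixture
textures are smooth. Passing them shows the algorithms implement their
definitions, not that the model reproduces biology; the bridge to the
physics is carried by the simulation studies below.

## Desk-scale studies and their limits

The bundled studies (`study_gnf_active()`, `study_gnf_passive()`,
`study_l169r_lp()`, `study_charge_neutrality()`) run minutes each on one
CPU, in the 42 d box (the small-system size used for quantitative
analysis; 30 d for the dense neutrality run at packing fraction 0.9):

* active wild type at packing fraction 0.4: 4 tau equilibration from the
  nematic lattice plus 2.5 tau of production at 0.15 tau cadence; the
  sub-box exponent lands near 0.8 — giant number fluctuations;
* the passive counterpart (same mechanics, `v0 = 0`) from
  stepwise-compressed mixed starts. Passive density relaxation is purely
  diffusive and box-scale modes stay frozen at their initialization draw
  for tens of tau, so the study pools two independent replicas (8 tau
  discarded, 6 tau sampled at 0.5 tau cadence each), which averages over
  two draws of the slow modes; production runs at a coarser passive
  timestep (2.5e-5 tau; density observables are insensitive to the
  bending-mode discretisation error). The exponent lands near the
  equilibrium 1/2, a few hundredths low from bead-level counting and the
  finite compressibility of the filament fluid;
* the mutant persistence length: 4 tau coarse equilibration, then a
  refined-timestep window pooling at least 1e5 joint angles (the
  curvature decorrelation time, ~`gamma*r0^2*d/k_bend` = 6e-5 tau, is far
  below the 0.025 tau cadence, so samples are effectively independent);
* charge neutrality: a 1.5 tau dense run, final-snapshot winding
  analysis.

Run lengths are an order of magnitude below the reference durations
(20-40 tau) and single-seed; they resolve the *exponents* and *identities*
robustly but not slow observables — ring lifetime statistics, defect
lifetime distributions, the full flexure-number phase diagram and the
212 d large-box patterns are out of desk scale and are not asserted
quantitatively. Fluctuation exponents from 20-frame windows carry a few
hundredths of scatter between seeds, well inside the 0.1 band the package
tests against.

## Known limitations

* No hydrodynamic interactions, no explicit monomer exchange: treadmilling
  is an effective body force, so monomer-scale kinetics (turnover times,
  GTPase coupling) are outside the model.
* Strictly 2D; filament crossing events that a quasi-2D membrane system
  permits are forbidden by excluded volume here.
* The Euler scheme's variance inflation at the default timestep means
  curvature *distributions* taken from collective runs are slightly
  broadened; quantitative variance work must use the refined timestep (the
  persistence study does).
* The attractive tail of the (4,2) potential is strongly reshaped by the
  printed linear shift at any moderate cutoff; studies of adhesion
  strength per se should treat `eps` as nominal and calibrate the
  effective well depth explicitly.
* Single-filament speed is `v0*N/(N+1)`, an O(1/N) discretisation of the
  intended `v0`.
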