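---
title: "Models and methods behind semiflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind semiflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(semiflex)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are: the energy model, the sampling machinery, the
density-of-states estimation, the microcanonical transition analysis, the
synthetic testbeds the tests rely on, and the known limitations.

## The coarse-grained chain

A single polymer is N beads connected by N−1 bonds. Three terms build the
energy (all in reduced units, ε_LJ = r₀ = k_B = 1):

* **Non-bonded pairs** (`nonbonded_potential()`): 12-6 Lennard-Jones with
  σ = 2^(−1/6) r₀ — so the minimum of depth 1 sits exactly at the bond
  reference length — truncated at r_c = 2.5σ and shifted by
  V_LJ(r_c) ≈ −0.0163169 so the potential is continuous (and zero) at the
  cutoff. Pairs (i, j) with |i − j| ≤ 1 are excluded: the bond potential
  already carries its own LJ term, so including them again would double
  count.
* **Bonds** (`bond_potential()`): FENE + LJ with R = (3/7) r₀ and
  K = (98/5) r₀². The logarithm diverges at |r − r₀| = R; outside that range
  a bond is invalid. Invalid states are represented by the sentinel `Inf`
  rather than an error so the Metropolis step can reject them uniformly —
  a conformation with a broken bond is representable, just never accepted.
* **Bending** (`bending_potential()`): κ[1 − cos(θ − θ₀)] at each of the
  N−2 interior monomers. θ is the angle between successive *bond vectors*
  b_l = r_{l+1} − r_l, so θ = 0 for a straight chain; with θ₀ = 0 any other
  convention would penalize straight segments, which is inconsistent with
  stiff chains preferring straight ground-state segments. The cosine is
  clamped to [−1, 1] before `acos` to survive collinear roundoff.

κ = 0 is the flexible reference chain; κ = 1 puts bending on the same scale
as the pair attraction; κ = 2 lets bending dominate. Torsion/dihedral terms,
solvent and charges are deliberately absent from the model.

Energy evaluation (and the Monte Carlo kernel) is compiled C++. Incremental
deltas recompute only what a move can change: a displacement touches one
monomer's non-bonded row, its one or two bonds and up to three bend angles;
a pivot changes only the bend angle at the pivot plus non-bonded pairs
straddling it, because the tail rotates rigidly. At N = 55 the naive
O(N) / O(N²/4) loops are faster than any neighbor-list bookkeeping, so no
cell lists are used.

## Sampling

`run_parallel_tempering()` runs K Metropolis threads at temperatures
T_1 < … < T_K with periodic replica exchanges.

* **Ladder** (`temperature_ladder()`): default 48 temperatures
  geometrically spaced in [0.1, 5.0]. Geometric spacing keeps neighboring
  exchange acceptance roughly uniform when the heat capacity varies over
  decades; an explicit list overrides it.
* **Moves**: a sweep is N attempted single-monomer displacements, each a
  uniform shift in a cube of edge r_d. Every 20–70 sweeps (interpolated
  from 70 at the coldest thread to 20 at the hottest) a pivot sweep of N−2
  tail rotations about a random axis through a random interior monomer is
  inserted: pivots decorrelate extended high-temperature coils cheaply,
  while compact low-temperature globules mostly need local moves.
* **Step calibration** (`calibrate_step_sizes()`): before any measurement,
  each thread's r_d is scaled by factors of 1.1 until the displacement
  acceptance lands in [0.45, 0.55], warm-starting each thread from the
  previous (colder) one — which also makes the calibrated r_d increase
  with temperature.
* **Exchanges**: every `exchange_period` sweeps (default 1500), neighbor
  pairs are offered a swap with the standard detailed-balance probability;
  epochs alternate even and odd pairs so every interface is tried at the
  same rate. A swap relabels threads only — the multiset of conformations
  is untouched.
* **Initial states**: every thread starts from the straight chain at bond
  length r₀ (always valid under FENE) and thermalizes before measurement.
* **Reproducibility**: each thread owns an independent counter-based RNG
  stream (xoshiro256++ seeded via splitmix64 from the master seed), plus
  one stream for the exchange scheduler; R's RNG is never touched, and a
  rerun with the same configuration is bit-identical.
* **Records**: per-sweep energy histograms on a fixed uniform grid
  (default width 0.5 for N = 55, range (−8N, 10N); outliers are clamped
  into edge bins and the analysis later trims to the support envelope),
  plus an (E, R²_gyr) time series at a configurable stride. Cached
  energies are re-synced against a full recomputation every 10³ sweeps so
  float drift cannot accumulate.

Thermalization length, stride and total sweeps are not fixed by the method;
they are configuration values echoed into every run container. The smoke
preset (N = 13, 8 temperatures in [0.3, 3.0], 5·10³ + 4·10⁴ sweeps, 4
independent runs) was sized to finish in about a minute while still
resolving the collapse peak; the paper preset (N = 55, 48 temperatures,
2·10⁵ + 2·10⁶ sweeps, 5 runs per κ) is the production scale and takes hours
to days per stiffness on one CPU.

`simulated_annealing()` reuses the same kernel with a geometrically
decreasing temperature schedule and on-the-fly step adaptation; it is the
ground-state verifier, run with restarts, reporting the best-ever
conformation.

## Density of states

`wham()` combines the per-thread histograms h(E; T_k) into one estimate
ĝ(E) through the self-consistent pair

    ĝ(E) = Σ_k h(E;T_k) / Σ_k M_k Z_k⁻¹ e^(−E/k_B T_k),
    Z_k  = Σ_E ĝ(E) e^(−E/k_B T_k),

iterated in log space (log-sum-exp throughout — no bare exponentials of
±E/T ever appear, which matters when E/T spans thousands). The gauge is
fixed by ln Z₁ = 0; ln g is only ever defined up to an additive constant,
and every downstream observable is invariant under that constant.
"Converged" means max |Δ ln Z_k| < 10⁻⁸ (configurable, with a 10⁵ iteration
cap and an explicit flag when not reached). Empty bins inside the support
envelope stay excluded — no interpolation happens at this stage.

Errors come from independent runs only: `combine_runs()` aligns each
replicate's gauge by the least-squares constant on the shared support and
reports the per-bin mean and standard error of the mean. With fewer than
two runs, errors are absent (`NA`), never silently zero.

## Microcanonical analysis

`microcanonical()` takes the estimate(s), builds S(E) = k_B ln ĝ(E), and
smooths it with a *single global Bézier curve* whose control points are all
support bins (degree ≈ number of bins). The Bernstein form gives analytic
parametric derivatives; derivatives with respect to energy follow by the
chain rule through the parameter-to-energy map (exactly affine for a
uniform grid, inverted by bisection otherwise). Evaluation goes through
log-space Bernstein weights, which stay numerically stable at degree ~10³
where naive binomial coefficients overflow. A decimation option
(`control_thin`) keeps every m-th bin as a control point for noisy data;
the default keeps all.

β = dS/dE, γ = dβ/dE and δ = dγ/dE are evaluated on a uniform grid
(default 10³ points). With replicate estimates, all four curves are
recomputed per run on the common grid and the cross-run spread becomes the
pointwise error.

`find_transitions()` applies the least-sensitive-inflection rules:

| order | dependence  | signature                                   |
|-------|-------------|---------------------------------------------|
| 1     | independent | positive-valued interior minimum of β       |
| 2     | independent | negative-valued interior peak of γ          |
| 2     | dependent   | positive-valued interior minimum of γ       |
| 3     | independent | positive-valued interior minimum of δ       |
| 3     | dependent   | negative-valued interior peak of δ          |

Dependent records are admitted only when an independent partner of the
next-lower order exists at lower transition energy (they are precursors in
the disordered phase). Numerical choices:

* a margin (default 2% of the support range per side) is excluded from the
  search, because the endpoint-interpolating Bézier curve is not smoothed
  there and its derivatives pick up boundary artifacts;
* an extremum must have prominence above 10⁻⁵ of max(curve span,
  span(S)/L^k) where L is the window width and k the derivative order —
  this floor ties "flat" to the entropy's own scale, so an exactly affine
  or Gaussian entropy yields no records despite float-level wiggles, while
  genuinely shallow physical extrema (the collapse peak of a short chain
  is one) survive;
* multiple same-sign extrema are kept as separate records, never merged;
* each record carries β_tr = β(E_tr), the extremal value of the
  classifying curve, and a significance = |value| / propagated error;
  records below significance 2 stay in the table but are flagged noisy
  (weak low-energy third-order hints are expected to sit in this
  category). Orders above 3 follow the same generic sign rules but are off
  by default and untested.

`transition_table()` reports each record against the putative ground-state
energy E_min (the lowest energy seen in sampling), as κ, E_tr,
ΔE = E_tr − E_min, β_tr, order, dependence.

## Canonical observables

`canonical_mean_energy()` and `heat_capacity()` reweight the density of
states to any temperature (log-sum-exp weights; C_V via the energy
variance, which equals d⟨E⟩/dT in the canonical ensemble and is
non-negative by construction). The structural fluctuation d⟨R²_gyr⟩/dT
cannot come from an energy-only density of states, so
`observable_temperature_derivative()` estimates it from the per-thread
(R²_gyr, E) time series by the covariance formula, reported at the ladder
temperatures. Canonical peaks are provided for comparison only — the
microcanonical records are the transition criterion, since canonical
response-function extrema are ambiguous transition markers in finite
systems.

## Structure analysis

`radius_of_gyration_sq()` uses uniform masses. `pair_distribution()` bins
*all* unordered pair distances (bonded included) into disjoint cells of
width 2 r_t with r_t = 0.01, centered at r_t(2m+1) — a partition, so counts
always sum to N(N−1)/2. `contact_map()` keeps non-bonded pairs (j > i+1)
with r_ij strictly below 1.2; `secondary_structure_streaks()` reports
maximal runs (length ≥ 2) of contacts with constant i+j (anti-diagonal:
hairpin turns) or constant j−i (diagonal: helix-like alignment). These are
descriptive geometric summaries; no claim beyond streak geometry is made.
Conformations export to XYZ and minimal PDB for visualization.

## Synthetic testbeds, and what passing them shows

`synthetic_dos()` provides closed-form ln g tables so every analysis stage
is testable without simulation:

* the **log-concave** family has strictly monotone β and extremum-free
  higher derivatives: the correct output is an empty transition table;
* the **two-Gaussian** family develops a convex intruder in S(E). The
  default parameterization (centers 0 and 60, widths 4 and 8, log-weight
  difference 35.6 on the grid [−25, 30]) was chosen once so that the
  intruder is *shallow*: β keeps exactly one positive interior minimum, and
  its value lies within a few percent of the Maxwell double-tangent slope
  computed independently from the raw curve's upper concave hull
  (`double_tangent_slope()`). A deep intruder would separate the two — the
  β minimum dips well below the Maxwell slope — which is physically fine
  but would make the double tangent useless as a tight oracle;
* a **near-flat cubic** β (β = β₀ − a(E−E*) − c(E−E*)³ with a small) has a
  strictly negative γ peak at E*: the second-order testbed. The small
  linear tilt keeps the peak's sign strictly negative; with a = 0 exactly,
  the analytic peak value is 0 and its classified sign would be at the
  mercy of smoothing roundoff.

`sample_histograms_from_dos()` draws exact categorical samples from
p_k(E) ∝ g(E) e^(−E/k_B T_k), giving the reweighting stage a ground truth
with known Poisson statistics.

These testbeds exercise the estimator and classifier against known answers;
they do not emulate the correlated, multimodal sampling noise of real
Monte Carlo data. What passing them shows is that the analysis machinery is
correct, not that any particular simulation is converged — convergence at
production scale is the job of independent runs, replica-mixing diagnostics
and the replicate error bars.

## Design decisions that were genuinely open

* **Exchange scheduling**: all even pairs, then all odd pairs on
  alternating epochs (one fair choice among several; a single random pair
  per epoch mixes more slowly at equal cost).
* **Pivot end-handling**: pivots rotate the tail only; rotating the head
  is equivalent by chain-reversal symmetry and therefore not separately
  implemented.
* **Run container**: a single structured JSON file per run (ladder,
  histograms, time series, minimum conformation, diagnostics, config echo,
  seed, package version) plus plain-text tabular exports for histograms,
  densities of states, curves and transition tables.
* **Canonical curves from the density of states, structural fluctuations
  from time series** — each data product supports exactly one of the two.
* **The desk-scale problem sizes** quoted above (smoke preset, the
  recovery-test sample counts, the annealing budgets in the tests) are the
  package's own test-design choices: large enough that the checked signals
  are well resolved, small enough to run routinely.

## Limitations

* The freezing regime of long stiff chains needs the production schedule;
  desk-scale runs resolve the collapse but not a converged low-temperature
  solid, and ground-state energies from short annealing runs are upper
  bounds, typically a few percent above the true minima.
* WHAM errors are replicate-based only; no per-histogram error propagation
  or autocorrelation correction is applied inside the estimator.
* The global Bézier smoother's bandwidth scales like the support width
  divided by √(number of control points); narrow features below that scale
  are smoothed away unless the bin width (or `control_thin`) is adjusted.
* Order-3 dependent records require an order-2 independent partner at
  lower energy; chains of dependencies beyond that rule are not searched.
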