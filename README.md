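# semiflex

Replica-exchange Monte Carlo simulation and microcanonical statistical
analysis of flexible and semiflexible coarse-grained polymers, for studying
how bending stiffness reshapes the conformational phase behavior of a single
chain — the Θ collapse from random coils to liquid globules, and the
freezing transition into solid (icosahedral) low-temperature structures that
disappears once bending penalties dominate the monomer–monomer attraction.

## The model

A chain of N monomers with positions X = (r₁, …, r_N) has energy

    E(X) = Σ_{i>j+1} V_NB(r_ij) + Σ_i V_B(r_i,i+1) + Σ_l V_bend(θ_l)

* **Non-bonded pairs** interact through a truncated and shifted 12-6
  Lennard-Jones potential, V_NB(r) = V_LJ(r) − V_LJ(r_c) for r < r_c = 2.5σ
  and 0 beyond, with σ = 2^(−1/6) r₀ so the minimum (depth ε_LJ) sits at the
  reference bond length r₀.
* **Bonds** combine the LJ term with a FENE (finitely extensible nonlinear
  elastic) potential, −(K R²/2) ln[1 − ((r − r₀)/R)²], R = (3/7) r₀,
  K = (98/5) r₀², restricting bond lengths to (r₀ − R, r₀ + R).
* **Bending** penalizes the angle θ between successive bond vectors,
  V_bend(θ) = κ [1 − cos(θ − θ₀)] with θ₀ = 0; κ = 0 is the flexible chain.

Everything is in reduced units (ε_LJ = r₀ = k_B = 1).

The chain is sampled by parallel tempering: K Metropolis threads at
temperatures T_k, single-monomer displacement moves (step size calibrated
per thread to ≈50% acceptance) interleaved with pivot rotations, and
periodic replica exchanges. Per-temperature energy histograms are combined
into one density of states g(E) by multiple-histogram reweighting (WHAM),
solved in log space. The microcanonical entropy S(E) = k_B ln g(E) is
smoothed by a global Bézier (Bernstein) curve with analytic derivatives, and
phase transitions are located and classified by the generalized inflection-
point method: a positive-valued minimum of β(E) = dS/dE marks a first-order
transition (the convex intruder / backbending signature), a negative-valued
peak of γ(E) = dβ/dE a second-order transition, and so on through
δ(E) = dγ/dE for third order, with dependent transitions admitted only as
higher-energy companions of a lower-order independent one.

## Worked example

A desk-scale end-to-end pipeline (N = 13 flexible chain, 8 temperatures in
[0.3, 3.0], four independent runs; about a minute on one CPU):

```r
library(semiflex)
cfg  <- preset_config("smoke", kappa = 0, seed = 1)
runs <- run_campaign(cfg)          # parallel tempering, 4 independent runs
fit  <- analyze_runs(runs)         # WHAM per run -> combined -> analysis
print(fit)
```

```
Microcanonical inflection-point analysis: E in [-41, 23.88], 1000 grid points
  errors from 4 independent runs
  4 transition(s):
 kappa       E_tr  delta_E    beta_tr order  dependence significance
    NA -33.466967  8.18852 2.86387096     2 independent     2.762120
    NA -13.984985 27.67050 0.91732793     2 independent    46.117263
    NA   2.120120 43.77561 0.13578921     3 independent     2.025114
    NA   8.743994 50.39948 0.01837096     2 independent     1.049191
```

The strongly significant second-order record at ΔE ≈ 27.7 (β_tr ≈ 0.92) is
the Θ collapse of the 13-mer: a negative-valued peak of γ(E), i.e. a
least-sensitive inflection point of β(E). The record near ΔE ≈ 8.2
(β_tr ≈ 2.9) is the low-temperature ordering signal of this very short
chain, and entries with significance below 2 are flagged as noise.
`delta_E = E_tr − E_min` measures each transition from the lowest energy
found in the runs (here E_min ≈ −41.0).

Production-scale runs (N = 55, κ ∈ {0, 1, 2}, 48 temperatures in
[0.1, 5.0], 5 independent runs — hours to days per stiffness on one CPU)
use the same pipeline via `preset_config("paper", kappa = ...)`, or the
command-line wrapper:

```sh
Rscript inst/cli/semiflex.R simulate --preset paper --kappa 0 --out results/paper/kappa0
Rscript inst/cli/semiflex.R wham     --runs results/paper/kappa0 --out dos_k0.tsv
Rscript inst/cli/semiflex.R analyze  --runs results/paper/kappa0 --kappa 0 --out analysis_k0
```

Ground-state search and structural characterization:

```r
sa <- simulated_annealing(model_params(55, kappa = 2),
                          annealing_schedule(0.7, 0.02, 140, 3000),
                          restarts = 3, seed = 31)
pair_distribution(sa$best_conformation)          # P(r), bins of half-width 0.01
contact_map(sa$best_conformation)                # non-bonded pairs with r < 1.2
secondary_structure_streaks(contact_map(sa$best_conformation))
```

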