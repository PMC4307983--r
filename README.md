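# galswitch

Deterministic modelling and single-cell quantification of the transient
bimodality of the yeast galactose (GAL) pathway under mixed glucose +
galactose inputs.

When budding yeast meets both sugars at once, only a fraction of cells
induces the GAL program early; the repressed remainder activates
coherently — and the population becomes unimodal again — precisely when
glucose runs out. `galswitch` implements both sides of the analysis that
explains this:

* **Circuit model.** A four-variable ODE model of the GAL switch
  (`G1_T`, `G80_T`, `G4_T`, `R*`): galactose converts the transducer G1
  to `G1*`, which sequesters the repressor G80 away from the activator
  G4 (dissociation constants `K_seq80`, `K_seq4`); free G4 drives G1 and
  G80 production through `h_act(G4_f) = G4_f^n/(K_A^n + G4_f^n)`;
  glucose activates a repressor `R*` (mass action,
  `dR*/dt = k_R·glu·(R_tot − R*) − k_Rd·R*`) that represses the *G1* and
  *G4* promoters through `h_rep(R*; K) = K^n/(K^n + R*^n)`. The model
  undergoes saddle-node bifurcations in glucose: monostable ON at low
  glucose, bistable in a band `[glu_low*, glu_high*]`, monostable OFF
  above. Analyses include bifurcation scans, regime maps, Latin-hypercube
  basin-of-attraction fractions, dominant eigenvalues of the ON state,
  quasi-steady-state sweeps, and the time-to-bifurcation statistic
  `delta_b`. Variants: a GAL80 open loop (constitutive G80) and a
  dilution-rate model (glucose scales decay rates instead of activating a
  repressor).
* **Quantification pipeline.** For time-resolved flow-cytometry event
  tables: per-cell expression as `log10(fluorescence/side_scatter)`,
  Gaussian-mixture modality calls (BIC + weight + separation rule),
  ON/OFF subpopulation tracking against a `10^-0.2` a.u. threshold, and
  the metrics `delta_a` (early-activation half-max time), `delta_g`
  (duration of bimodality), `F_ON-mid`, response time, and subpopulation
  growth rates (`log2` count slopes). Plus Hill fits to sugar-depletion
  curves (`k_half`, fractional half-max shifts, metabolic delay), OD600
  growth rates, and expected-vs-observed galactose consumption.
* **Synthetic experiments.** A seeded two-cohort generator
  (`generate_experiment()`, `generate_condition_grid()`) with analytic
  ground truth for every metric, emulating robot-style sampling every
  20 min for 14 h, sequential sugar consumption, a diauxic lag, and a
  ~15% faster-growing repressed cohort.

## Worked example

Where is the bistable band at 150 nM galactose?

```r
library(galswitch)
p <- default_params("repressor")
bifurcation_scan(p, gal_fixed = 150, glu_grid = 10^seq(0.5, 3.2, length.out = 30))
#> bifurcation scan at gal = 150 nM
#>   regimes: mono_ON -> bistable -> mono_OFF
#>   glu_low_star = 82.9 nM, glu_high_star = 267.7 nM
```

So at this galactose dose the circuit is bistable for glucose between
about 83 and 268 nM: a culture whose glucose decays by consumption
traverses OFF → bistable → ON, and the coherent activation of the
repressed cells is predicted at the moment glucose crosses 82.9 nM.

Quantify a synthetic mixed-sugar experiment end to end:

```r
ex <- generate_experiment(synthetic_config())   # 0.1% glu + 0.1% gal
rep <- run_pipeline(ex$events, ex$sugars, ex$od, seed = 7)
rep$summary
#>   condition delta_a delta_g f_on_mid response_time rate_on rate_off
#> 1 synthetic   1.213   6.581   0.4567         1.861  0.5609   0.6414
#>   k_half_glucose k_half_galactose
#> 1          5.199            8.584
ex$truth[c("delta_a_true", "delta_g_true", "f_on_mid_true")]
#> $delta_a_true  [1] 1.2
#> $delta_g_true  [1] 6.597
#> $f_on_mid_true [1] 0.45
```

The early cohort reaches half-max expression at ~1.2 h (`delta_a`); the
repressed cohort follows only ~6.6 h later (`delta_g`), at glucose
depletion; 46% of cells are ON at the bimodal midpoint (`F_ON-mid`); and
the repressed cohort outgrows the activated one
(`rate_off / rate_on ≈ 1.14`, log2 units/h) — early GAL induction carries
a growth cost while glucose lasts. Galactose's half-depletion time trails
glucose's by ~3.4 h (`metabolic_delay(...)` of the two Hill fits).

The numbered scripts under `analysis/` run the full set of analyses
(bifurcation structure and variant comparisons, basin/eigenvalue trends,
the delayed-galactose `delta_b` design, metric recovery on a condition
grid, sugar and growth kinetics) and write tidy tables under `results/`.

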