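---
title: "Methods: bistable GAL dynamics and single-cell bimodality metrics"
author: "galswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bistable GAL dynamics and single-cell bimodality metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`galswitch` models and quantifies the transient bimodality of the yeast
galactose (GAL) regulatory program under mixed glucose + galactose inputs.
It has two halves that meet in the middle:

1. a deterministic ODE model family of the GAL circuit with glucose
   repression, together with the dynamical-systems analyses built on it
   (equilibria, saddle-node bifurcation scans, basin-of-attraction
   sampling, dominant eigenvalues, quasi-steady-state regime sweeps, and
   the time-to-bifurcation statistic `delta_b`);
2. a quantification pipeline for time-resolved single-cell fluorescence
   (mixture-based modality calls, ON/OFF subpopulation tracking, the
   `delta_a` / `delta_g` / `F_ON-mid` / response-time metrics, Hill fits
   to sugar-depletion curves, and growth-rate estimation), exercised
   against a seeded synthetic-experiment generator whose ground truth is
   analytic.

# The circuit model

State variables are total concentrations (nM): the signal transducer pool
`G1_T`, the repressor pool `G80_T`, the activator pool `G4_T`, and the
active glucose repressor `R*`. Galactose activates a fraction of G1,

$$G1^* = G1_T \frac{gal^m}{K_{gal}^m + gal^m},$$

and two binding equilibria are taken as fast: G1\*–G80 (dissociation
constant `K_seq80`) and G4–G80 (`K_seq4`). Free G80 solves the monotone
conservation relation

$$G80_f + \frac{G1^*\,G80_f}{K_{seq80}+G80_f}
        + \frac{G4_T\,G80_f}{K_{seq4}+G80_f} = G80_T,$$

which has a unique non-negative root (found by safeguarded bisection, both
in R and in the compiled right-hand side); free G4 follows as
$G4_f = G4_T K_{seq4}/(K_{seq4}+G80_f)$. Free G4 drives transcription
through a Hill activation $h_{act}(G4_f; K_A, n_A)$, closing the positive
feedback loop (more G1 → more sequestered G80 → more free G4), while G80
production by G4 closes the negative loop.

Glucose enters through mass-action activation of a repressor pool,

$$\frac{dR^*}{dt} = k_R\,glu\,(R_{tot}-R^*) - k_{Rd}\,R^*,$$

with `R*` repressing the *G1* and *G4* promoters through
$h_{rep}(R^*; K_{R1}, n_R)$ and $h_{rep}(R^*; K_{R4}, n_R)$:

$$\frac{dG1_T}{dt} = b_1 + \alpha_1\,h_{act}(G4_f)\,h_{rep}(R^*;K_{R1}) - d\,G1_T$$
$$\frac{dG80_T}{dt} = b_{80} + \alpha_{80}\,h_{act}(G4_f) - d\,G80_T$$
$$\frac{dG4_T}{dt} = b_4 + \alpha_4\,h_{rep}(R^*;K_{R4}) - d\,G4_T$$

Two variants probe the circuit logic. The **open-loop** variant cuts the
G80 feedback, replacing G80 production by the constant `g80_const`,
calibrated to 40% of the fully induced wild-type production
($0.4\,(b_{80}+\alpha_{80})$): removing the negative loop enlarges the
bistable region. The **dilution** variant removes the repressor entirely
and instead lets glucose scale each species' decay rate,
$d\,(1 + s_i\,h_{act}(glu; K_g, n_g))$ — the hypothesis that glucose acts
only through growth-rate-mediated dilution.

## Default parameters

Concentrations are nM and times hours throughout the model half of the
package. The shipped defaults (see `default_params()`) were fixed by a
randomized search against the calibration the analyses require — a
bistable glucose band at 150 nM galactose lying inside glu ∈ [10, 1000]
nM with monostable ON below it and monostable OFF above it, the same
topology at 75 and 300 nM galactose, and a unique low-G1 state without
galactose — and are versioned in `R/model_params.R`. The repression
constants `K_R1 = 64.64` and `K_R4 = 32.48` nM are defined so that a 20%
*reduction in affinity* (i.e. both K scaled by 1.25) gives 80.8 and
40.6 nM. The decay rate `d = 0.5`/h corresponds to dilution at a ~1.4 h
doubling time; `K_gal = 60` nM places half-activation well below the
150 nM reference dose; the sequestration constants (0.25 and 0.4 nM) are
tight relative to the pools, which is what makes the sequestration switch
ultrasensitive.

## Numerical choices

* Integration: `deSolve::lsoda`, rtol `1e-8`, atol `1e-10` nM. For
  basin sampling the right-hand side is compiled C (`src/gal_model.c`);
  the R and compiled paths are asserted to agree in the test suite.
* Equilibria: multistart damped Newton (Armijo backtracking, coordinates
  projected non-negative) from Latin-hypercube starts over
  `[0, 2(\alpha_i+b_i)/d]` per protein and `[0, R_tot]` for `R*`, plus
  basal and fully-induced anchor states. Roots are deduplicated at `1e-4`
  relative distance and polished to residual `< 1e-10` nM/h. Saddles
  between attractors have thin Newton basins, so the search additionally
  bisects each segment joining two attractors by forward-flow
  classification — the basin boundary lies on the saddle's stable
  manifold, and a short integration from it lands next to the saddle.
* Jacobians: central finite differences with relative step `1e-6`.
* Stability: all eigenvalue real parts negative. The "dominant"
  eigenvalue is the one of smallest magnitude at the ON equilibrium; it
  sets the slowest relaxation and vanishes at the saddle-node.
* Saddle-node thresholds: bisection between neighbouring grid cells of
  different regime to relative precision `1e-3` (geometric midpoints, as
  the grids are logarithmic).
* Basin classification: Latin-hypercube initial states integrated to
  200 h (stragglers near a saddle get a 4× extension), endpoints assigned
  to the nearest equilibrium in `log1p` state space; samples whose final
  residual exceeds `1e-8` nM/h are counted separately and warned about
  above 0.1%. Monostable points short-circuit to 0 or 1. Fractions are
  bit-reproducible for a fixed seed.
* ON/OFF calls for a *single* stable state: scans compare `g1_total`
  against the geometric mean of the ON/OFF branch levels at the nearest
  bistable grid point; without any bistable cell the fallback is the
  geometric mean of the basal (`b_1/d`) and fully induced
  (`(b_1+\alpha_1)/d`) levels, and the threshold is user-overridable.

## The reduced-affinity direction

Scaling both repression constants by γ rescales the saddle-node points in
`R*`-space by exactly γ (the steady-state system depends on glucose only
through `R*`, and on `R*` only through the two `h_rep` terms), and
`R*(glu)` is strictly increasing. Both glucose thresholds therefore move
*up* when affinity is reduced — the bistable window shifts to higher
glucose. The observable consequence for a culture whose glucose decays by
consumption is a *shorter* bimodal epoch: the trajectory reaches the
(now higher) lower threshold sooner, so the predicted `delta_b` and
`delta_g` contract. The acceptance tests assert this shift-and-contract
behaviour on the time axis rather than any particular direction of the
upper threshold, which is the form the package's equations actually
determine.

# The quantification pipeline

Per-cell expression is `log10(fluorescence / side_scatter)`; events with
non-positive side scatter are rejected and non-positive fluorescence is
clipped to a configurable floor (both counted, never silent).

**Modality.** Each time point's distribution is fit with 1- and
2-component normal mixtures (the 2-component fit by EM with 5 seeded
restarts, quantile-anchored plus random initializations, sd floored at
`1e-4`). The call is *bimodal* only if the 2-component fit wins by BIC
**and** the minor weight is ≥ `w_min = 0.05` **and** the means are at
least `2\sqrt{(\sigma_1^2+\sigma_2^2)/2}` apart. All three constants are
arguments. The rule is deliberately conservative: a BIC win alone often
reflects heavy tails rather than two populations.

**Branch assignment.** When bimodal, the upper/lower component means are
the ON/OFF subpopulation means. Unimodal time points are assigned by
threshold (default `-0.2` log10 units, i.e. a fluorescence ratio of
`10^-0.2`): a low mean is the repressed cohort's mean — which is what
makes the OFF branch's half-max well defined before its activation — and
a high mean is the activated cohort's. Two refinements keep the branch
series unbiased at the ends, where the mixture cannot resolve cohorts
that genuinely coincide: before the first bimodal time point the
unimodal-low mean is filled backward into the ON branch (the cohorts are
still coincident), and after a bimodal epoch a unimodal-high mean is
assigned to both branches (the OFF cohort has activated and merged).
Without these fills the observed min/max window of each branch is
truncated and the half-max times inherit a systematic bias of a few
tenths of an hour.

**Metrics.** `half_max_time` uses the min/max of the observed window (not
an asymptote), first upward crossing, linear interpolation.
`delta_a` is the ON branch's half-max time; `delta_g` is the OFF branch's
half-max time minus the ON branch's; `F_ON-mid` interpolates the
above-threshold fraction at the midpoint of the two half-max times;
the response time is the first crossing of `F_ON = 0.5`. Undefined
metrics are `NA` with reason codes, never zeros.

**Growth rates.** Subpopulation rates are OLS slopes of `log2(count)`
versus time, with counts scaled to culture density when the event table
carries `events_per_ul` (otherwise flagged unscaled). The default window
is the *stable* bimodal plateau — bimodal time points where the ON mean
has completed its rise and the OFF mean is still clearly below threshold
— because on the rising edges threshold counts track the rise, not cohort
sizes. OD-based rates are finite differences of `log(OD600)` assigned to
interval midpoints, optionally smoothed with a centered 5-point moving
average.

**Sugar kinetics.** Depletion curves are fit with the decreasing Hill
form `floor + (s0 - floor) k^n/(k^n + t^n)` by Levenberg–Marquardt with
a small ladder of restarts; the floor is fixed at zero unless freed,
since a residual offset is rarely identifiable from 40-point series and
the fits are used mainly for their half-depletion time `k_half`. Series
declining less than 20% from their maximum are rejected as non-decaying
rather than fit badly. `halfmax_shift` and `metabolic_delay` are the
derived comparisons; `expected_consumption` scales a galactose-only
reference rate by the measured ON fraction and density.

# The synthetic-experiment generator

The generator (`synthetic_config()` / `generate_experiment()`) is a
two-cohort *statistical* emulator, not a per-cell simulation: every truth
metric is analytic, which is what makes tolerance statements exact. It
reproduces the features the pipeline relies on:

* an early activated cohort whose log10 mean rises logistically
  (half-rise `rise_half_on` after the stimulus) and a repressed cohort
  that stays at baseline until glucose depletion, then rises with
  half-rise `rise_half_off` — so distributions are transiently bimodal
  and the OFF cohort activates coherently at depletion;
* glucose consumed in proportion to population size, depleting before
  galactose; pre-depletion galactose consumption is a configurable leak
  (`gal_leak`), default 5% of the full per-density rate, emulating the
  near-absence of galactose use while glucose remains;
* exponential growth with a diauxic lag of the OFF cohort, and an
  OFF:ON growth-rate ratio (default 1.15) during the glucose phase;
  cohort shares are anchored so the ON share equals `p_on` exactly at
  the bimodal midpoint, which keeps `F_ON-mid` truth equal to `p_on`
  while the count series still carry the configured rate differential;
* robot-style sampling every 20 min for 14 h, 2000 events per sample,
  lognormal side scatter, and event-level log10 noise `sd_log = 0.15`.

Defaults emulate a 0.1% glucose + 0.1% galactose culture inoculated at
200 cells/µl with growth rates 0.45/h (glucose) and 0.35/h (galactose):
glucose then depletes near 6.8 h, within the observation window. The
condition grid maps the configured ON fraction monotonically up in
galactose and down in glucose, and the depletion time grows with the
glucose dose, so the estimated `delta_g` must increase with glucose —
the grid-level property the tests check (Spearman ρ > 0.9).

What the generator does *not* emulate: cell-to-cell switching between
states, instrument drift and spillover, asymmetric or heavy-tailed
fluorescence noise, density-dependent growth saturation, and any
mechanistic coupling between expression and consumption beyond the leak
factor. Passing tests on synthetic data therefore demonstrate estimator
correctness under the stated statistical structure, not robustness to
every artifact of real cytometry.

# Problem sizes

The test suite and the acceptance script run desk-scale: bifurcation
scans use 10–14 point logarithmic glucose grids with bisection
refinement; regime maps 13 × 9 cells; basin fractions 2000
Latin-hypercube samples × 3 seeds per glucose level; modality accuracy
200 labelled samples of 5000 events; and the recovery grid 5 glucose ×
4 galactose levels × 3 seeds at the default 2000 events per sample.
These sizes were chosen so each analysis completes in minutes on one
core while keeping Monte-Carlo error well inside the stated tolerances
(binomial s.e. ≈ 0.011 on a 2000-event fraction).

# Known limitations

* The equilibrium search is multistart, not continuation: an extremely
  narrow bistable sliver between grid points could in principle be
  missed; the bisection refinement bounds this by the `1e-3` relative
  threshold precision.
* The EM modality rule shares the usual weakness of BIC-based selection:
  strongly skewed unimodal data can be called bimodal. The separation
  and weight guards mitigate but do not eliminate this.
* `delta_b` assumes a non-increasing glucose trajectory after its first
  crossing; schedules that re-add glucose should be analysed with
  `quasi_static_regimes()` instead.
* The dilution variant is included as the comparator hypothesis; its
  defaults produce a narrower bistable region than the repressor model,
  consistent with its role as the less robust explanation.
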