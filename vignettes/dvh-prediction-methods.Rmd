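---
title: "Beam-informed DVH prediction and biologically related planning constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam-informed DVH prediction and biologically related planning constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beamdvh)
```

## The problem

Knowledge-based treatment planning tries to tell a planner, before
optimization starts, what dose an organ at risk (OAR) can realistically be
held to. For nasopharyngeal carcinoma treated with volumetric modulated arc
therapy (VMAT), the achievable dose to structures such as the brainstem,
spinal cord, parotid glands or lenses depends on patient anatomy in a way
that simple geometric summaries capture poorly. `beamdvh` implements a
dosimetric alternative: describe each patient-organ by the cumulative
dose-volume histograms (DVHs) the organ would receive from nine static
conformal beams at equally spaced gantry angles (160°, 120°, 80°, 40°, 0°,
320°, 280°, 240°, 200°, indexed by field index FI = 1..9), and learn a map
from those nine curves to the composite-plan DVH the optimizer actually
achieves. Predicted curves are then converted to equivalent uniform doses
(EUD) and turned into slightly tightened, bias-corrected constraints that
can be handed to an inverse planner.

The package implements the full chain — DVH representation, sequence model,
EUD and constraint generation, evaluation statistics — plus a synthetic
cohort generator, because clinical nine-beam/plan DVH pairs are not
publicly available. Everything downstream of the generator treats its
output exactly as it would treat clinical exports.

## DVH representation

All curves live on a fixed percentage-volume grid: the dose quantile
$D_v$ at $v = \Delta v, 2\Delta v, \dots, 1$, meaning a fraction $v$ of the
structure receives at most $D_v$. The default bin width is
$\Delta v = 0.001$ (0.1%), i.e. 1000 points per curve. Resampling by
percentage volume rather than by absolute dose or volume makes every curve
the same length regardless of organ size, which is what lets one recurrent
model serve all organs, and concentrates model capacity on the shape of the
curve rather than its parameterization.

Conventions, chosen once and used everywhere:

* The grid is closed at $v = 1$, so the maximum dose is always represented
  (`max_dose()` is the last grid value).
* Quantile curves are non-decreasing, finite, non-negative; every
  constructor and transformer validates or enforces this.
* `dvh_from_voxels()` uses linear interpolation of the empirical
  distribution function (quantile type 4), which resolves flat and jump
  regions to the lowest dose attaining each volume level.
* The conventional dose-binned form (`to_dose_binned()`) reports, at each
  dose edge, the fraction of volume grid points at or above that edge — a
  counting convention. The two forms are mutual inverses: exactly (to
  1e-6 Gy) when the dose edges bracket the curve's jump values, and to
  within one edge spacing otherwise. This is an information limit of the
  binned form, not an implementation tolerance: a coarse dose grid simply
  cannot localize a jump more finely than its own spacing.
* Hottest-fraction metrics ($D_{98}$, $D_{1cc}$, ...) follow the
  order-statistic reading: $D_x$ is the dose of the bin containing the
  coldest voxel of the hottest $x$ fraction (fractional bin position
  $(1-x)/\Delta v + 1$, linearly interpolated). This agrees exactly with
  brute-force order statistics on voxel lists, including at jump points,
  where a naive "quantile at $v = 1-x$" reading under-reports the hot-side
  dose.
* D1cc requires the organ volume (`total_volume_cc`); metric tables emit
  `NA` plus a note for rows where it is missing rather than failing.

## Equivalent uniform dose and constraints

The generalized EUD over the volume grid is the power mean

$$EUD = \Big(\sum_v \Delta v\, D_v^{\,k}\Big)^{1/k},$$

with one exponent $k$ per organ category: 10.0 for the spinal cord, 9.8 for
the brainstem, optic nerves and optic chiasm, 6.8 for the larynx, 2.0 for
the lens and 3.9 for the parotid glands. A PRV shares its parent organ's
$k$; bilateral organs share one entry. Where only a tolerance dose $D_{50}$
is known, $k = 0.15 \times D_{50}$ (the Monaco protocol rule); the package
ships no default $D_{50}$ values, the registry accepts user-supplied ones.
Large $k$ weights hot spots (serial organs), $k = 1$ is the mean dose
(parallel organs). Negative, target-type exponents are rejected.

Numerics: the sum is computed as
$D_{max}\,(\sum \Delta v\,(D_v/D_{max})^k)^{1/k}$ so that $k \approx 10$
with doses near 70 Gy cannot overflow; an all-zero curve returns 0 by
convention. The Riemann sum runs over the grid $v = \Delta v \dots 1$.

Predictions carry a small systematic bias that differs by organ. It is
removed with the training-cohort mean ratio

$$c_{OAR} = \frac{1}{n}\sum_P \frac{EUD_P}{EUD'_P},$$

which by construction makes the training mean of truth over corrected
prediction exactly 1. The exported planning constraint is
$cEUD' = \alpha\, c_{OAR}\, EUD'$ with $\alpha = 0.97$ by default — slightly
below 1 so the optimizer is pushed marginally past the predicted achievable
dose. For strictly serial structures (spinal cord, lenses) a maximum-dose
constraint is generated by the identical correct-and-tighten process
applied to $D_{max}$. Whether $\alpha$ should also apply to the max-dose
constraint is not a settled convention; this package applies it uniformly
and exposes `alpha` as configuration.

## The sequence model

The predictor is a stack of three gated recurrent units with hidden-state
sizes 18, 9 and 1, run once along the volume grid from $v = \Delta v$ to
$v = 1$. Design decisions worth stating explicitly:

* **Sequence arrangement.** The sequence axis is the volume-bin index
  (1000 steps at the default grid); step $t$ carries nine features, the
  nine beams' dose quantiles at grid point $t$, each divided by the
  normalization dose (70 Gy, the highest prescription level). The
  alternative arrangement — nine sequence steps of 1000-dimensional
  vectors — is coherent too; it was not chosen because it makes the
  recurrence length 9 and the per-step input dimension grid-dependent,
  which defeats the point of percentage resampling. The chosen arrangement
  keeps the model independent of both organ and grid.
* **Output head.** The third GRU has state size 1 and its state sequence
  *is* the predicted curve (no extra projection layer). There is no output
  activation; validity is restored after rescaling by clipping at zero and
  projecting onto the monotone cone with a running maximum. The projection
  is exact for curves that are already monotone and is the cheapest
  monotone regression consistent with one forward pass.
* **Objective and training.** Mean squared difference between predicted
  and actual plan curves over all grid points of all training samples
  (one sample = one patient-organ pair), minimized with Adam
  (learning rate $10^{-3}$, 200 epochs, batch 16 by default — all
  configuration, none of it sacred). One pooled, organ-independent model
  is trained on all organs together; per-organ residual bias is exactly
  what $c_{OAR}$ absorbs.
* **Determinism.** One integer seed drives parameter initialization
  (uniform in $\pm 1/\sqrt{H}$ per layer) and batch shuffling. Training
  twice with the same seed, data and config is bit-identical; the caller's
  RNG stream is left untouched. Checkpoints are JSON with parameters
  written at 17 significant digits, so save/load reproduces predictions
  bit for bit and carries the normalization constant with it.

The recurrent core (forward pass and backpropagation through time) is
implemented in C++ via RcppArmadillo; its gradients are tested against
finite differences at every layer.

## The synthetic cohort

The generator stands in for a treatment planning system. Per patient-organ,
each beam curve is a monotone power law
$D_v^{(b)} = A\, g_b\, v^{\gamma_b}$ with amplitude
$A \sim U(0.3, 1) \times 70$ Gy shared across the nine beams, per-beam
intensity $g_b \sim U(0.2, 1)$ and steepness $\gamma_b \sim U(0.5, 3)$. The
composite plan is a damped quadratic power mean

$$D_v^{plan} = m \Big(\sum_b u_b \,(D_v^{(b)})^2\Big)^{1/2},$$

with simplex weights $u$ and a sparing factor $m \in (0.5, 0.9)$: the
composite sits below the naive beam combination, as an optimizer that
spares the organ would put it. Smooth noise — a random cubic polynomial in
$v$ rescaled to `noise_sd_gy` (default 1 Gy) — is added before clipping and
monotonization; smooth rather than white noise so the running maximum does
not systematically inflate the curve tail. All latent draws are persisted
(`latents.csv`), so every downstream quantity can be recomputed from first
principles in tests.

Two sparing modes exist because two different questions are asked of the
generator. With `sparing = "patient"` (the default), $u$ and $m$ are drawn
per patient: realistic between-patient optimizer variability, which no
pointwise function of the beam curves can fully resolve — the right regime
for exercising the evaluation machinery. With `sparing = "fixed"`
(uniform $u$, midpoint $m$) and `noise_sd_gy = 0`, the composite is one
exact deterministic function of the nine beam curves, so the map is
learnable by construction and a prediction failure indicates an
implementation bug, not a data limit. The learnability benchmarks use the
noiseless fixed mode for exactly that reason.

What the generator does **not** emulate: anatomy, beam geometry or physics;
correlations between organs of one patient; the heavy left tail of organs
far from the target; organ-specific curve shapes. Passing tests on this
cohort demonstrate that the machinery is correct and that the model class
can learn a TPS-like composite map — they say nothing about prediction
accuracy on clinical patients, which requires clinical training data.

Cohorts split by patient, never by organ, 80/20 by default, and generation
is byte-deterministic given the seed.

## Evaluation

Per-organ accuracy and precision over test patients:
$\delta_{OAR} = \sum_P \delta_{P,OAR}/n$ and
$\sigma_{OAR} = \sqrt{\sum_P (\delta_{P,OAR}-\delta_{OAR})^2/(n-1)}$, where
$\delta_{P,OAR}$ is the per-patient EUD error. The error primitive is
**signed** (predicted minus true) by default, with the absolute variant
behind `signed = FALSE`: a field convention writes the per-patient error
with an absolute value, yet negative organ-level means are routinely
reported, so the package provides both and does not guess intent. Bilateral
organs contribute one entry per side.

Agreement between paired dose quantities uses Bland-Altman limits:
mean difference $\pm\, 1.96$ sample standard deviations, plus the fraction
of differences inside the limits. Paired comparisons use the Wilcoxon
signed-rank test: zero differences dropped, average ranks for ties, and —
below 13 informative pairs — the exact conditional null distribution
obtained by enumerating all $2^n$ sign assignments of the observed ranks
(exact even under ties). Above that, the tie-corrected normal approximation
without continuity correction. The exact/asymptotic switch at $n = 12$ is a
documented constant chosen to keep enumeration ($2^{12}$ assignments)
trivially cheap.

## Numerical choices and degenerate inputs

* Curves are compared at 1e-6 Gy absolute tolerance in tests.
* `to_quantile()` inverts the binned form by first crossing with a 1e-9
  level tolerance, guarding exact-level matches against one-ulp rounding;
  flat segments resolve to the lowest dose attaining the level.
* Empty structures, negative doses, non-monotone curves, zero predicted
  EUDs, all-zero difference vectors and unmatched patient/structure pairs
  all fail fast with named errors rather than propagating garbage.
* File I/O validates on read and reports file, row and violated invariant.
  CSV doubles use the shortest round-trippable representation; checkpoint
  parameters use 17 significant digits.

## Benchmark problem sizes

The package's own benchmark experiments (test suite and acceptance script)
run the full study design — 100 patients, 8 organ categories, 80/20 split,
pooled 18/9/1 model — on a 100-bin volume grid ($\Delta v = 0.01$) with 150
training epochs at learning rate $3\times 10^{-3}$. A 100-bin grid resolves
the synthetic curves' power-law shapes to well below the EUD tolerances of
interest while keeping a full train-predict-evaluate cycle near a minute;
$\Delta v$ remains configurable and defaults to 0.001 in the API. On the
noiseless fixed-mode cohort this setup reaches a held-out mean absolute EUD
error of ~0.3 Gy, about 91% below the mean-training-curve baseline; the
single-sample memorization check reproduces its plan curve within 0.5 Gy
pointwise.

## Known limitations

* The composite map of the synthetic cohort is pointwise in $v$; a real
  optimizer couples volume levels. A model that exploits sequence context
  can look better here than it would clinically.
* The power-mean exponent registry covers the organ categories above;
  temporal lobes have no published exponent and require a user-supplied
  $k$ or $D_{50}$.
* Constraint export is one-way: the package emits constraints and never
  solves the planning problem, so claims about plan quality end at the
  constraint table.
* Under per-patient sparing the Bayes error of the prediction problem is
  bounded away from zero by design; headline accuracy numbers from the
  noiseless mode must not be read as achievable clinical accuracy.
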