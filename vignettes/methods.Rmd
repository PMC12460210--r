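---
title: "Methods: EEG connectivity analysis of rapid bimanual visuomotor learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG connectivity analysis of rapid bimanual visuomotor learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netlearn)
```

`netlearn` implements an end-to-end analysis of short-term changes in EEG
functional connectivity during bimanual visuomotor tracking: phase-coupling
estimation with the corrected imaginary phase-locking value (ciPLV),
percolation thresholding, weighted closeness centrality, edge-wise
network-based statistics (NBS), and a principal-component regression (PCR)
linking node metrics to tracking performance. Because human recordings of
this kind are not freely redistributable, the package ships seeded synthetic
generators that reproduce the statistical structure each stage assumes, so
the full chain is testable end to end. This vignette explains the models,
the tunable parameters, the numerical choices, and what the synthetic tests
do and do not demonstrate.

## The behavioral task and its score

The tracking task asks each hand to follow a pseudorandom track. Tracks are
sums of 20 sine components,

$$g(y, t) = \sum_{i=1}^{20} A_i \sin\!\big(f_i\,(y + t/6) + \phi_i\big),$$

with amplitudes $A_i \sim U(1, 10)$, phases $\phi_i \sim U(-180^\circ,
180^\circ)$, and frequencies drawn uniformly from a difficulty-dependent
range: $U(0.01, 0.5)$ (easy), $U(0.01, 0.75)$ (moderate), $U(0.01, 1)$
(hard). Behavioral traces are sampled at 50 Hz (the display refresh rate).
Two conventions are deliberately fixed where the task description leaves
them open: phases are interpreted in degrees (the printed $\pm 180$ bounds
are degree-valued) and converted to radians inside the sum, and the track is
evaluated at a single normalized vertical coordinate ($y = 0$ by default),
because the score consumes one scalar series per hand per trial. Difficulty
varies only the frequency range; amplitude ranges are held fixed.

Per-trial performance is the Pearson correlation between cursor and track,
clipped below at zero:

$$r = \max\!\left(0,\ \mathrm{cor}(c, g)\right) \in [0, 1].$$

Correlation (rather than RMSE or absolute error) makes the score invariant
to positive affine miscalibration of the cursor and robust to occasional
large deviations. Trial scores are averaged within each subject × session ×
hand cell, and the two hands are then reduced to one *bimanual performance*
score: the first principal component of the standardized (left, right)
matrix, pooled over sessions and subjects, with the sign fixed so the
component correlates positively with the mean of the two hands. Pooling
both sessions gives 40 observations for a 20-subject cohort, which is the
sample all downstream regressions operate on.

## Connectivity estimation

Raw EEG (16 channels, 512 Hz in study-faithful runs) is band-pass filtered
0.5–100 Hz with an eighth-order Butterworth filter and notch-filtered
around 50 Hz with a fourth-order Butterworth band-stop (default width
4 Hz). Both filters run forward–backward (`signal::filtfilt`), because any
phase distortion would corrupt the phase-synchronization estimates
downstream; the zero-phase pass doubles the effective attenuation, which is
harmless here. Manual preprocessing steps that depend on human judgment or
montage geometry — ICA artifact rejection and true spline surface-Laplacian
re-referencing — are out of scope; a crude nearest-neighbour (Hjorth)
Laplacian with a fixed adjacency map is available via
`surface_laplacian_nn()` for sensitivity analyses, and is off by default.

Recordings are cut into sliding windows of 4 s with a 2 s stride;
`floor((T - 4)/2) + 1` full windows fit in $T$ seconds, ragged tails are
dropped. A 60 s trial therefore yields 29 windows and a pooled 240 s
session 119; windows can be pooled across the trials of a session before
estimation (pass a list of recordings to `sliding_windows()`), which is the
default pipeline behaviour for session-level matrices.

For each window, each channel is Hann-tapered and Fourier transformed at
the native frequency grid (0.25 Hz for 4 s windows). For channels $x, y$
and each in-band frequency bin, the unit-normalized cross-spectrum
$S_{xy}/|S_{xy}|$ is averaged over windows ($\mathbb{E}$), giving the
classical phase-locking value

$$\mathrm{PLV} = \big| \mathbb{E}[ S_{xy}/|S_{xy}| ] \big|$$

and its corrected imaginary form

$$\mathrm{ciPLV} = \frac{\big|\mathbb{E}\big[\Im(S_{xy}/|S_{xy}|)\big]\big|}
 {\sqrt{1 - \big|\mathbb{E}\big[\Re(S_{xy}/|S_{xy}|)\big]\big|^{2}}}.$$

PLV saturates for synchrony at zero phase lag, which is exactly what volume
conduction and source leakage produce; ciPLV discards the real (zero-lag)
part and renormalizes, so instantaneous synchrony scores 0 while a
consistent non-zero lag scores up to 1. Both estimators are computed per
frequency bin and then averaged across the bins of a band (theta 3–7,
alpha 7–13, beta 13–35, gamma 35–50 Hz); computing on band-filtered signals
directly would be the alternative, but bin-then-average keeps the
estimator's frequency resolution explicit and is the documented default.
When $|\mathbb{E}[\Re]| = 1$ the denominator vanishes — the phase
difference is identically zero, so the imaginary part is identically zero
too — and the bin is scored 0; the count of such bins is attached to the
result as the `"degenerate_bins"` attribute. With 16 channels the matrices
have $\binom{16}{2} = 120$ unique undirected entries.

## Graph metrics

Weak, likely spurious edges are pruned by percolation: edges are removed in
ascending weight order and the last fully connected state is kept. Tied
weights are removed as one batch, with connectivity checked after the
batch, so the result is deterministic and independent of any edge ordering.
The surviving minimum weight `tau` equals the bottleneck (minimum edge) of
the maximum spanning tree, which provides an independent oracle used in the
tests. Already-disconnected input is an error that names the components.

Node importance is weighted closeness centrality with path lengths defined
as reciprocal connectivity weights,

$$C(i) = \frac{N - 1}{\sum_{j \ne i} l(i, j)},$$

where $l(i,j)$ is the Dijkstra shortest-path distance with edge lengths
$1/w$. Multi-hop paths may legitimately beat weak direct edges and are
allowed. Closeness is computed on the percolation-thresholded graph by
default (`node_metric_table(threshold = TRUE)`); a switch computes it on
the raw matrices instead, since either ordering is defensible.

## Edge-wise testing (NBS)

Between-session differences are tested edge-wise with the network-based
statistic. Each unique edge gets a paired t statistic of the post−pre
differences across subjects; edges beyond the component-forming threshold
`T` (default 2.75) in the configured direction form a supra-threshold
graph, whose connected components are the candidate subnetworks. Family-
wise error is controlled by permutation: because the two sessions are
repeated measures on one cohort, the exchangeability-correct permutation is
a within-subject pre/post swap, i.e. a sign flip of each subject's
difference matrix. For each of `k` permutations the maximal component
extent (edge count) is recorded; a component of extent $e$ gets

$$p = \frac{1 + \#\{\text{null max extent} \ge e\}}{k + 1},$$

so the observed labeling is part of the reference and $p \ge 1/(k+1) > 0$.
When the full flip space is affordable ($2^n \le k$) it is enumerated
exactly. One-sided contrasts are run per direction (default `decrease`,
the direction of training-related connectivity reductions); `both`
thresholds $|t|$. Component size is extent only — edge count, not summed
t — matching how such subnetworks are conventionally reported. Edges whose
differences have (numerically) zero variance get statistic 0 rather than an
unbounded value, with a message.

## Linking node metrics to performance

For each band, per-node closeness is screened against bimanual performance
with partial Spearman correlations controlling for session and participant:
both variables are rank-transformed, residualized on the dummy-coded
controls (participant as $n{-}1$ fixed-effect columns), and the residuals
correlated. The p-value uses the t approximation with degrees of freedom
reduced by the number of control columns, and the 95% CI is Fisher-z based
with the same reduction — reasonable defaults, documented as such rather
than claims about any particular software's internals. Screening is
Bonferroni-corrected over the 16 nodes at $\alpha = 0.05$.

Significant nodes are typically strongly intercorrelated (variance
inflation factors from `vif()` make this visible), so the selected columns
are standardized and reduced to their first principal component — exactly
one component, sign-fixed to correlate positively with performance. Both
the component and the outcome are residualized on the controls, and the
partial OLS line

$$y' = \beta_0\, x' + \beta_1$$

is fit, reporting $R^2$. `pcr_fit()` returns a classed model with the
usual `print`, `summary`, `coef`, `predict`, `residuals` and `plot`
methods. Out-of-sample predictability comes from leave-one-out
cross-validation (`loocv_pcr()`): every fold refits the entire chain —
standardization, PCA, control models, OLS — on the remaining observations
and predicts the held-out control-residualized outcome; reported are
cross-validated $R^2 = 1 - SSE/SST$ and RMSE. Node selection is, by
default, fixed externally and *not* re-run per fold (so the CV measures
the predictability of the chosen node set); `rescreen = TRUE` also re-runs
screening inside each fold and records the per-fold selections. A held-out
participant's fixed effect is estimable because their other-session
observation remains in the training fold.

Two consequences of the sign convention are worth knowing. First, the
fitted slope is non-negative by construction, so under a true null its
magnitude is small but its sign is not symmetric around zero. Second,
cross-validated $R^2$ can be negative — that is the expected outcome for
pure-noise outcomes and is left uncorrected.

## Synthetic data: what it emulates, and what it does not

`gen_coupled_eeg()` builds multichannel signals from independent
$1/f$-shaped background noise plus, per coupled pair, a shared unit-variance
band-limited Gaussian carrier (band-pass-filtered white noise). The second
channel of a pair receives
$\text{strength}\cdot\text{rotated carrier} + \sqrt{1-\text{strength}^2}\cdot
\text{independent carrier}$, where the rotation shifts every spectral
component by `phase_lag` radians via the analytic signal. This yields
stationary, controllable narrow-band phase lags: expected ciPLV grows
monotonically with `strength` at fixed non-zero lag, reaches 1 for a
noiseless fully shared carrier, and the `phase_lag = 0` case reproduces the
volume-conduction trap (PLV ≈ 1, ciPLV ≈ 0) that motivates the corrected
estimator.

`gen_cohort()` generates paired pre/post cohorts in two modes. *Matrix
mode* draws connectivity matrices directly — per-edge baselines
$\mu_e \sim U(0.25, 0.55)$ fixed per cohort, within-subject noise of SD
`noise_sd` (default 0.05 ciPLV units), an additive session effect
`effect_size` on exactly the `effect_edges`, clipped to $[0,1]$ — and is
what makes $10^3$–$10^5$-permutation simulations affordable. *EEG mode*
synthesises raw recordings through `gen_coupled_eeg()` for full-pipeline
integration runs. With `effect_size = 0` the sessions are exchangeable
draws from one distribution, the null configuration for family-wise-error
simulation. Behavioral trials are generated alongside (baseline 0.55,
post-session improvement `session_shift = 0.16`, a realistic training
effect for this task), and an optional per-observation latent can link
behavior to connectivity: the latent displaces all edges incident to
designated `link_nodes` (floored at 0.02 so the graph stays connected for
percolation) and enters the behavior score with slope `behavior_link`,
planting a monotone node-metric/performance association whose node set is
known ground truth.

The generators emulate the *statistical* structure the analysis assumes —
narrow-band phase coupling, paired sessions, monotone brain–behavior links
— not the physics or physiology of EEG. There is no head model, no volume
conduction between channels (beyond the explicitly generated zero-lag
case), no artifacts, no non-stationarity, and no realistic spatial
correlation structure. Passing tests therefore demonstrate that the
estimators and tests recover what they claim from data satisfying their
assumptions; they say nothing about robustness to violations real
recordings would add.

## Numerical choices and degenerate inputs

- ciPLV bins with $|\mathbb{E}[\Re]| \ge 1 - 10^{-9}$ score 0 (imaginary
  part identically zero there); zero-power bins contribute 0 rather than
  NaN.
- Percolation treats tied weights as one removal batch; a spanning tree or
  an all-equal-weights graph is returned unchanged.
- Paired t statistics with difference variance below $10^{-12}$ are set to
  0 (the statistic is unbounded or undefined); the same floor applies
  inside the permutation loop.
- Zero-variance inputs to the performance score, degenerate PCA (constant
  column, zero-variance component), disconnected graphs, and missing
  subject × session × hand cells are explicit errors, not silent NAs.
- All generators restore the caller's RNG state; every stochastic stage of
  the pipeline derives its seed deterministically from the global seed.

## Problem sizes used in the test suite

The suite validates oracle equivalences on 100 random graphs per property
(percolation vs maximum-spanning-tree bottleneck, closeness vs
Floyd–Warshall, paired t vs the textbook formula); family-wise error on
200 null cohorts of 20 subjects at 1000 sign-flip permutations; NBS
sensitivity on 40 planted-effect cohorts (4-edge connected subnetwork at 5
within-subject SDs, ≥ 95% recovery); and the full screening → PCA →
regression chain on 12 seeded cohorts with planted node associations
(≥ 90% recover all planted nodes). These sizes were chosen to give stable
Monte-Carlo margins while keeping the default test run in the low minutes.

## Known limitations

- The nearest-neighbour Laplacian is a coarse stand-in for a spline surface
  Laplacian and is not used by default.
- ciPLV is bivariate and non-directional; multivariate or directed measures
  are out of scope.
- The partial-Spearman p-value and CI are approximations (t with reduced
  df; Fisher z); exact permutation inference for the screening step is not
  implemented.
- The synthetic cohort's within-subject variance is a modelling choice, not
  an estimate from any dataset; effect sizes for power checks are stated in
  units of that choice.
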