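---
title: "Methods: two-scale like-to-like connectivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-scale like-to-like connectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The question

Cortical excitatory neurons connect preferentially to neurons with
similar visual tuning ("like-to-like" wiring). A connection between two
neurons requires two things to happen: the presynaptic axon must travel
near the postsynaptic dendrite, and synapses must actually form where
they do. likewire separates selectivity at these two anatomical scales:

* **Axonal scale** -- how much dendritic cable of a partner lies within
  reach of the axon, measured as the *axon-dendrite co-travel distance*
  `Ld` (micrometres of dendrite within 5 um of the axon).
* **Synaptic scale** -- how many synapses form *per millimetre of
  co-travel*, `Nsyn / Ld`, i.e. selectivity left after conditioning on
  opportunity.

A functional-similarity effect can live at either scale; distinguishing
them is the core of the analysis. Functional similarity comes in three
flavours: in silico signal correlation (response similarity), cosine
similarity of readout feature weights ("what" tuning), and
receptive-field center distance ("where" tuning).

# Geometry: Ld, proximities, cohorts

Skeletons are piecewise-linear arbors in um. Both skeletons of a pair
are discretized so that no edge exceeds 1 um (cable length preserved
exactly); all vertex pairs within 5 um (closed ball) are found with a
uniform-grid spatial hash whose results are *exactly* those of the
brute-force all-pairs search -- the test suite asserts identity, not
approximate agreement, on random scenes. `Ld` sums the lengths of
dendritic edges with at least one endpoint in the proximal vertex set;
with 1 um edges the alternative (both endpoints) differs by at most one
micrometre per proximity boundary, and the inclusive reading is used.
Synapses attach to a proximity if they lie within 3 um of any proximal
vertex of either skeleton (the union of the proximal pair set).

Control cohorts per presynaptic neuron: *connected* partners have at
least one synapse; *ADP controls* have axon-dendrite proximity
(`Ld > 0`) but no synapse; *same-region controls* have neither, and sit
in the region of the postsynaptic targets. A candidate qualifying for
both controls is assigned to the ADP control. Functional inclusion
requires `CCmax > 0.4` and `CCabs > 0.2`; orientation analyses
additionally require `gOSI > 0.25`. Where one neuron has several
functional traces, the trace with the higher CCmax is kept (the
full-scale protocol selects by an oracle score this package does not
compute; the reliability ceiling is the closest available selector).

# The Tweedie law for Ld

Most neuron pairs never come close, so `Ld` is continuous and
non-negative with a point mass at zero. The package models it with the
Tweedie exponential-dispersion family with index `xi` in (1, 2): a
compound Poisson-Gamma law, `Ld = sum_{i=1..N} z_i` with
`N ~ Poisson(lambda)` proximity points and Gamma-distributed per-point
co-travel. For mean `mu` and dispersion `phi`,

```
lambda = mu^(2 - xi) / (phi * (2 - xi))
shape  = (2 - xi) / (xi - 1)          # per-point Gamma shape
scale  = phi * (xi - 1) * mu^(xi - 1)
```

giving `E = mu`, `Var = phi * mu^xi`, `P(Ld = 0) = exp(-lambda)`. The
sampler draws by this construction (exact zeros included). The density
is evaluated by the compound-Poisson series over the latent count with
adaptive truncation: terms are accumulated outward from the dominant
index until the next term falls below `1e-10` of the running maximum in
log space. The index `xi` is either fixed (default 1.5) or chosen by a
profile over a grid in (1, 2) with step 0.05, with the dispersion
profiled out by one-dimensional optimization at each grid point; grid
profiling was preferred to a joint optimization because the joint
surface is nearly flat in `xi` at desk-scale n.

# Regression models

All three models share the fixed-effect structure
`~ similarity * projection` with a grouping intercept per (presynaptic
neuron x projection type):

* `fit_ld_model` -- Tweedie, log link, response `Ld` (zeros included);
* `fit_nsyn_model` -- Poisson, response `Nsyn` (mixes both scales);
* `fit_density_model` -- Poisson with `log(Ld)` in millimetres as a
  fixed offset, restricted to `Ld > 0`: its slopes are the
  synaptic-scale coefficients (synapses per mm of co-travel).

Two estimation backends are provided and agree within one standard
error on synthetic data. The `"glmm"` backend fits the random-intercept
model by Laplace-approximated maximum likelihood via glmmTMB, which
also estimates `xi`. The `"glm"` backend is an exact fixed-effects
fallback with one intercept per group; groups whose responses are all
zero are removed first -- their intercept diverges to minus infinity,
their likelihood contribution tends to one, and they carry no
information about the slopes, so dropping them is exact profiling and
removes an IRLS instability caused by extreme offsets in sparse groups.
If the IRLS still diverges, the fit restarts from the marginal rate.
The fast fallback is the default in replicate studies; coverage of the
95% Wald intervals is checked by simulation (the acceptance suite
requires at least 90 of 100 replicates to cover the planted slope).

*Conditional like-to-like slopes* per projection are
`beta_1 + beta_3[projection]`, computed from a contrast vector with a
delta-method standard error from the fixed-effect covariance; the test
suite verifies these against `emmeans::emtrends` to machine precision.
P-values are Wald, adjusted by Benjamini-Hochberg within the family of
projections reported for one fit. For the synaptic scale only
projection types with more than 30 synapses, more than 5 presynaptic
neurons, and no presynaptic neuron holding more than half the synapses
are reported.

A Nakagawa-style pseudo-R^2 is reported in marginal and conditional
flavours, with the observation-level variance on the latent log scale
taken from the lognormal approximation: `log(1 + 1/mu)` for Poisson and
`log(1 + phi * mu^(xi - 2))` for Tweedie, at the mean fitted response.

The paired cohort tests compare, across presynaptic neurons with more
than 10 connected targets, the mean similarity to connected vs ADP vs
same-region partners (paired t-tests, BH-adjusted, alpha 0.05). The
two-step residual regression first removes the Ld-explained part of
similarity by ordinary least squares, then regresses the residuals on
synapse count and mean log10 cleft volume -- anatomy beyond proximity.

The visualization summaries subtract each presynaptic neuron's mean
similarity and mean outcome before binning (removing presyn-level
offsets), then report per-bin means with a bootstrap SD over 1000 pair
resamples, recomputing the presyn means inside every resample. Bins
need more than 10 pairs and more than 10 distinct presynaptic neurons.
The `Ld` variant uses unconnected pairs; the `Nsyn/Ld` variant uses all
pairs with positive co-travel, with presyn means taken over the same
eligible set (the narrower reading of the protocol would centre on a
different set than it bins, which is not well defined for presynaptic
neurons without unconnected positive-Ld pairs).

# Functional similarity metrics

Signal correlation averages responses in 500 ms non-overlapping bins
per trial, concatenates trials, and takes the Pearson correlation.
`CCmax` implements the reliability ceiling
`sqrt((N Var(ybar) - mean Var(y)) / ((N - 1) Var(ybar)))`; note the
estimator carries an `N/(N-1)` factor relative to the population value
`sqrt(s^2 / (s^2 + sigma^2/N))`, so sampling fluctuation can push it
slightly above one -- the value is clipped to [0, 1], which is harmless
because only its ordering against the 0.4 threshold is used. `CCabs` is
the Pearson correlation of a prediction with the trial-averaged
response. Feature similarity is the cosine of the readout weight
vectors. RF center distance is the angle between the two eye-to-point
rays with the eye 15 cm from, and normal to, the monitor center.

Orientation tuning uses the 16-direction curve. `gOSI` is the vector
sum `|sum R e^{2i theta}| / sum R`; `OSI` contrasts the preferred and
orthogonal orientations after pooling opposite directions, with the
preferred orientation taken from the fitted curve when available
(the estimator of the preferred-orientation response is otherwise
unspecified). The bimodal von Mises curve

```
f(theta) = A/(2 pi I0(k)) * (p e^{k cos(theta - mu)} +
                             (1-p) e^{-k cos(theta - mu)}) + b
```

is fitted by least squares with 8 equally spaced starting values of
`mu`, box constraints `kappa` in [0, 20] and `p` in [0, 1], and an
amplitude parameter (the curves being fitted are response averages, not
densities). The Bessel factor is evaluated with the exponentially
scaled `besselI` so large `kappa` proposals cannot overflow. Fits with
`kappa` near zero or negligible modulation are flagged degenerate
(`mu` is unidentifiable on a flat curve). On noiseless curves with
`kappa >= 1` the preferred orientation is recovered to within one
degree.

STA receptive fields on sparse-noise protocols estimate on- and
off-maps as response-weighted dot indicators (mean-removed), combined
by pixelwise maximum, and fitted with a 2D Gaussian; fits with
r-squared above 0.5 count as well fit. The STA-prediction correlation
that gates "well-characterized" (threshold 0.2) is computed by 2-fold
cross-validation -- maps from half the frames predict the other half --
because the in-sample correlation is inflated by shared noise at desk
scale (about 0.16 for a pure-noise neuron on 4000 frames), which would
defeat the threshold.

# Common input: rho and rho-prime

For presynaptic neuron `i` with synapse counts `Nsyn_ij` to its
candidate partners and pairwise similarities `Sim_jk` among those
partners,

```
rho(i) = sum_{j != k} Sim_jk Nsyn_ij Nsyn_ik /
         sum_{j != k} Nsyn_ij Nsyn_ik
```

is the synapse-weighted mean similarity of the postsynaptic cohort,
defined when at least two partners are connected. Its pairwise
expectation `rho'(i)` replaces the counts with predictions from a
single joint Poisson model containing all three similarities,
projection type, and all similarity-by-projection interactions; the
candidate set for `rho'` is all functionally included candidates of
`i`, the computable analog of "any two neurons in the volume". The
partner-pair similarity defaults to signal correlation (configurable);
in the synthetic pipeline the feature cosine is used, which is the
deterministic in silico signal correlation of the factor-model
generator. `compare_rho` is a paired t-test of `rho` against `rho'`
across presynaptic neurons: a positive mean difference is common-input
structure beyond any pairwise rule.

**Design choice -- how higher-order structure is planted.** The obvious
mechanism (boost the synapse rate when presyn and postsyn share a
feature-cluster label) turns out to be almost entirely *explainable* by
the pairwise rule: the shared label is strongly collinear with
presyn-target similarity, the joint model absorbs the boost, and
`rho - rho'` stays near zero. The generator therefore assigns each
presynaptic neuron a *target community* drawn independently of its own
tuning and boosts the log synapse rate onto members of that community.
This leaves the marginal pairwise rule untouched while making the
targets of one presynaptic neuron mutually similar -- structure no
pairwise model can reproduce. A consequence worth knowing: *negative*
boosts (ensemble avoidance) also produce a positive `rho - rho'`,
because excluding a coherent community likewise concentrates the
realized target set relative to the smooth pairwise prediction. `rho`
measures concentration, not the sign of the ensemble preference.

# The recurrent-network experiment

A vanilla RNN -- trainable linear input map, `tanh` recurrent layer
driven by the static input at every step, linear readout of the final
hidden state -- is trained with categorical cross-entropy and Adam
(full backpropagation through time, hand-written, deterministic under
the seed). The full-scale configuration in the literature uses 1000
hidden units, 20 timesteps and MNIST; the package's study condition is
a download-free desk-scale analog: 8 Gaussian-blob classes on 28x28
images (blob sd 2.5, centre jitter 1 px, pixel noise sd 0.2), 64
hidden units, 12 timesteps, 12 epochs, batch 128.

One deliberate design choice matters here: the images are scaled by a
gain of 0.03. With a strong static drive, a 64-unit network solves the
blob task through the input map alone and ablating recurrent weights
changes nothing -- the experiment is vacuous. The weak drive keeps the
hidden units in their sensitive range so the recurrent amplification
must carry the computation (about half the accuracy is lost when the
recurrent weights are removed), reproducing the regime in which the
full-scale experiment operates.

A unit's "response" is its final-timestep activation per stimulus (what
the readout sees); the dynamics are deterministic, so signal
correlation is response correlation over the held-out stimulus set.
Directed pairs with weight above 0.01 count as connected (the
threshold's percentile in the weight distribution is reported).
Ablation candidates need weight above 0.01 *and* signal correlation
above 0.2; ablated weights are set to zero permanently and cumulative
along the ablation schedule. Random-control ablations are drawn from
the remaining connected weights, stratified into deciles of absolute
weight matched to the like-to-like sample, so the two conditions remove
the same strength distribution (verified by a Kolmogorov-Smirnov check
in the tests). The post-post analysis reuses the rho machinery on the
thresholded graph with one synapse per connected pair.

# The synthetic generator and what it does (not) show

The generator emulates: areas laid out along the cortical sheet with
AL/RL pooled as HVA; deterministic retinotopy within each area (degrees
per um, so a zero gradient collapses all RF centers exactly); feature
vectors from a mixture of unit-norm cluster directions (the clusters
double as community labels); trial-structured responses from a low-rank
factor model whose loadings *are* the feature weights -- signal
correlation and feature cosine are coupled by construction, with a
tunable estimation-noise decoupling for the pair-table column;
direction-tuning blocks from each neuron's planted von Mises curve; Ld
from the compound Poisson-Gamma law with a log-linear similarity rule
and presyn random intercepts; synapse counts Poisson with a log-Ld
offset and their own similarity rule; log-normal cleft volumes with a
similarity-dependent mean.

Defaults (the package's study conditions): 40 presynaptic neurons, 2000
candidates with 50 sampled per presyn (2000 pairs -- replicate studies
at this size keep 100-replicate coverage runs within minutes on one
CPU), feature dimension 64 (512 available by configuration), Tweedie
`xi = 1.5`, `phi = 4`, baseline `E[Ld] = 5 um`, baseline synapse rate
40 per mm, planted feature-similarity slopes 0.8 (axonal) and 0.6
(synaptic), presyn intercept sd 0.3, 10 trials of 30 s at 10 Hz. The
planted higher-order condition uses a boost of 2 on the log rate
(about a 7-fold rate increase onto the target ensemble), chosen as a
strong, unambiguous clustering level for desk-scale power.

What passing tests show: the estimators recover exactly the structure
the generator plants, with calibrated intervals, and the pipeline's
dissociation logic behaves correctly when the truth is known. What they
do not show: anything about real tissue. Real skeletons are not random
walks or geometric primitives; real Ld need not be exactly Tweedie (the
generator treats the assumed law as exact); real signal correlations
are not a noisy copy of a feature cosine; segmentation and proofreading
errors, which dominate practical connectomics effort, are not
simulated.

# Numerical choices and limitations

* Distance comparisons use closed balls (`<=`), matching "within".
* Proximities are kept per pair as one merged object, not per contact
  site; nothing downstream needs per-site resolution.
* Ties in the orientation grid and in `cut` binning follow R's
  defaults; bin edges are nudged by 1e-9 so the minimum lands in the
  first bin; a degenerate (zero-spread) delta-similarity axis gets one
  unit-width bin.
* The bootstrap resamples pairs, not presynaptic neurons, and is
  seed-controlled by the caller.
* Random effects are intercepts only; random slopes are out of scope.
* The Tweedie series density is O(terms) per observation in R; profile
  grids at desk scale take seconds, and the GLMM backend is preferred
  when `xi` itself is of interest.
* `compare_rho` uses a paired t-test across presynaptic neurons; the
  per-presyn differences are treated as exchangeable, which the
  replicate calibration supports at the default n.
* CSV (plus SWC and YAML sidecars) is the on-disk interchange; tables
  of millions of pairs would want a binary columnar format instead.
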