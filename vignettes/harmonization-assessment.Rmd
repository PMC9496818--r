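---
title: "Assessing connectome harmonization on the Shannon–Fisher plane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing connectome harmonization on the Shannon–Fisher plane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connharmony)
```

# The problem

Pooling resting-state fMRI connectomes across acquisition sites mixes
biological signal with scanner- and protocol-dependent measurement effects.
Harmonization methods claim to remove the latter; this package implements an
assessment workflow that checks the claim on the data themselves. Each
subject's connectome is reduced to two global coordinates — normalized
network Shannon entropy and normalized network Fisher information — and the
acquisition site is tested as a predictor of each coordinate with the
Kruskal–Wallis test. If harmonization worked, the site should carry no
information about where a subject falls on this plane.

This vignette records the models, the parameter choices and their defaults,
the numerical decisions, and what the synthetic validation does and does not
establish.

# From BOLD series to a connectome

For each subject we take an ROI time-series matrix (T timepoints × N
regions, repetition time `tr` seconds) and compute the phase-interaction
matrix:

1. Band-pass 0.04–0.07 Hz. Only the band edges are scientifically
   meaningful; the filter realization is our choice: a Butterworth of order
   2 applied forward–backward (`signal::filtfilt`), i.e. zero-phase.
   Zero-phase filtering matters because any filter delay would contaminate
   the instantaneous phases extracted next. The effective attenuation is the
   squared magnitude response; the test suite checks measured tone gains
   against the transfer function evaluated analytically.
2. Instantaneous phase per region via the Hilbert analytic signal
   (FFT construction). Phases of a narrow-band signal are well defined;
   applying this to unfiltered data is not prevented but is documented as
   unsupported.
3. Edge weight = time average of cos(φ_i(t) − φ_j(t)), giving ⟨P⟩ with unit
   diagonal and entries in [−1, 1]. The average runs over the T available
   samples; subjects may have different T, and no resampling is done.
   Hilbert phases are unreliable near the series ends, so an optional
   `trim` parameter (default 0) excludes the first and last k samples from
   the average; tests that assert exact values trim 20–50 samples of their
   2048-sample tones.

Pearson correlation matrices (`pearson_connectivity()`, or matrices
supplied directly) are accepted as an alternative connectome kind for
datasets distributed in that form.

Edge features are the strict upper triangle in row-major order
(`vectorize_matrix()`); the layout is arbitrary for harmonization, which is
per-feature, but node order matters to the Fisher measure, so ROI order is
preserved exactly as given in the input files and the round trip
(`devectorize()`) is bitwise lossless.

# Harmonization models

All three harmonizers operate on the cohort table: J subjects × V =
N(N−1)/2 edge features plus phenotypes (site, age, sex, diagnosis).

**ComBat** (`fit_combat()` / `apply_combat()`) assumes
y_tjv = α_v + X_tj β_v + γ_tv + δ_tv ε_tjv and removes the shrunken site
location and scale effects while restoring covariate effects. Flavor
choices, all following the standard parametric empirical-Bayes variant:

* Site effects are identified by constraining their sample-size-weighted sum
  to zero, i.e. α_v is the weighted mean of the per-site intercepts.
* Standardized residuals use the pooled variance σ̂²_v (denominator J).
* Hyperpriors: normal on γ (moment-matched mean/variance across features)
  and inverse-gamma on δ² (moment-matched shape/scale); conditional
  posterior means are iterated until the largest parameter change is below
  `eb_tol = 1e-4`, capped at 100 iterations.
* `eb = FALSE` switches off shrinkage, giving the exact per-site
  location/scale adjustment. Two algebraic identities hold only in that
  form and are tested there: equality with a brute-force per-feature
  implementation, and exact preservation of pooled feature means under an
  intercept-only design. With shrinkage these hold approximately; the
  residual perturbation in a null cohort is roughly 0.2 × the residual SD
  (scale-estimation noise times the most extreme standardized residuals),
  which the null-identity test exercises at noise SD 0.05.
* The test suite also cross-checks the full EB fit against an independent
  reference implementation (`sva::ComBat`) to ~1e−4.

δ is identified only relative to the pooled variance (the weighted mean of
δ² is 1 by construction), so recovery tests compare estimates after undoing
that normalization with the generating values.

**CovBat** (`covbat()`) reuses the ComBat fit (intercepts and covariate
effects are not re-estimated — the reconstruction adds back the ComBat
α̂ + Xβ̂), forms zero-mean ComBat residuals, and corrects their leading
principal-component scores: for components k ≤ K each site's score mean is
removed and its score scale is divided out relative to the pooled scale
(plain per-site mean/SD, no empirical Bayes on scores; the pooled target is
mean 0 and the pooled per-component variance). K is the smallest component
count capturing `var_frac` (default 0.9) of the residual variance. PCA is
computed by thin SVD of the J × V residual matrix, which is cheap in the
J ≪ V regime typical for connectomes.

A note on what "covariance site effects" CovBat can fix: the correction
acts on per-component means and variances in the pooled principal basis.
A site difference realized as a small-angle rotation of one site's
covariance is invisible to it — the two sites sit symmetrically about the
pooled axes with identical per-component moments — and a difference realized
as an eigenvalue permutation creates near-ties in the pooled spectrum, so
the sample principal axes mix and the difference leaks into off-diagonal
score covariance that the model does not touch. The covariance-validation
harness therefore constructs the case the model does cover: both sites share
a random eigenbasis with a well-separated pooled spectrum (8·0.5^k,
q = 6 structured components over V = 45 features) and per-component
variances shifted ±40% in opposite directions at the two sites. There CovBat
removes 64–79% of the Frobenius distance between site covariances at
100 subjects/site, versus 26–41% for ComBat alone.

**Traveling-subject** (`fit_traveling_subject()` /
`apply_traveling_subject()`) models y_jv = x^m m_v + x^d d_v + x^p p_v +
const_v + e on a companion dataset in which the same participants are
scanned at every site. Measurement bias m (per site × feature), subject
factors p, and — only when several diagnosis levels are present, which a
healthy-traveler design does not have — disorder factors d, are one-hot
encoded with sum-to-zero constraints on each block and estimated by ridge
regression (`lambda_l2`, default 0.1; the constant is unpenalized). The
sampling-bias term of the general model is confounded with m inside a
single dataset and is not estimated here — that is precisely why the
companion dataset is required, and `apply` refuses cohorts containing sites
the model never saw. Harmonization subtracts m̂ from each subject's
features and nothing else, so the operation is a fixed per-site translation:
deliberately non-idempotent, and exactly invertible.

Harmonized values are *not* clipped to [−1, 1]; downstream binarization is
threshold-based and tolerant of small excursions.

# Network information measures

Connectomes are binarized with a strict inequality (edge iff weight >
threshold; default 0.5, diagonal forced to 0). Per node, the single-step
random-walk distribution is p_{i→j} = a_ij / k_i over the N−1 other nodes in
ascending node order. Then:

* nodal entropy S = −Σ p ln p (0·ln 0 = 0), normalized by ln(N−1);
* nodal Fisher information = ½ Σ over the N−2 consecutive pairs of
  (√p_next − √p)²;
* network H and F are the means over all N nodes.

Numerical and convention decisions:

* **Isolated nodes** (k_i = 0) leave both measures undefined; we assign
  H(i) = 0 and F(i) = 1, the maximally ordered convention consistent with
  the plane's limits (empty graph → (0, 1), complete graph → (1, 0)).
* **Fisher ordering**: the measure depends on the order in which the
  distribution is traversed. We fix ascending node order (skipping i).
  Reordering (e.g. sorting the probabilities) changes F by small amounts;
  natural ROI order is the convention here, which is also why ROI order is
  preserved end to end.
* **Fisher normalization**: the ½ prefactor is taken as the definition even
  though a single boundary jump then scores ½ rather than 1; F ≤ 1 still
  holds (two unit jumps, as for a mid-list singleton, reach exactly 1).
* N ≥ 3 is required (ln(N−1) degenerates at N = 2).

The implementation is verified against a deliberately naive brute-force
loop evaluation on several hundred random graphs with N ≤ 6, plus
hand-derived anchors (star on 4 nodes → (0.25, 0.375); path on 3 nodes →
(1/3, 1/3); complete graphs → (1, 0)).

# Quantifying residual site effects

`kruskal_wallis()` wraps `stats::kruskal.test` (rank-based, tie correction
always applied — H and F tie exactly for identical graphs; chi-square
p-value with sites − 1 degrees of freedom). p-values are reported as
p′ = −log₁₀ p; the base is fixed by the conventional 1.301 ↔ 0.05
correspondence. No multiplicity correction is applied across the report by
default, matching how such tables are conventionally presented; a
Bonferroni option exists in `assess_cohort()`. Type-I calibration of the
test at the sizes used here is verified by simulation (2000 null draws,
nominal 0.05 held within ±0.02).

`threshold_sweep()` re-runs the assessment over thresholds 0.2–0.8: the
binarization threshold is a nuisance parameter and verdicts are expected to
be stable across that range, which the acceptance suite checks on synthetic
cohorts.

# The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the harmonization
models assume, with every parameter seeded and returned as ground truth:

* Edge features are built on the Fisher-z scale: a base connectome
  (per-edge levels ~ N(0.6, 0.5²), so tanh-mapped weights straddle the
  whole binarization sweep range), plus covariate effects (age slope
  0.002/year, sex shift 0.05, diagnosis shift 0.15 on a contiguous 10% edge
  block so covariate protection is measurable), a per-subject scalar factor
  (SD 0.1), additive site effects, and site-scaled noise (SD 0.25); by
  default the sum is mapped through tanh into (−1, 1) so features look like
  phase-interaction values. The tanh mapping is a generator convention —
  harmonization still operates on the mapped values directly, which is also
  why ComBat removes the (now mildly nonlinear) injected effects only
  approximately; the `link = "identity"` mode exists for studying the
  estimators under their own linear assumptions.
* Additive site effects γ_tv combine a site-level shift (SD =
  `site_additive_sd`, default 0.2) with per-edge jitter at half that SD,
  centered across sites per feature. The shared site-level component is what
  makes the effect visible on the plane coordinates: a pure zero-mean
  per-edge scramble moves individual edges across the binarization
  threshold in both directions and largely cancels in H and F. The
  multiplicative effect is a per-site noise scale drawn log-uniformly from
  `site_multiplicative_range` (default 0.8–1.25).
* `generate_traveling_companion()` scans `n_travelers` healthy participants
  once at every site, sharing the cohort's measurement biases (m_true =
  γ_true) with per-traveler factors held constant across sites — the
  structure a 9-traveler × 12-site reference design has.
* `generate_time_series_cohort()` emits narrow-band sinusoids whose
  pairwise phase lags encode a target connectome (an edge with constant lag
  d averages to cos d), with per-site lag perturbations and white noise, to
  exercise the full filter → phase → ⟨P⟩ pipeline.

**Study conditions used in validation.** The end-to-end acceptance harness
uses the generator defaults — 4 sites × 40 subjects, N = 16 ROIs (V = 120
edges) — over 50 seeded replicates; parameter-recovery harnesses use 2 sites
× 50–100 subjects (ComBat), 9 travelers × 12 sites (traveling-subject), and
the covariance construction above (CovBat). These sizes keep the whole
suite within a few minutes on one CPU while leaving comfortable
signal-to-noise margins; they are the package's standard validation
conditions, stated here so results are interpretable, not tuned per test
run. The mis-specified traveling variant in the end-to-end harness fits the
companion with an extremely large ridge penalty (λ = 10⁶), collapsing m̂
toward zero — a deliberate failure mode that leaves the original site
signature in place and mirrors how an under-corrected dataset looks in this
assessment.

# What the synthetic validation shows — and what it does not

Passing tests establish that each estimator recovers the effects it models
(additive offsets to ±0.05, scales to 15%, measurement bias to RMSE < 0.02),
that the information measures are exactly the defined quantities, that the
full chain detects injected site effects (p′ ≫ 1.301 before harmonization)
and stops detecting them after ComBat/CovBat in ≥ 90% of replicates, stably
across thresholds 0.2–0.8, and that the Kruskal–Wallis criterion is
calibrated.

They do not establish performance on real data: the generator draws
Gaussian edge noise with at most a rank-q covariance structure, makes site
effects exactly additive/multiplicative on a known scale, has no head
motion, no outlier subjects, no demographic confounding between site and
diagnosis, and no hemodynamic forward model behind its sinusoidal
time-series mode. On real cohorts, demographic heterogeneity across sites
in particular is indistinguishable from a site effect for this assessment
and cannot be removed by any of the three harmonizers.

# Known limitations

* Binarization discards weight information; threshold-free (weighted-graph)
  generalizations of the plane are out of scope.
* Windowed/dynamic connectivity is not supported — time is collapsed
  immediately by the ⟨P⟩ average.
* The Fisher measure's dependence on node order is a convention, not a
  graph invariant.
* CovBat corrects per-component score moments only; covariance differences
  orthogonal to that family (rotations, axis permutations with degenerate
  pooled spectra) are provably outside its reach, as discussed above.
* ComBat/CovBat assume every site is represented at fit time; there is no
  out-of-site extrapolation.
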