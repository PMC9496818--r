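# connharmony

Information-theoretic assessment of multi-site connectome harmonization.

Resting-state fMRI studies routinely pool subjects scanned at different
acquisition sites. Scanner hardware, sequence settings and calibration leave
non-biological "site effects" in the derived functional connectomes, and a
harmonization step (ComBat, CovBat, or a traveling-subject measurement-bias
model) is applied before any group analysis. The question this package
answers is the follow-up one: **did harmonization actually work?** It does so
by collapsing each subject's connectome to two information-theoretic
coordinates and testing whether the acquisition site still predicts them.

The toolkit is aimed at neuroimaging methodologists and anyone curating a
multi-site functional-connectivity dataset. It works from plain-text ROI
time-series tables (or precomputed correlation matrices) plus a phenotype
table; no imaging formats are required.

## The method

1. **Phase-interaction connectome.** Each ROI's BOLD series is band-passed
   (0.04–0.07 Hz, zero-phase Butterworth), instantaneous phases
   φ<sub>i</sub>(t) are extracted with the Hilbert transform, and the edge
   weight is the time-averaged phase coherence

   ⟨P⟩<sub>ij</sub> = (1/T) Σ<sub>t</sub> cos(φ<sub>i</sub>(t) − φ<sub>j</sub>(t)),

   which is 1 for in-phase, 0 for orthogonal and −1 for anti-phase regions.
   Pearson correlation matrices are supported as an alternative connectome.

2. **Harmonization.** The subjects × edges feature table
   y<sub>tjv</sub> = α<sub>v</sub> + X<sub>tj</sub>β<sub>v</sub> + γ<sub>tv</sub> + δ<sub>tv</sub>ε<sub>tjv</sub>
   is adjusted by parametric empirical-Bayes ComBat (shrunken per-site
   location γ\* and scale δ\* effects removed, protected covariates — age,
   sex, diagnosis — restored), by CovBat (ComBat plus per-site
   center/scale correction of the leading principal-component scores of the
   residuals, aligning within-site covariance), or by subtracting
   measurement biases m̂<sub>v</sub> estimated by ridge regression from a
   traveling-subject companion dataset (the same participants scanned at
   every site).

3. **Shannon–Fisher plane.** Each connectome is binarized (edge iff weight
   > 0.5 by default), turned into per-node random-walk distributions
   p<sub>i→j</sub> = a<sub>ij</sub>/k<sub>i</sub>, and summarized by the
   normalized network Shannon entropy H (mean nodal entropy / ln(N−1); 1
   for a complete graph) and the normalized network Fisher information F
   (mean of ½ Σ (√p<sub>next</sub> − √p)²; 0 for a complete graph, 1 for an
   empty one). Every subject becomes a point (H, F) in the unit square.

4. **Site-effect quantification.** The Kruskal–Wallis test is run across
   sites on the H values (measure SE) and on the F values (measure FI),
   reported as p′ = −log₁₀(p). Residual site effects show as p′ > 1.301
   (p < 0.05); successful harmonization leaves both measures below it.

A fully seeded simulator generates multi-site cohorts with known additive
and multiplicative site effects, covariate effects and a traveling-subject
companion, so the whole chain is testable without any external data.

## Worked example

```r
library(connharmony)

cfg <- sim_config(n_sites = 4, subjects_per_site = 40, n_rois = 16, seed = 42)
cohort <- generate_cohort(cfg)$cohort
cohort
#> <conn_cohort> 160 subjects x 120 edge features (N = 16 ROIs), 4 site(s)

combat_fit <- fit_combat(cohort)          # protects age, sex, diagnosis
combat_fit
#> <combat_model> 4 sites x 120 features; covariates: age, sex, diagnosis;
#> EB converged in 4 iteration(s)
harmonized <- apply_combat(combat_fit, cohort)

pts_raw  <- shannon_fisher_points(cohort,     threshold = 0.5)
pts_harm <- shannon_fisher_points(harmonized, threshold = 0.5)
head(pts_raw, 3)
#> # A tibble: 3 x 4
#>   subject_id site       H     F
#> 1 sub0001    site01 0.675 0.559
#> 2 sub0002    site01 0.659 0.605
#> 3 sub0003    site01 0.803 0.412

dplyr::bind_rows(assess_cohort(pts_raw,  "unharmonized"),
                 assess_cohort(pts_harm, "combat"))
#>   variant      measure h_statistic  p_value p_prime significant
#> 1 unharmonized SE           80.1   2.98e-17 16.5    TRUE
#> 2 unharmonized FI           74.8   4.00e-16 15.4    TRUE
#> 3 combat       SE            0.728 8.67e- 1  0.0621 FALSE
#> 4 combat       FI            0.601 8.96e- 1  0.0476 FALSE

plot_plane(pts_raw)     # ggplot scatter of (H, F) colored by site
```

Reading: before harmonization the site predicts both plane coordinates
overwhelmingly (p′ ≈ 16, far above the 1.301 significance cut); after
ComBat both drop to p′ < 0.1 — no detectable residual site effect. The
`covbat()` and `fit_traveling_subject()`/`apply_traveling_subject()`
variants slot into the same two lines, and `threshold_sweep()` repeats the
verdicts over binarization thresholds 0.2–0.8.

A command-line wrapper over the same functions lives at
`inst/cli/connharmony.R` (subcommands `simulate`, `connectivity`,
`assess`).

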