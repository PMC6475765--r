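# taulong

ROI-level statistical machinery for longitudinal tau-PET and structural
MRI studies of atypical Alzheimer's disease (logopenic progressive
aphasia, LPA, and posterior cortical atrophy, PCA), built for
neuroimaging statisticians who need the full analysis chain — biomarker
quantification, a Bayesian hierarchical model of regional annualized
change, lobe-wise posterior comparisons, and multimodal association
analyses — as tested, reusable code. Raw scans from such studies are
rarely shareable, so the package ships a synthetic-cohort generator that
draws data from the model's own generative form with recorded ground
truth: every stage can be exercised, and its calibration measured,
without any imaging data.

## The model

Quantification turns images or ROI tables into analysis quantities: the
tissue-masked median uptake of each of 84 atlas ROIs is divided by the
median uptake of cerebellar crus grey matter to give SUVR; annualized
change is (follow-up − baseline) / (interval in days / 365.25);
log-Jacobian determinants of a longitudinal deformation are annualized
by × 365.25 / days; grey-matter volumes are normalized by total
intracranial volume; amyloid positivity uses a global SUVR cut-point of
1.42 (boundary inclusive).

The core model predicts the annualized change y<sub>ir</sub> of subject
*i* in ROI *r* with group-specific regional random intercepts and
decade-scaled baseline-age effects:

    y_ir = alpha_{g(i),r} + beta_{g(i),r} * (age_i - 65)/10 + eps_ir

    alpha_{g,.} ~ Normal(mu_a[g], tau_a[g])     (regional intercepts)
    beta_{g,.}  ~ Normal(mu_b[g], tau_b[g])     (regional decade effects)
    eps_ir      ~ Normal(0, sigma)

with standard-Normal priors on the hypermeans and half-standard-Normal
priors on all scales. A purpose-built Gibbs sampler (conjugate normal
block updates, slice updates for the non-conjugate scales; C++ core)
draws the posterior over many independent, overdispersed chains;
convergence is monitored with the Gelman–Rubin statistic. Atypical-AD
estimates are the sample-size-weighted average of the LPA and PCA
effects (18:12), contrasted against the cognitively unimpaired group at
the age center. Lobe-wise summaries reduce the 84 regional contrasts to
8 lobes and report, for every lobe pair, the posterior probability that
one lobe changes faster than the other.

Association analyses relate baseline measures to rates of change in the
patients: partial Pearson correlation matrices (adjusted for baseline
age) with max-statistic permutation family-wise-error correction, and
sparse canonical correlation analysis via penalized matrix decomposition
with a lasso penalty of 0.2 on both datasets.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
synthetic cohort (18 LPA / 12 PCA / 45 controls, 84 ROIs) and write
their tables under `results/`. Running them in order prints, among other
things:

```
$ Rscript analysis/01_simulate_cohort.R
<cohort_table> 75 subjects (CU=45, LPA=18, PCA=12) x 84 ROIs, modality tau
age range 53.3-79.6 years; scan interval 348-405 days
true mean annualized tau change: LPA 0.078, PCA 0.070, CU 0.010 SUVR/yr

$ Rscript analysis/03_fit_change_model.R
tau: 4000 retained draws, max hyper R-hat 1.001
largest pooled contrasts vs controls (median [95% CI]):
  ROI 80: +0.136 [+0.113, +0.159]
  ROI 49: +0.129 [+0.107, +0.152]
  ROI 33: +0.121 [+0.098, +0.143]
```

The fitted contrasts are the annualized tau accumulation of the pooled
atypical-AD group relative to controls: ROIs whose generating intercept
gap was around 0.06–0.13 SUVR/yr are recovered with tight 95% intervals
and R-hat at 1.00. `analysis/04_lobe_comparison.R` prints the 8×8
lobe-comparison matrix (entries clipped to `<0.001` / `>0.999` for
display; each off-diagonal pair sums to exactly 1), and
`analysis/05_associations.R` reports, per pairing, the largest partial
correlation, the count of FWE-significant entries and the first sparse
canonical correlation with its nonzero-weight counts.

The same stages are available programmatically, e.g.:

```r
library(taulong)
coh  <- generate_cohort(simulation_params("tau", seed = 1))
fit  <- fit_mcmc(hier_spec("desk", seed = 2),
                 build_model_input(coh, compute_annualized_changes(coh)))
ctr  <- relative_to_controls(pooled_atypical_effect(fit, 18, 12), fit)
head(summarize_regions(ctr), 3)
comparison_matrix(lobe_average(ctr))
```

or end to end via `run_pipeline(pipeline_config("runs/demo", seed = 1))`.

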