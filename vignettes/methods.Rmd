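---
title: "Methods: hierarchical modelling of regional biomarker change"
author: "taulong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical modelling of regional biomarker change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its statistical methods:
the model and its assumptions, the quantification conventions, what the
synthetic-data generator does and does not emulate, the numerical
choices inside the sampler and the association engine, and the known
limitations. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Scientific setting

Atypical Alzheimer's disease — the language-predominant (logopenic
progressive aphasia, LPA) and visual-predominant (posterior cortical
atrophy, PCA) variants — shows regionally heterogeneous tau accumulation
and grey-matter atrophy. Two-timepoint tau-PET and structural MRI give,
per subject and atlas ROI, an annualized rate of change for each
modality. The statistical questions the package answers are: how fast
does each region change in patients relative to cognitively unimpaired
(CU) controls; how does baseline age modulate those rates; which lobes
change faster than which; and how do baseline measures relate to
subsequent rates of change across modalities.

## Quantification conventions

* **ROI summary**: the median uptake over an ROI's voxels whose
  grey-matter probability exceeds 0.5. The median resists the outlying
  values of mostly-non-tissue voxels; the mask threshold is a package
  convention (only "masking on the segmentation" is standard practice)
  and is configurable.
* **SUVR**: ROI median divided by the cerebellar crus grey-matter
  median; the reference region has SUVR 1 identically.
* **Annualization**: one year is fixed at 365.25 days everywhere — the
  convention the log-Jacobian scaling states explicitly — so SUVR
  changes and log-Jacobians are directly comparable per year.
* **Amyloid positivity**: global SUVR ≥ 1.42. The boundary is treated
  as inclusive; published cut-point procedures rarely state strictness,
  and the choice only matters for values exactly at the cut-point.
* **Volumes**: ROI volumes are normalized by total intracranial volume.
  Annualized log-Jacobians (≈ % volume change per year for small
  deformations) are consumed as given; estimating deformations from
  images is out of scope.

## The hierarchical change model

For subject $i$ (group $g(i)$, baseline age $a_i$) and ROI $r$:

$$y_{ir} = \alpha_{g(i),r} + \beta_{g(i),r}\, x_i + \varepsilon_{ir},
\qquad x_i = \frac{a_i - 65}{10}, \qquad
\varepsilon_{ir} \sim \mathcal N(0, \sigma),$$

$$\alpha_{g,\cdot} \sim \mathcal N(\mu^\alpha_g, \tau^\alpha_g), \quad
\beta_{g,\cdot} \sim \mathcal N(\mu^\beta_g, \tau^\beta_g), \quad
\mu \sim \mathcal N(0,1), \quad \tau, \sigma \sim \mathcal N^+(0,1).$$

Age is centered at 65 (the patients' median age) and scaled by decade,
so $\alpha$ is the annualized change of a 65-year-old and $\beta$ the
change in that rate per decade of baseline age. Partial pooling across
the 84 ROIs within each group stabilizes regional estimates and
addresses multiplicity without per-ROI corrections. The three groups
(LPA, PCA, CU) are fitted jointly in one model sharing $\sigma$;
atypical-AD estimates are formed per posterior draw as the
sample-size-weighted average $(18\,\theta_{LPA,r} + 12\,\theta_{PCA,r})/30$,
and the contrast against controls subtracts the CU draw, i.e. it is a
full posterior contrast evaluated at the age center. Region summaries
are empirical quantiles (posterior median, 80% and 95% intervals,
linear interpolation of order statistics).

Choices where the design was genuinely open:

* *Weighted average*: weights are the group sample sizes; "weighted"
  alone does not determine them, and size-weighting reproduces the
  pooled-cohort estimand.
* *Contrast construction*: "relative to cognitively unimpaired" is
  implemented as a posterior draw-wise difference of intercepts at the
  age center, the simplest contrast consistent with reporting a single
  relative rate per ROI.
* *Residual structure*: one shared $\sigma$ across regions and groups
  (a single "random error term"); a per-region $\sigma$ is available via
  `per_region_sigma = TRUE` in `hier_spec()`.
* *Outcome scaling*: tau changes are modelled in native SUVR/yr and
  volume changes in %/yr. The $\mathcal N(0,1)$ hyperpriors are weakly
  informative on both scales (observed rates are well inside ±1), so no
  standardization is applied.
* *Joint vs separate models*: one joint model per modality with
  post-hoc pooling per draw; fitting the groups jointly shares only
  $\sigma$, so group estimates remain essentially independent while the
  pooled contrast stays a proper posterior functional.

### MCMC schedule and bookkeeping

Two profiles are packaged. The production (`"paper"`) schedule runs 200
parallel chains, each 80,000 post-burn-in iterations thinned to every
40th value after a 15,000-iteration burn-in — 200 × 2,000 = 400,000
retained draws. The printed form of such schedules is ambiguous about
whether the stated length includes burn-in; the package's default
reading treats it as post-burn-in (matching the 400,000 total) and
exposes the other reading via `post_burnin = FALSE` rather than
reconciling silently. The desk profile (4 chains × 10,000 post-burn-in,
thin 10, burn-in 2,000; 4,000 retained draws) is used by the test suite
and analysis scripts; at the study's dimensions one desk fit takes
about 2 s and reaches Gelman–Rubin statistics ≈ 1.00 on all
hyperparameters.

### Sampler

The sampler is a purpose-built Gibbs scheme with a C++
(RcppArmadillo) core:

* $(\alpha_{g,\cdot}, \beta_{g,\cdot})$: joint 2×2 conjugate normal
  regression update per group, vectorized over ROIs. The likelihood
  enters only through fixed per-group sufficient statistics
  ($\mathbf 1'Y$, $x'Y$, $\sum y^2$, $n$, $\sum x$, $\sum x^2$), so an
  iteration costs $O(G \times R)$ regardless of subject count.
* $\mu$: conjugate normal updates.
* $\tau, \sigma$ (half-Normal priors, non-conjugate): univariate slice
  sampling on the log scale (stepping-out with shrinkage, unit step
  width), which is tuning-free and robust across the scales the two
  modalities produce.

Numerical choices: scales are confined to $[10^{-8}, 10^6]$ so the
slice cannot wander to $-\infty$ on degenerate noise-free data (where
the residual sum of squares is exactly zero and the conditional for
$\sigma$ is improper at the origin); the closed-form residual sum of
squares is clamped at zero against floating-point cancellation; a
non-finite conditional log-density aborts the chain with diagnostics.
Chains are seeded `seed + 1000*chain` and initialized overdispersed
(hypermeans from $\mathcal N(0,1)$, scales from $|\mathcal N(0,1)|+0.1$,
regional effects from their prior at the drawn hyperparameters), which
gives the Gelman–Rubin diagnostic genuine between-chain dispersion to
detect failures. The statistic itself is the classical non-split
potential scale reduction factor.

One test cross-checks the sampler against an independent JAGS
implementation of the same model on a small fixture: posterior means
and sds of the hypermeans, hyper-sds and residual sd agree to within
small Monte-Carlo error. JAGS serves only as an oracle; the package
never uses it for fitting.

## Lobe comparisons

Per posterior draw, regional contrasts are averaged (unweighted) over
each lobe's member ROIs; the comparison matrix entry $p_{ij}$ is the
fraction of draws in which lobe $j$'s average exceeds lobe $i$'s. Tied
draws — measure zero for continuous posteriors, but possible in
degenerate inputs — are split half to each side, which preserves the
complement identity $p_{ij} + p_{ji} = 1$ exactly. Raw probabilities
are kept in machine output; the display format clips to `<0.001` /
`>0.999` as comparison tables are conventionally printed. No
multiplicity adjustment is applied across lobe pairs: the entries are
posterior event probabilities, not tests.

The packaged ROI→lobe map (84 ROIs = 42 bilateral regions across
frontal, sensorimotor, medial/lateral temporal, medial/lateral
parietal, medial/lateral occipital lobes) is a documented convention
modelled on standard adult-lifespan-template parcellations; published
studies rarely print their exact assignment, so the map is
user-overridable everywhere it is consumed.

## Association analyses

**Partial correlations.** Every column of both datasets is residualized
on the covariates (with intercept) by QR decomposition and the
cross-correlation matrix of residuals computed in one BLAS call; a
brute-force residualize-then-correlate oracle agrees to $10^{-12}$
(machine precision of the two routes). The default covariate is
baseline age — the only covariate the surrounding analyses use;
configurable including none, in which case the result is the plain
Pearson matrix. Constant columns yield flagged `NA` entries, never a
silent zero.

**maxT permutation FWE correction.** Freedman–Lane style: the subject
rows of the residualized second dataset are permuted and the permuted
data re-residualized on the covariates (the $(I-H)P_\pi(I-H)Y$
construction — omitting the second projection measurably inflates the
family-wise error at this sample size), then the full $|r|$ matrix is
recomputed and its maximum recorded; adjusted p-values are
$(1 + \#\{\max_b \ge |r_{ij}|\})/(B+1)$, so the attainable minimum is
$1/(B+1)$ and adjusted ≥ unadjusted elementwise. Correction is
per-matrix (the whole 84×84 family), the stricter of the plausible
readings of a "permutation approach to correct for multiple
comparisons". Under a global-null simulation at study scale
(30 subjects, 84×84, 1,000 permutations, 500 replicates) the empirical
family-wise error rate sits near the nominal 0.05 within Monte-Carlo
error — the acceptance script recomputes this each run.

**Sparse CCA.** The penalized matrix decomposition of the
column-standardized cross-covariance $Z = X'Y/(n-1)$: alternating
updates $u \leftarrow \mathrm{normalize}(S(Zv, \delta_u))$ with
$\delta_u$ found by bisection (200 iterations, feasibility tolerance
$10^{-10}$) so that $\|u\|_1 \le c = \text{penalty}\cdot\sqrt{\dim}$,
met with equality when active; symmetrically for $v$; convergence when
successive weight changes fall below $10^{-6}$ (cap 200 iterations,
non-convergence returns the best iterate flagged). Initialization is
the leading right singular vector of $Z$ (deterministic; the seed only
feeds optional random restarts). Subsequent components deflate
$Z \leftarrow Z - d\,uv'$ with $d = u'Zv$; two components are retained
by default. Penalties below $1/\sqrt{\dim}$ are rejected — an L2-unit
vector always has $\|u\|_1 \ge 1$, so such constraints are infeasible
(at the study's 84 ROIs the floor is 0.109, well under the 0.2
default). Each pair is oriented so its largest-magnitude $u$ entry is
positive, and the reported correlation is the Pearson correlation of
the projected scores $Xu$ and $Yv$. With penalties at 1 the constraint
is inactive and the solution equals the leading singular vectors — the
SVD oracle used in tests.

## The synthetic-cohort generator

`generate_cohort()` draws from the model's own generative form: per
group, regional intercepts and decade slopes from their group-level
normals; per subject, a true annualized change
$\alpha + \beta(a-65)/10$; measurement noise enters the follow-up value
only, so the observed annualized change equals truth plus
$\mathcal N(0, \text{residual sd})$ — the simplest structure consistent
with the model's single residual term. Defaults mirror the targeted
study design: 18 LPA / 12 PCA / 45 CU; 84 ROIs; ages uniform on 53–80
years (the printed patient age range); scan intervals uniform on
348–406 days (the printed inter-quartile envelope of the scan
intervals). Group-level rates were chosen once as field-realistic
values inside the printed ranges (tau ≈ 0–0.15 SUVR/yr: LPA 0.08,
PCA 0.07, CU 0.01 with regional sds 0.02–0.03 and residual sd 0.05;
volume: −1.5 %/yr patients vs −0.3 controls, residual 0.8 %/yr) with
negative tau decade effects and positive volume decade effects, matching
the direction of reported age effects. Volume values are stored as
percent of a nominal baseline (≈100, with a few percent of
normalization scatter), so their annualized change is on the
log-Jacobian %/yr scale. The residual error structure is shared across
regions by default, matching the model default; a per-region vector is
accepted (the error structure is not derivable from a printed model
statement, so both are exposed).

What the generator does **not** emulate: PET noise physics and
scanner effects, spatial autocorrelation between neighbouring ROIs,
longitudinal reference-region drift, and any genuine cross-modal
coupling (tau and volume cohorts share subjects but draw independent
effects). Passing tests therefore demonstrate the *statistical
machinery* — calibration, identities, oracle agreement — on data obeying
the model's assumptions; they do not validate the model against real
imaging data. In particular the association stage on default synthetic
cohorts finds essentially no FWE-significant cross-modal correlations,
which is the correct null behaviour, not a reproduction of the
empirical findings.

`generate_phantom()` builds small 3D uptake/label/grey-matter volumes
in which each ROI's tissue-masked median equals a stated target
*exactly*: an odd number of voxels survives the mask and their values
straddle the target symmetrically, so the sample median is an attained
value; two sub-threshold voxels per ROI carry 10× outlier values the
mask must exclude. This makes extraction-versus-construction an exact
oracle for the quantification stage.

## Problem sizes and reproducibility

The test suite and acceptance script use the desk MCMC profile, 50
replicate fits for coverage (95% intervals for the six group hypermeans,
empirical coverage ≥ 90% asserted), 500 global-null replicates × 1,000
permutations for the family-wise error rate, and 84-dimensional
fixtures for the association oracles — sizes chosen so the full suite
runs in a few minutes on one CPU while leaving Monte-Carlo error well
inside the asserted tolerances. All randomness flows from explicit
seeds: cohort seeds, chain seeds (`seed + 1000*chain`), permutation
seeds, and the pipeline's documented per-stage offsets; reruns with the
same configuration are draw-identical.

## Known limitations

* Voxel-wise analyses (statistical parametric maps), image
  registration/segmentation, deformation estimation and partial-volume
  correction are out of scope; the package consumes ROI-level values.
* Complete cases only: subjects must have both timepoints in every ROI
  (as the two-timepoint design implies); missing cells are reported,
  not imputed.
* The classical (non-split) Gelman–Rubin statistic can miss
  within-chain non-stationarity that split-chain variants would flag;
  with many short overdispersed chains this is a minor risk.
* SCCA components are reported without permutation-based significance
  or cross-validation (not part of the targeted analysis chain).
* The lobe map is a convention; analyses sensitive to the exact
  assignment should supply their own.
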