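---
title: "Methods: polygenic risk scores and radiotherapy toxicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic risk scores and radiotherapy toxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Rheumatoid arthritis (RA) shares risk loci with DNA-damage-response genes
(*ATM*, *RAD51B* among them), which motivates the hypothesis that patients
with a high germline genetic predisposition to RA are more radiosensitive
and so experience more normal-tissue toxicity after curative-intent
radiotherapy. `radiotox` implements the full analysis required to test that
hypothesis in a prospective cohort: a polygenic risk score (PRS) computed
from imputed genotype dosages at 101 RA risk loci, Standardized Total
Average Toxicity (STAT) scores built from longitudinal CTCAE grade records,
and a per-site battery of univariable and multivariable linear regressions
with Bonferroni control over endpoint families. Because the clinical
cohorts such a study uses are not publicly deposited, the package ships a
synthetic-cohort generator that emulates their structure, so every stage is
testable end to end.

# The risk score

For sample $s$ over retained model variants $v$ with risk-allele dosage
$d_{sv} \in [0,2]$,

$$\mathrm{PRS}_s = \sum_v d_{sv}, \qquad
  \mathrm{wPRS}_s = \sum_v w_v\, d_{sv}.$$

The default weight is the per-risk-allele odds ratio itself,
$w_v = \mathrm{OR}_v$, which is the literal form of "weighting the dosage
by the odds ratio"; `weight_scheme = "log_or"` substitutes
$w_v = \ln \mathrm{OR}_v$, the form conventional in most PRS software. Both
are exposed because the two differ only by an affine-like rescaling of the
weights with no effect on any null hypothesis tested here, and the default
follows the analysis being reproduced.

## Harmonization

Genotype files do not agree on which allele a dosage counts, so every model
variant is classified against the panel before scoring. Matching is by
`variant_id` first with a `chrom:pos` fallback (positional collisions are
dropped, never guessed). The four reconcilable orientations map onto
`direct`, `swapped` ($d \to 2-d$), `strand_flipped` and
`strand_flipped_swapped` ($d \to 2-d$); anything else is
`unmatched_dropped`. Palindromic (A/T, C/G) variants are strand-undecidable
from allele labels alone: the default keeps them with exact-label matching,
which is correct whenever one imputation pipeline produced the panel on a
consistent reference strand, and `drop_ambiguous = TRUE` removes them for
heterogeneous data. Dosages outside $[0,2]$ by at most $10^{-6}$ are
clamped as serialization noise; larger excursions abort, because they
indicate a corrupt file rather than rounding.

Missing dosages are imputed as $2 \times \mathrm{eaf}$ when the model
carries an effect-allele frequency, else as the cohort mean at that
variant, and are counted per sample. The alternative — rescaling the score
to the observed variants — silently changes the score's scale across
samples and was rejected.

# Toxicity scoring

Day 0 anchors at the last radiotherapy fraction. Baseline is the latest
record at day $\le 0$; acute toxicity is the maximum CTCAE grade over days
1–90 ("within 3 months") and late toxicity the maximum over days 91–730
(3 months to 2 years). The two windows partition follow-up exactly, so no
record is double-counted. The anchor (start vs end of treatment) is a
genuinely open reading of "within 3 months of radiotherapy"; the end-of-
treatment anchor was chosen because acute reactions peak in the weeks after
completion, and it is explicit and testable here.

The delta measure, $\max(\text{window max} - \text{baseline},\, 0)$,
isolates the increase attributable to radiotherapy; it is floored at zero
so that symptom improvement is not scored as negative toxicity. Deltas are
engaged per endpoint only when at least 80% of that endpoint's patients
have a baseline (`use_delta = "auto"`); below that, raw maxima are used
with a warning, since a delta computed on a small baseline subset changes
the estimand mid-cohort.

STAT z-standardizes each endpoint's chosen value across patients with
non-missing data (sample, $n-1$, standard deviation — declared so tests
are exact) and averages the available z-values per patient. Endpoints with
zero variance carry no ranking information and are dropped with a logged
reason; patients with no available endpoint get `NA` rather than an
arbitrary 0. When nothing is missing or dropped, the cohort mean of STAT
is 0 by construction — a property the tests assert to $10^{-10}$. The
standardization population is the analysis cohort itself, the natural
choice for a single-cohort application.

# The association battery

Per site, STAT-acute and STAT-late are regressed on PRS and wPRS, each as
a continuous predictor and dichotomized above the 90th percentile, in
univariable models and in multivariable models with the site's preselected
adjustment set (prostate: age, diabetes, prior surgery, hormone therapy,
BED; lung: sex, age, smoking, technique, FEV1, V20 lungs, V35 esophagus,
BED, COPD; breast: age, smoking, cardiovascular disease, BMI, breast
volume, diabetes, postoperative infection, boost). These overall-toxicity
tests are evaluated at $\alpha = .05$ with family size 1. Individual
endpoints are analyzed multivariably only, and their thresholds divide
$\alpha$ by the endpoint-family size — 14 acute and 5 late endpoints for
prostate, 5 and 5 for lung, 2 and 7 for breast — displaying as .004, .01
and .007 at 3 decimals. Comparisons always use the unrounded threshold;
rounding only at display avoids artifacts exactly at the boundary.

Numerical choices: ordinary least squares via QR with complete-case
handling and per-row `n` reported (no imputation of covariates, since none
is described for the analysis being reproduced); a rank-deficient design is
an error naming the collinear terms rather than a silent drop; the
percentile threshold is the linearly interpolated type-7 sample quantile
with a strict `>` flag ("more than 90th percentile"); prescriptions are
converted to the biologically effective dose
$\mathrm{BED} = D\,(1 + d/(\alpha/\beta))$ with $\alpha/\beta = 10$ Gy;
categorical covariates are reference-coded against the most frequent level,
a deterministic rule chosen where none was specified.

# What the synthetic cohorts emulate

`simulation_config()` defaults define the study conditions: 500 patients,
101 variants with $\mathrm{eaf} \sim U(0.05, 0.95)$ and
$\ln \mathrm{OR} \sim N(0, 0.1)$ (the effect-size scale of autoimmune GWAS
hits), Hardy-Weinberg genotypes without linkage disequilibrium, dosage
noise SD 0.05, and per-site covariate marginals from typical presentation
ranges and standard fractionation regimens. Toxicity is generated from a
latent scale: per patient, endpoint and visit,

$$L = \text{window shift} + \text{covariate term} +
      \gamma \cdot \mathrm{wPRS}_{std} + \varepsilon, \qquad
  \varepsilon = N(0,1) + \Gamma(2, 0.5) - 1,$$

and the CTCAE grade is the count of thresholds (defaults 1.0, 2.0, 3.2,
4.5) below $L$, capped at 4. The centered-Gamma component gives the
right-sided skew observed in real STAT histograms; the thresholds were set
so that most assessments are grade 0–1 and under 5% reach grade 3+, the
qualitative shape of published incidence. Baseline assessments (day −7)
use a lower shift and no genetic effect; follow-up visits sit on a fixed
schedule (days 14/45/80 and 180/365/540/720) so window maxima are exactly
predictable in tests. Deliberately absent: linkage disequilibrium,
population structure, informative dropout, endpoint correlation beyond the
shared latent covariate term, and visit-time jitter — so passing tests
demonstrate the statistical machinery, not robustness to those real-data
features.

# Operating characteristics, and why recovery is latent-scale

Two Monte-Carlo suites characterize the battery (sizes chosen to estimate
the rates tightly while keeping the default runs in the minutes range):

* **Type-I error** — 1000 null cohorts of 500 patients run through the full
  observable pipeline (dosages → scores → grades → STAT → multivariable
  fit); the rejection rate at .05 must sit in the 99% binomial band
  [0.033, 0.069]. Under $\gamma = 0$ the null holds on every scale, so this
  validates the whole chain end to end.
* **Effect recovery** — 200 cohorts of 2000 patients with a planted
  $\gamma = 0.5$. The planted effect lives on the latent toxicity scale,
  and thresholding a latent variable into 5 ordinal grades attenuates any
  grade-scale regression coefficient by a factor that depends on the
  threshold layout, so "estimate within 10% of truth" is only a
  well-defined contract on the latent scale. Recovery therefore regresses
  the generator's recorded acute-window latent (its clean linear readout)
  on the standardized score plus the multivariable adjustment set, where
  OLS is unbiased and 95% CI coverage must fall in [0.92, 0.98]. The
  grade-scale consequence of the same planting is checked separately: a
  large $\gamma$ must yield a strong Spearman correlation between score
  and observed maximum grade.

# Known limitations

The Mann-Whitney comparison uses exact enumeration only for tiny untied
groups and the tie-corrected normal approximation otherwise; the latter is
what any realistically sized diagnosis contrast uses. Palindromic-variant
handling assumes a strand-consistent imputation pipeline unless
`drop_ambiguous` is set. STAT is computed within-cohort, so scores are not
comparable across cohorts standardized separately. Toxicity beyond 730
days, patient-reported-outcome weighting, LD-aware scoring and partitioned
risk scores are out of scope.
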