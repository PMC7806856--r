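---
title: "Methods: urinary cytokine panels, ROC diagnostics and the screen-confirm cascade"
author: "cytocascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urinary cytokine panels, ROC diagnostics and the screen-confirm cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocascade)
```

## The analysis problem

IC/BPS and OAB are storage-phase bladder conditions with heavily
overlapping symptoms and no accepted non-invasive test to tell them apart.
Multiplex bead immunoassays quantify dozens of inflammation-related
proteins in self-voided urine at once, so a panel of cytokine
concentrations (pg/mL) per subject is a natural candidate biomarker
substrate. This package implements the complete analysis chain for a
three-arm design (IC/BPS, OAB, asymptomatic controls): assay-level QC,
group comparison, per-marker diagnostic evaluation, covariate-adjusted
effect sizes, and a two-stage diagnostic classifier, together with a
synthetic cohort generator that reproduces the statistical structure the
chain assumes.

The cohort container is a `CytokineExperiment` (a thin
`SummarizedExperiment`): a markers × subjects concentration matrix, subject
covariates (`group`, `age`, `sex`, `bmi`, `dm`) in `colData`, panel
metadata in `rowData`. Missing measurements are `NA` and are dropped
pairwise per analysis — each marker's statistics use all subjects measured
for that marker. Per-cytokine exclusion counts in published group tables
imply exactly this per-marker bookkeeping; nothing is imputed.

## QC rules

Two rules, applied in this order:

1. **3-SD outlier exclusion.** Per marker × group, the mean and sample SD
   (n − 1 denominator, the convention of clinical tables) are computed once
   on all pre-exclusion values; values *strictly* outside
   [mean − k·SD, mean + k·SD] are excluded (k = 3 by default). The rule is
   deliberately single-pass: iterating would shrink the SD and exclude
   more, changing the published-style outlier counts. Boundary values are
   kept, which also makes the zero-variance case (SD = 0) well defined:
   everything equals the mean and is kept.
2. **Below-LOD flagging.** A marker is flagged when any group's
   post-exclusion mean falls below the marker's minimum detectable
   concentration. Flagged markers stay in group summaries (the study
   design still reports them) and are only withheld from diagnostic tables
   on request (`dropLodFlagged = TRUE`): published diagnostic tables retain
   some below-LOD markers, so exclusion is a policy choice, not a fact of
   the data, and the package makes it explicit rather than guessing.

A caveat the tests quantify rather than hide: on lognormal data with
CV near 1 — which several markers exhibit — the population mass beyond
3 SD is on the order of 2%, so genuine draws are flagged alongside
injected anomalies (about 0.3 flags per marker × group cell of 40 at the
default settings), and cells that catch two or more injected outliers
inflate their sample SD enough to shield some injections from the
threshold. Recovery of magnitude-5 injections therefore plateaus around
80%, a property of the rule on heavy-tailed data, not an implementation
artifact. The test suite asserts the oracle-verified facts: every flagged
value lies strictly outside its pre-exclusion interval, counts are
conserved, flagging is order-invariant, and the per-cell exclusion counts
stay in the reported 0–2 range in well over 90% of cells.

## Group comparison

Classical (equal-variance) one-way ANOVA per marker on raw concentrations,
with Tukey HSD pairwise post hoc; Bonferroni-adjusted pairwise t tests,
Welch's ANOVA and a log transform are available as options. Raw-scale
classical ANOVA is the default because it is what standard clinical
software produces by default and what the emulated analysis reports;
the omnibus F is verified against a first-principles sum-of-squares
computation, and the suite checks the nominal type-I error empirically
under the global null. Post hoc p-values are always computed but flagged
significant only below α = 0.05. Which post hoc procedure produced the
published significant-pair lists is not documented anywhere, so numerical
agreement with any specific published pair list is not claimed.

## ROC diagnostics

For a contrast (diseased = IC/BPS ∪ OAB vs control, or IC/BPS vs OAB) and
marker, the positive class is the diseased side (resp. IC/BPS). The AUC is
the Mann–Whitney probability P(X⁺ > X⁻) + ½·P(X⁺ = X⁻), computed by
midranks and verified in tests against explicit enumeration of all
positive × negative pairs and against an independent ROC implementation.
With `direction = "auto"` the orientation with AUC ≥ 0.5 is selected and
recorded — some markers run lower in the positive class (IL-10, IL-12p70
and IL-17A for IC/BPS vs OAB; IL-17A for diseased vs control), and
published tables mark exactly this with direction footnotes.

The operating cutoff maximises Youden's J = sens + spec − 1, the standard
single-threshold criterion and the only simple one consistent with
reporting a single sens/spec pair. Candidate thresholds are the midpoints
between consecutive distinct observed values plus one candidate beyond
each extreme; the reported cutoff is therefore a half-step value exactly
like the published ones (1.385, 7.805, 9.035 …), which is itself the
evidence that midpoint reporting is the convention being emulated.
Positivity at a cutoff is strict (`value > cutoff` under `pos_higher`), so
midpoints classify every observed value unambiguously. J ties break toward
higher sensitivity, then the lower threshold — screening favours
sensitivity, and the tie-break is fixed so results are deterministic.

### The rate→count consistency oracle

Raw subject-level data behind the published tables were never deposited,
so AUCs and cutoffs are not recomputable. What *is* exactly recomputable
is the arithmetic linking each published row's sensitivity/specificity to
its PPV/NPV through integer confusion counts:

- class sizes are the enrolled group sizes minus that marker's per-group
  excluded-outlier counts (e.g. MIP-1β, diseased vs control:
  80 − (1 + 2) = 77 positives, 30 − 1 = 29 negatives);
- tp = round(sens·n⁺/100), tn = round(spec·n⁻/100), rounding half *up*
  (the behaviour of the SPSS lineage of software; one published row sits
  exactly on a .5 boundary and discriminates the conventions);
- PPV/NPV follow from counts.

`confusionFromRates()` implements this; all 22 published diagnostic rows
reproduce their printed PPV and NPV to the printed decimal, including the
screening stage's published "diagnostic rates" (81.6%/68.4%), which are
exactly the screening marker's PPV/NPV under this identity. The identity
also settles an ambiguity: the IC/BPS-vs-OAB section only reproduces if
the positive class is IC/BPS for *every* row, with the direction footnote
(higher values indicate OAB) encoding orientation only.

## Adjusted odds ratios

Per marker and contrast, `case ~ marker + age + sex + bmi + dm` by
maximum-likelihood logistic regression on complete cases. Sex is coded
F = 0 / M = 1, diabetes no = 0 / yes = 1, continuous covariates enter
unscaled. The marker OR is rescaled to a clinically readable increment —
OR per `unit` pg/mL = exp(β·unit), with the published unit table (100 for
MCP-1, 0.1 for IL-10, 0.01 for NGF, …) as default — and carries a Wald
95% CI, matching the symmetric-on-log-scale intervals of standard output.
(Quasi-)separation is detected from fitted probabilities pinned at 0/1 and
reported as `converged = FALSE` with `NA` estimates rather than a spurious
huge OR. Published OR values themselves depend on the raw covariate-marker
joint distribution and are not reproducible from summaries; the suite
instead verifies the estimator (parameter recovery, rescaling identity,
CI coverage, null behaviour) on cohorts with known truth.

## The diagnostic cascade

Stage 1 screens with MIP-1β > 1.385 pg/mL (the highest-sensitivity marker
for diseased vs control): screen-negatives are called CONTROL and the
remaining markers are never consulted. Stage 2 assigns screen-positives:
eotaxin > 9.035, CXCL10 > 40.495 and RANTES > 9.305 each vote IC/BPS;
IL-10 > 1.025 votes OAB (IL-10 runs higher in OAB). The published
algorithm scores each confirmation cytokine separately and never defines a
joint rule, so the joint decision here is an explicit, configurable
extension: votes combine under `majority` (default), `any`, `all` or
`single`, and a simultaneous IC and OAB call resolves per `on_conflict`
(default INDETERMINATE; `prefer_ic`/`prefer_oab` available). A
screen-positive with no firing confirmation rule is INDETERMINATE;
subjects missing the screen marker are unevaluable and reported as such.

Evaluation reports the screen stage's PPV/NPV (identical, by construction
and by test, to `metricsAtCutoff()` on the screen marker over the same
subjects), each confirmation rule's single-rule correct rate among
screen-positive truly-diseased subjects, and overall three-class accuracy
(INDETERMINATE counts as wrong). Published confirmation-stage rates
(73.3/72.7/69.7/60%) depend on the joint marker distribution in the raw
study data — their exact denominator is not even stated — so they are
checked nowhere; the screening-stage rates, which the consistency oracle
pins down exactly, are.

## The synthetic cohort generator

The generator emulates the study conditions: group sizes 40/40/30,
covariates per the published per-group summaries (normal age truncated to
the observed range, normal BMI, binomial sex and diabetes with the
published proportions — controls all female), and per marker × group
concentrations from a lognormal moment-matched to the published mean/SD:
σ² = ln(1 + sd²/mean²), μ = ln(mean) − σ²/2, giving exactly the requested
arithmetic moments. Lognormal is the default family because concentrations
are nonnegative and right-skewed — several markers have SD ≈ mean, which
no symmetric positive-valued family can produce; a zero-truncated Gaussian
is available for sensitivity analysis (its realised moments deviate from
the targets by the truncation, so moment-matching claims apply to the
lognormal only).

Markers are independent within subject by default — no published
covariance exists — with an optional Gaussian copula for sensitivity
studies; any chosen correlation is a stand-in, and joint-rule performance
on independent markers should be read as a lower bound of what correlated
markers could support. Covariates do not influence markers by default (no
published effect sizes); an optional log-scale linear covariate effect
exists for exercising the adjusted-model code. Outlier injection replaces
a cell with probability 0.025 by mean + U(5, 8)·SD of its cell, recording
position and value as ground truth; 0.025 × 40 ≈ 1 expected injection per
cell keeps per-cell counts in the reported 0–2 range (≈99% of cells in
simulation). Generation is fully determined by the spec's seed.

## Numerical and scale choices

- Problem sizes used by the checked-in tests and the acceptance script:
  moment recovery at 10⁵ subjects per group; outlier recovery, ANOVA
  type-I (500 replicates) and logistic recovery (200 replicates at
  n = 2000) at study scale; brute-force AUC oracles up to 10⁴ pairs.
- Reports render floats at 3 decimals (percentages at 1 decimal match the
  published style); cohort CSVs round-trip doubles exactly via `%.17g`.
- Marker keys are ASCII aliases (`MIP-1b`, `IFNa2`) with Unicode display
  names carried separately, avoiding encoding-dependent key bugs.
- `excludeOutliers()` requires ≥ 2 non-missing values; ANOVA skips markers
  without two groups of two; empty predicted classes yield `NA` metrics,
  never 0.

## Known limitations

- No assay plate effects, batch drift or creatinine normalisation are
  modelled (none were applied in the emulated workflow).
- Passing moment-recovery and screening-rate tests on synthetic cohorts
  shows the pipeline is faithful to the stated marginal structure; it says
  nothing about inter-marker correlation, covariate-marker dependence or
  assay artefacts in real data.
- In-sample Youden cutoffs are optimistically biased; no cross-validation
  or confidence intervals are provided, mirroring the emulated analysis.
- The sample SD of the heaviest-tailed cells (CV ≈ 1.7) has a relative
  Monte-Carlo SE of ≈ 3% even at n = 10⁵, so SD-recovery checks at the 5%
  tolerance sit at ≈ 1.6σ and are inherently tight.
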