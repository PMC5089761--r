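---
title: "Composite gene-environment risk scoring for multiple sclerosis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite gene-environment risk scoring for multiple sclerosis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msrisk)
library(dplyr)
```

## The model

Multiple sclerosis arises from environmental exposures acting on genetic
susceptibility. msrisk implements a composite risk score that combines both
axes in a single additive model on the log10-odds scale:

$$S_i = \sum_j w_j \cdot x_{ij}, \qquad w_j = \log_{10}(\mathrm{OR}_j),$$

where $x_{ij}$ indicates that participant $i$ carries risk-factor level $j$,
and each $\mathrm{OR}_j$ is a published literature odds ratio. A factor that
is absent — or unmeasured — contributes exactly 0. Weights are rounded to two
decimal places, the precision of the source estimates; an odds ratio whose
95% confidence interval strictly contains 1 is zeroed (a non-significant
level is treated as no evidence of effect). An interval that *touches* 1 at
its lower bound is retained: the third anti-EBNA-1 quintile (OR 3.2,
CI 1.0–10.4) keeps its weight 0.51, matching the published ledger, so the
zeroing rule is `ci_low < 1 < ci_high`, not `<=`.

The ledger covers six environmental factors — female sex (OR 2.22), month of
birth (April/May/October/November carry small ORs; all other months 0),
infectious mononucleosis history (OR 2.17), anti-EBNA-1 IgG quintile
(undetectable 0.33 through Q5 9.4), deseasonalised serum 25-hydroxyvitamin D
quintile (only Q5, OR 0.38, survives the CI rule), ever-smoking (OR 1.52) —
plus HLA-DRB1\*1501 zygosity (heterozygote 3.1, homozygote 6.2) and a panel
of 57 non-MHC susceptibility SNPs from genome-wide association, each with a
single per-SNP odds ratio (1.08–1.22). The HLA tag SNP rs1315388 is routed
through the zygosity weights and excluded from the SNP loop to avoid double
counting.

Four score variants are computed (`score_variants()`): genetic scope
HLA-only or full panel, each with or without the vitamin D term. Vitamin D
status is confounded by supplementation in treated patients, which is why
the score is also reported without it.

## Encoding decisions

**Smoking.** "Ever smoking" is self-report OR serum cotinine strictly above
3.08 ng/ml, the conventional ELISA cut-off separating current smokers from
non-smokers. The rule is monotone: more evidence can only move a participant
towards "ever".

**EBNA-1 quintiles.** Cutpoints are the 20/40/60/80th percentiles
(linear-interpolation quantile definition) of the *detectable* titres in a
reference group — by default the combined unaffected siblings and healthy
controls of the cohort being scored, so that case titres do not distort the
reference distribution. Titres below the assay's limit of detection form
their own, protective, level (weight −0.48). The LOD is an argument
(`ebna_lod`) because it is assay-specific. Ties at a cutpoint go to the
lower quintile.

**Vitamin D.** Serum 25-OHvD is first deseasonalised: a first-harmonic
cosinor (mesor + sine/cosine pair with a 365.25-day period, ordinary least
squares) is fitted to a reference set of (value, sampling-day) pairs, and
the fitted seasonal component at the participant's sampling day is
subtracted. The deseasonalised reference mean equals the cosinor mesor
exactly (OLS residuals have mean zero). Whether the seasonal reference
should be controls only or all participants is not prescribed; the default
is all participants with a measurement, and any reference can be supplied
(`vitd_reference`). Quintiles then use fixed literature cutpoints 63.2 /
75.3 / 84.8 / 99.1 nmol/l. The printed band edges leave 0.1-unit gaps
(63.2 vs 63.3); these are resolved as contiguous half-open intervals,
upper-inclusive, so 75.3 falls in Q2.

**Intentionally absent encoders.** Latitude of birth (a single non-UK
birthplace in the source cohort), age (no usable epoch-specific odds
ratios), and childhood BMI (unreliably recalled) are deliberately not part
of the model.

## Genotypes and dosage

Genotypes are read from VCF (GT field, biallelic sites, rsID in the ID
column) or a dosage TSV. Risk-allele counts are oriented against the
panel's risk allele, honouring REF/ALT orientation; sites where neither
allele matches are recorded missing with a warning, and strand-ambiguous
A/T and C/G sites are flagged rather than silently flipped.

The per-genotype dosage rule for the 57 non-HLA SNPs is not uniquely
determined by a single per-SNP odds ratio. The default is a **carriage
(dominant) model** — at least one risk allele contributes the weight once —
because only HLA carries explicit heterozygote/homozygote odds ratios; an
**additive model** (weight × allele count) is available via
`dosage_model = "additive"`. Missing genotypes contribute 0, consistent
with the absent-factor rule. A consequence worth noting: 57 summed carriage
weights span at most ~6.3 log10-odds units, so cohort mean differences
between full-genetic and HLA-only variants larger than that are not
reachable under carriage dosing; the exact accumulation rule behind the
published full-genetic means cannot be reverse-engineered from a single
odds-ratio column, and no attempt is made to guess it.

## Cohort analytics

**AUC.** `roc_auc()` computes the rank-based (Mann-Whitney) AUC with
midrank ties — the probability a random case outscores a random control —
with a DeLong placement-variance confidence interval (Hanley-McNeil behind
`ci_method = "hanley"`), truncated to [0, 1]. The implementation is checked
in the test suite against both a brute-force pairwise oracle and an
independent reference implementation.

**Group comparison.** `compare_groups()` runs a classical one-way ANOVA,
pairwise Welch t-tests with Bonferroni adjustment (`min(1, n_pairs * p)`),
and per-group Shapiro-Wilk normality checks. Welch tests are used for the
post-hoc pairs because group variances are not assumed equal; only the
Bonferroni correction itself is prescribed by convention.

**Septile stratification.** `septile_partition()` cuts a score distribution
at mean ± 0.25, 0.75 and 1.25 sample SDs into 7 bands (upper-inclusive
boundaries). For a Gaussian score the top band holds
$\Phi(-1.25) \approx 10.6\%$ of the cohort — the high-risk sibling fraction
that a pre-symptomatic trial would enrich for. The mean and SD default to
the partitioned group's own distribution ("within that group"), but can be
supplied externally (`center`, `scale`).

**Sample size.** `two_proportion_sample_size()` is the classical
normal-approximation formula with pooled variance under the null and
unpooled under the alternative, rounded up. At (p1 = 0.15, p2 = 0.04,
two-sided α = 0.05, power 0.8) it returns 111 per group. The companion
published figure of 76 siblings for (0.19, 0.04) is not reproduced by the
pooled (70), unpooled, arcsine or continuity-corrected variants of the
formula; since the method behind that figure is unstated, it is recorded
here as unexplained rather than fitted.

## The cohort simulator

No participant-level data accompany the published study, so
`simulate_cohort()` generates family-structured cohorts **under the
additive model itself**, making every pipeline stage testable end to end:

- **Genetics.** Founders draw genotypes binomial(2, freq) per SNP
  (Hardy-Weinberg). Each proband and their siblings inherit by Mendelian
  single-allele transmission from a shared simulated parent pair, giving
  the expected 0.5 proband–sibling allele-sharing correlation. No linkage
  disequilibrium is modelled.
- **Disease.** Liability is `baseline + ln(10) · S` on the natural-log-odds
  scale, so the generative odds ratios equal the ledger's odds ratios
  exactly. Probands are rejection-sampled conditional on disease; siblings
  and controls conditional on being unaffected. The baseline is calibrated
  by Monte Carlo to a target population prevalence.
- **Exposures** are independent, matching the additive (no-interaction)
  model: female 0.5; infectious mononucleosis 6%; ever-smoking 40% (30% of
  ever-smokers current, with cotinine drawn well above the cut-off);
  uniform birth months; EBNA-1 titre lognormal(log 50, 1.2) with LOD 5
  (≈3% undetectable); 25-OHvD cosinor with mesor 70 nmol/l, amplitude 15,
  residual SD 15 — an unsupplemented temperate-latitude profile. These
  defaults were fixed once as field-plausible values.
- **Default sizes** are the enrolled study groups, 78 / 121 / 103, and the
  default target prevalence is 0.005, a realistic lifetime MS risk.

`recover_parameters()` closes the loop: a logistic regression of proband
vs control status on the factor indicators recovers each generative effect
(`ln(10) · w`) within its 95% Wald interval for the large majority of the
~70 modelled terms — slope estimates are consistent under case-control
sampling, so the recovery run uses a 2% prevalence, which keeps the
conditional proband sampling cheap without changing the effects being
recovered.

What the simulator deliberately does **not** emulate: correlated exposures,
gene-environment interaction, linkage disequilibrium, genotyping error, or
the age structure of a real cohort. Green tests therefore demonstrate the
internal consistency of the scoring-analysis pipeline, not the clinical
validity of the score on real participants; the published cohort's AUCs
(0.77–0.82) and group means depend on unreleased data and are not
reproduction targets.

## Numerical and degenerate-input choices

- Weight rounding uses R's `round()` (2 dp); `full_precision = TRUE`
  retains exact log10 values for sensitivity analyses.
- Quantile cutpoints use `stats::quantile()` type 7; all band assignments
  are upper-inclusive, so boundary values fall in the lower band.
- A cosinor reference needs ≥ 2 distinct sampling days; an all-one-day
  reference is rejected rather than silently fitting an unidentifiable
  model. Deseasonalised values can in principle go non-positive; such
  values are treated as missing at the quintile step.
- `septile_partition()` rejects zero-SD inputs; `roc_auc()` rejects empty
  groups; rejection sampling aborts after a bounded number of batches when
  the requested prevalence is unreachable.
- Problem sizes in the test suite (up to 2000 per group for distributional
  checks, 5000 per group for parameter recovery, 1000 replicates for the
  ANOVA type-I simulation, 100,000 draws for the septile tail) were chosen
  so each check's Monte-Carlo error is well inside its assertion band.

## A worked run

```{r example, eval = FALSE}
coh <- simulate_cohort(seed = 1)          # 78 / 121 / 103, defaults
scores <- score_cohort(coh$phenotypes, coh$genotypes, ebna_lod = 5)
compare_groups(scores)                    # MS > SIB > HC, ANOVA p << 0.001
roc_auc(scores$score[scores$group == "MS"],
        scores$score[scores$group == "HC"])
septile_partition(scores$score[scores$group == "SIB"])$top_fraction
```

On ledger-generated cohorts the proband mean exceeds the sibling mean,
which exceeds the control mean — the intermediate-sibling pattern — and the
sibling top-septile fraction sits near the Gaussian tail mass of ~10.6%.
These are outputs of the generative model round-tripping through the
pipeline, computed afresh in the test suite, not empirical claims about
real cohorts.

## Known limitations

- Weights are literature constants; the package never re-estimates them
  from data.
- The score is a relative ranking tool: no calibration from score to
  absolute disease probability is provided or implied.
- The carriage-vs-additive ambiguity above means absolute full-genetic
  score levels are convention-dependent; comparisons within one convention
  are unaffected.
- Only Table-level MHC information (the DRB1\*1501 tag) is modelled; other
  MHC alleles reported in the source GWAS are not in the ledger.
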