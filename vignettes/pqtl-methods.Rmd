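---
title: "Methods: censoring-aware pQTL mapping and two-cohort meta-analysis"
author: "pqtlmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censoring-aware pQTL mapping and two-cohort meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqtlmeta)
```

This vignette documents the statistical model behind `pqtlmeta`, the
parameters that matter, the design choices made where the design was
genuinely open, and what the simulation-based tests do and do not
demonstrate about real data.

## Data model

A study consists of two cohorts, each a `cohort_bundle` aligning four
tables over an identical, lexicographically ordered subject list:

* **genotypes** — additive alt-allele dosages in {0, 1, 2, NA} with variant
  metadata (id, chromosome, 1-based position, alleles). Native storage is a
  tab-separated dosage table; VCF (GT fields, biallelic) and PLINK
  .ped/.map text import adapters are provided.
* **biomarkers** — raw assay-unit measurements with a per-analyte lower
  limit of quantification (LLOQ) and a below-LLOQ mask. A value recorded
  below the LLOQ is *censored*, not missing; genuinely missing values are
  excluded per regression instead.
* **covariates** — site, sex, age, BMI, smoking pack-years, current-smoker
  status, optionally seven complete-blood-count (CBC) cell counts.
  Subjects with any missing covariate are dropped at read time
  (complete-case), with the dropped count logged.
* **phenotypes** — continuous (percent emphysema, FEV1 % predicted) and
  binary (chronic bronchitis, any exacerbation) disease measures.

## Variant quality control

Variants are filtered on missingness (keep if rate ≤ 0.05), minor allele
frequency (keep if MAF ≥ 0.01), and a Hardy–Weinberg exact test (keep if
p ≥ 0.001). The HWE test is the standard exact conditional test on the
heterozygote count given the allele totals — the sum of probabilities of
all heterozygote counts no more probable than the observed one, without a
mid-p correction — matching the convention of the GWAS toolchains this
pipeline interoperates with. Removal is the union of the three filters;
for reporting, a removed variant is attributed to the first filter it
fails, in the order missingness → MAF → HWE, so the kept set is
order-invariant while the report stays unambiguous. Monomorphic tables
return p = 1 by convention, and variants with all dosages missing fail the
missingness filter rather than producing an undefined MAF downstream.

Genotype principal components are computed on standardized dosages
(mean 0, unit variance, missing set to the mean — mean imputation is
confined to the PCA; association scans use per-variant complete cases)
after residualizing each variant on the covariate design, via SVD of the
residual matrix. All eigenvalues are returned so the number of PCs carried
into the scan can be chosen from a scree inspection; the default is one
PC, and the per-cohort count is configuration, since cohorts genotyped on
different platforms can require different adjustments. The sign of each
component is fixed by making its largest-magnitude loading positive, for
determinism across platforms and subject orderings.

## Biomarker preparation

The preprocessing order is fixed and tested: (1) values below the LLOQ are
imputed as half the LLOQ; (2) the analyte is transformed by the rank-based
inverse normal transformation (INT)
`qnorm((rank - 0.5)/m)` with average ranks for ties; (3) for censored
analytes the tobit truncation value is set to the minimum transformed
value among non-censored observations minus 1e-10.

Decisions worth recording:

* **Triage boundaries.** More than 90% censored → dropped; less than 10% →
  linear; otherwise tobit. The boundary readings are literal: exactly 10%
  or 90% censored goes to tobit.
* **INT offset.** The (r − 0.5)/m offset keeps extreme quantiles finite; no
  particular offset is canonical, and rank-based transforms are invariant
  to the choice up to monotone detail.
* **Ties.** All half-LLOQ-imputed values tie and therefore share one
  transformed value. That value never enters the censored likelihood —
  the censored mask does — so the tie convention is harmless; it only
  seeds the optimizer's initialization.
* **The censored mask is taken from the below-LLOQ indicator**, never
  reconstructed by comparing transformed values to the truncation value:
  c is derived from the mask, not vice versa.

When a tobit-mode biomarker must serve as a covariate (trio models,
variance decompositions), its censored entries are replaced by the
conditional expectation of the latent value given censoring: for linear
predictor mu and scale sigma, `mu - sigma * phi(a)/Phi(a)` with
`a = (c - mu)/sigma` — the mean of a normal truncated above at c. When
`Phi(a)` underflows (far-tail censoring), the first-order asymptotic form
`c + sigma/a` is used with a warning. This fill is validated against
numerical quadrature to 1e-6 over a grid of (mu, sigma, c).

A biomarker panel can carry structure beyond the measured covariates
(e.g., batch or platform effects). The first principal component of the
transformed panel (conditional-expectation-filled for tobit analytes) is
offered as an additional covariate. Under the `auto` policy it is included
only when no covariate design column associates with it at the Bonferroni
level 0.05/(number of terms): a PC1 that merely re-expresses age or sex
would be redundant (and slightly harmful) as an adjustment, whereas a PC1
orthogonal to the covariates captures structure worth removing. The PCA is
computed on the non-residualized panel precisely so that this screen is
meaningful; each cohort makes its own inclusion decision.

## Association engines

Three engines share a Wald convention `p = 2 Phi(-|beta/se|)` so per-cohort
results feed the meta-analysis coherently:

* **OLS** (linear-mode analytes, continuous phenotypes) via QR least
  squares; aliased columns are dropped with a warning.
* **Tobit** (censored analytes): the left-censored gaussian likelihood is
  maximized by BFGS in (beta, log sigma) — the log parametrization makes
  the search unconstrained — with analytic gradients, initialized from OLS
  on the observed response (the tied censored values only seed this
  initialization; conditional-expectation initialization would itself
  require a tobit fit). Because BFGS terminates on function improvement,
  up to five Newton steps with the observed information polish the optimum
  so the gradient max-norm criterion (< 1e-6) reflects true convergence.
  Standard errors come from the inverse observed information. Collapse of
  sigma toward zero or failure to converge flags the fit; flagged results
  are excluded from meta-analysis with a message.
* **Logistic** (binary phenotypes) via iteratively reweighted least
  squares; separation is flagged through diverging coefficients.

The genome-wide scan regresses each prepared analyte on every QC-passing
variant with the cohort covariate design, complete-case per variant. For
linear-mode analytes with no missing dosages, response and dosages are
residualized on the covariate design once (Frisch–Waugh), which is
numerically identical to per-variant OLS and keeps a 2,000-variant scan in
milliseconds. In-sample monomorphic variants return beta = 0, p = 1,
flagged. Dosage is additive in the alt allele throughout; no dominance
terms. Site enters as one-hot indicators with the alphabetically first
level as reference.

## Meta-analysis, significance, replication

Per-cohort (beta, p) pairs become signed z-scores
`z = sign(beta) |qnorm(p/2)|` — evaluated in log space for extreme
p-values so |z| stays accurate beyond the underflow point of doubles — and
are combined as

`Z = (n1 z1 + n2 z2)/(n1 + n2)`, `meta-p = 2 Phi(-|Z|)`.

This sample-size weighting with an arithmetic-mean denominator is **not**
the classical Stouffer normalization and is conservative: for equal
z-scores and unequal n, |Z| is strictly smaller than the classical
`(sqrt(n1) z1 + sqrt(n2) z2)/sqrt(n1+n2)`. The weighted form is the
package default for fidelity to the two-cohort analysis convention it
implements; the classical variant sits behind `method = "classical"`, and
the conservativeness is verified over a grid in the tests. A
`log10_meta_p` column accompanies every meta p-value because genuinely
interesting pQTLs can reach p-values far below the double range.

Genome-wide significance is a strict `meta_p < threshold` with a default
of 8e-10 — a Bonferroni-style level for several hundred thousand variants
by on the order of ninety analytes; the exact denominator is study-specific,
so the threshold is configuration and `bonferroni_threshold()` computes
0.05/(variants × analytes) for a user's own panel. Replication of a
discovery-cohort association requires both significance in the other
cohort at 0.05/m (m = discovery count) and agreement of effect direction.

## Recursive conditioning

Within an analyte, candidate variants (marginal meta-p below 1e-8 — a
deliberately looser pool than the significance call) are dissected by
forward selection: select the top meta hit; refit every remaining candidate
per cohort with **all** previously selected dosages in the design;
meta-combine; accept the best candidate while its conditional meta-p beats
0.05/T with T the remaining-candidate count (K − 1 in the first round).
Conditioning on all selected variants — not only the first — is the
forward-regression reading of the procedure; conditioning on the top SNP
alone would re-admit proxies of the second signal. Candidates with dosage
r² > 0.99 against a selected variant are skipped as proxies to keep the
conditional design well-posed. Ties on the minimum conditional meta-p
break by larger |Z|, then lexicographic variant id. Each analyte keeps its
triage mode (tobit analytes are conditioned by tobit refits) throughout.

## Trio causal classification

For a pQTL SNP g, biomarker B, and phenotype D, three regressions per
cohort give four slope tests:

| test | model | slope |
|------|-------|-------|
| t_SD | D ~ g + C | g |
| t_SD_given_B | D ~ g + B + C | g |
| t_BD_given_S | D ~ g + B + C | B |
| t_SB_given_D | B ~ g + D + C | g |

Testing the biomarker–disease slope with D as response or with B as
response probes the same conditional dependence, so only the D-response
version enters the battery. Each test is meta-combined across cohorts
exactly as the pQTL scan is, and a dependence call is meta-p < 0.01. The
decision table maps call patterns to graphs by d-separation: *causal*
(g → B → D) requires the SNP–disease association to vanish given the
mediator; *reactive* (g → D → B) the SNP–biomarker association to vanish
given disease; *independent* (B ← g → D) biomarker–disease independence
given the SNP; *collide* (g → B ← D) marginal SNP–disease independence
turning into dependence given the biomarker; *complete* keeps all four
dependencies; anything else is *other*. Treating a non-significant test as
evidence of conditional independence is inherent to the procedure — it is
accept-the-null logic, inherited rather than endorsed — so all four meta
p-values are always emitted for the user to judge margins; an
underpowered collide-vs-complete distinction, for example, hinges only on
the marginal SNP–disease test.

Model details: binary phenotypes use logistic models for M1/M2 (with the
caveat that odds ratios are non-collapsible, so the conditional and
marginal SNP slopes are not on identical scales); tobit-mode biomarkers
enter M1/M2 through conditional-expectation-filled values and are refit by
tobit in M3; the biomarker PC1 is excluded from the M3 design to avoid
conditioning a response on a function of itself. Percent emphysema may
optionally be log(x + 0.1)-transformed before modeling; FEV1 % predicted
is left untransformed. Exacerbations are modeled as a binary
any-exacerbation indicator.

## Reporting metrics

The variance decomposition is sequential R²: clinical covariates first,
then the top independent signal, then the second. The order is fixed and
matters — it mirrors the question "what do genetics add beyond clinical
factors", and hierarchical increments are the natural reading of a
clinical/SNP/unknown partition. The four components are algebraically
guaranteed to sum to 1. Tobit analytes are decomposed on filled values and
flagged approximate. The phenotype comparison reports three nested-model
R² values (covariates; + biomarker; + SNP), monotone by construction for
linear models, McFadden pseudo-R² with a flag for binary phenotypes. The
CBC sensitivity analysis correlates −log10 p between scans with and
without cell-count covariates; raw-p correlation is reported alongside but
is dominated by the uniform bulk of null pairs, which is why the log scale
is primary.

## The synthetic generator

`simulate_study()` emulates the structure the analysis assumes, at the
two-cohort sizes of the emulated design (defaults n1 = 750, n2 = 590):

* **Genotypes**: per-variant MAF uniform on [0.01, 0.5], shared across
  cohorts; genotypes as two independent Bernoulli(MAF) allele copies
  (Hardy–Weinberg by construction). LD proxies copy the block seed
  variant's alleles with probability q, giving allele correlation ~q and
  dosage r² ~ q² — directly controllable, which is what testing the
  conditioning step needs; no coalescent realism is attempted.
* **Covariates**: site uniform; sex Bernoulli(0.5); age N(66, 8); BMI
  N(28, 5); pack-years N(50, 25) truncated at 10; current smoker
  Bernoulli(0.3) — magnitudes typical of a smoking-enriched COPD cohort
  over 45. Optional log-normal CBC counts at adult reference means.
* **Biomarkers**: latent trait = standardized-covariate effects + planted
  per-allele slopes + batch loading + gaussian noise, with noise budgeted
  so latent variance is ~1 unless specified; raw value = exp(latent), so
  the raw scale is realistically right-skewed while the INT used by the
  scan makes the analysis insensitive to that choice. The LLOQ sits at a
  configured quantile of the raw distribution, so triage classes are hit
  deliberately. `slope_for_variance()` converts a target variance fraction
  into a per-allele slope.
* **Phenotypes**: generated under a per-trio causal graph (causal,
  reactive, independent, collide, complete, null) with strong default edge
  coefficients; graphs with an edge into the biomarker regenerate that
  analyte including its censoring. Binary phenotypes go through a logistic
  link at ~35% prevalence.

All randomness derives from the single config seed through a
tag-hashing splitter (`seed`, tag) → stream, so the same configuration is
byte-identical everywhere and sub-streams (genotypes cohort 1, covariates
cohort 2, ...) are reproducible independently.

**What passing tests show — and what they do not.** The generator matches
the analysis model: gaussian latent traits, exact HWE, additive effects,
homogeneous effects across cohorts (a multiplier knob exists), independent
subjects. Pass rates on these simulations validate correctness of the
machinery — estimator consistency, type-I error control, d-separation
signatures, recovery of planted signals — not robustness to population
structure, relatedness, batch-confounded genotyping, assay isoform
artifacts, or model misspecification, none of which the generator
emulates.

## Numerical choices and problem sizes

Tolerances: tobit convergence requires gradient max-norm < 1e-6 (Newton
polish usually drives it below 1e-10) within 200 iterations;
conditional-expectation fills match quadrature to 1e-6; the HWE
implementation agrees with exhaustive enumeration to 1e-9 over all tables
with n ≤ 50; hierarchical R² components sum to 1 within 1e-9. Degenerate
inputs have defined behavior: monomorphic variants (p = 1, flagged),
single-site cohorts (no site indicators), all-identical analyte values
(transform to 0 with a warning), all-censored analytes (error; triage
should have dropped them), empty subject intersections (error).

The validation suite runs null scans at 2,000 variants × 3 analytes at
full cohort sizes (750 + 590); power, conditioning, and trio-recovery
checks use 20–100 seeded replicates at full sizes with small variant
panels — chosen as the smallest problem sizes at which the binomial noise
of a pass criterion (e.g. ≥ 95% single-signal selection) is comfortably
resolved. The tobit-vs-OLS bias comparison uses 500 replicates at n = 500
and 30% censoring, where OLS attenuation (~0.04 on a 0.3 slope) exceeds
the tobit bias by several fold.

## Known limitations

* Two cohorts only; >2-cohort weights would be a trivial extension but are
  untested here, and no heterogeneity statistics (I², Q) are computed.
* The weighted meta statistic is conservative by construction; users who
  want calibrated null behavior under unequal n should use the classical
  option.
* Trio classification inherits accept-the-null logic and is only as good
  as its power; at these cohort sizes collide and complete are genuinely
  hard to separate, and confusion flows toward complete.
* Autosomal analysis only; no X-chromosome dosage conventions, no
  kinship/mixed models, no imputation to reference panels.
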