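---
title: "Methods: polygenic risk modulation of cannabis-associated psychotic experiences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic risk modulation of cannabis-associated psychotic experiences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Cannabis use is associated with self-reported psychotic experiences —
auditory and visual hallucinations, persecutory delusions, and delusions of
reference — and the association may be stronger in people genetically
predisposed to schizophrenia. `prsinteract` implements the full analysis
chain needed to ask that question in a genotyped, phenotyped cohort:

1. construct a schizophrenia polygenic risk score (PRS) from external GWAS
   summary statistics by pruning + thresholding;
2. estimate covariate-adjusted odds ratios (AORs) relating cannabis
   exposure to each psychotic-experience outcome;
3. test whether the PRS modulates those associations with a
   likelihood-ratio test (LRT) on the exposure-by-PRS product term,
   protected against covariate confounding.

Because the motivating data are restricted-access, the package ships a
synthetic-cohort generator with the statistical structure the analysis
assumes, so every stage is exercised end to end without any download.

## The synthetic cohort

### Genotypes

`simulate_genotypes()` draws biallelic autosomal SNPs in Hardy–Weinberg
equilibrium by construction: each individual receives two latent
haplotypes; within an LD block the latent normals follow an AR(1) process
with parameter `ld_rho`, and a haplotype carries the alternate allele
where its latent value falls below the MAF quantile (a Gaussian copula).
Marginally every variant is binomial(2, maf); adjacent variants within a
block are correlated. Dichotomizing the latent attenuates the correlation:
by Monte-Carlo calibration, latent 0.9 yields dosage Pearson r of about
0.66–0.71 across common MAFs, latent 0.6 about 0.33–0.41, latent 0.3 about
0.13–0.19. The block-and-window structure is deliberately simple — enough
to exercise LD pruning, not a model of human LD maps. Variants sit on one
chromosome at 10 kb spacing, so the default 500 kb pruning window spans
about 50 variants. A configurable fraction of variants receives
strand-ambiguous (A/T, C/G) allele pairs to exercise harmonization.

### External GWAS

`simulate_gwas_sumstats()` draws true per-allele log-odds-ratios
spike-and-slab (`causal_fraction` of variants get Normal(0, `effect_sd`)
effects) and observes them with Normal(0, se) noise, where
`se = 1/sqrt(2 N f (1-f))` is the standard approximation for a log-OR at
allele frequency `f` and GWAS size `N`; p-values are two-sided Wald. To
make harmonization non-trivial, a fraction of records is reported with
swapped alleles (beta negated, frequency flipped) and a fraction on the
complement strand.

### Phenotypes

`simulate_cohort_phenotypes()` builds, per individual:

* **genetic liability** — the standardized true-weight score over
  mean-imputed dosages;
* **schizophrenia status** — a liability-threshold model: liability plus
  independent standard-normal noise exceeding the `1 - scz_prevalence`
  quantile of the total (used only to select the PRS p-value threshold by
  AUC, mirroring how the score is validated against a diagnosed
  phenotype);
* **cannabis-use frequency** — an ordinal 0–4 (never/ever/monthly/weekly/
  daily) drawn by ordered thresholds on a latent normal correlated
  `gec_rho` with liability, so gene–environment correlation is a single
  parameter. The default category probabilities are the observed
  proportions in a 109,308-person biobank cohort (79.6% never, 13.4%
  ever-only, 2.4% monthly, 3.3% weekly, 1.3% daily);
* **four psychotic-experience items** — Bernoulli with logistic
  probability `beta0 + beta_exposure*X + beta_prs*L + beta_gxe*X*L +
  covariates`. Default intercepts are the logits of published never-user
  prevalences (auditory 1.3%, visual 2.8%, persecutory 0.6%, reference
  0.6%) and default exposure effects echo published per-risk-unit AORs
  (about 1.18–1.24). `pe_any` is derived, not simulated: 1 if any
  non-missing item is endorsed, missing only when all four are missing;
* **onset age, distress, help-seeking** — generated independently given
  any experience (uniform onset over 10–50 years; distress probability
  0.43 and help-seeking 0.23, echoing published ever-user proportions).
  No joint model is imposed because none is published; the independence
  null keeps the quality-dichotomy analyses honest;
* **a diagnosis flag** (1% by default) standing in for the
  psychotic-disorder exclusion applied at cohort assembly.

One global seed feeds named substreams (genotypes, sumstats, phenotypes),
so each stage can be regenerated independently and all outputs are
byte-reproducible.

### What the generator does *not* emulate

Realistic human LD, ancestry structure, relatedness, X-chromosome biology,
item correlation beyond the shared liability and exposure, and
genotype-imputation error models. Because the four items are conditionally
independent given the linear predictor, the derived `pe_any` baseline
(~5–6%) sits a little above the published 4.1% never-user figure, whose
items are positively correlated. Passing tests therefore demonstrate the
*procedures* are correct under a faithful-but-simplified generative model;
they do not certify performance on real biobank data.

## PRS construction

`build_prs()` follows the standard pruning + thresholding recipe:

1. **Variant QC** (`qc_filter_variants()`): non-duplicate, autosomal SNPs
   with call rate > 95%, exact Hardy–Weinberg p > 1e-10, minor allele
   frequency > 0.1%, imputation info > 0.8. All comparisons are strict
   (info exactly 0.8 fails). The HWE test is the exact conditional test
   (summing probabilities of heterozygote counts no more probable than
   observed, margins fixed), which is well defined at rare-variant counts
   where the chi-square approximation is not. Fractional (imputed)
   dosages are rounded to hard calls within tolerance 0.1 for this test;
   more-fractional variants are exempt from the HWE filter and logged.
2. **Harmonization** (`harmonize_sumstats()`): records match the panel by
   chromosome and position (IDs are labels only, robust to ID-version
   drift); orientation is resolved by exact allele match first, then
   complement-strand match; strand-ambiguous (palindromic) records,
   panel-missing records, and conflicting duplicates are dropped with
   per-reason tallies. When the effect allele is the panel reference
   allele, the score contribution `beta*(2 - dose)` is stored as weight
   `-beta` plus a per-variant offset `2*beta` — an exact algebraic
   identity, verified in tests.
3. **Threshold selection** (`select_p_threshold()`): candidates default to
   {0.05, 0.005, 0.0005, 0.00005}; each is thresholded, pruned, scored,
   and evaluated by AUC against schizophrenia status; the argmax wins,
   ties to the least strict candidate. Whether the published analysis
   computed its AUCs on pruned or unpruned scores is ambiguous (the steps
   are listed threshold-then-prune); both orders are exposed via
   `auc_on = "pruned"` (default) / `"unpruned"`.
4. **LD pruning** (`ld_prune()`): greedy scan in genome order; within a
   500 kb window (inclusive at both ends), any pair with dosage r² ≥ 0.5
   loses its larger-p member (position breaks ties). Which member to drop
   is not specified in the published recipe; keeping the smaller GWAS p
   maximizes retained association signal and matches common practice.
   The output is certified: no retained pair within the window reaches
   the r² threshold (brute-force checked in tests).
5. **Scoring** (`score_individuals()`): weight times alt-allele dose,
   summed, plus offsets; missing dosages are mean-imputed per variant
   within the scoring cohort; variants entirely missing are dropped with
   a warning.

The AUC (`concordance_auc()`) is the concordance statistic — the
probability a random case outranks a random control, ties counted one
half — computed by the midrank formula and tested against the all-pairs
definition.

## Association analysis

Three exposure codings: ever-use binary; "risk units" (never 0, ever 1,
monthly 2, weekly 3, daily 4); and per-category indicators against
never-use. Per-category AORs come from one model with indicator coding,
not four separate two-group fits, so all categories share a single
covariate adjustment (the published table is ambiguous on this; the
pairwise alternative is available by subsetting).

Fits use iteratively reweighted least squares (`stats::glm.fit`, binomial
logit, deviance tolerance 1e-10, 100 iterations), standard errors from the
inverse observed information, listwise deletion with exact accounting, and
categorical covariates expanded to k−1 indicators against their most
frequent level (deterministic, avoids sparse references). Wald 95%
intervals with z = 1.96 throughout. Apparent separation (any |beta| > 15)
is flagged, not corrected — at biobank-scale n this arises only in tiny
strata, which the tables mark as non-converged.

Derived outcome dichotomies implement complementary exclusion: the
early-onset regression (onset strictly before 18) codes adult-onset
individuals missing, and vice versa; distress and help-seeking pairs are
analogous. Differences between paired coefficients use the Z-test
`(b1-b2)/sqrt(se1^2+se2^2)` with a two-sided normal p-value.

## Interaction testing

`build_interaction_designs()` constructs nested designs sharing one row
mask: reduced = intercept + exposure + PRS + covariates + covariate×
exposure + covariate×PRS; full adds the single exposure×PRS product. The
covariate-interaction ("Keller") terms sit in *both* models so a
confounded covariate interaction cannot masquerade as a gene–environment
effect. The PRS is standardized to mean 0, SD 1 over the analysis rows
before any product is formed; this is numerically safer and provably
inconsequential — the LRT p is affine-invariant in the raw PRS (tested to
1e-6). Collinear columns are dropped pairwise from both designs so the
tested product term is always the sole extra column (df = 1).

"Interaction" here means the product term on the log-odds scale tested by
the LRT (`chi2 = 2*Δloglik` against chi-square), exactly as the model
comparison defines it; no additive-risk-scale (RERI) measure is computed.
BH correction (`bh_adjust()`, the step-up `min tail p*n/i` rule) is
applied within each exposure's family of five outcome tests by default,
mirroring how the published tables correct; `fdr_family = "joint"` pools
all ten.

PRS quintiles are assigned by rank with stable (input-order) tie-breaking,
so bin sizes never differ by more than one; within each quintile the
ever-use AOR is re-estimated with the same covariates minus all PRS terms
(the PRS is the stratifier).

## Numerical and design choices

* Positions are 1-based as in VCF; pruning windows are inclusive:
  |pos_i − pos_j| ≤ 500,000 counts as in-window.
* Missing tokens: "NA" written, "NA" or empty accepted on read.
* Cohort assembly applies exclusions in fixed order (diagnosis → missing
  exposure → all outcomes missing), attributing each row to its first
  failing rule so reports are deterministic and reconcile exactly.
* Never-users are assigned frequency 0 (they are never asked the
  frequency question).
* Constant-dosage variants have undefined correlation; pruning treats
  them as r² = 0 and scoring keeps them (they contribute a constant).
* A monomorphic variant has exact-HWE p = 1.

## Problem sizes used by the test-bench experiments

The statistical experiments in the test suite run at sizes chosen to give
each property adequate Monte-Carlo resolution:

* **Type-I error of the LRT**: 1,000 replicates of n = 2,000 cohorts with
  the interaction coefficient set to zero, a reduced covariate set (sex +
  one continuous), and the true standardized liability as the PRS column —
  the property under test is the *test's* size under the generative
  model; PRS estimation noise is exercised separately by the end-to-end
  experiments. Expected rejection at the 5% level within the 95% binomial
  band [0.037, 0.064].
* **Parameter recovery**: interaction log-OR 0.25, 100 replicates at
  n = 5,000; mean estimate within ±0.08 and 95% CI coverage in
  [0.92, 0.98].
* **Threshold-selection ordering**: the dense-weak-polygenic regime needs
  per-variant GWAS power low enough that lenient thresholds add true
  signal — effect SD 0.03 at GWAS n = 8,000 over 1,200 variants with 30%
  causal, evaluated on an n = 4,000 cohort with a case-enriched
  (prevalence 0.2) schizophrenia label for stable AUC estimation. Under
  strong per-variant power the ordering flattens, because the strictest
  thresholds already capture the signal; that regime is the complement of
  the one this experiment instantiates.
* **End-to-end**: the default 5,000 × 2,000 cohort runs the whole
  pipeline in well under a minute on one CPU; detection of a strong
  (0.25) interaction through the *estimated* PRS is checked over 20
  seeds at FDR 10%.

## Known limitations

* The generator's four outcome items are conditionally independent; real
  psychotic-experience items co-occur, so derived any-experience
  quantities are approximations.
* No survey weights, missing-covariate imputation, Firth correction, or
  reference-panel LD clumping; shrinkage PRS methods are out of scope.
* Quintile stratification with heavy ties splits tie blocks by input
  order rather than erroring; with meaningful PRS variation this is the
  behaviour one wants, but exactly tied scores straddling a boundary are
  assigned deterministically, not randomly.
* The exact HWE test requires hard calls; strongly fractional dosages
  bypass the HWE filter (logged) rather than being force-rounded.
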