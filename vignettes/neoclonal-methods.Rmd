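---
title: "Methods: neoantigen clonality, immune signatures, and context-dependent survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neoantigen clonality, immune signatures, and context-dependent survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A tumour's predicted neoantigen repertoire is read from a table of
peptide–HLA pairs, each carrying a predicted binding affinity (IC50,
nanomolar) and the variant allele frequency (VAF) of the source mutation.
Peptides with IC50 ≤ 500 nM are *binders*, ≤ 50 nM *strong binders*; both
thresholds are inclusive and follow the conventional cut-offs for MHC class
I presentation. The package's central quantity is the

* **binder-weighted VAF**: the sum of source-variant VAFs over all binder
  peptides. A mutation that yields several binder peptides contributes once
  per peptide, so the sum weights mutations by clonal prevalence *and*
  peptide yield; it scales with overall burden.

* **Clonality Score**: binder-weighted VAF divided by (binder count + 1).
  Dividing by the count removes the burden axis, leaving a VAF-weighted
  ranking of tumours from predominantly subclonal to predominantly clonal
  neoantigen origin. The +1 pseudocount keeps tumours with zero predicted
  binders at a well-defined score of 0. VAF is a proxy: it is confounded by
  tumour purity, ploidy and local copy number, so the score ranks tumours
  rather than estimating a cancer-cell fraction.

Four sensitivity variants (raw binder-weighted VAF, mean VAF per binder,
normalisation by total peptide count, and the natural log of the score with
an offset ε = 10⁻⁶, configurable) let analyses check that conclusions do
not hinge on the exact formulation; the log variant is a monotone transform
of the primary score, so rank-based analyses are unchanged by construction.

Composite immune signatures are geometric means of gene panels on a
TPM-like scale, `exp(mean(log(x + 0.01)))`. The 0.01 pseudocount avoids
undefined logarithms at zero expression and is applied uniformly to all
panels (configurable per panel); cytolytic activity (CYT) is the special
case of GZMA and PRF1 with the same offset. Eight panels are built in:
17-gene exhaustion, 6-gene core exhaustion, 17-gene antigen presentation,
6-gene MHC class I, 14-gene immunosuppression, 10-gene IFN-γ, a 13-gene
ESTIMATE-style infiltration composite, and CYT. Missing panel genes are
dropped and reported; below 80% panel coverage (configurable) the score is
NA rather than silently computed from a fragment. Whether composite scores
should tolerate incomplete panels at all was an open design question; we
chose drop-and-report because hard failure would make the scores unusable
on any expression matrix with trimmed annotation, while silent computation
would hide the problem.

## The statistical battery

Variables in this setting are heavily skewed, so association tests are
rank-based throughout: Spearman correlations with average ranks for ties
and a two-sided t-approximation on n − 2 degrees of freedom; Kruskal–Wallis
with tie correction and Dunn's post-hoc z tests; Mann–Whitney with exact
small-sample p-values where tie-free. Partial Spearman correlations are
computed by rank residualization: rank-transform both variables and the
covariate, regress each ranked variable on the ranked covariate by least
squares, and correlate the residuals (t on n − 3 df). On tie-free data this
equals the closed-form partial correlation of the ranks, which the test
suite verifies to 10⁻¹⁰. A covariate with zero rank variance degrades to the
plain correlation with a warning; a covariate rank-identical to either
variable is refused rather than returning a spurious number. Families of
correlations declared together are adjusted together with Benjamini–
Hochberg; each results table is treated as one family, since finer-grained
family definitions are a matter of analysis intent, not of the algorithm.
Missingness is handled by pairwise (not listwise) deletion so each
correlation uses every complete pair, and each result reports its own n.

Survival models use the Cox partial likelihood with the Efron tie
approximation (follow-up is recorded in days, so ties are expected).
Continuous covariates are z-standardised on each model's complete-case
subset, making hazard ratios per-SD comparable across terms; logical and
0/1 covariates pass through. The clonality × immune-context interaction is
the product of the two standardised main effects — not re-standardised — so
the main effects keep their per-SD reading. Immune context strata are
defined by the median of TIDE dysfunction on the analysis subset, with the
boundary value assigned to the hot stratum; the median is always recomputed
from the data at hand, never hard-coded from any particular cohort. The
four-phenotype classification splits Pan-Immune Score and Clonality Score
at their medians (again ≥ goes to the hot/high side, medians computed on
the classified complete cases), and the categorical survival model
dummy-codes the four labels with Hot/LowClonality as reference.

Unsupervised validation clusters z-standardised (Clonality, TIDE
dysfunction) pairs: k-means with 25 random restarts under a fixed seed, and
full-covariance Gaussian mixtures with BIC for model selection (argmin of
−2 log L + k log n) and AIC reported alongside. Concordance with the
median-split labels uses the Adjusted Rand Index; hot/cold concordance
between alternative immune scores uses percent agreement and Cohen's kappa.
The ARI reference defaults to the labels built on the same feature pair as
the clustering, since comparing partitions across different feature spaces
conflates disagreement about structure with disagreement about features.

## Public peptides and coverage

A peptide is *public* when its exact sequence is predicted in at least two
distinct patients (sequence identity only by default; an allele-matched
mode additionally requires a shared HLA restriction, for the stricter
reading under which a shared peptide is only actionable with a shared
presenting allele). The set-cover curve ranks patients by public-peptide
count (ties broken by patient id for reproducibility) and accumulates the
covered fraction of the public universe; a greedy marginal-gain ordering is
available behind a flag but the count-ranked curve is the default, matching
how such curves are usually reported. HLA "supertypes" here are allele
groups — gene letter plus first allele field (C07, A02, ...) — because the
coverage analysis groups patients by top-ranked restricting allele, with
the top allele defined as the binder-count argmax; a lookup table can
override the mapping. Each patient belongs to exactly one group via their
top allele, and "Other" is a real group that participates in combination
strategies.

## The synthetic cohort generator

`generate_cohort()` exists so the pipeline can be validated against ground
truth without redistributing controlled-access data. It is a first-class,
tested module, and its defaults are the package's statement of the study
conditions it emulates: a 527-patient head-and-neck-like cohort.

The core is a latent pair (C, I) — clonality and immune infiltration — from
a Gaussian copula. The target Spearman correlation (default −0.5) is hit
exactly in distribution via the conversion ρ_P = 2 sin(π ρ_S / 6). Every
observable is then a noisy function of the latents:

* **Mutations and VAFs.** Per-patient variant counts are negative binomial
  (mean 105 × exp(0.25 C), size 2, ≈ 2.8 mutations/Mb at 38 Mb covered —
  the scale of exome cohorts in this disease); the loading on C makes
  mutation burden rise with clonality, planting the positive
  clonality–TMB association. Each variant is clonal with probability
  plogis(0.3 + 1.2 C); clonal VAFs concentrate near purity/2
  (Beta(60, 4) multiplier — the heterozygous diploid approximation),
  subclonal VAFs sit below (Beta(3, 15) multiplier). Purity is
  Beta(300, 100) (mean 0.75). The purity spread and the mixture shapes are
  deliberately tight: they control how faithfully the computed Clonality
  Score reads the latent C (rank correlation ≈ 0.95 at these defaults),
  and the planted-correlation recovery checks assume a score that measures
  what was planted rather than drowning it in measurement noise. Real
  cohorts have wider purity distributions and correspondingly noisier
  scores; the generator is a validation instrument, not a purity model.
* **Peptides.** Poisson(3) peptides per variant, log-normal IC50
  (meanlog log 500, sdlog 1.4, so ≈ half of peptides are binders and
  ≈ 10% of binders are strong — the ratio seen in practice), lengths 8–11
  weighted toward 9-mers. A 400-peptide shared pool sampled with Zipf
  weights (exponent 1.2) at rate 0.08 creates a small public fraction with
  a realistic few-patients-cover-much skew; all other peptides are random
  amino-acid strings. HLA alleles are drawn per patient from a small
  frequency table in which HLA-C alleles dominate peptide restriction, so
  the supertype analyses see C-group-dominated structure.
* **Expression and scores.** log-expression = baseline + 0.8 I (+ −0.15 C
  on antigen-presentation genes, the planted APM deficit) + N(0, 0.4), so
  geometric-mean panel scores are approximately log-linear in I. TIDE
  dysfunction (0.8 I + N(0, 0.35)), Pan-Immune (0.9 I + N(0, 0.15)), TIDE
  exclusion (−0.5 I + noise) and CIBERSORT-like fractions (logistic link)
  are noisy monotone functions of I.
* **Survival.** Event times are exponential with log-hazard
  ln(1.3)·age_z + ln(0.88)·CS_z + ln(0.85)·CS_z·TIDE_z, computed from the
  cohort's *own* clonality score (identical formula to the analysis side),
  with independent exponential censoring (rates 1/1500 and 1/1600 per day,
  ≈ 50% events). The two clonality coefficients were chosen jointly so the
  implied per-SD effect is ≈ ln(0.77) in the hot half (E[TIDE_z | hot]
  ≈ 0.8) and ≈ 0 in the cold half — protective clonality confined to
  immune-hot tumours, with an interaction hazard ratio of 0.85.
* **Missingness** is applied last (HPV 1.3%, survival 8.5%, TIDE 1.1%,
  purity 7%), emulating the exclusion accounting a real merged cohort
  needs; the generator records how much it removed so the survival-subset
  bookkeeping can be checked exactly.

What the generator does *not* emulate: sequence-level realism beyond
alphabet validity, linkage between mutations, copy-number-driven VAF
distortion, batch structure in expression, or the marginal distributions of
any particular cohort. Passing the test suite therefore establishes that
the pipeline's algebra, ranking behaviour, calibration and determinism are
correct under the planted structure — not that any biological conclusion
transfers to real tumours.

## Numerical choices and degenerate inputs

Zero-binder patients get Clonality Score 0 and NA mean-VAF-per-binder;
mean ΔIC50 is the mean of log10(mutant/wild-type IC50) over peptides with
wild-type affinity (scale-free; a raw-difference convention is available)
and NA when no wild-type affinities exist. Ties: dominant genes and top
alleles break lexicographically with a warning; set-cover ranking breaks by
patient id. Duplicate (patient, peptide, allele, variant) rows keep the
first occurrence with a warning. Missing values are serialized as empty
TSV fields and read back as NA — never 0, never imputed — and numeric
columns round-trip at full precision (17 significant digits). All
randomness funnels through explicit seeds, and rerunning any stage with the
same inputs and seed is byte-identical.

Problem sizes used in the checks: the formula oracles run on hundreds of
small random instances; the planted-correlation and phenotype checks use a
2 000-patient cohort; interaction recovery and null calibration use 50–100
replicates of 400-patient survival simulations; the end-to-end determinism
check runs a 200-patient cohort twice. These sizes give the Monte-Carlo
bands quoted in the tests comfortable margins while keeping a full run of
the suite on one CPU in a couple of minutes.

## Limitations

The Clonality Score inherits every caveat of VAF: purity, ploidy and copy
number shift it, and it ranks rather than measures clonal architecture.
Bulk expression signatures conflate immune-cell abundance with per-cell
state, so "exhaustion" panels here track infiltration as much as
dysfunction. The public-peptide analysis treats predicted binders as
interchangeable with presented antigens, which they are not. And the
generator's planted structure is linear-Gaussian at heart; pipelines that
pass here can still misbehave on data with heavier tails, structured
missingness, or batch effects.
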