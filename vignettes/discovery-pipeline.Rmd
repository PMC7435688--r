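---
title: "Models and methods behind the gutsterol discovery pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the gutsterol discovery pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutsterol)
```

# Overview

`gutsterol` implements a metagenome-wide screen for microbial enzyme
families whose carriage explains a binary metabolite phenotype — modelled
on the search for the gut bacterial cholesterol dehydrogenases that
produce fecal coprostanol — plus the downstream statistics that connect
carriage ("encoder" status) to stool sterols and serum lipids. Because
the real cohorts behind such analyses are controlled-access and many
gigabytes in size, the package ships a synthetic-study generator that
reproduces the statistical structure the pipeline assumes, with a planted
ground truth. This vignette documents the models, the defaults and why
they were chosen, the numerical decisions, and what the synthetic tests
do and do not establish about real data.

# The discovery screen

## Sequence identity and clustering

The screen operates on clusters of homologous proteins rather than single
genes: divergent species carrying the same enzyme would otherwise each
contribute a weak, fragmented signal. Clustering is greedy and
CD-HIT-like:

* sequences are sorted longest-first (ties broken lexicographically by
  id, so the order is deterministic);
* each sequence joins the **first** existing representative it matches at
  the identity and coverage thresholds, otherwise it founds a new
  cluster (`best_match = TRUE` switches to best-scoring assignment);
* identity is counted as identical aligned residues divided by the
  **length of the shorter sequence**, and coverage as the aligned span of
  the shorter sequence over its length — the CD-HIT convention, applied
  to both the nucleotide catalog stage (95% identity / 90% coverage,
  inclusive `>=`) and the protein family stage (strictly `>` 50%
  identity, mirroring the ">50% amino-acid identity" convention).

The protein stage's coverage requirement is not fixed by convention, so
the package defaults to 50% coverage-of-shorter there; it is an explicit
argument throughout.

Alignments are ends-free ("overlap") global alignments computed with
`Biostrings::pairwiseAlignment`, scored +1 per match and +0.01 per
mismatch with affine gaps (open 10, extend 1). The nominally cleaner
match/mismatch scheme of +1/0 has a subtle flaw under ends-free
alignment: trimming a terminal mismatch is free, so coverage would be
under-reported for sequences that differ at their ends (a single
substitution in a 10-mer must give identity 0.9 with coverage 1.0, not
0.9/0.9). The +0.01 mismatch bonus makes the aligner retain terminal
mismatches while never changing which alignment maximizes the match
count; gap placement is unaffected because a gap pair still costs far
more than any run of mismatches gains.

Greedy clustering compares each incoming sequence against every existing
representative. To keep that affordable the package uses a **lossless
prefilter**: the score of a free-gap alignment (match 1, mismatch 0, no
gap penalty) equals the longest common subsequence, which upper-bounds
the match count of *any* alignment; if that bound, divided by the shorter
length, is below the identity threshold, the pair can be skipped without
risk. A counting k-mer filter, the usual engineering choice, is *not*
lossless at a 50% identity threshold (at 50% divergence no shared k-mer
is guaranteed), which is why the bound-based filter was preferred. For
unrelated proteins over the 20-letter alphabet the LCS fraction sits near
0.25, far below the 0.5 threshold, so almost all random pairs are
rejected by the prefilter alone.

## Detection, scoring, and prioritization

Counts are TPM-normalized per sample (counts divided by gene length, each
sample column rescaled to 1e6; all-zero samples stay zero). A cluster is
detected in a sample when any member gene has TPM > 0. Against the binary
coprostanol call, each cluster with at least 1% prevalence among the
paired samples receives the confusion counts and

$$\mathrm{sensitivity} = \frac{TP}{TP+FN}, \qquad
  \mathrm{specificity} = \frac{TN}{TN+FP},$$

with zero-denominator ratios reported as missing rather than zero.
Samples lacking either the metagenomic or the metabolomic measurement are
excluded (intersection semantics). Candidates are retained at strictly
`> 0.3` sensitivity and `> 0.9` specificity — the boundary values
themselves are rejected.

Candidates are then ranked by homology evidence. Query mapping is a
ublast-like local alignment (BLOSUM62, affine gaps 10/1), with identity
counted over alignment columns and coverage over the query; isolate
proteomes are mapped at ≥50% identity and characterized enzymes at the
inclusive ≥25%, both with ≥50% query coverage. Because the evidence
combination behind such funnels is rarely explicit, the package does not
guess a single rule: tier 1 requires the screen pass plus both hit types,
tier 2 exactly one, tier 3 the screen alone, with specificity then
sensitivity ordering within tiers. Scores are computed per cohort;
pooling cohorts before scoring is possible but not the default, since
detection rates differ systematically between cohorts.

# Host-association models

* **Odds ratios.** OR = ad/bc with the Woolf log-normal interval; any
  zero cell triggers the Haldane–Anscombe +0.5 correction of all cells,
  flagged in the result. Because the estimator behind published
  encoder/converter ORs is typically unstated, a conditional
  maximum-likelihood estimate with Fisher's exact interval is exposed as
  an alternative rather than asserting one method; the output labels
  which was used.
* **Metabolite transforms.** Abundances are log10-transformed with a 1e-5
  pseudo-count substituted for zeros, then z-scored with the sample
  (n−1) standard deviation, within cohort — never pooled across cohorts.
* **Regression.** `fit_linear` is ordinary least squares (via `lm`) with
  Wald tests; categorical covariates are dummy-coded against the first
  alphabetical level. `fit_logistic` is an in-package IRLS maximizing the
  binomial likelihood, converging on a log-likelihood change below 1e-8
  (at most 100 iterations); complete separation is detected from
  diverging coefficients or saturated fitted probabilities and raised as
  an error rather than returning meaningless estimates.
* **Repeated measures.** `fit_random_intercept` fits
  $y = X\beta + u_{g} + \varepsilon$, $u \sim N(0, \tau^2)$,
  $\varepsilon \sim N(0, \sigma^2)$ by maximum likelihood, profiling over
  $\lambda = \tau^2/\sigma^2$ with a closed-form GLS solve per $\lambda$
  (Woodbury identity per group) and a bounded one-dimensional
  optimization of $\log\lambda$ over [−15, 15]; the boundary
  $\tau^2 = 0$ is always compared against the interior optimum, so the
  mixed likelihood can never fall below the OLS-equivalent one. Wald
  tests use the GLS information matrix — a deliberate simplification
  relative to Satterthwaite degrees of freedom, adequate at the group
  counts simulated here. A logistic mixed model is out of scope;
  subject-level aggregation with `fit_logistic` is the documented
  workaround.
* **Multiple testing.** `adjust_bh` is the Benjamini–Hochberg step-up
  (delegating to `p.adjust`), order-preserving.

# Lipids, meta-analysis, quantification

Friedewald LDL is TC − HDL − TG/2.2 in mmol/L (divisor 5 in mg/dL mode);
triglycerides above 4.5 mmol/L violate the equation's validity and raise
an error, while negative LDL results are returned but flagged. Per-study
encoder effects are the encoder coefficient and standard error from a
covariate-adjusted linear model (age, sex, antibiotics, statin by
default; a named sensitivity mode adds CVD status and its interaction
with encoder status).

Pooling is inverse-variance random-effects with the DerSimonian–Laird
moment estimator — the historic default of the standard meta-analysis
software — with REML available behind a flag but never the default:

$$\tau^2 = \max\!\left(0,\ \frac{Q-(k-1)}{\sum w - \sum w^2 / \sum w}\right),
\qquad I^2 = \max\!\left(0, \frac{Q-(k-1)}{Q}\right)\times 100,$$

where $w = 1/\mathrm{se}^2$ and $Q$ is the fixed-effect heterogeneity
statistic. GWAS per-allele effects in SD units are converted to mmol/L by
multiplying with the trait SD of a reference cohort, reported to three
decimals as is conventional for per-allele lipid effects.

Targeted quantification is a free-intercept linear standard curve with
inverse prediction (optional dilution factor applied after inversion,
covering serial methanol dilutions) and molar ratios, each sterol's
concentration over the summed cholesterol + cholestenone + coprostanol
concentrations of the sample; an all-zero sample is an error, never 0/0.

# The synthetic-study generator

The generator is first-class, tested code; its defaults *are* the study
conditions the pipeline is designed around:

| parameter | default | rationale |
|---|---|---|
| samples / species / genes per species | 200 / 30 / 6 | a catalog small enough to cluster in seconds yet large enough that background families dominate the screen |
| encoder species | 4 | a small clade of related carriers |
| planted identity range | 0.55–0.90 to the root | a divergent family spanning roughly 50–95% pairwise identity |
| encoder clade mean relative abundance | 1.4% | observed average carriage abundance |
| encoder species prevalence | 0.16 each (clade ≈ 50% of samples) | middle of the 37–92% per-cohort clade prevalence range |
| coprostanol detection: delta / epsilon | 0.95 / 0.02 | near-deterministic conversion when a carrier is present; a small mechanism-agnostic background rate for positives without a known carrier (limit-of-detection or unknown distant homologs — the generator does not commit to either explanation) |
| stool cholesterol reduction | ×0.25–0.45 | 55–75% reduction in carriers |
| cholestenone fold increase | ×3.3–5.4 | observed fold-change range |
| serum TC encoder effect | −0.15 mmol/L | the planted host-level effect |
| TC noise sd | 0.9 mmol/L | a realistic serum TC standard deviation |
| covariates | age N(50, 12), sex Bern(0.5), antibiotics Bern(0.1), statin Bern(0.15) | documented, configurable defaults; effects 0.015 (age/yr, centered at 50), −0.3 (male), 0 (antibiotics), −1.0 (statin) mmol/L |
| counts | Poisson (negative-binomial size optional) | overdispersion off by default for simplicity |

Species presence is Bernoulli per sample; present species draw log-normal
abundances renormalized per sample. When encoder species are present,
their joint share is drawn log-normally with mean fixed at the configured
clade abundance and split among the present carriers, so the clade
calibrates exactly to its target. Gene counts have expectation
depth × species share × gene length / species gene content. One RNG
stream per study, seeded from the config and recorded in `config.json`;
identical config and seed give a byte-identical bundle.

**The planted family.** Variants of the root protein substitute along one
shared, randomly ordered divergence path: a variant with substitution
load *k* carries the first *k* family-wide substitutions. Members
therefore differ only by their difference in load, the nested structure
of a clade radiating from a common ancestor, and any two members share at
least `1 − (1 − low)` identity — which is what keeps a family planted at
0.55–0.90 identity to its root inside a single >50%-identity cluster, as
a real star-shaped family would be. Independent uniform substitutions
would instead produce mutual identities near the product of the
identities to the root and fragment the family. Indels (default 0.01 per
site, single residues, length change capped at 5%) are drawn per variant
but placed at least 100 residues apart and 60 from the termini: under
affine gap scores, clustered or terminal indels make gap recovery
unprofitable and can push realized alignment identity several points
below the substitution load, while well-separated indels keep the
realized identity within about 0.03 of the target.

**Repeated measures.** With `samples_per_participant > 1`, consecutive
samples share a participant and a Gaussian intercept (sd 0.3, log10
scale) on metabolite abundances, giving the random-intercept model
something real to estimate.

**What the generator does not emulate.** Read-level artifacts (FASTQ,
mapping error), assembly chimerism, phylogenetically realistic sequence
evolution, strain-level variation, compositional coupling between
species, and covariate–microbiome correlations (age and disease do not
shift carriage probability). Passing the planted-recovery tests therefore
demonstrates that the pipeline's logic is correct under its assumed
statistical structure — not that the thresholds are optimal for any real
cohort.

# Numerical choices and degenerate inputs

* TPM of an all-zero sample is all-zero, not an error; nonzero columns
  sum to 1e6 within 1e-6 relative tolerance.
* Undefined sensitivity or specificity (no positives / no negatives among
  paired samples) is `NA`, never 0.
* An empty sequence set clusters to an empty result; an empty query set
  maps to an empty hit table; a zero-sample study writes valid headered
  files.
* `odds_ratio` errors when a margin of the 2×2 table is zero (the +0.5
  correction cannot rescue an empty row or column); `molar_ratios` errors
  on an all-zero sample; `transform_metabolite` errors on constant input.
* Ties in greedy clustering are broken by id; ties in best-member query
  mapping by coverage then id.
* The profile-likelihood search runs on $\log\lambda \in [-15, 15]$ with
  tolerance 1e-10, bounds far outside any plausible variance ratio at the
  simulated group sizes.

# Problem sizes used in the tests

The recovery suite simulates twenty discovery studies of 200 samples and
30 species (4 carriers) and checks that the planted family passes the
0.3/0.9 screen and ranks tier-1 first in at least 18; interval coverage
uses 100 replicates at n = 300 (odds ratio 40) and 100 cohort triples of
n = 800 (TC effect −0.15 mmol/L, median I² below 10). Oracle-equivalence
suites compare pairwise identity to a full dynamic-programming alignment
on 100 random pairs, confusion counts to brute-force tallies on 1,000
vector pairs, and the DL, BH, OLS and random-intercept estimators to
independent closed forms, with `metafor` and `lme4` as external
cross-checks. These sizes keep the default test run to a few minutes on a
single CPU while leaving the Monte-Carlo margins wide.

# Known limitations

* The greedy clustering is order-dependent by design (CD-HIT semantics);
  the refinement property against single-linkage components is tested,
  but cluster boundaries near the identity threshold can differ from a
  best-match assignment.
* Local-alignment identity (per column) and global identity (per shorter
  sequence) are different quantities; query-mapping thresholds are not
  interchangeable with clustering thresholds.
* The Woolf interval is log-symmetric; strongly asymmetric published
  intervals suggest conditional methods, which is why the exact
  alternative is exposed.
* The random-intercept model covers Gaussian outcomes only, with normal
  Wald tests; no Satterthwaite correction, no crossed or nested designs.
* DerSimonian–Laird is known to underestimate $\tau^2$ for small k; REML
  is available but deliberately non-default.
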