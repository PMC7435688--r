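# gutsterol

Discovery of gut microbial cholesterol-metabolizing enzyme families from
paired metagenomics and metabolomics, with downstream host-association
statistics.

## The problem

Gut bacteria reduce cholesterol to coprostanol, a poorly absorbed sterol
that leaves the body in stool. The enzyme families responsible are largely
absent from reference genomes, so they must be found directly in assembled
metagenomes: the tell-tale signal is that a protein family's
presence/absence across samples tracks the detection of coprostanol in the
paired stool metabolome. `gutsterol` implements that discovery funnel as a
reusable, fully testable pipeline, together with the association and
meta-analysis machinery used to connect carriage of such enzymes
("encoder" status) to stool sterols and serum lipids. A synthetic-study
generator plants a known enzyme family in a simulated community so that
every stage can be verified against ground truth without any external
download.

## What it computes

**Screening.** Proteins are greedily clustered into families of homologs
(CD-HIT-style: longest first, join the first representative at >50%
amino-acid identity over the shorter sequence). A family is *detected* in
a sample when any member gene has TPM > 0. Against the binary coprostanol
call, each family receives

    sensitivity = TP / (TP + FN),    specificity = TN / (TN + FP)

with candidates retained at sensitivity > 0.3 and specificity > 0.9, then
prioritized into tiers by local-alignment homology (BLOSUM62) to isolate
proteomes (≥50% identity, ≥50% query coverage) and characterized enzymes
(≥25% identity, ≥50% coverage).

**Association.** Encoder/converter 2×2 tables give odds ratios with Woolf
intervals, `exp(log OR ± z·√(1/a+1/b+1/c+1/d))`, Haldane–Anscombe
corrected on zero cells (Fisher's exact interval available). Stool
metabolites are log10-transformed (pseudo-count 1e-5 for zeros),
z-scored, and modelled by OLS, IRLS logistic, or a profile-ML
random-intercept model for repeated measures.

**Lipids and meta-analysis.** Friedewald LDL = TC − HDL − TG/2.2 (mmol/L,
valid for TG ≤ 4.5); per-cohort encoder effects from covariate-adjusted
linear models; DerSimonian–Laird random-effects pooling with

    tau² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw)),   I² = max(0, (Q−(k−1))/Q)·100

and GWAS per-allele effects converted from SD units to mmol/L. Targeted
quantification utilities cover linear standard curves, inverse prediction
and sterol molar ratios.

## Worked example

```r
library(gutsterol)

cfg   <- simulation_config(n_samples = 200, seed = 1)
study <- simulate_study(cfg)
study
#> synthetic_study: 184 genes x 200 samples (30 species, 4 encoders)
#>   200 participants, seed 1; coprostanol positive in 105 samples

res <- run_discovery(study,
  genome_queries = c(isolate_proteome  = study$root_protein),
  enzyme_queries = c(characterized_hsd = simulate_enzyme_family(
    study$root_protein, 1, c(0.35, 0.40), seed = 2)))
res$clusters
#> cluster_set: 184 sequences in 181 clusters (identity >0.50, coverage 0.50, aa)
head(res$report, 3)
#>     cluster_id  TP FP TN FN sensitivity specificity prevalence has_genome_hit has_enzyme_hit tier
#> 1 cluster_0001 104  2 93  1        0.99       0.979      0.530           TRUE           TRUE    1
#> 2 cluster_0002  41  0 95 64        0.39       1.000      0.205          FALSE          FALSE    3
#> 3 cluster_0003  41  0 95 64        0.39       1.000      0.205          FALSE          FALSE    3
```

The planted family (`cluster_0001`) is the unique tier-1 candidate: it
passes the 0.3/0.9 screen and is hit by both homology queries. Carriage of
the family is then tied to converter status and serum lipids:

```r
tpm <- compute_tpm(study$counts,
                   setNames(study$gene_info$length_nt, study$gene_info$gene_id))
det <- detection_matrix(tpm, res$clusters)
cls <- classify_samples(det[planted_cluster_id(res$clusters, study), , drop = FALSE],
                        metabolite_calls(study$metabolites))
odds_ratio(contingency_counts(cls))
#> OR = 4836.00 [95% CI: 431.45, 54205.72] (woolf)

set.seed(3)
eff <- do.call(rbind, lapply(1:3, function(i) {
  ph <- simulate_host_phenotypes(runif(800) < 0.5, cfg, seed = NULL)
  study_effect(ph, "TC", study = paste0("cohort_", i))
}))
meta_random_effects(eff$estimate, eff$se, labels = eff$study)
#>      study estimate     se ci_low ci_high weight
#> 1 cohort_1  -0.0978 0.0646 -0.224 0.02877  0.321
#> 2 cohort_2  -0.1066 0.0641 -0.232 0.01915  0.325
#> 3 cohort_3  -0.1159 0.0615 -0.237 0.00463  0.354
#> pooled = -0.107 [-0.179, -0.035]; tau^2 = 0.0000, Q = 0.042, I^2 = 0.0%
```

The simulated odds ratio is far larger than anything estimable in a real
cohort because the synthetic coupling between carriage and conversion is
nearly deterministic at these settings; the pooled total-cholesterol
difference estimates the planted −0.15 mmol/L encoder effect within its
interval. See `vignette` sources under `vignettes/` for the full account
of the models and generator.

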