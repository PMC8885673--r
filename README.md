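# probindex

Analysis toolkit for a paired (pre/post) probiotic supplementation pilot
trial in unaffected siblings of type 1 diabetes patients, where systemic
inflammation is read out by **plasma-induced transcription**: a fixed
healthy donor's PBMC are cultured with each subject's plasma and the induced
transcriptome, measured on expression arrays, reports on plasma-borne
immune mediators.

The central statistic is the **composite inflammatory index**

```
I.I.com = mean(log2 intensity, inflammatory probe set)
          ---------------------------------------------
          mean(log2 intensity, regulatory probe set)
```

computed over a 1,374-probe signature split into 307 inflammatory and 1,067
regulatory transcripts. High values mean inflammatory bias; low values mean
regulatory bias. Around it the package provides the trial's full analysis
chain:

* per-subject index scoring, percent change, and ±5% responder bins
  (strict inequalities), with the one-tailed paired t-test on the cohort;
* paired per-transcript differential induction with Benjamini–Hochberg FDR
  restricted to the index probe set, fold-change signatures, reference
  signature correlation, and a signed-network upstream-regulator activation
  z-score (z = (agree − disagree)/√overlap, |z| ≥ 2 significant);
* taxonomy-aware OTU-table analysis: rank collapsing with mapped-fraction
  reporting, Shannon/richness alpha diversity, Bray–Curtis + PCoA beta
  diversity, and LDA-effect-size (LEfSe-style) differential abundance at
  |LDA| ≥ 2.0, p ≤ 0.05;
* paired Wilcoxon signed-rank statistics on cytokine/chemokine/SCFA panels
  with the trial's change-table filter (|change| > 5%, p < 0.2), the
  ≥ 2-autoantibody subgroup exclusion, dietary fiber standardised to the
  IOM target (14 g / 1000 kcal/day), memory:naive CD4 ratios, and Pearson
  correlations with index change;
* a seeded synthetic-cohort generator that emulates every input at the
  trial's scale (25 paired subjects, 173 OTUs, planted mediator effects),
  so the whole pipeline runs and is tested without any external data.

## Worked example

```r
library(probindex)

design <- cohort_design(n_subjects = 25, seed = 1)   # trial-scale cohort
sim    <- simulate_expression(design, expression_effect_model())
scored <- score_cohort(sim$matrix, sim$partition, sim$pairs, threshold = 5)

mean(scored$iicom_pre)   # 1.014022
mean(scored$iicom_post)  # 0.8979741
table(scored$responder_class)
#> reduced  stable increased
#>      25       0         0
paired_t_one_tailed(scored$iicom_pre, scored$iicom_post, "less")$p_value
#> 6.230015e-38
```

The planted anti-inflammatory effect (−0.6 log2 on inflammatory probes,
+0.1 on regulatory) lowers the cohort index from 1.01 to 0.90 — about an
11% reduction — and every simulated subject crosses the −5% responder
threshold because the generator's shift is uniform across subjects (real
cohorts are more heterogeneous; see the methods vignette). Downstream:

```r
res <- paired_differential_test(sim$matrix, sim$pairs, fdr_rate = 0.20)
sum(res$passes_fdr)      # 1197 of 1374 probes at FDR < 20%

otus <- simulate_otu_table(community_effect_model(), seed = 1001)
fam  <- collapse_to_rank(otus, "family")
lefse <- lda_effect_size(fam, attr(otus, "visit"), seed = 2)
abs(subset(lefse, significant & grepl("Lachnospiraceae", feature))$lda_score)
#> 4.625964  (post-enriched, as planted)
```

The numbered drivers under `analysis/` run the same stages as a narrative
workflow (`01_simulate.R` … `05_mediators_covariates.R`), writing their
tables under `results/`.

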