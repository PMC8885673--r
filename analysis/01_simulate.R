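#!/usr/bin/env Rscript
# Stage 1: generate the synthetic paired cohort — expression arrays, gene-set
# partition, subject metadata, OTU table, analyte panels, diet and T-cell
# covariates — and write them in the interchange formats the later stages
# read. One master seed drives everything.

suppressMessages(library(probindex))
seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- cohort_design(seed = seed)            # 25 paired subjects
expr <- simulate_expression(design, expression_effect_model())
write_expression_tsv(expr$matrix, file.path(out, "expression.tsv"))
write_partition_gmt(expr$partition, file.path(out, "index_sets.gmt"))
write.csv(expr$pairs, file.path(out, "subjects.csv"), row.names = FALSE)

otus <- simulate_otu_table(community_effect_model(), seed = seed + 1000L)
write_otu_tsv(otus, file.path(out, "otu_table.tsv"))
write.csv(data.frame(sample_id = colnames(otus$counts),
                     visit = attr(otus, "visit")),
          file.path(out, "otu_sample_visits.csv"), row.names = FALSE)

# covariates are coupled to the realised index change, so score first
scored <- score_cohort(expr$matrix, expr$partition, expr$pairs)
cov <- simulate_covariates(design, scored$percent_change, seed = seed + 3000L)
write.csv(cov$ffq, file.path(out, "ffq.csv"), row.names = FALSE)
write.csv(cov$tcell, file.path(out, "tcell_frequencies.csv"), row.names = FALSE)
write.csv(cov$panel, file.path(out, "mediator_panel.csv"), row.names = FALSE)
write.csv(cov$scfa, file.path(out, "scfa_panel.csv"), row.names = FALSE)

cat(sprintf("wrote synthetic cohort (n = %d subjects, %d probes, %d OTUs) to %s\n",
            design$n_subjects, nrow(expr$matrix), nrow(otus$counts), out))
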