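#!/usr/bin/env Rscript
# Stage 5: paired mediator/SCFA statistics with the trial's change-table
# filter (|change| > 5%, p < 0.2), the multi-autoantibody sensitivity
# analysis for butyrate, and diet / CD4 T-cell correlations with index
# change.

suppressMessages(library(probindex))
dat <- "results/data"
out <- "results/tables"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel <- read.csv(file.path(dat, "mediator_panel.csv"))
scfa <- read.csv(file.path(dat, "scfa_panel.csv"))
scored <- read.csv(file.path(out, "index_per_subject.csv"))

med <- mediator_change_table(panel, abs_change_threshold = 5, p_threshold = 0.2)
write.csv(med, file.path(out, "mediator_change_table.csv"), row.names = FALSE)
cat(sprintf("mediators retained by the |change| > 5%%, p < 0.2 filter: %d\n",
            nrow(med)))
print(transform(med, percent_change = round(percent_change, 1),
                pre_mean = round(pre_mean, 1), post_mean = round(post_mean, 1),
                p_value = signif(p_value, 2)), row.names = FALSE)

but <- scfa[scfa$analyte == "butyrate", ]
pre_m <- mean(but$value[but$visit == "pre"])
post_m <- mean(but$value[but$visit == "post"])
cat(sprintf("butyrate: %.2f -> %.2f uM, %.2f-fold\n",
            pre_m, post_m, fold_change_of_means(pre_m, post_m)))

# sensitivity: drop subjects with >= 2 autoantibodies, one-tailed paired t
but <- merge(but, scored[, c("subject_id", "autoantibody_count")])
kept <- exclude_subgroup(but)
w <- merge(kept[kept$visit == "pre", c("subject_id", "value")],
           kept[kept$visit == "post", c("subject_id", "value")],
           by = "subject_id", suffixes = c("_pre", "_post"))
tt <- paired_t_one_tailed(w$value_pre, w$value_post, "greater")
cat(sprintf("butyrate after excluding %d multi-autoantibody subjects: p = %.3f (paired t, 1-tail)\n",
            length(attr(kept, "removed_subjects")), tt$p_value))

# diet: fiber standardized to the IOM target (14 g / 1000 kcal/day)
ffq <- read.csv(file.path(dat, "ffq.csv"))
pct_iom <- fiber_percent_of_iom_target(ffq$fiber_g_per_day, ffq$kcal_per_day)
fr <- pearson_with_p(pct_iom, scored$percent_change)
cat(sprintf("fiber %%IOM vs index change: r = %.3f, p = %.3f (%.0f%% reach the target)\n",
            fr$r, fr$p_value, 100 * mean(pct_iom >= 100)))

# CD4 T cells: memory:naive ratio change vs index change
tc <- read.csv(file.path(dat, "tcell_frequencies.csv"))
ratio <- memory_naive_ratio(tc$pct_memory, tc$pct_naive)
rc <- percent_change(ratio[tc$visit == "pre"], ratio[tc$visit == "post"])
tr <- pearson_with_p(rc, scored$percent_change)
cat(sprintf("memory:naive ratio change vs index change: r = %.2f, p = %.3f\n",
            tr$r, tr$p_value))
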