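#' Baseline cohort summary
#'
#' Continuous characteristics are summarised as mean (sd); categoricals as
#' frequency (%) over non-missing values; adherence additionally as mean,
#' median and range. With a single subject the sd is reported as absent
#' (NA), not zero.
#'
#' @param subjects data frame of subject metadata (as produced by
#'   [simulate_expression()]'s `pairs`): columns among `age`, `sex`,
#'   `hla_risk`, `autoantibody_count`, `adherence` are summarised when
#'   present.
#' @return a `cohort_summary` list with `n`, `continuous` (per-variable
#'   mean/sd), `categorical` (per-variable count/percent tables) and
#'   `adherence` (mean/median/range).
#' @export
summarize_cohort <- function(subjects) {
  if (nrow(subjects) == 0L) stop("empty cohort")
  n <- nrow(subjects)
  cont_vars <- intersect(c("age"), names(subjects))
  continuous <- lapply(subjects[cont_vars], function(x) {
    x <- x[!is.na(x)]
    list(n = length(x), mean = mean(x),
         sd = if (length(x) > 1L) stats::sd(x) else NA_real_)
  })
  cat_vars <- intersect(c("sex", "hla_risk", "autoantibody_count"), names(subjects))
  categorical <- lapply(subjects[cat_vars], function(x) {
    x <- x[!is.na(x)]
    tab <- table(x)
    data.frame(level = names(tab), count = as.integer(tab),
               percent = 100 * as.integer(tab) / length(x),
               stringsAsFactors = FALSE)
  })
  adherence <- if ("adherence" %in% names(subjects)) {
    a <- subjects$adherence[!is.na(subjects$adherence)]
    list(mean = mean(a), median = stats::median(a), range = range(a))
  } else NULL
  structure(list(n = n, continuous = continuous, categorical = categorical,
                 adherence = adherence),
            class = "cohort_summary")
}

#' Run the full synthetic-trial analysis pipeline
#'
#' Executes the stages in order — cohort summary, index scoring and paired
#' test, differential induction with FDR control, microbiome diversity and
#' LDA-effect-size contrasts, mediator/SCFA paired statistics, covariate
#' correlations — on a cohort generated from one seed, and writes every
#' table plus a machine-readable JSON manifest of the headline statistics
#' (with md5 hashes of the written inputs). Identical config and seed give
#' identical manifests.
#'
#' @param seed integer master seed; stage seeds are derived from it.
#' @param output_dir directory for tables and the manifest (created if
#'   needed); `NULL` skips writing.
#' @param design,expr_model,otu_model component models; defaults are the
#'   trial-scale study conditions.
#' @param fdr_rate,responder_threshold,lefse_alpha,lefse_cutoff,
#'   mediator_change_threshold,mediator_p_threshold analysis thresholds
#'   (defaults are the trial's printed values).
#' @return invisible list with all stage results and the manifest.
#' @export
run_pipeline <- function(seed = 1L, output_dir = NULL,
                         design = cohort_design(seed = seed),
                         expr_model = expression_effect_model(),
                         otu_model = community_effect_model(),
                         fdr_rate = 0.20, responder_threshold = 5,
                         lefse_alpha = 0.05, lefse_cutoff = 2.0,
                         mediator_change_threshold = 5,
                         mediator_p_threshold = 0.2) {
  design$seed <- as.integer(seed)
  # stage 1: cohort + expression
  expr <- simulate_expression(design, expr_model)
  cohort <- summarize_cohort(expr$pairs)
  scored <- score_cohort(expr$matrix, expr$partition, expr$pairs,
                         threshold = responder_threshold)
  index_test <- paired_t_one_tailed(scored$iicom_pre, scored$iicom_post,
                                    direction = "less")
  responder_counts <- table(scored$responder_class)

  # stage 2: differential induction among index probes
  diff <- paired_differential_test(expr$matrix, expr$pairs,
                                   subset = c(expr$partition$inflammatory,
                                              expr$partition$regulatory),
                                   fdr_rate = fdr_rate)
  n_pass <- sum(diff$passes_fdr)

  # stage 3: microbiome
  otus <- simulate_otu_table(otu_model, seed = seed + 1000L)
  visit <- attr(otus, "visit")
  fam <- collapse_to_rank(otus, "family")
  alpha_div <- data.frame(
    sample_id = colnames(otus$counts), visit = visit,
    shannon = apply(otus$counts, 2L, shannon_index),
    richness = apply(otus$counts, 2L, richness),
    stringsAsFactors = FALSE)
  bc <- bray_curtis_matrix(otus)
  ord <- pcoa_ordination(bc)
  lefse <- lda_effect_size(fam, visit, alpha = lefse_alpha,
                           lda_cutoff = lefse_cutoff, seed = seed + 2000L)

  # stage 4: mediators, SCFAs, covariates
  cov <- simulate_covariates(design, scored$percent_change,
                             seed = seed + 3000L)
  med_table <- mediator_change_table(cov$panel,
                                     abs_change_threshold = mediator_change_threshold,
                                     p_threshold = mediator_p_threshold)
  but <- cov$scfa[cov$scfa$analyte == "butyrate", ]
  but_pre <- but$value[but$visit == "pre"]
  but_post <- but$value[but$visit == "post"]
  butyrate_fold <- fold_change_of_means(mean(but_pre), mean(but_post))
  pct_iom <- fiber_percent_of_iom_target(cov$ffq$fiber_g_per_day,
                                         cov$ffq$kcal_per_day)
  fiber_corr <- pearson_with_p(pct_iom, scored$percent_change)
  tc <- cov$tcell
  ratio <- memory_naive_ratio(tc$pct_memory, tc$pct_naive)
  r_pre <- ratio[tc$visit == "pre"]
  r_post <- ratio[tc$visit == "post"]
  ratio_change <- percent_change(r_pre, r_post)
  tcell_corr <- pearson_with_p(ratio_change, scored$percent_change)

  results <- list(cohort = cohort, scored = scored, index_test = index_test,
                  responder_counts = responder_counts, differential = diff,
                  alpha_diversity = alpha_div, bray_curtis = bc,
                  pcoa = ord, lefse = lefse, mediator_table = med_table,
                  covariates = cov)

  manifest <- list(
    seed = as.integer(seed),
    n_subjects = design$n_subjects,
    iicom_pre_mean = mean(scored$iicom_pre),
    iicom_post_mean = mean(scored$iicom_post),
    iicom_paired_p_one_tailed = index_test$p_value,
    responders_reduced = unname(responder_counts[["reduced"]]),
    responders_stable = unname(responder_counts[["stable"]]),
    responders_increased = unname(responder_counts[["increased"]]),
    n_probes_tested = nrow(diff),
    n_probes_fdr_pass = n_pass,
    fraction_fdr_pass = n_pass / nrow(diff),
    shannon_mean_pre = mean(alpha_div$shannon[visit == "pre"]),
    shannon_mean_post = mean(alpha_div$shannon[visit == "post"]),
    n_lefse_significant = sum(lefse$significant),
    mediator_rows_retained = if (is.null(med_table)) 0L else nrow(med_table),
    butyrate_fold_change = butyrate_fold,
    fiber_iicom_pearson_r = fiber_corr$r,
    tcell_ratio_iicom_pearson_r = tcell_corr$r)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      expression = file.path(output_dir, "expression.tsv"),
      otu = file.path(output_dir, "otu_table.tsv"),
      scored = file.path(output_dir, "index_per_subject.csv"),
      differential = file.path(output_dir, "differential_induction.tsv"),
      alpha = file.path(output_dir, "alpha_diversity.csv"),
      lefse = file.path(output_dir, "lda_effect_size.tsv"),
      mediators = file.path(output_dir, "mediator_change_table.csv"))
    write_expression_tsv(expr$matrix, paths[["expression"]])
    write_otu_tsv(otus, paths[["otu"]])
    utils::write.csv(scored, paths[["scored"]], row.names = FALSE)
    utils::write.table(diff, paths[["differential"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.csv(alpha_div, paths[["alpha"]], row.names = FALSE)
    utils::write.table(lefse, paths[["lefse"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.csv(if (is.null(med_table)) data.frame() else med_table,
                     paths[["mediators"]], row.names = FALSE)
    manifest$input_hashes <- as.list(tools::md5sum(unname(paths)))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  results$manifest <- manifest
  invisible(results)
}
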