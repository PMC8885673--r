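#' Composite inflammatory index (I.I.com)
#'
#' The composite inflammatory index summarises a plasma-induced transcription
#' profile as the ratio of the mean log2 intensity of an "inflammatory" probe
#' set to the mean log2 intensity of a "regulatory" probe set. High values
#' indicate inflammatory bias of the induced transcriptome; low values indicate
#' regulatory bias. The default mode computes one ratio over the full
#' partition. In grouped mode, when the partition carries per-probe subset
#' labels (the index was originally built from several discovery data
#' subsets), the ratio is computed within each subset and the unweighted mean
#' of the per-subset ratios is returned.
#'
#' The ratio of mean *log* intensities is not invariant to rescaling of the
#' raw intensities: adding a constant c to every log intensity maps a ratio
#' a/b to (a+c)/(b+c). Matrices must therefore share a normalisation (the
#' arrays behind this assay are globally median-normalised) before index
#' values are compared across samples.
#'
#' @param matrix numeric matrix of log2 intensities, probes in rows (rownames
#'   are probe ids), samples in columns (colnames are sample ids).
#' @param partition a gene-set partition as returned by
#'   [gene_set_partition()]: list with character vectors `inflammatory` and
#'   `regulatory`, and optionally `subset_label`, a named character vector
#'   mapping probe id to a subset tag.
#' @param sample_id column to score.
#' @param grouped if `TRUE` and the partition carries subset labels, average
#'   the per-subset ratios; otherwise one global ratio.
#' @param log_scale if `FALSE`, means are taken on the raw (2^x) scale
#'   instead of the log2 scale.
#' @return the index value, a positive unitless ratio.
#' @export
compute_iicom <- function(matrix, partition, sample_id,
                          grouped = FALSE, log_scale = TRUE) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  if (!sample_id %in% colnames(matrix)) {
    stop("sample '", sample_id, "' not found in expression matrix")
  }
  probes <- c(partition$inflammatory, partition$regulatory)
  missing <- setdiff(probes, rownames(matrix))
  if (length(missing) > 0L) {
    stop("probes absent from expression matrix: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) sprintf(" (+%d more)", length(missing) - 10L) else "")
  }
  x <- matrix[, sample_id]
  if (!log_scale) x <- 2^x
  ratio_for <- function(inf_ids, reg_ids) {
    denom <- mean(x[reg_ids])
    if (denom == 0) stop("mean regulatory intensity is zero; index undefined")
    mean(x[inf_ids]) / denom
  }
  if (grouped && !is.null(partition$subset_label)) {
    lab <- partition$subset_label
    subsets <- sort(unique(lab))
    ratios <- vapply(subsets, function(s) {
      ids <- names(lab)[lab == s]
      ratio_for(intersect(partition$inflammatory, ids),
                intersect(partition$regulatory, ids))
    }, numeric(1))
    mean(ratios)
  } else {
    ratio_for(partition$inflammatory, partition$regulatory)
  }
}

#' Construct a gene-set partition
#'
#' @param inflammatory,regulatory disjoint, non-empty character vectors of
#'   probe ids. The trial's index uses 307 inflammatory and 1,067 regulatory
#'   probes (1,374 in total).
#' @param subset_label optional named character vector (names are probe ids)
#'   tagging each probe with its discovery data subset, enabling grouped-mode
#'   scoring.
#' @return a `gene_set_partition` list.
#' @export
gene_set_partition <- function(inflammatory, regulatory, subset_label = NULL) {
  if (length(inflammatory) == 0L || length(regulatory) == 0L) {
    stop("both probe sets must be non-empty")
  }
  if (length(intersect(inflammatory, regulatory)) > 0L) {
    stop("inflammatory and regulatory probe sets must be disjoint")
  }
  structure(list(inflammatory = as.character(inflammatory),
                 regulatory = as.character(regulatory),
                 subset_label = subset_label),
            class = "gene_set_partition")
}

#' Percent change between paired index values
#'
#' @param pre,post index values (pre must be nonzero).
#' @return 100 * (post - pre) / pre, sign preserved.
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0)) stop("pre value is zero; percent change undefined")
  100 * (post - pre) / pre
}

#' Classify a subject's index response
#'
#' Subjects are binned by percent change in the index: below -threshold is
#' `"reduced"`, above +threshold is `"increased"`, otherwise `"stable"`.
#' Inequalities are strict, so a change of exactly +/- threshold is stable.
#'
#' @param percent_change percent change(s) in the index.
#' @param threshold positive percent threshold (default 5, the trial's
#'   responder definition).
#' @return factor with levels reduced, stable, increased.
#' @export
classify_responder <- function(percent_change, threshold = 5) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive percent")
  }
  cls <- ifelse(percent_change < -threshold, "reduced",
                ifelse(percent_change > threshold, "increased", "stable"))
  factor(cls, levels = c("reduced", "stable", "increased"))
}

#' One-tailed paired t-test
#'
#' Classical paired t on post - pre differences with a declared direction.
#' The direction is an analysis choice fixed in advance (the trial's primary
#' outcome was a one-tailed test of index reduction); it is never inferred
#' from the data.
#'
#' @param pre,post equal-length numeric vectors (n >= 3).
#' @param direction `"less"` tests post < pre; `"greater"` tests post > pre.
#' @return list with `statistic` (t), `p_value`, `df`, `mean_difference`.
#' @export
paired_t_one_tailed <- function(pre, post, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  if (length(pre) < 3L) stop("need at least 3 pairs")
  d <- post - pre
  if (all(d == 0)) stop("all paired differences are zero; test degenerate")
  if (stats::sd(d) == 0) {
    # identical nonzero shift in every pair: t is infinite in the shift's
    # direction and the one-tailed p degenerates to 0 or 1
    t_inf <- sign(mean(d)) * Inf
    p <- if ((direction == "less") == (mean(d) < 0)) 0 else 1
    return(list(statistic = t_inf, p_value = p, df = length(d) - 1L,
                mean_difference = mean(d)))
  }
  ht <- stats::t.test(post, pre, paired = TRUE, alternative = direction)
  list(statistic = unname(ht$statistic),
       p_value = ht$p.value,
       df = unname(ht$parameter),
       mean_difference = unname(ht$estimate))
}

#' Score every subject of a paired cohort
#'
#' Computes the index for each subject's pre and post sample, the percent
#' change, and the responder class.
#'
#' @param matrix expression matrix (probes x samples, log2).
#' @param partition [gene_set_partition()].
#' @param pairs data frame with columns `subject_id`, `pre_sample_id`,
#'   `post_sample_id` (extra metadata columns are carried through).
#' @param threshold responder percent threshold.
#' @inheritParams compute_iicom
#' @return data frame, one row per subject, with `iicom_pre`, `iicom_post`,
#'   `percent_change`, `responder_class` appended.
#' @export
score_cohort <- function(matrix, partition, pairs, threshold = 5,
                         grouped = FALSE) {
  stopifnot(all(c("subject_id", "pre_sample_id", "post_sample_id") %in% names(pairs)))
  pre <- vapply(pairs$pre_sample_id, function(s)
    compute_iicom(matrix, partition, s, grouped = grouped), numeric(1))
  post <- vapply(pairs$post_sample_id, function(s)
    compute_iicom(matrix, partition, s, grouped = grouped), numeric(1))
  pc <- percent_change(pre, post)
  out <- pairs
  out$iicom_pre <- unname(pre)
  out$iicom_post <- unname(post)
  out$percent_change <- unname(pc)
  out$responder_class <- classify_responder(pc, threshold)
  out
}
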