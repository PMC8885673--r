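#' Per-subject fold-change signature
#'
#' Post minus pre log2 intensity per probe for one subject: the per-probe
#' log2 fold change of induced transcription after supplementation.
#'
#' @param matrix expression matrix (probes x samples, log2).
#' @param pre_sample_id,post_sample_id column names of the subject's pre and
#'   post samples.
#' @return named numeric vector of log2 fold changes (one per probe).
#' @export
fold_change_signature <- function(matrix, pre_sample_id, post_sample_id) {
  for (s in c(pre_sample_id, post_sample_id)) {
    if (!s %in% colnames(matrix)) stop("sample '", s, "' not found in matrix")
  }
  matrix[, post_sample_id] - matrix[, pre_sample_id]
}

#' Paired differential-induction test with FDR control
#'
#' Per-probe paired test of post vs pre induction over subjects, with
#' Benjamini-Hochberg adjustment restricted to the tested probe subset. With
#' exactly two paired conditions the per-probe ANOVA reduces to the paired
#' t-test (F = t^2), which is what is computed. A probe passes at the
#' configured false-discovery rate iff its q-value is strictly below the rate.
#'
#' @param matrix expression matrix (probes x samples, log2).
#' @param pairs data frame with `pre_sample_id` and `post_sample_id` columns,
#'   one row per subject (>= 3 subjects).
#' @param subset probe ids to test and to adjust over; defaults to all rows.
#'   Adjusting within the index probe set (rather than array-wide) matches
#'   reporting the number of differentially induced index transcripts.
#' @param fdr_rate false-discovery rate (default 0.20).
#' @return data frame with columns `probe_id`, `mean_log_fold_change`
#'   (post - pre averaged over subjects), `p_value`, `q_value`, `passes_fdr`.
#' @export
paired_differential_test <- function(matrix, pairs, subset = rownames(matrix),
                                     fdr_rate = 0.20) {
  if (length(subset) == 0L) stop("probe subset is empty")
  if (nrow(pairs) < 3L) stop("need at least 3 subject pairs")
  missing <- setdiff(subset, rownames(matrix))
  if (length(missing) > 0L) {
    stop("subset probes absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  pre <- matrix[subset, pairs$pre_sample_id, drop = FALSE]
  post <- matrix[subset, pairs$post_sample_id, drop = FALSE]
  d <- post - pre
  n <- ncol(d)
  mean_d <- rowMeans(d)
  sd_d <- apply(d, 1L, stats::sd)
  tstat <- mean_d / (sd_d / sqrt(n))
  p <- 2 * stats::pt(abs(tstat), df = n - 1L, lower.tail = FALSE)
  p[sd_d == 0 & mean_d == 0] <- 1  # constant zero difference: no evidence
  q <- bh_adjust(p)
  data.frame(probe_id = subset,
             mean_log_fold_change = unname(mean_d),
             p_value = unname(p),
             q_value = unname(q),
             passes_fdr = unname(q < fdr_rate),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving BH q-values with monotonicity enforcement (delegates to
#' [stats::p.adjust()]).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1 | is.na(p_values))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pearson correlation of a fold-change signature to a reference
#'
#' Used to compare the post-supplement signature over the differentially
#' induced probes to a reference cohort's signature (e.g. unrelated healthy
#' controls).
#'
#' @param fold_change,reference equal-length numeric vectors (n >= 3), both
#'   with nonzero variance.
#' @return Pearson r.
#' @export
signature_correlation <- function(fold_change, reference) {
  if (length(fold_change) != length(reference)) stop("vectors must have equal length")
  if (length(fold_change) < 3L) stop("need at least 3 probes")
  if (stats::sd(fold_change) == 0 || stats::sd(reference) == 0) {
    stop("zero variance; correlation undefined")
  }
  stats::cor(fold_change, reference)
}

#' Upstream-regulator activation z-score
#'
#' Generic activation score for a regulator given a signed target network and
#' observed per-probe regulation directions:
#' z = (N_agree - N_disagree) / sqrt(N_overlap), where a target agrees when
#' expected sign x observed sign = +1. Calls: activated at z >= 2, inhibited
#' at z <= -2, consistent with the convention that |z| >= 2 is significant.
#' Only targets present in both the network and the observations contribute.
#'
#' @param network named numeric vector of expected signs (+1/-1), names are
#'   target probe ids, for a single regulator.
#' @param observed_directions named numeric vector of observed signs (+1/-1),
#'   e.g. `sign(fold_change_signature(...))`.
#' @return list with `z`, `n_overlap`, `call` in
#'   {"activated", "inhibited", "none"}.
#' @export
regulator_activation_z <- function(network, observed_directions) {
  if (any(network == 0)) stop("network signs must be +1 or -1, not 0")
  common <- intersect(names(network), names(observed_directions))
  if (length(common) == 0L) stop("no overlapping targets; no evidence for a call")
  agree <- network[common] * observed_directions[common]
  z <- sum(agree) / sqrt(length(common))
  call <- if (z >= 2) "activated" else if (z <= -2) "inhibited" else "none"
  list(z = unname(z), n_overlap = length(common), call = call)
}
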