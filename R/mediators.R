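#' Paired Wilcoxon signed-rank test
#'
#' Wilcoxon signed-rank on paired differences (the "paired Wilcoxon" of the
#' analyte panels). Zero differences are dropped before ranking (Wilcoxon's
#' original treatment); the exact null distribution is used for n <= 25
#' non-zero pairs without ties, the normal approximation with continuity
#' correction otherwise.
#'
#' @param pre,post equal-length numeric vectors; at least 5 non-zero
#'   differences are required.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to post relative to pre.
#' @return list with `statistic` (V, sum of positive-difference ranks),
#'   `p_value`, `n_used` (non-zero pairs), `exact` (logical).
#' @export
paired_signed_rank <- function(pre, post, alternative = "two.sided") {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  d <- post - pre
  nz <- d[d != 0]
  if (length(nz) == 0L) stop("all paired differences are zero; test degenerate")
  if (length(nz) < 5L) stop("need at least 5 non-zero paired differences")
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(stats::wilcox.test(
    post, pre, paired = TRUE, alternative = alternative,
    exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic),
       p_value = ht$p.value,
       n_used = length(nz),
       exact = exact)
}

#' Mediator change table
#'
#' Per-analyte percent change of the cohort mean
#' (100 * (post_mean - pre_mean) / pre_mean) with a paired signed-rank
#' p-value, retaining analytes whose absolute change strictly exceeds
#' `abs_change_threshold` percent with p strictly below `p_threshold`, sorted
#' by p. This is the trial's screening filter for the analyte panel (more
#' than 5% absolute change at p < 0.2 by default). A per-subject-ratio
#' alternative (mean of per-subject percent changes) is available via
#' `change_on`.
#'
#' @param panel long-format data frame with columns `subject_id`, `visit`
#'   (values "pre"/"post"), `analyte`, `value`.
#' @param abs_change_threshold percent (default 5).
#' @param p_threshold p-value cutoff (default 0.2).
#' @param change_on `"means"` (percent change of group means, default) or
#'   `"subjects"` (mean of per-subject percent changes).
#' @param min_subjects minimum complete pairs per analyte (default 5);
#'   analytes missing a visit for too many subjects are excluded with a
#'   warning.
#' @return data frame `analyte`, `pre_mean`, `post_mean`, `percent_change`,
#'   `p_value`, filtered and sorted by p.
#' @export
mediator_change_table <- function(panel, abs_change_threshold = 5,
                                  p_threshold = 0.2,
                                  change_on = c("means", "subjects"),
                                  min_subjects = 5L) {
  change_on <- match.arg(change_on)
  stopifnot(all(c("subject_id", "visit", "analyte", "value") %in% names(panel)))
  rows <- lapply(split(panel, panel$analyte), function(a) {
    wide <- merge(a[a$visit == "pre", c("subject_id", "value")],
                  a[a$visit == "post", c("subject_id", "value")],
                  by = "subject_id", suffixes = c("_pre", "_post"))
    if (nrow(wide) < min_subjects) {
      warning("analyte '", a$analyte[1L], "' excluded: only ", nrow(wide),
              " complete pre/post pairs", call. = FALSE)
      return(NULL)
    }
    pre_mean <- mean(wide$value_pre)
    post_mean <- mean(wide$value_post)
    pc <- if (change_on == "means") {
      100 * (post_mean - pre_mean) / pre_mean
    } else {
      mean(100 * (wide$value_post - wide$value_pre) / wide$value_pre)
    }
    p <- if (all(wide$value_post == wide$value_pre)) {
      1  # no change at all: certainly not retained
    } else {
      paired_signed_rank(wide$value_pre, wide$value_post)$p_value
    }
    data.frame(analyte = a$analyte[1L], pre_mean = pre_mean,
               post_mean = post_mean, percent_change = pc, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out <- out[abs(out$percent_change) > abs_change_threshold &
               out$p_value < p_threshold, , drop = FALSE]
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fold change of cohort means
#'
#' @param pre_mean,post_mean mean concentrations (pre_mean > 0).
#' @return post_mean / pre_mean.
#' @export
fold_change_of_means <- function(pre_mean, post_mean) {
  if (any(pre_mean <= 0)) stop("pre mean must be positive")
  post_mean / pre_mean
}

#' Percent reduction of cohort means
#'
#' @param pre_mean,post_mean mean concentrations (pre_mean > 0).
#' @return 100 * (pre_mean - post_mean) / pre_mean.
#' @export
percent_reduction_of_means <- function(pre_mean, post_mean) {
  if (any(pre_mean <= 0)) stop("pre mean must be positive")
  100 * (pre_mean - post_mean) / pre_mean
}

#' Exclude a subject subgroup
#'
#' Pure filter removing records of subjects matched by `predicate` (by
#' default, subjects with two or more islet autoantibodies, the trial's
#' seroconversion-risk subgroup). Retained records are untouched.
#'
#' @param records data frame with a `subject_id` column and the metadata
#'   columns the predicate uses (default needs `autoantibody_count`).
#' @param predicate function of the records data frame returning a logical
#'   vector flagging rows to remove.
#' @return the filtered data frame, with the removed subject ids attached as
#'   attribute `"removed_subjects"`. Warns if everything is removed.
#' @export
exclude_subgroup <- function(records,
                             predicate = function(df) df$autoantibody_count >= 2) {
  flag <- predicate(records)
  removed <- unique(records$subject_id[flag])
  out <- records[!flag, , drop = FALSE]
  if (nrow(out) == 0L) warning("all subjects excluded by predicate", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "removed_subjects") <- removed
  out
}

#' Dietary fiber as percent of the IOM target
#'
#' The Institute of Medicine guideline is 14 g dietary fiber per 1000
#' kcal/day; intake is standardised as the percentage of that target
#' achieved: 100 * fiber_g / (14 * kcal / 1000).
#'
#' @param fiber_g_per_day grams of fiber per day.
#' @param kcal_per_day caloric intake per day (> 0).
#' @return percent of the IOM target achieved.
#' @export
fiber_percent_of_iom_target <- function(fiber_g_per_day, kcal_per_day) {
  if (any(kcal_per_day <= 0)) stop("kcal per day must be positive")
  100 * fiber_g_per_day / (14 * kcal_per_day / 1000)
}

#' Memory to naive CD4 T-cell ratio
#'
#' Percent CD4+CD45RO+ (memory) divided by percent CD4+CD45RA+ (naive).
#'
#' @param pct_memory,pct_naive percentages (naive > 0).
#' @return the ratio.
#' @export
memory_naive_ratio <- function(pct_memory, pct_naive) {
  if (any(pct_naive <= 0)) stop("naive percentage must be positive")
  pct_memory / pct_naive
}

#' Pearson correlation with p-value
#'
#' Pearson r with the two-sided p-value from the t transform
#' (t = r sqrt(n-2) / sqrt(1-r^2), n-2 df).
#'
#' @param x,y equal-length numeric vectors, n >= 3, nonzero variances.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector; correlation undefined")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}
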