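test_that("signed-rank test matches exhaustive enumeration and known exact p", {
  # all post > pre, n = 6: one-sided p = 1/64
  pre <- c(1, 2, 3, 4, 5, 6)
  post <- pre + c(0.5, 1.1, 0.7, 2.2, 1.4, 0.9)
  res <- paired_signed_rank(pre, post, alternative = "greater")
  expect_true(res$exact)
  expect_equal(res$p_value, 1 / 64)
  expect_equal(res$p_value, signed_rank_enum_p(post - pre, "greater"))

  # random fixtures, n = 8: identical to full sign-pattern enumeration
  set.seed(29)
  for (i in 1:10) {
    d <- round(rnorm(8, 0.2, 1), 3)
    d <- d[d != 0]
    if (length(d) < 5 || any(duplicated(abs(d)))) next
    p0 <- rep(0, length(d))
    r <- paired_signed_rank(p0, d)
    expect_equal(r$p_value, signed_rank_enum_p(d, "two.sided"), tolerance = 1e-12)
  }

  # antisymmetric differences: two-sided p = 1 up to discreteness
  d <- c(1.5, -1.5, 2.5, -2.5, 3.5, -3.5)
  r <- suppressWarnings(paired_signed_rank(rep(0, 6), d))
  expect_gte(r$p_value, 0.8)

  expect_error(paired_signed_rank(1:6, 1:6), "degenerate")
  expect_error(paired_signed_rank(1:4, c(1, 2, 3, 5)), "at least 5")
})

test_that("mediator change table applies strict thresholds on mean change and p", {
  n <- 10L
  subj <- sprintf("S%02d", 1:n)
  set.seed(31)
  base <- rlnorm(n, log(100), 0.05)
  mk <- function(analyte, post_vals, pre_vals = base) {
    data.frame(subject_id = rep(subj, 2), visit = rep(c("pre", "post"), each = n),
               analyte = analyte, value = c(pre_vals, post_vals))
  }
  panel <- rbind(
    mk("planted_down", base * (1 - 0.164) * exp(rnorm(n, 0, 0.01))),
    mk("unchanged", base),
    mk("exactly5", rep(105, n), pre_vals = rep(100, n)),  # change = 5.0 exactly
    mk("small_change", base * exp(rnorm(n, 0, 0.005))))
  tab <- mediator_change_table(panel)
  expect_true("planted_down" %in% tab$analyte)
  expect_lt(tab$percent_change[tab$analyte == "planted_down"], 0)
  expect_lt(abs(tab$percent_change[tab$analyte == "planted_down"] - (-16.4)), 1.5)
  expect_false("unchanged" %in% tab$analyte)
  expect_false("exactly5" %in% tab$analyte)
  expect_false("small_change" %in% tab$analyte)

  # row count non-increasing as either threshold tightens
  n1 <- nrow(mediator_change_table(panel, abs_change_threshold = 1, p_threshold = 0.5))
  n2 <- nrow(mediator_change_table(panel, abs_change_threshold = 10, p_threshold = 0.5))
  n3 <- nrow(mediator_change_table(panel, abs_change_threshold = 1, p_threshold = 0.01))
  expect_lte(n2, n1)
  expect_lte(n3, n1)

  # an analyte missing a visit is excluded with a warning, not silently
  broken <- rbind(panel, data.frame(subject_id = subj[1:3], visit = "pre",
                                    analyte = "lonely", value = 1:3))
  expect_warning(mediator_change_table(broken), "lonely")
})

test_that("fold change and percent reduction of means match printed arithmetic", {
  expect_equal(round(fold_change_of_means(0.94, 1.32), 2), 1.40)
  expect_equal(fold_change_of_means(7, 7), 1)
  expect_equal(fold_change_of_means(2, 1), 0.5)
  expect_error(fold_change_of_means(0, 1), "positive")

  expect_equal(round(percent_reduction_of_means(119.0, 96.1), 1), 19.2)
  expect_equal(percent_reduction_of_means(5, 5), 0)
  expect_equal(percent_reduction_of_means(100, 0), 100)
})

test_that("subgroup exclusion is a pure filter that reports removed ids", {
  rec <- data.frame(subject_id = sprintf("S%02d", 1:25),
                    autoantibody_count = c(rep(0, 19), rep(1, 2), rep(2, 3), 3),
                    value = rnorm(25))
  out <- exclude_subgroup(rec)
  expect_equal(nrow(out), 21)
  expect_setequal(attr(out, "removed_subjects"), sprintf("S%02d", 22:25))
  expect_equal(out$value, rec$value[rec$autoantibody_count < 2])

  none <- exclude_subgroup(rec, predicate = function(df) rep(FALSE, nrow(df)))
  expect_equal(none$subject_id, rec$subject_id)
  expect_warning(exclude_subgroup(rec, predicate = function(df) rep(TRUE, nrow(df))),
                 "all subjects")
})

test_that("fiber standardisation is linear in fiber, inverse-linear in kcal", {
  expect_equal(fiber_percent_of_iom_target(14, 1000), 100)
  expect_equal(round(fiber_percent_of_iom_target(18, 1722), 1), 74.7)
  expect_equal(fiber_percent_of_iom_target(28, 1000), 200)
  f <- 11; k <- 1500
  expect_equal(fiber_percent_of_iom_target(2 * f, k),
               2 * fiber_percent_of_iom_target(f, k))
  expect_equal(fiber_percent_of_iom_target(f, 2 * k),
               fiber_percent_of_iom_target(f, k) / 2)
  expect_error(fiber_percent_of_iom_target(10, 0), "positive")
})

test_that("memory:naive ratio is the direct percentage quotient", {
  expect_equal(memory_naive_ratio(30, 60), 0.5)
  expect_equal(memory_naive_ratio(42, 42), 1)
  set.seed(37)
  mem <- runif(20, 10, 60); nai <- runif(20, 10, 60)
  expect_equal(memory_naive_ratio(mem, nai), mem / nai)
  expect_error(memory_naive_ratio(30, 0), "positive")
})

test_that("Pearson r with p agrees with the t transform", {
  x <- 1:14
  y <- vector_with_exact_r(x, 0.67)
  res <- pearson_with_p(x, y)
  expect_equal(res$r, 0.67, tolerance = 1e-10)
  t_stat <- 0.67 * sqrt(12) / sqrt(1 - 0.67^2)
  expect_equal(res$p_value, 2 * pt(t_stat, 12, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_lt(abs(res$p_value - 0.009), 0.002)  # the n=14 association scale

  xx <- seq_len(10)
  expect_equal(pearson_with_p(xx, 2 * xx + 3)$r, 1)
  set.seed(41)
  big <- rnorm(10000)
  expect_lt(abs(pearson_with_p(big, rnorm(10000))$r), 0.05)
  expect_error(pearson_with_p(xx, rep(1, 10)), "constant")
})
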