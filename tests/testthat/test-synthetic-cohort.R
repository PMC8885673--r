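test_that("generators are bit-identical under a fixed seed", {
  d <- cohort_design(n_subjects = 6, seed = 99)
  m <- expression_effect_model(n_inflammatory = 15, n_regulatory = 45)
  expect_identical(simulate_expression(d, m), simulate_expression(d, m))

  cm <- community_effect_model(n_otus = 30, n_samples_per_visit = 4,
                               depth_mean = 800)
  expect_identical(simulate_otu_table(cm, seed = 7),
                   simulate_otu_table(cm, seed = 7))
  expect_false(identical(simulate_otu_table(cm, seed = 7),
                         simulate_otu_table(cm, seed = 8)))

  delta <- c(-12, -8, -6, -2, 3, 7)
  cov1 <- simulate_covariates(d, delta, seed = 3)
  set.seed(123)  # generator must not depend on ambient RNG state
  cov2 <- simulate_covariates(d, delta, seed = 3)
  expect_identical(cov1, cov2)
})

test_that("expression generator honours dimensions, sets, and invalid input", {
  d <- cohort_design(n_subjects = 5, seed = 2)
  m <- expression_effect_model(n_inflammatory = 10, n_regulatory = 30)
  sim <- simulate_expression(d, m)
  expect_equal(dim(sim$matrix), c(40L, 10L))
  expect_length(sim$partition$inflammatory, 10L)
  expect_length(sim$partition$regulatory, 30L)
  expect_equal(nrow(sim$pairs), 5L)
  expect_true(all(sim$pairs$pre_sample_id %in% colnames(sim$matrix)))
  expect_error(expression_effect_model(n_inflammatory = 0), ">= 1")
  expect_error(cohort_design(n_subjects = 1), "at least 2")
  expect_error(cohort_design(frac_high_risk_hla = 1.2), "\\[0, 1\\]")
})

test_that("null expression effects give near-zero mean index change", {
  d <- cohort_design(n_subjects = 10, seed = 1)
  m0 <- expression_effect_model(n_inflammatory = 50, n_regulatory = 150,
                                delta_inflammatory = 0, delta_regulatory = 0)
  changes <- vapply(1:40, function(i) {
    di <- d; di$seed <- i
    sim <- simulate_expression(di, m0)
    sc <- score_cohort(sim$matrix, sim$partition, sim$pairs)
    mean(sc$percent_change)
  }, numeric(1))
  se <- sd(changes) / sqrt(length(changes))
  expect_lt(abs(mean(changes)), 4 * se + 0.05)
})

test_that("planted expression deltas are recovered by the differential stage", {
  d <- cohort_design(n_subjects = 12, seed = 4)
  m <- expression_effect_model(n_inflammatory = 40, n_regulatory = 120,
                               delta_inflammatory = -0.5,
                               delta_regulatory = 0.2, noise_sd = 0.2)
  sim <- simulate_expression(d, m)
  res <- paired_differential_test(sim$matrix, sim$pairs)
  inf_fc <- mean(res$mean_log_fold_change[res$probe_id %in% sim$partition$inflammatory])
  reg_fc <- mean(res$mean_log_fold_change[res$probe_id %in% sim$partition$regulatory])
  # planted shift recovered within 2 standard errors of the probe-set mean
  se_inf <- sd(res$mean_log_fold_change[res$probe_id %in% sim$partition$inflammatory]) / sqrt(40)
  se_reg <- sd(res$mean_log_fold_change[res$probe_id %in% sim$partition$regulatory]) / sqrt(120)
  expect_lt(abs(inf_fc - (-0.5)), 2 * se_inf + 0.02)
  expect_lt(abs(reg_fc - 0.2), 2 * se_reg + 0.02)
})

test_that("OTU generator conserves depth and spans 7-rank lineages", {
  cm <- community_effect_model(n_otus = 25, n_samples_per_visit = 5,
                               depth_mean = 1000, fixed_depth = TRUE)
  tab <- simulate_otu_table(cm, seed = 11)
  expect_true(all(colSums(tab$counts) == 1000))
  expect_true(all(vapply(tab$lineage,
                         function(l) length(strsplit(l, ";")[[1]]) == 7L,
                         logical(1))))
  pois <- simulate_otu_table(community_effect_model(
    n_otus = 25, n_samples_per_visit = 5, depth_mean = 1000), seed = 11)
  expect_lt(abs(mean(colSums(pois$counts)) - 1000), 60)

  # single dominant OTU: every sample is one OTU, Shannon 0 downstream
  single <- community_effect_model(n_otus = 1, n_samples_per_visit = 3,
                                   concentration = 5, depth_mean = 500,
                                   enriched_families = c())
  stab <- simulate_otu_table(single, seed = 2)
  expect_true(all(apply(stab$counts, 2, shannon_index) == 0))

  bad <- community_effect_model(n_otus = 4, n_samples_per_visit = 2)
  bad$concentration <- numeric(0)
  expect_error(simulate_otu_table(bad, seed = 1), "empty concentration")
  expect_error(community_effect_model(depth_mean = 0), "positive")
})

test_that("post-visit enrichment raises the planted family's abundance", {
  cm <- community_effect_model(n_otus = 60, n_samples_per_visit = 15,
                               depth_mean = 8000,
                               enriched_families = c(Lachnospiraceae = log(2)))
  tab <- simulate_otu_table(cm, seed = 31)
  fam <- collapse_to_rank(tab, "family")
  ab <- sweep(fam$counts, 2, colSums(fam$counts), "/")
  lach <- grep("Lachnospiraceae", rownames(ab))
  visit <- attr(tab, "visit")
  expect_gt(mean(ab[lach, visit == "post"]), mean(ab[lach, visit == "pre"]))
})

test_that("covariate copula hits target correlations at the limits", {
  d_big <- cohort_design(n_subjects = 10000, seed = 5)
  delta <- rnorm(10000, -8, 10)
  cov0 <- simulate_covariates(d_big, delta, target_corr_tcell = 0,
                              target_corr_fiber = 0, seed = 17)
  pct <- fiber_percent_of_iom_target(cov0$ffq$fiber_g_per_day,
                                     cov0$ffq$kcal_per_day)
  expect_lt(abs(cor(pct, delta)), 0.1)

  d14 <- cohort_design(n_subjects = 14, seed = 5)
  delta14 <- rnorm(14)
  cov1 <- simulate_covariates(d14, delta14, target_corr_tcell = 1, seed = 3)
  ratio <- memory_naive_ratio(cov1$tcell$pct_memory, cov1$tcell$pct_naive)
  rc <- percent_change(ratio[cov1$tcell$visit == "pre"],
                       ratio[cov1$tcell$visit == "post"])
  expect_gt(cor(rc, delta14), 0.999)

  expect_error(simulate_covariates(d14, delta14, target_corr_tcell = 1.5),
               "\\[-1, 1\\]")
  expect_error(simulate_covariates(d14, rnorm(3)), "one entry per subject")
})

test_that("covariate panels carry the planted mediator and butyrate effects", {
  d <- cohort_design(n_subjects = 25, seed = 8)
  cov <- simulate_covariates(d, rnorm(25, -8, 6), seed = 19)
  il12 <- cov$panel[cov$panel$analyte == "IL-12p40", ]
  pc <- percent_change(mean(il12$value[il12$visit == "pre"]),
                       mean(il12$value[il12$visit == "post"]))
  expect_lt(pc, -5)
  but <- cov$scfa[cov$scfa$analyte == "butyrate", ]
  expect_gt(fold_change_of_means(mean(but$value[but$visit == "pre"]),
                                 mean(but$value[but$visit == "post"])), 1)
  expect_true(all(cov$panel$value >= 0))
  expect_true(all(cov$scfa$value >= 0))
})
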