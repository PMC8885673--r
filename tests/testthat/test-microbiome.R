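test_that("rank collapsing preserves totals, pools unassigned, is idempotent", {
  counts <- matrix(c(10L, 20L, 5L, 0L,
                     1L, 2L, 3L, 4L), nrow = 4,
                   dimnames = list(paste0("o", 1:4), c("s1", "s2")))
  lin <- c("k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__Blautia; s__",
           "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__Roseburia; s__",
           "k__Bacteria; p__Bacteroidetes; c__Bacteroidia; o__Bacteroidales; f__Bacteroidaceae; g__; s__",
           "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__; g__; s__")
  tab <- otu_count_table(counts, lin)
  fam <- collapse_to_rank(tab, "family")
  expect_equal(colSums(fam$counts), colSums(counts))  # conservation
  expect_true("unassigned" %in% rownames(fam$counts))
  expect_equal(attr(fam, "mapped_fraction"),
               (sum(counts) - sum(counts[4, ])) / sum(counts))
  again <- collapse_to_rank(fam, "family")
  expect_equal(sort(rownames(again$counts)), sort(rownames(fam$counts)))
  expect_equal(again$counts[rownames(fam$counts), ], fam$counts)

  # all OTUs one family at phylum level: single assigned feature
  phy <- collapse_to_rank(otu_count_table(counts[1:2, ], lin[1:2]), "phylum")
  expect_equal(nrow(phy$counts), 1L)
  expect_equal(unname(phy$counts[1, ]), unname(colSums(counts[1:2, ])))
  expect_error(collapse_to_rank(tab, "tribe"), "unknown rank")
})

test_that("mapped-at-family fraction is reported on a read-count fixture", {
  counts <- matrix(c(999100L, 900L), nrow = 2,
                   dimnames = list(c("o1", "o2"), "s1"))
  lin <- c("k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__; s__",
           "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__; g__; s__")
  fam <- collapse_to_rank(otu_count_table(counts, lin), "family")
  expect_equal(round(100 * attr(fam, "mapped_fraction"), 2), 99.91)
})

test_that("Shannon index matches the direct sum and its analytic bounds", {
  expect_equal(shannon_index(c(0, 0, 7)), 0)
  expect_equal(shannon_index(c(5, 5)), 1.0)
  x <- c(1, 2, 3, 4)
  p <- x / sum(x)
  expect_equal(shannon_index(x), -sum(p * log2(p)), tolerance = 1e-12)
  expect_equal(shannon_index(x, base = exp(1)), -sum(p * log(p)), tolerance = 1e-12)
  expect_error(shannon_index(c(0, 0)), "no reads")

  # H <= log2(richness), equality iff uniform; cross-check against vegan
  set.seed(13)
  for (i in 1:25) {
    cts <- rpois(20, 5)
    if (sum(cts) == 0) next
    expect_lte(shannon_index(cts), log2(richness(cts)) + 1e-12)
    expect_equal(shannon_index(cts, base = exp(1)),
                 unname(vegan::diversity(cts, index = "shannon")),
                 tolerance = 1e-10)
  }
  expect_equal(shannon_index(rep(3, 8)), log2(8))
})

test_that("richness counts strictly positive entries", {
  expect_equal(richness(c(0, 0, 5)), 1)
  expect_equal(richness(numeric(0)), 0)
  expect_equal(richness(rep(1L, 173)), 173)
})

test_that("Bray-Curtis matches the definition, its bounds, and vegan", {
  expect_equal(bray_curtis(c(6, 0, 2), c(0, 1, 1)), 0.8)
  expect_equal(bray_curtis(c(3, 1), c(3, 1)), 0)
  expect_equal(bray_curtis(c(5, 0), c(0, 5)), 1)
  set.seed(17)
  for (i in 1:20) {
    a <- rpois(15, 10); b <- rpois(15, 10)
    if (sum(a) == 0 || sum(b) == 0) next
    d <- bray_curtis(a, b)
    expect_equal(d, bray_curtis(b, a))
    expect_true(d >= 0 && d <= 1)
    expect_equal(d, as.numeric(vegan::vegdist(rbind(a, b), "bray")),
                 tolerance = 1e-12)
  }
  expect_error(bray_curtis(c(0, 0), c(1, 1)), "zero-total")
})

test_that("PCoA recovers Euclidean configurations and flags bad input", {
  # 3 equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  res3 <- pcoa_ordination(d3)
  pos <- res3$eigenvalues[res3$eigenvalues > 1e-9]
  expect_length(pos, 2L)
  expect_equal(pos[1], pos[2], tolerance = 1e-10)

  # round trip: distances of known 2-D points are recovered
  set.seed(19)
  pts <- matrix(rnorm(16), ncol = 2)
  d <- as.matrix(dist(pts))
  res <- pcoa_ordination(d)
  expect_equal(as.matrix(dist(res$coordinates)), unname(d), tolerance = 1e-8,
               ignore_attr = TRUE)

  # two samples: one axis whose separation equals the distance
  d2 <- matrix(c(0, 2.5, 2.5, 0), 2)
  res2 <- pcoa_ordination(d2)
  expect_equal(ncol(res2$coordinates), 1L)
  expect_equal(abs(diff(res2$coordinates[, 1])), 2.5, tolerance = 1e-10)

  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("LDA effect size flags a planted zero-variance signal", {
  fx <- make_planted_otu(planted = TRUE)
  res <- lda_effect_size(fx$table, fx$labels, seed = 42)
  row <- res[res$feature == "f__Lachnospiraceae", ]
  expect_true(row$significant)
  expect_equal(row$enriched_class, "B")
  expect_gte(abs(row$lda_score), 2)
})

test_that("identical class distributions yield no significant features", {
  fx <- make_planted_otu(planted = FALSE)
  res <- lda_effect_size(fx$table, fx$labels, seed = 42)
  expect_false(any(res$significant))
})

test_that("LDA significance is monotone in the cutoff and alpha", {
  sim <- simulate_otu_table(community_effect_model(
    n_otus = 40, n_samples_per_visit = 10, depth_mean = 5000,
    enriched_families = c(Lachnospiraceae = log(3))), seed = 23)
  fam <- collapse_to_rank(sim, "family")
  labels <- attr(sim, "visit")
  n_prev <- Inf
  for (cut in c(1, 2, 3, 4)) {
    res <- lda_effect_size(fam, labels, lda_cutoff = cut, seed = 5)
    expect_lte(sum(res$significant), n_prev)
    n_prev <- sum(res$significant)
  }
  n_prev <- Inf
  for (a in c(0.10, 0.05, 0.01)) {
    res <- lda_effect_size(fam, labels, alpha = a, seed = 5)
    expect_lte(sum(res$significant), n_prev)
    n_prev <- sum(res$significant)
    expect_equal(res$significant, res$p_value <= a & abs(res$lda_score) >= 2)
  }
  expect_error(lda_effect_size(fam, rep("A", ncol(fam$counts)), seed = 1),
               "two classes")
  expect_error(lda_effect_size(fam, c("B", rep("A", ncol(fam$counts) - 1)),
                               seed = 1), "at least 2 samples")
})
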