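GG_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
GG_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Construct an OTU count table
#'
#' Counts are held OTU-by-sample (taxa in rows) with one Greengenes-style
#' lineage string per OTU (semicolon-delimited, `k__`/`p__`/.../`s__`
#' prefixes, possibly truncated below the deepest assigned rank).
#'
#' @param counts non-negative integer matrix, OTUs in rows (rownames = OTU
#'   ids), samples in columns (colnames = sample ids).
#' @param lineage character vector of lineage strings, one per OTU row.
#' @return an `otu_count_table` list with elements `counts` and `lineage`.
#' @export
otu_count_table <- function(counts, lineage) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(lineage) != nrow(counts)) {
    stop("need one lineage string per OTU row")
  }
  if (is.null(rownames(counts))) rownames(counts) <- paste0("OTU", seq_len(nrow(counts)))
  structure(list(counts = counts, lineage = as.character(lineage)),
            class = "otu_count_table")
}

# Split a lineage string into named rank components; empty string where
# the prefix is present but unnamed (e.g. "g__") or the lineage is truncated.
parse_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";\\s*")[[1]]
  out <- stats::setNames(rep("", 7L), GG_RANKS)
  for (p in parts) {
    hit <- which(startsWith(p, GG_PREFIXES))
    if (length(hit) == 1L) out[hit] <- sub("^.__", "", p)
  }
  out
}

#' Collapse an OTU table to a taxonomic rank
#'
#' Counts are summed over OTUs sharing the lineage prefix through `rank`.
#' OTUs with no name at that rank are pooled into an explicit `"unassigned"`
#' feature rather than dropped, so the fraction of reads mapped at the rank
#' can be reported (the trial reports, e.g., the fraction of reads mapped to
#' at least the family level).
#'
#' @param table an [otu_count_table()].
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return an `otu_count_table` of collapsed features with an attached
#'   `mapped_fraction` attribute (fraction of total reads assigned at the
#'   rank). Collapsing is idempotent at a fixed rank and preserves per-sample
#'   totals exactly.
#' @export
collapse_to_rank <- function(table, rank) {
  stopifnot(inherits(table, "otu_count_table"))
  ri <- match(rank, GG_RANKS)
  if (is.na(ri)) stop("unknown rank '", rank, "'")
  lin <- vapply(table$lineage, parse_lineage, character(7L))
  keys <- character(nrow(table$counts))
  assigned <- logical(nrow(table$counts))
  for (i in seq_len(nrow(table$counts))) {
    ranks_i <- lin[, i]
    if (nzchar(ranks_i[ri])) {
      keys[i] <- paste0(GG_PREFIXES[1:ri], ranks_i[1:ri], collapse = "; ")
      assigned[i] <- TRUE
    } else {
      keys[i] <- "unassigned"
    }
  }
  agg <- rowsum(table$counts, group = keys)
  total <- sum(table$counts)
  mapped <- if (total > 0) sum(table$counts[assigned, , drop = FALSE]) / total else NA_real_
  out <- otu_count_table(agg, rownames(agg))
  attr(out, "mapped_fraction") <- mapped
  out
}

#' Shannon diversity of one sample
#'
#' H = -sum p_i log_base(p_i) over OTUs with nonzero counts. Base 2 (bits)
#' by default; base e gives nats.
#'
#' @param counts non-negative counts for one sample (total > 0).
#' @param base logarithm base (default 2).
#' @return diversity in log-base units.
#' @export
shannon_index <- function(counts, base = 2) {
  if (sum(counts) <= 0) stop("sample has no reads; diversity undefined")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' OTU richness of one sample
#'
#' @param counts counts for one sample.
#' @return number of OTUs with count > 0.
#' @export
richness <- function(counts) {
  sum(counts > 0)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' 1 - 2 sum(min(a_i, b_i)) / (sum a + sum b), in \[0, 1\]. Bray-Curtis is a
#' semi-metric: it is symmetric with zero self-dissimilarity but may violate
#' the triangle inequality.
#'
#' @param a,b equal-length non-negative count/abundance vectors with
#'   positive totals.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop("samples must have equal length")
  if (sum(a) <= 0 || sum(b) <= 0) stop("zero-total sample; dissimilarity undefined")
  1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
}

#' Bray-Curtis distance matrix over the samples of an OTU table
#'
#' @param table an [otu_count_table()].
#' @return symmetric matrix of pairwise Bray-Curtis dissimilarities.
#' @export
bray_curtis_matrix <- function(table) {
  counts <- table$counts
  n <- ncol(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(counts[, i], counts[, j])
    }
  }
  d
}

#' Principal coordinate analysis (classical multidimensional scaling)
#'
#' Eigendecomposition of the double-centred Gower matrix of a squared
#' distance matrix. Axes are ordered by eigenvalue. For semi-metric
#' dissimilarities (e.g. Bray-Curtis) some eigenvalues can be negative;
#' these are reported but their axes are dropped from the coordinates by
#' default.
#'
#' @param distance_matrix symmetric matrix with zero diagonal.
#' @param eps eigenvalues below `eps * max(eigenvalue)` are treated as null
#'   and their axes dropped.
#' @return list with `coordinates` (samples x retained axes), `eigenvalues`
#'   (all, including negative), `relative_eigenvalues` (fraction of the
#'   positive sum).
#' @export
pcoa_ordination <- function(distance_matrix, eps = 1e-9) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8) || any(abs(diag(d)) > 1e-8)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  n <- nrow(d)
  # full k requested on purpose; null/negative axes are pruned below
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1L, eig = TRUE))
  eig <- fit$eig
  keep <- which(eig > eps * max(eig))
  coords <- fit$points[, keep, drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(keep))
  pos <- sum(eig[eig > 0])
  list(coordinates = coords,
       eigenvalues = eig,
       relative_eigenvalues = if (pos > 0) eig / pos else eig)
}

# Per-sample relative abundance scaled to a fixed total (default one
# million, the convention under which LDA-effect scores are reported).
relative_abundance <- function(table, scale = 1e6) {
  counts <- table$counts
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("zero-total sample in table")
  sweep(counts, 2L, totals, "/") * scale
}

#' LDA effect size (LEfSe-style) differential abundance
#'
#' Two-stage biomarker discovery for a two-class (e.g. pre vs post
#' supplement) design, following the published procedure: per-feature
#' abundances are scaled to a common per-sample total (one million by
#' default); features are screened by Kruskal-Wallis rank test at `alpha`
#' (for two classes this is the Wilcoxon rank-sum test up to the chi-square
#' approximation); surviving features are scored by a bootstrap-averaged
#' linear-discriminant effect size. Each bootstrap iteration fits an LDA to a
#' random two-thirds subsample, projects samples on the unit discriminant
#' axis, and takes the feature effect as the mean of (i) the absolute
#' between-class difference of the feature's raw scaled means and (ii) the
#' feature's |unit LDA coefficient| times the between-class separation along
#' the axis. The reported score is sign(class2 - class1 mean) *
#' log10(1 + mean bootstrap effect). A feature is significant iff its screen
#' p-value <= `alpha` and |score| >= `lda_cutoff`.
#'
#' Features constant within every class (zero within-group variance) are
#' given a tiny seeded jitter inside the LDA fit, mirroring the original
#' implementation's handling; the screen p-value is unaffected.
#'
#' @param table an [otu_count_table()] (typically collapsed to a rank, or a
#'   stack of several ranks).
#' @param class_labels factor/character of length ncol(counts), exactly 2
#'   levels, each with >= 2 samples.
#' @param alpha screen significance level (default 0.05).
#' @param lda_cutoff absolute log10 effect-size threshold (default 2.0).
#' @param n_boot bootstrap LDA iterations (default 30, the published
#'   default).
#' @param seed integer seed for the bootstrap subsampling.
#' @param scale per-sample abundance total (default 1e6).
#' @return data frame with `feature`, `enriched_class`, `p_value`,
#'   `lda_score` (signed log10 effect), `significant`.
#' @export
lda_effect_size <- function(table, class_labels, alpha = 0.05,
                            lda_cutoff = 2.0, n_boot = 30L, seed = 1L,
                            scale = 1e6) {
  cls <- factor(class_labels)
  if (nlevels(cls) != 2L) stop("exactly two classes are required")
  if (any(tabulate(cls) < 2L)) stop("each class needs at least 2 samples")
  ab <- relative_abundance(table, scale = scale)
  if (length(cls) != ncol(ab)) stop("one class label per sample is required")
  lev <- levels(cls)

  pvals <- apply(ab, 1L, function(x) {
    if (stats::sd(x) == 0) return(1)
    stats::kruskal.test(x, cls)$p.value
  })
  keep <- which(pvals <= alpha)
  mean1 <- rowMeans(ab[, cls == lev[1L], drop = FALSE])
  mean2 <- rowMeans(ab[, cls == lev[2L], drop = FALSE])
  enriched <- ifelse(mean2 >= mean1, lev[2L], lev[1L])

  scores <- rep(0, nrow(ab))
  if (length(keep) > 0L) {
    sub <- t(ab[keep, , drop = FALSE])  # samples x features for lda()
    colnames(sub) <- paste0("f", seq_len(ncol(sub)))
    rng <- local_rng(seed)
    n <- nrow(sub)
    take <- max(4L, floor(2 * n / 3))
    eff <- matrix(NA_real_, n_boot, ncol(sub))
    b <- 1L
    tries <- 0L
    while (b <= n_boot && tries < 50L * n_boot) {
      tries <- tries + 1L
      idx <- sample.int(n, take)
      if (any(tabulate(cls[idx], nbins = 2L) < 2L)) next
      x <- sub[idx, , drop = FALSE]
      y <- cls[idx]
      # wiggle features constant within a class so lda() is well-posed
      for (j in seq_len(ncol(x))) {
        if (any(tapply(x[, j], y, stats::sd) == 0)) {
          x[, j] <- x[, j] + stats::rnorm(nrow(x), 0, max(x[, j], 1) * 1e-6)
        }
      }
      fit <- try(suppressWarnings(MASS::lda(x, grouping = y, tol = 1e-10)),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      w <- fit$scaling[, 1L]
      w_unit <- w / sqrt(sum(w^2))
      ld <- drop(x %*% w_unit)
      sep <- abs(mean(ld[y == lev[1L]]) - mean(ld[y == lev[2L]]))
      gm <- abs(fit$means[1L, ] - fit$means[2L, ])
      eff[b, ] <- (gm + abs(w_unit) * sep) / 2
      b <- b + 1L
    }
    restore_rng(rng)
    m <- colMeans(eff, na.rm = TRUE)
    m[is.nan(m)] <- 0
    sgn <- sign(mean2[keep] - mean1[keep])
    sgn[sgn == 0] <- 1
    scores[keep] <- sgn * log10(1 + abs(m))
  }

  data.frame(feature = rownames(ab),
             enriched_class = enriched,
             p_value = unname(pvals),
             lda_score = unname(scores),
             significant = unname(pvals <= alpha & abs(scores) >= lda_cutoff),
             stringsAsFactors = FALSE)
}

# Scoped RNG: draw from a reproducible stream without clobbering the
# caller's random state.
local_rng <- function(seed) {
  prev <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  prev
}

restore_rng <- function(prev) {
  if (is.null(prev)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", prev, envir = globalenv())
  }
  invisible(NULL)
}
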