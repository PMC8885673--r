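# Fixture builders shared across the suite.

# Tiny expression matrix with named probes/samples from a value vector.
make_expr <- function(values, probe_ids, sample_ids) {
  matrix(values, nrow = length(probe_ids),
         dimnames = list(probe_ids, sample_ids))
}

# Independent Benjamini-Hochberg step-up from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, mapped back to input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m))
  }
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Exhaustive Wilcoxon signed-rank null: enumerate all 2^n sign patterns of
# the ranked absolute differences and return the exact p-value for the
# observed statistic V (sum of positive-difference ranks).
signed_rank_enum_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- grid %*% r
  ge <- mean(v_all >= v_obs)
  le <- mean(v_all <= v_obs)
  switch(alternative,
         greater = ge,
         less = le,
         two.sided = min(1, 2 * min(ge, le)))
}

# Sample vector y with exact sample Pearson correlation rho to x.
vector_with_exact_r <- function(x, rho, seed = 1) {
  set.seed(seed)
  e <- rnorm(length(x))
  e <- residuals(lm(e ~ x))
  z1 <- scale(x)[, 1]
  z2 <- e / sd(e)
  rho * z1 + sqrt(1 - rho^2) * z2
}

# Small paired-visit OTU table with a planted class difference in feature 1.
make_planted_otu <- function(n_per_class = 6L, planted = TRUE) {
  a <- matrix(0L, nrow = 3L, ncol = 2L * n_per_class)
  # class A: feature1 low; class B: feature1 high; zero within-class variance
  a[1, ] <- rep(c(50L, if (planted) 500L else 50L), each = n_per_class)
  a[2, ] <- 300L
  a[3, ] <- 650L
  colnames(a) <- paste0("s", seq_len(ncol(a)))
  rownames(a) <- c("f__Lachnospiraceae", "f__Bacteroidaceae", "f__Ruminococcaceae")
  lin <- c("k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__; s__",
           "k__Bacteria; p__Bacteroidetes; c__Bacteroidia; o__Bacteroidales; f__Bacteroidaceae; g__; s__",
           "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Ruminococcaceae; g__; s__")
  list(table = otu_count_table(a, lin),
       labels = rep(c("A", "B"), each = n_per_class))
}
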