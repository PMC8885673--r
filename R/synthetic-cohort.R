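#' Cohort design for the synthetic trial
#'
#' Defaults reproduce the pilot-trial conditions: 25 paired pre/post
#' subjects, 40% carrying a high-risk HLA haplotype (DR3 and/or DR4), 16%
#' with two or more islet autoantibodies (and 8% with exactly one).
#'
#' @param n_subjects number of paired subjects (>= 2).
#' @param frac_high_risk_hla,frac_multi_autoantibody,frac_single_autoantibody
#'   proportions in \[0, 1\].
#' @param seed integer seed; all cohort randomness flows from it.
#' @return a `cohort_design` list.
#' @export
cohort_design <- function(n_subjects = 25L, frac_high_risk_hla = 0.40,
                          frac_multi_autoantibody = 0.16,
                          frac_single_autoantibody = 0.08, seed = 1L) {
  if (n_subjects < 2L) stop("need at least 2 subjects")
  props <- c(frac_high_risk_hla, frac_multi_autoantibody, frac_single_autoantibody)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects),
                 frac_high_risk_hla = frac_high_risk_hla,
                 frac_multi_autoantibody = frac_multi_autoantibody,
                 frac_single_autoantibody = frac_single_autoantibody,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Expression effect model for the synthetic arrays
#'
#' Log-normal probe intensities on the log2 scale with additive subject
#' random effects: the log2 intensity of probe p in subject s at visit v is
#' baseline_mean + probe offset + subject effect + visit * delta(set(p)) +
#' noise. Defaults plant a modest anti-inflammatory shift (inflammatory
#' probes down, regulatory probes up post-supplement) sized so the cohort's
#' composite index drops by roughly a tenth, the direction and approximate
#' magnitude the trial reports; probe-set sizes default to the published
#' 307/1,067 split.
#'
#' @param n_inflammatory,n_regulatory probe-set sizes (>= 1).
#' @param baseline_mean,baseline_sd grand mean and probe-offset sd (log2).
#' @param subject_sd sd of the additive per-subject effect (log2).
#' @param delta_inflammatory log2 shift of inflammatory probes post-visit
#'   (<= 0 for an anti-inflammatory effect).
#' @param delta_regulatory log2 shift of regulatory probes post-visit (>= 0).
#' @param noise_sd residual sd (log2).
#' @return an `expression_effect_model` list.
#' @export
expression_effect_model <- function(n_inflammatory = 307L, n_regulatory = 1067L,
                                    baseline_mean = 6, baseline_sd = 1,
                                    subject_sd = 0.2,
                                    delta_inflammatory = -0.6,
                                    delta_regulatory = 0.1,
                                    noise_sd = 0.15) {
  if (n_inflammatory < 1L || n_regulatory < 1L) stop("probe counts must be >= 1")
  if (baseline_sd < 0 || subject_sd < 0 || noise_sd < 0) {
    stop("standard deviations must be non-negative")
  }
  structure(list(n_inflammatory = as.integer(n_inflammatory),
                 n_regulatory = as.integer(n_regulatory),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 subject_sd = subject_sd,
                 delta_inflammatory = delta_inflammatory,
                 delta_regulatory = delta_regulatory,
                 noise_sd = noise_sd),
            class = "expression_effect_model")
}

#' Simulate a paired plasma-induced transcription cohort
#'
#' @param design a [cohort_design()].
#' @param model an [expression_effect_model()].
#' @return list with `matrix` (probes x 2 n_subjects log2 intensities,
#'   columns `<subject>_pre` / `<subject>_post`), `partition`
#'   ([gene_set_partition()]), and `pairs` (subject/visit metadata data
#'   frame). Identical design and model give bit-identical output.
#' @export
simulate_expression <- function(design, model) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(model, "expression_effect_model"))
  n <- design$n_subjects
  n_probes <- model$n_inflammatory + model$n_regulatory
  probe_ids <- c(sprintf("INF_%04d", seq_len(model$n_inflammatory)),
                 sprintf("REG_%04d", seq_len(model$n_regulatory)))
  subj_ids <- sprintf("S%02d", seq_len(n))
  sample_ids <- c(rbind(paste0(subj_ids, "_pre"), paste0(subj_ids, "_post")))

  prev <- local_rng(design$seed)
  on.exit(restore_rng(prev))

  probe_offset <- stats::rnorm(n_probes, 0, model$baseline_sd)
  subj_effect <- stats::rnorm(n, 0, model$subject_sd)
  delta <- c(rep(model$delta_inflammatory, model$n_inflammatory),
             rep(model$delta_regulatory, model$n_regulatory))

  mat <- matrix(NA_real_, n_probes, 2L * n,
                dimnames = list(probe_ids, sample_ids))
  for (s in seq_len(n)) {
    base_s <- model$baseline_mean + probe_offset + subj_effect[s]
    mat[, 2L * s - 1L] <- base_s + stats::rnorm(n_probes, 0, model$noise_sd)
    mat[, 2L * s] <- base_s + delta + stats::rnorm(n_probes, 0, model$noise_sd)
  }

  n_multi <- round(design$frac_multi_autoantibody * n)
  n_single <- round(design$frac_single_autoantibody * n)
  aab <- rep(0L, n)
  aab[sample.int(n, min(n, n_multi + n_single))] <- c(rep(2L, n_multi),
                                                      rep(1L, n_single))[seq_len(min(n, n_multi + n_single))]
  hla <- rep("low", n)
  hla[sample.int(n, round(design$frac_high_risk_hla * n))] <- "high"
  pairs <- data.frame(
    subject_id = subj_ids,
    pre_sample_id = paste0(subj_ids, "_pre"),
    post_sample_id = paste0(subj_ids, "_post"),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.64, 0.36)),
    age = round(stats::runif(n, 6.2, 17.7), 1L),
    hla_risk = hla,
    autoantibody_count = aab,
    adherence = pmin(100, pmax(52, round(stats::rnorm(n, 95, 8)))),
    stringsAsFactors = FALSE)

  partition <- gene_set_partition(
    inflammatory = probe_ids[seq_len(model$n_inflammatory)],
    regulatory = probe_ids[model$n_inflammatory + seq_len(model$n_regulatory)])

  list(matrix = mat, partition = partition, pairs = pairs)
}

# Family-level taxonomy backbone used for synthetic lineages. Families
# include those the trial's differential-abundance analysis highlights.
SYNTHETIC_TAXONOMY <- data.frame(
  family = c("Lachnospiraceae", "Ruminococcaceae", "Bacteroidaceae",
             "Prevotellaceae", "Bifidobacteriaceae", "Lactobacillaceae",
             "Veillonellaceae", "Enterobacteriaceae", "Porphyromonadaceae",
             "Peptostreptococcaceae", "Mogibacteriaceae", "Clostridiaceae",
             "Rikenellaceae", "Erysipelotrichaceae", "Streptococcaceae"),
  order_ = c("Clostridiales", "Clostridiales", "Bacteroidales",
             "Bacteroidales", "Bifidobacteriales", "Lactobacillales",
             "Clostridiales", "Enterobacteriales", "Bacteroidales",
             "Clostridiales", "Clostridiales", "Clostridiales",
             "Bacteroidales", "Erysipelotrichales", "Lactobacillales"),
  class_ = c("Clostridia", "Clostridia", "Bacteroidia", "Bacteroidia",
             "Actinobacteria", "Bacilli", "Clostridia",
             "Gammaproteobacteria", "Bacteroidia", "Clostridia",
             "Clostridia", "Clostridia", "Bacteroidia", "Erysipelotrichia",
             "Bacilli"),
  phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes", "Bacteroidetes",
             "Actinobacteria", "Firmicutes", "Firmicutes", "Proteobacteria",
             "Bacteroidetes", "Firmicutes", "Firmicutes", "Firmicutes",
             "Bacteroidetes", "Firmicutes", "Firmicutes"),
  stringsAsFactors = FALSE)

make_lineage <- function(family, otu_index, assigned_at_family = TRUE) {
  row <- SYNTHETIC_TAXONOMY[SYNTHETIC_TAXONOMY$family == family, ]
  if (assigned_at_family) {
    sprintf("k__Bacteria; p__%s; c__%s; o__%s; f__%s; g__Genus%02d; s__",
            row$phylum, row$class_, row$order_, family, otu_index %% 20L)
  } else {
    sprintf("k__Bacteria; p__%s; c__%s; o__%s; f__; g__; s__",
            row$phylum, row$class_, row$order_)
  }
}

#' Community effect model for the synthetic 16S OTU tables
#'
#' Dirichlet-multinomial sampling with family-structured Greengenes-style
#' lineages. Defaults emulate the trial's sequencing scale: 173 OTUs over 15
#' families, 25 samples per visit, a mean depth near 20,600 reads/sample
#' (about one million reads over 50 samples), a small unassigned-at-family
#' mass so the mapped-at-family fraction is just below 1, and 1.4-fold
#' post-supplement enrichment of Lachnospiraceae, Bifidobacteriaceae and
#' Lactobacillaceae (the probiotic's constituent and butyrogenic families).
#'
#' @param n_otus number of OTUs.
#' @param n_samples_per_visit paired samples per visit.
#' @param concentration optional Dirichlet concentration vector (one entry
#'   per OTU, all > 0); built from the family backbone when `NULL`.
#' @param depth_mean mean reads per sample (> 0).
#' @param enriched_families named numeric vector of post-visit natural-log
#'   fold enrichments applied to the concentrations of OTUs in those
#'   families.
#' @param fixed_depth if `TRUE`, every sample gets exactly `depth_mean`
#'   reads; default draws Poisson(depth_mean) depths, matching per-sample
#'   read-count variation.
#' @return a `community_effect_model` list (with `lineage` and `family`
#'   per OTU).
#' @export
community_effect_model <- function(n_otus = 173L, n_samples_per_visit = 25L,
                                   concentration = NULL, depth_mean = 20600,
                                   enriched_families = c(
                                     Lachnospiraceae = log(1.4),
                                     Bifidobacteriaceae = log(1.4),
                                     Lactobacillaceae = log(1.4)),
                                   fixed_depth = FALSE) {
  if (n_otus < 1L) stop("need at least 1 OTU")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  fams <- SYNTHETIC_TAXONOMY$family
  # family weights: a few dominant gut families, long tail; last OTU slot of
  # each 40th index left unassigned at family to give mapped fraction < 1
  fam_weight <- stats::setNames(
    c(20, 18, 16, 8, 3, 2, 4, 2, 3, 3, 2, 6, 4, 3, 3), fams)
  family_of <- rep(fams, length.out = n_otus)
  unassigned <- seq_len(n_otus) %% 40L == 0L
  lineage <- vapply(seq_len(n_otus), function(i)
    make_lineage(family_of[i], i, assigned_at_family = !unassigned[i]),
    character(1))
  if (is.null(concentration)) {
    concentration <- fam_weight[family_of] / as.numeric(table(family_of)[family_of])
    concentration[unassigned] <- 0.05
    concentration <- unname(concentration)
  }
  if (length(concentration) != n_otus || any(concentration <= 0)) {
    stop("concentration must be a positive vector with one entry per OTU")
  }
  structure(list(n_otus = as.integer(n_otus),
                 n_samples_per_visit = as.integer(n_samples_per_visit),
                 concentration = concentration,
                 depth_mean = depth_mean,
                 enriched_families = enriched_families,
                 fixed_depth = fixed_depth,
                 family = family_of,
                 lineage = lineage),
            class = "community_effect_model")
}

# One Dirichlet draw via normalised gammas.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # guard tiny-alpha underflow
  g / sum(g)
}

#' Simulate a paired pre/post OTU count table
#'
#' Per sample, community proportions are a Dirichlet draw from the model's
#' concentration vector (post samples use concentrations multiplied by
#' exp(log-fold enrichment) for OTUs in enriched families) and counts are a
#' multinomial draw at Poisson- or fixed-depth.
#'
#' @param model a [community_effect_model()].
#' @param seed integer seed.
#' @return an [otu_count_table()] with columns `<subject>_pre` then
#'   `<subject>_post` and a `visit` attribute.
#' @export
simulate_otu_table <- function(model, seed = 1L) {
  stopifnot(inherits(model, "community_effect_model"))
  if (length(model$concentration) == 0L) stop("empty concentration vector")
  n <- model$n_samples_per_visit
  subj_ids <- sprintf("S%02d", seq_len(n))
  sample_ids <- c(paste0(subj_ids, "_pre"), paste0(subj_ids, "_post"))
  visit <- rep(c("pre", "post"), each = n)

  alpha_pre <- model$concentration
  mult <- rep(1, model$n_otus)
  for (fam in names(model$enriched_families)) {
    mult[model$family == fam] <- exp(model$enriched_families[[fam]])
  }
  alpha_post <- alpha_pre * mult

  prev <- local_rng(seed)
  on.exit(restore_rng(prev))
  counts <- matrix(0L, model$n_otus, 2L * n,
                   dimnames = list(sprintf("OTU_%03d", seq_len(model$n_otus)),
                                   sample_ids))
  for (j in seq_len(2L * n)) {
    alpha <- if (visit[j] == "pre") alpha_pre else alpha_post
    p <- rdirichlet1(alpha)
    depth <- if (model$fixed_depth) round(model$depth_mean) else
      stats::rpois(1L, model$depth_mean)
    if (depth > 0) counts[, j] <- stats::rmultinom(1L, depth, p)[, 1L]
  }
  out <- otu_count_table(counts, model$lineage)
  attr(out, "visit") <- visit
  out
}

# Couple a new variable to `anchor` at population correlation rho via a
# bivariate Gaussian construction (Gaussian copula with normal marginals).
couple_to <- function(anchor, rho, mean = 0, sd = 1) {
  z1 <- (anchor - base::mean(anchor)) / stats::sd(anchor)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(length(anchor))
  mean + sd * z2
}

#' Simulate trial covariates coupled to index change
#'
#' Generates the food-frequency summary, CD4 T-cell frequencies, mediator
#' panel and SCFA panel for a cohort, with the diet and T-cell covariates
#' tied to a supplied per-subject index percent-change vector through a
#' Gaussian copula at specified target correlations. Defaults reproduce the
#' trial's observed associations (+0.67 for the percent change in the
#' memory:naive CD4 ratio, -0.401 for fiber as percent of the IOM target)
#' and plant the trial's mediator percent changes and the butyrate shift
#' (0.94 -> 1.32 uM cohort means) as small paired effects.
#'
#' @param design a [cohort_design()].
#' @param delta_iicom numeric vector (length n_subjects) of index percent
#'   changes to couple against.
#' @param target_corr_tcell,target_corr_fiber target Pearson correlations in
#'   \[-1, 1\].
#' @param mediator_effects named numeric vector of planted percent changes
#'   of the cohort mean per mediator (negative = reduced post-supplement);
#'   unlisted panel analytes are simulated null.
#' @param butyrate_means length-2 numeric, planted pre/post cohort mean
#'   butyrate (uM).
#' @param seed integer seed.
#' @return list of data frames: `ffq` (subject_id, kcal_per_day,
#'   fiber_g_per_day), `tcell` (subject_id, visit, pct_memory, pct_naive),
#'   `panel` and `scfa` (long format: subject_id, visit, analyte, value,
#'   unit).
#' @export
simulate_covariates <- function(design, delta_iicom,
                                target_corr_tcell = 0.67,
                                target_corr_fiber = -0.401,
                                mediator_effects = c(
                                  "IL-12p40" = -16.4, "IL-13" = -31.1,
                                  "IL-15" = -30.3, "IL-18" = -8.1,
                                  "IL-28A" = -6.7, "CCL2" = -8.6,
                                  "CCL21" = -6.4, "CCL24" = -10.4,
                                  "TRAIL" = 8.1,
                                  "IL-6" = 0, "TNF-a" = 0, "IL-10" = 0,
                                  "IFN-y" = 0),
                                butyrate_means = c(0.94, 1.32),
                                seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  n <- design$n_subjects
  if (length(delta_iicom) != n) stop("delta_iicom must have one entry per subject")
  for (rho in c(target_corr_tcell, target_corr_fiber)) {
    if (abs(rho) > 1) stop("target correlations must lie in [-1, 1]")
  }
  subj_ids <- sprintf("S%02d", seq_len(n))
  prev <- local_rng(seed)
  on.exit(restore_rng(prev))

  # diet: percent of IOM fiber target coupled (negatively) to index change
  kcal <- pmin(2744, pmax(742, stats::rnorm(n, 1722, 450)))
  pct_iom <- pmax(10, couple_to(delta_iicom, target_corr_fiber, mean = 75, sd = 25))
  ffq <- data.frame(subject_id = subj_ids,
                    kcal_per_day = kcal,
                    fiber_g_per_day = pct_iom / 100 * 14 * kcal / 1000,
                    stringsAsFactors = FALSE)

  # T cells: percent change of memory:naive ratio coupled to index change
  pct_naive_pre <- pmin(80, pmax(10, stats::rnorm(n, 45, 10)))
  pct_memory_pre <- pmin(80, pmax(5, stats::rnorm(n, 35, 8)))
  ratio_change_pct <- couple_to(delta_iicom, target_corr_tcell, mean = -5, sd = 15)
  ratio_pre <- pct_memory_pre / pct_naive_pre
  ratio_post <- pmax(0.05, ratio_pre * (1 + ratio_change_pct / 100))
  pct_naive_post <- pct_naive_pre
  pct_memory_post <- pmin(95, ratio_post * pct_naive_post)
  tcell <- data.frame(
    subject_id = rep(subj_ids, 2L),
    visit = rep(c("pre", "post"), each = n),
    pct_memory = c(pct_memory_pre, pct_memory_post),
    pct_naive = c(pct_naive_pre, pct_naive_post),
    stringsAsFactors = FALSE)

  # mediator panel: lognormal baselines, planted percent shift of the mean
  panel <- do.call(rbind, lapply(names(mediator_effects), function(a) {
    pre <- stats::rlnorm(n, meanlog = log(50), sdlog = 0.4)
    post <- pre * (1 + mediator_effects[[a]] / 100) *
      exp(stats::rnorm(n, 0, 0.08))
    data.frame(subject_id = rep(subj_ids, 2L),
               visit = rep(c("pre", "post"), each = n),
               analyte = a, value = c(pre, post), unit = "pg/ml",
               stringsAsFactors = FALSE)
  }))

  # SCFAs: butyrate planted to the trial's cohort means, others null
  scfa_means <- c(acetate = 50, propionate = 2, valerate = 0.3,
                  hexanoate = 0.1)
  scfa <- do.call(rbind, lapply(names(scfa_means), function(a) {
    m <- scfa_means[[a]]
    pre <- stats::rlnorm(n, meanlog = log(m) - 0.18, sdlog = 0.6)
    post <- pre * exp(stats::rnorm(n, 0, 0.3))
    data.frame(subject_id = rep(subj_ids, 2L),
               visit = rep(c("pre", "post"), each = n),
               analyte = a, value = c(pre, post), unit = "uM",
               stringsAsFactors = FALSE)
  }))
  # butyrate: skewed marginal matched to the planted pre mean; post scales
  # every subject toward the planted fold change with subject noise
  fold <- butyrate_means[2L] / butyrate_means[1L]
  sdlog <- 1.1
  pre_b <- stats::rlnorm(n, meanlog = log(butyrate_means[1L]) - sdlog^2 / 2,
                         sdlog = sdlog)
  post_b <- pre_b * fold * exp(stats::rnorm(n, 0, 0.25) - 0.25^2 / 2)
  scfa <- rbind(scfa, data.frame(
    subject_id = rep(subj_ids, 2L),
    visit = rep(c("pre", "post"), each = n),
    analyte = "butyrate", value = c(pre_b, post_b), unit = "uM",
    stringsAsFactors = FALSE))
  rownames(scfa) <- NULL

  list(ffq = ffq, tcell = tcell, panel = panel, scfa = scfa)
}
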