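---
title: "Methods: composite inflammatory index and paired trial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite inflammatory index and paired trial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probindex)
```

# The analysis this package implements

`probindex` analyses a single-arm paired clinical design: each subject
contributes one pre-supplement and one post-supplement sample per assay, and
every statistic is a paired contrast. The assays are (i) plasma-induced
transcription — a fixed healthy donor's PBMC are cultured with each
subject's plasma and the induced transcriptome is read on expression arrays,
so the transcriptome acts as a reporter of plasma-borne immune mediators;
(ii) stool 16S profiles summarised as OTU count tables with Greengenes-style
lineages; (iii) plasma mediator and short-chain fatty-acid (SCFA) panels;
and (iv) diet (food-frequency) and CD4 T-cell frequency covariates.

## The composite inflammatory index

The index condenses a 1,374-probe signature, partitioned into 307
"inflammatory" and 1,067 "regulatory" transcripts, into one number per
sample:

$$ I.I._{com} = \frac{\overline{\log_2 I}_{\text{inflammatory}}}
                     {\overline{\log_2 I}_{\text{regulatory}}} $$

High values indicate inflammatory bias of the induced transcriptome, low
values regulatory bias. Two points deserve care:

* **Scale.** The ratio of mean *log* intensities is used (`log_scale =
  TRUE`). The alternative reading — mean raw intensities — is available via
  `log_scale = FALSE`. The log2 form matches how array data are processed
  and stored. Because a ratio of log means is not invariant to rescaling
  (adding $c$ to every log intensity maps $a/b$ to $(a+c)/(b+c)$), matrices
  must share a normalisation before index values are compared; the test
  suite asserts the exact algebraic behaviour rather than pretending
  invariance.
* **Grouping.** The published index was assembled by averaging ratios over
  several discovery data subsets, but the subset memberships are not part
  of the publicly available annotation. Both modes are therefore provided:
  the default pooled two-set ratio, and a grouped mode (`grouped = TRUE`)
  that averages per-subset ratios unweighted when the partition carries
  subset labels. They coincide when subsets are homogeneous.

Responder classification bins each subject's percent change in the index at
a ±5% threshold with *strict* inequalities: a subject at exactly −5.0% is
"stable". The primary cohort-level test is a one-tailed paired t-test whose
direction is declared in the call (`direction = "less"` for an
anti-inflammatory hypothesis) and never inferred from the data.

## Differential induction

Per-probe paired testing uses the paired t-test; with exactly two paired
conditions this is the two-level repeated-measures ANOVA ($F = t^2$), so
nothing is lost relative to an ANOVA formulation. Multiplicity is handled by
Benjamini–Hochberg step-up adjustment computed *within the tested probe
subset* (the 1,374 index probes by default) because the quantity of interest
is the number of differentially induced index transcripts; array-wide
adjustment is available by passing a larger subset. A probe passes at rate
$q^*$ iff its q-value is strictly below $q^*$ (default 0.20). Whether the
original commercial-suite FDR was applied per-contrast or jointly with
covariates is not documented; the per-contrast choice is the simple,
reproducible one and is what is implemented.

The upstream-regulator activation score implements only the generic,
publicly described core: for a user-supplied signed target network,
$z = (N_{agree} - N_{disagree}) / \sqrt{N_{overlap}}$, with activation
called at $z \ge 2$ and inhibition at $z \le -2$. Curated literature
networks are deliberately out of scope; users supply their own.

## Microbiome analysis

OTU tables are collapsed to a rank by summing counts over OTUs sharing the
lineage prefix; OTUs unnamed at the rank are pooled into an explicit
`unassigned` feature so the mapped-at-rank fraction is reportable.
Alpha diversity is Shannon entropy (base 2 by default, configurable) and
observed richness; no rarefaction is applied by default because the
upstream normalisation of the motivating data set is unstated, and a
seeded fixed-depth subsample can be layered on by the user. Beta diversity
is Bray–Curtis (a semi-metric: symmetric, zero self-distance, but the
triangle inequality can fail, so none is asserted) with classical-scaling
PCoA; negative eigenvalues are reported and their axes dropped.

The LDA-effect-size procedure follows the published two-class biomarker
workflow: per-sample abundances are scaled to a common total of $10^6$;
features are screened by Kruskal–Wallis at $\alpha = 0.05$ (identical in
rank structure to the two-sample Wilcoxon rank-sum test for two classes);
surviving features are scored by a bootstrap-averaged linear-discriminant
effect size (30 iterations, two-thirds subsampling, each class required at
least twice per subsample), reported as $\mathrm{sign} \cdot \log_{10}(1 +
\text{effect})$ and thresholded at $|LDA| \ge 2.0$. Exact numeric parity
with the original package is not promised — direction and threshold
behaviour are what the tests assert. Features with zero within-class
variance in a bootstrap draw receive a tiny seeded jitter
($\sigma = 10^{-6} \times$ feature maximum) so the discriminant is
well-posed, mirroring the original implementation's wiggle. Whether the
original analysis ran one-against-all or all-against-all is immaterial in a
two-class design.

## Mediator panels and covariates

The "paired Wilcoxon rank sum test" named in clinical reporting is
implemented as the Wilcoxon *signed-rank* test on paired differences — the
standard paired Wilcoxon procedure; this interpretation is flagged here
because the phrase is ambiguous. Zero differences are dropped before
ranking (Wilcoxon's original treatment); the exact null distribution is
used for ≤ 25 untied non-zero pairs, the normal approximation with
continuity correction otherwise.

The mediator screen tabulates analytes whose cohort-level percent change
exceeds 5% in absolute value with p < 0.2, both strict. Percent change is
computed on group means (ratio of means) by default, matching how cohort
percent-change figures are conventionally quoted; a mean-of-per-subject
ratios alternative is available (`change_on = "subjects"`) because the two
differ under skewed baselines and the convention of the motivating analysis
is unstated.

Dietary fiber is standardised to the Institute of Medicine target of 14 g
per 1000 kcal/day: $100 \cdot f / (14 \cdot kcal/1000)$. The CD4 covariate
is the memory:naive ratio (%CD45RO+ / %CD45RA+). Correlations are Pearson
with the t-transform p-value ($n-2$ df); at $n = 14$ and $r = 0.67$ this
gives $p \approx 0.009$, consistent with permutation-style values to within
rounding.

# The synthetic cohort

The generator exists so the full pipeline is exercised end-to-end without
the trial's raw data, which are deposited externally and depend on a
gene-set annotation published elsewhere. Its defaults are fixed study
conditions, not tuning knobs:

* **Cohort**: 25 paired subjects; 40% high-risk HLA; 16% with ≥ 2 islet
  autoantibodies and 8% with one; adherence high with a long lower tail.
* **Expression**: log-normal probe intensities on the log2 scale — value =
  baseline mean (6.0) + probe offset (sd 1.0) + additive subject effect
  (sd 0.2) + visit shift + noise (sd 0.15). The post-visit shift is
  −0.6 log2 for the 307 inflammatory probes and +0.1 for the 1,067
  regulatory probes, sized so the cohort index falls by roughly 11%, the
  direction and approximate magnitude of the motivating result. No
  per-probe effect sizes are published, so the calibration is to the index
  change only.
* **Microbiome**: Dirichlet-multinomial counts over 173 OTUs in 15 gut
  families, mean depth 20,600 reads/sample (Poisson-distributed by default
  because real per-sample read counts vary; a fixed-depth flag exists), a
  small unassigned-at-family mass so the mapped fraction sits just below
  100%, and 1.4-fold post-visit enrichment of Lachnospiraceae,
  Bifidobacteriaceae and Lactobacillaceae — the supplement's constituent
  and butyrogenic families.
* **Covariates**: coupled to the realised per-subject index change through
  a Gaussian copula with Gaussian marginals, so a target *population*
  correlation is hit exactly and sample correlations converge as $n$
  grows. Defaults: +0.67 for the memory:naive ratio change, −0.401 for
  fiber as %IOM. Mediator panels plant the reported percent changes
  (IL-12p40 −16.4%, IL-13 −31.1%, IL-15 −30.3%, IL-18 −8.1%, IL-28A −6.7%,
  CCL2 −8.6%, CCL21 −6.4%, CCL24 −10.4%, TRAIL +8.1%) beside null
  analytes; butyrate uses a skewed log-normal marginal matched to cohort
  means 0.94 → 1.32 µM.

All randomness flows from one integer seed per artifact through a scoped
RNG, so identical seeds give bit-identical outputs and generators do not
disturb the caller's random state.

## What the generator does and does not emulate

It reproduces the *statistical structure* the analysis assumes: paired
design, probe-set mean shifts, compositional count sampling, planted
family enrichment, copula-coupled covariates. It does not emulate
probe-level correlation structure within gene sets, batch effects,
compositional interactions between families, subject-level heterogeneity
of the transcriptional response (the planted shift is uniform across
subjects, so simulated cohorts are more homogeneous than real ones — the
16/4/5 responder split of a real cohort is exercised through a constructed
fixture instead), or pharmacokinetics of the supplement. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not biological fidelity of any particular dataset.

# Numerical choices and degenerate inputs

* A constant nonzero paired shift (zero-variance differences) yields an
  infinite t and a degenerate one-tailed p of 0 or 1 rather than an error;
  an all-zero difference vector is a hard error, never a silent NaN.
* BH adjustment validates p ∈ [0, 1] and enforces step-up monotonicity; a
  single p-value maps to itself.
* Zero-variance vectors are rejected by correlation functions; all-zero
  samples are rejected by diversity and dissimilarity functions.
* PCoA requires symmetry and a zero diagonal, prunes axes with
  eigenvalues ≤ 10⁻⁹ × the leading eigenvalue, and reports negative
  eigenvalues rather than hiding them.
* Kruskal–Wallis screen p-values for features with zero overall variance
  are set to 1 (no evidence) instead of propagating NaN.
* Dirichlet draws guard against total gamma underflow at tiny
  concentrations by placing the mass on the largest-concentration OTU.

# Problem sizes in the test suite

The statistical acceptance checks simulate at the cohort's own scale
(n = 25 subjects, 1,374 probes) with 500 replicates for the type-I and
power properties of the index test, 1,000 replicates for
correlation-target recovery at n = 14, 200 label shuffles for the
LDA-effect null calibration, and 1,000 random vectors for the BH oracle;
these sizes give binomial Monte-Carlo error well inside the asserted
margins while the whole suite completes in well under a minute.

# Known limitations

* Grouped-mode index scoring cannot reproduce the published per-subset
  weighting because the subset memberships are not public.
* The LDA-effect scorer targets behavioural (direction/threshold) parity
  with the original biomarker tool, not bit parity.
* The activation z-score omits literature-derived networks and any
  bias-corrected variant; it is only the core statistic on user-supplied
  networks.
* Percent-change conventions (ratio of means vs mean of ratios) matter for
  skewed analytes; both are implemented and the default is documented
  above.
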