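---
title: "Methods: TME subtyping and prognostic scoring"
author: "tmescore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TME subtyping and prognostic scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bulk tumor RNA-seq mixes tumor cells with the immune and stromal cells of
the tumor microenvironment (TME). The composition of that infiltrate
carries prognostic information and is linked to immune-checkpoint-inhibitor
response, but it is not directly observable in bulk data. `tmescore`
implements a complete construction from bulk expression plus survival
follow-up to (i) TME subtypes and (ii) a per-sample prognostic score with a
survival-optimal cutpoint, and characterizes the resulting subtypes against
somatic mutation data and response surrogates.

The pipeline, in the order `tme_fit()` executes it:

1. **Deconvolution.** Per-sample proportions of 22 leukocyte types are
   estimated by regressing the sample's marker-gene vector on a signature
   matrix (marker genes x cell types). The default solver is linear
   nu-support-vector regression on z-scored marker vectors, with nu chosen
   from {0.25, 0.5, 0.75} by lowest reconstruction RMSE; the alternative is
   Lawson–Hanson non-negative least squares on raw linear values. Either
   way, negative coefficients are clipped to zero and the vector is
   renormalized, so the output is a relative composition on the simplex.
   Permutation p-values per sample are deliberately out of scope — only
   point estimates feed the downstream stages.
2. **TME patterns.** Samples are clustered on their fraction vectors.
   The number of clusters K comes from consensus clustering: repeated
   K-means (k-means++ seeding, Lloyd iterations, best of restarts) on
   random 80% subsamples of the samples, accumulated into a consensus
   matrix per K; the proportion of ambiguous clustering, PAC =
   CDF(0.9) − CDF(0.1) of the off-diagonal consensus entries, scores each
   K. All K whose PAC is within 0.01 of the minimum are candidates and the
   **largest** candidate wins — grouping as finely as the evidence
   supports. The within-cluster SSE (elbow) curve is attached for
   diagnostics but never drives the decision, since a clear inflection
   point cannot be assumed. Final labels come from K-means at the chosen
   K.
3. **Differential expression.** Genes separating the TME patterns are
   found with a moderated two-sample t-test on `log2(x + 1)` values:
   per-gene pooled variances are shrunk toward an empirical-Bayes prior
   whose scale and degrees of freedom are estimated by moment matching on
   the marginal distribution of log sample variances (trigamma inversion),
   and the moderated t is referred to a t distribution with residual +
   prior degrees of freedom. Benjamini–Hochberg adjustment is applied
   across genes, and the screening thresholds are strict inequalities:
   adjusted p < 0.05 and |log2FC| > log2(1.5). When more than two TME
   patterns exist, one-vs-rest contrasts are run and their DEG sets
   unioned (the contrast scheme is configurable; the default follows the
   documented two-cluster path).
4. **Signature reduction.** Samples are re-clustered on the DEG matrix
   (consensus K selection again, fresh), and a random-forest classifier of
   those classes ranks DEGs by permutation importance. Genes are retained
   when their importance exceeds the mean + 1 SD of the importances from a
   decoy forest trained on shuffled labels. The importances are the *raw*
   (unscaled) mean decrease in accuracy: the decoy spread is the reference
   scale, and the per-gene normalization of scaled importances would erase
   exactly the quantity the rule thresholds. A `top_n` rule is available
   as an alternative.
5. **Score construction.** Each signature gene is screened with a
   univariate Cox proportional-hazards model on its `log2(x + 1)`
   expression and assigned by the **sign** of its coefficient (magnitude
   is never used): negative = favorable (hazard-decreasing), positive =
   risk. The per-sample score is

   `TMEscore = sum over favorable genes of log2(x + 1) - sum over risk genes of log2(x + 1)`

   **Orientation.** The score adds the favorable set and subtracts the
   risk set, so a higher score always means a more favorable immune
   context and the `TMEscore-high` subtype is, by construction, the
   better-prognosis group. This is the only orientation under which the
   construction is internally consistent: each signature gene's marginal
   Cox sign tracks its association with the favorable subtype, so a score
   that *added* hazard-positive genes would be anti-correlated with
   survival and would label the short-survival group "high". The log2
   pseudo-count transform is the standard one and matches the scale of the
   Cox screen.
6. **Dichotomization.** The score is split at the maximally selected rank
   statistic: every midpoint between consecutive distinct score values
   whose split leaves at least `minprop` (default 0.1) of the samples on
   each side is scored by the standardized log-rank statistic of the
   induced two-group comparison, and the argmax is the cutpoint (ties go
   to the lower cutpoint). A permutation p-value (re-randomizing the score
   vector) is available; the pipeline itself only needs the cutpoint, so
   it defaults to 0 permutations.
7. **Characterization.** Cell-type correlation network with per-cell-type
   survival direction, rank-sum comparisons of cell fractions / TIDE-like
   response scores / MSI groups (MSI-L and MSS are collapsed, as is
   conventional), tumor mutation burden (non-silent mutations per 38 Mb of
   exome by default — both choices configurable since TMB definitions
   vary), per-gene mutation-frequency Fisher tests (raw p is the headline,
   BH-adjusted values are also emitted), variant-allele-fraction
   comparisons, and a paired ROC comparison (DeLong) of the TME score
   against TMB as response biomarkers.

## Survival primitives

The survival core is implemented from its defining formulas and verified
against independent references in the test suite:

* **Product-limit estimator** with censored-only times reducing the
  at-risk counts without steps.
* **Log-rank test** as the Mantel–Haenszel observed-minus-expected sum
  over the 2x2 table at each distinct event time, with the hypergeometric
  variance.
* **Univariate Cox regression** by Newton–Raphson on the partial
  likelihood with Efron's tie correction (day-resolution survival data has
  ties), convergence at |Δβ| < 1e-8 or 50 iterations, standard errors from
  the observed information, and a score test at β = 0 (for a binary
  covariate with untied times it equals the log-rank chi-square — an
  identity the tests exercise). A monotone likelihood (|β| escaping past
  20) is reported as non-convergence rather than a spurious estimate.
* **Maxstat cutpoint** as above; the per-split statistic is exactly the
  log-rank z of that split, so an exhaustive scan with the log-rank test
  is the oracle.

## The synthetic cohort generator

`simulate_cohort()` defines the study conditions every recovery test runs
under. It emulates a TCGA-like cohort of 400 bladder-tumor samples:

* **Composition.** Two latent subtypes with Dirichlet-distributed
  fractions over the 22 types (concentration 5 per type). The immune-rich
  subtype is enriched in CD8 T cells, follicular-helper T cells, activated
  dendritic cells and Tregs; the immune-poor subtype in M0/M2 macrophages
  and resting CD4 memory T cells, with macrophage totals near 17% vs 34% —
  the direction and rough magnitude of the published contrast.
* **Expression.** Marker genes are `signature %*% fractions`; 1000
  background genes have log-normal baselines, 150 of them planted as
  differentially expressed at |log2FC| = 1 (alternating direction);
  everything is multiplied by log-normal noise (sigma 0.1 on the natural
  log scale, a qualitative match to RNA-seq mean-variance behavior) and
  clipped at zero.
* **Gene panel vs cohort randomness.** The marker signature, background
  baselines and the identity of the planted DE genes are drawn under a
  separate `panel_seed` (default 101) from the per-sample randomness.
  Cohorts simulated at different seeds therefore share one gene panel —
  the way independent patient cohorts share one transcriptome — which is
  what makes frozen-model transfer to a validation cohort meaningful.
* **Survival.** Exponential event times with the immune-poor subtype at
  hazard ratio 2.5 and a baseline two-year median; independent exponential
  censoring calibrated to a 50% censoring fraction (typical of TCGA
  follow-up). Exponential forms keep closed-form oracles available.
* **Mutations.** A 200-gene panel headed by recurrently mutated
  bladder-cancer genes (TTN, TP53, KMT2D, KDM6A, ARID1A, PIK3CA, RB1,
  FGFR3, ...). Counts are Poisson with subtype means 55 vs 48 — a
  deliberately weak TMB contrast. VAFs are Beta(2,2) scaled by a
  per-sample purity in [0.35, 0.95], with five genes (RB1, KDM6A, TP53,
  PIK3CA, KMT2D) given subtype-shifted VAF distributions.
* **Response.** The responder flag is Bernoulli with a logit driven by
  immune composition (CD8 + Tfh + activated DC − M0 fractions) plus a
  small mutation-count term, so composition-based scores should
  out-predict TMB without TMB being useless. The TIDE-like
  `response_score` is the negative composition signal plus noise (lower =
  better predicted response); MSI-H is more frequent in the immune-rich
  subtype.

What the generator does **not** emulate: gene-gene co-expression beyond
the shared composition signal, batch effects, non-proportional hazards,
informative censoring, copy-number structure, or mutational trinucleotide
context. Passing recovery tests therefore show the pipeline is correct and
well-calibrated under its own assumptions, not that those assumptions hold
in any particular real cohort.

## Numerical choices and degenerate inputs

* PAC thresholds (0.1, 0.9): the conventional defaults; consensus
  repetitions default to 100 at subsample fraction 0.8 (sampling over
  samples only, features kept), with 5 k-means restarts inside each
  repetition and 25 for the final labeling.
* Zero-variance genes in the DE test get p = 1 and a flag when their mean
  difference is also zero; zero-variance genes in the Cox screen are
  excluded and logged, as are non-convergent fits; a gene with an exactly
  zero coefficient is excluded rather than arbitrarily signed.
* Undefined correlations (zero-variance cell types) are reported as `NA`
  and flagged, never as 0; in the hierarchical cell clustering they are
  treated as distance 0 with a warning.
* Wilcoxon comparisons use exact enumeration up to a combined n of 20
  without ties, otherwise the tie-corrected normal approximation without
  continuity shift (identical groups then give exactly p = 1); fully tied
  data yields p = 1.
* Maxstat ties between equal statistics resolve to the lower cutpoint;
  BH adjustment is order-invariant; model JSON is written at 17
  significant digits so scores and cutpoints round-trip bit-exactly.
* The nu-SVR and NNLS solvers agree on identifiable noiseless mixtures;
  NNLS is the exact reference there and the tests pin it at 1e-6.

## Problem sizes used by the tests

The recovery and calibration tests run at the generator's default cohort
size (n = 400) for the end-to-end checks, with smaller replicate cohorts
(n = 80–200) where a property is measured over 10–25 seeded repetitions
(K-selection rate, DE calibration averaged over ten 200-gene null
cohorts, maxstat-vs-exhaustive-scan equality over 25 replicates). These
sizes were chosen so each property estimate has small Monte-Carlo error
relative to its acceptance band.

## Known limitations

* The deconvolution is relative: fractions sum to 1 by construction, so
  statements about absolute infiltration are out of reach.
* The Cox screen is univariate per gene; genes are oriented by marginal
  sign only, so strongly correlated gene pairs can both enter with the
  same sign even if jointly redundant. The random-forest reduction
  mitigates but does not eliminate redundancy.
* The maxstat permutation p-value is honest but conservative at small n;
  the asymptotic improved-Bonferroni bound is not implemented because the
  pipeline consumes only the cutpoint.
* Validation-set application freezes both the gene sets and the cutpoint
  (the stricter choice); `recut = TRUE` re-estimates the cutpoint on the
  new cohort when its score scale differs, at the cost of no longer being
  a fully frozen model.
* With real data the responder label for the ROC comparison must come
  from an external response score thresholded by the user; the package
  never computes a TIDE-like score itself, it only consumes one.
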