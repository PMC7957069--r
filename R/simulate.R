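# Synthetic-cohort generator. Emulates a TCGA-like bladder-cancer cohort:
# bulk expression formed as mixtures of 22 immune cell types over a marker
# signature plus background genes, two latent TME subtypes with distinct
# Dirichlet composition, planted differentially expressed genes, exponential
# survival tied to the latent subtype, and a per-sample somatic mutation
# table. Ground truth is recorded before noise so every downstream stage can
# be scored.

#' Generate a marker-gene signature matrix
#'
#' Builds a basis matrix for deconvolution: each cell type receives
#' `n_markers_per_type` marker genes whose expression in that type exceeds
#' expression in every other type by more than `fold`.
#'
#' @param n_markers_per_type Markers per cell type (>= 5).
#' @param n_types Number of cell types (default 22; named as the standard
#'   leukocyte panel when 22).
#' @param fold Minimum enrichment of a marker in its own type (> 1).
#' @param seed Integer seed (optional).
#' @return Numeric matrix, markers x cell types, non-negative, full column
#'   rank.
#' @export
generate_signature_matrix <- function(n_markers_per_type = 10L, n_types = 22L,
                                      fold = 4, seed = NULL) {
  if (n_markers_per_type < 5L)
    stop_typed("tme_value_error", "need n_markers_per_type >= 5")
  if (fold <= 1)
    stop_typed("tme_value_error", "need fold > 1")
  maybe_seed(seed)
  types <- if (n_types == 22L) LM22_CELL_TYPES else
    sprintf("CellType%02d", seq_len(n_types))
  m <- n_markers_per_type * n_types
  sig <- matrix(0, nrow = m, ncol = n_types,
                dimnames = list(character(m), types))
  row <- 1L
  for (k in seq_len(n_types)) {
    for (i in seq_len(n_markers_per_type)) {
      base <- rlnorm(1L, meanlog = log(20), sdlog = 0.4)
      off <- base * runif(n_types - 1L, 0.4, 1.0)
      own <- fold * base * runif(1L, 1.05, 1.5)
      sig[row, -k] <- off
      sig[row, k] <- own
      rownames(sig)[row] <- sprintf("MRK_%02d_%02d", k, i)
      row <- row + 1L
    }
  }
  if (qr(sig)$rank < n_types)
    stop_typed("tme_value_error",
               "signature matrix is column-rank deficient; increase markers")
  sig
}

#' Simulate survival times under an exponential hazard model
#'
#' Event times are exponential with hazard `baseline_rate * exp(beta *
#' score)`; censoring times are drawn from an independent exponential whose
#' rate is calibrated so the expected censoring fraction matches
#' `censor_rate`.
#'
#' @param score Numeric per-sample score (the log-linear covariate).
#' @param baseline_rate Baseline hazard (> 0), per day.
#' @param beta Log hazard ratio per unit of `score`.
#' @param censor_rate Target censoring fraction in `[0, 1)`.
#' @param seed Integer seed (optional).
#' @return A list with `os_time` and `os_event` (1 = death observed).
#' @export
simulate_survival <- function(score, baseline_rate = log(2) / 730, beta = 0,
                              censor_rate = 0.5, seed = NULL) {
  if (baseline_rate <= 0)
    stop_typed("tme_value_error", "need baseline_rate > 0")
  if (censor_rate < 0 || censor_rate >= 1)
    stop_typed("tme_value_error", "need 0 <= censor_rate < 1")
  maybe_seed(seed)
  n <- length(score)
  hazard <- baseline_rate * exp(beta * score)
  t_event <- rexp(n, rate = hazard)
  if (censor_rate == 0)
    return(list(os_time = t_event, os_event = rep(1L, n)))
  # expected censoring fraction for censor rate r: mean over samples of
  # r / (r + hazard_i); solve for r
  f <- function(r) mean(r / (r + hazard)) - censor_rate
  r <- stats::uniroot(f, lower = baseline_rate * 1e-8,
                      upper = baseline_rate * 1e8, tol = 1e-12)$root
  t_cens <- rexp(n, rate = r)
  list(os_time = pmin(t_event, t_cens),
       os_event = as.integer(t_event <= t_cens))
}

# Subtype-specific mixing weights over the 22 types. The immune-rich
# ("high") subtype is enriched in CD8 T cells, follicular helper T cells,
# activated dendritic cells and Tregs; the immune-poor ("low") subtype in
# M0/M2 macrophages and resting CD4 memory T cells (macrophage totals of
# roughly 17% vs 34%).
subtype_composition <- function(types) {
  w_high <- setNames(rep(1, length(types)), types)
  w_low <- w_high
  bump <- function(w, at, by) { w[at] <- by; w }
  w_high <- bump(w_high, "T cells CD8", 4)
  w_high <- bump(w_high, "T cells follicular helper", 2)
  w_high <- bump(w_high, "Dendritic cells activated", 2)
  w_high <- bump(w_high, "T cells regulatory (Tregs)", 1.8)
  w_high <- bump(w_high, "Monocytes", 1.5)
  w_high <- bump(w_high, "Macrophages M0", 1.5)
  w_high <- bump(w_high, "Macrophages M1", 1.7)
  w_high <- bump(w_high, "Macrophages M2", 1.7)
  w_low <- bump(w_low, "Macrophages M0", 5)
  w_low <- bump(w_low, "Macrophages M1", 2)
  w_low <- bump(w_low, "Macrophages M2", 2.5)
  w_low <- bump(w_low, "T cells CD4 memory resting", 2)
  w_low <- bump(w_low, "T cells CD8", 0.6)
  w_low <- bump(w_low, "T cells follicular helper", 0.6)
  w_low <- bump(w_low, "Dendritic cells activated", 0.6)
  w_low <- bump(w_low, "T cells regulatory (Tregs)", 0.7)
  list(high = w_high / sum(w_high), low = w_low / sum(w_low))
}

# 200-gene somatic mutation panel with bladder-cancer driver symbols.
mutation_panel <- function() {
  drivers <- c("TTN", "TP53", "KMT2D", "KDM6A", "ARID1A", "PIK3CA", "RB1",
               "FGFR3", "ELF3", "STAG2", "EP300", "KMT2A", "NFE2L2", "DZIP1",
               "POLR2A", "ALMS1", "SOX5", "LRRC37B", "PCDHB12", "PPFIA2",
               "ZNF462", "CREBBP", "ERBB2", "ERBB3", "FAT1", "SPTAN1", "ATM",
               "ERCC2", "ASXL2", "RHOB")
  weights <- c(8, 7, 4, 4, 3.5, 3, 2.5, 2.5, 2, 2, 2, 1.5, 1.5, 1.5, 1.5,
               1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5,
               1.5, 1.5, 1.5)
  filler <- sprintf("PNL%03d", seq_len(200L - length(drivers)))
  data.frame(gene = c(drivers, filler),
             weight = c(weights, rep(0.6, length(filler))),
             stringsAsFactors = FALSE)
}

variant_class_probs <- c(
  Missense_Mutation = 0.62, Silent = 0.18, Nonsense_Mutation = 0.07,
  Frame_Shift_Del = 0.04, Frame_Shift_Ins = 0.03, Splice_Site = 0.03,
  In_Frame_Del = 0.02, Translation_Start_Site = 0.005,
  Nonstop_Mutation = 0.005)

#' Simulate a TCGA-like tumor cohort with recorded ground truth
#'
#' Bulk expression is `signature %*% fractions` on the marker genes plus
#' independent background genes (a subset planted as differentially
#' expressed between the two latent subtypes), under multiplicative
#' log-normal noise. Cell fractions are Dirichlet draws with
#' subtype-specific means. Overall survival is exponential with the
#' immune-poor subtype at hazard ratio `hr`; censoring is independent
#' exponential at rate `censor_rate`. Somatic mutations are Poisson counts
#' over a 200-gene panel with subtype-specific gene weights and
#' Beta(2,2)-times-purity variant allele fractions. The immunotherapy
#' responder flag is driven by immune composition and only weakly by
#' mutation count.
#'
#' @param n_samples Cohort size (default 400).
#' @param signature Marker signature matrix; generated with defaults when
#'   `NULL`.
#' @param prop_high Expected share of the immune-rich subtype (default 0.5).
#' @param concentration Dirichlet concentration per cell type (default 5;
#'   the parameter vector is `concentration * n_types * mean_proportions`).
#' @param n_bg_genes Background (non-marker) genes (default 1000).
#' @param n_de_genes Planted differentially expressed background genes
#'   (default 150; alternating up/down in the immune-rich subtype).
#' @param de_lfc Planted log2 fold change (default 1).
#' @param noise_sd Standard deviation of the multiplicative log-normal
#'   noise on the natural-log scale (default 0.1).
#' @param hr Hazard ratio of the immune-poor vs immune-rich subtype
#'   (default 2.5).
#' @param baseline_rate Baseline hazard per day (default `log(2)/730`, a
#'   two-year median for the favorable subtype).
#' @param censor_rate Target censoring fraction (default 0.5).
#' @param mut_mean_high,mut_mean_low Mean somatic mutation count per sample
#'   by subtype (defaults 55 and 48: a deliberately weak TMB contrast).
#' @param seed Integer seed for the per-sample randomness (default 7).
#' @param panel_seed Integer seed for the gene panel (marker signature,
#'   background baselines, and which genes carry the planted effect).
#'   Cohorts simulated with different `seed` but the same `panel_seed`
#'   share one gene panel, the way independent patient cohorts share one
#'   transcriptome, so a model frozen on one transfers to the other.
#' @return A list of class `"tme_cohort"` with elements `expression`
#'   (genes x samples), `clinical`, `maf`, `signature`, and `truth`
#'   (`true_fractions`, `true_subtype`, `true_de_genes`, `true_beta`,
#'   `latent_risk`, `responder`, `mutation_counts`, `purity`).
#' @export
simulate_cohort <- function(n_samples = 400L, signature = NULL,
                            prop_high = 0.5, concentration = 5,
                            n_bg_genes = 1000L, n_de_genes = 150L,
                            de_lfc = 1, noise_sd = 0.1, hr = 2.5,
                            baseline_rate = log(2) / 730, censor_rate = 0.5,
                            mut_mean_high = 55, mut_mean_low = 48,
                            seed = 7L, panel_seed = 101L) {
  if (n_de_genes > n_bg_genes)
    stop_typed("tme_value_error",
               "n_de_genes (%d) exceeds background gene count (%d)",
               n_de_genes, n_bg_genes)

  # gene panel: fixed by panel_seed, shared across cohorts
  maybe_seed(panel_seed)
  if (is.null(signature)) signature <- generate_signature_matrix()
  bg_genes <- sprintf("GENE%04d", seq_len(n_bg_genes))
  baseline <- rlnorm(n_bg_genes, meanlog = log(30), sdlog = 1)
  lfc <- numeric(n_bg_genes)
  if (n_de_genes > 0)
    lfc[seq_len(n_de_genes)] <- de_lfc * rep_len(c(1, -1), n_de_genes)
  names(lfc) <- bg_genes

  types <- colnames(signature)
  n_types <- length(types)
  samples <- sprintf("SAMPLE_%04d", seq_len(n_samples))

  # per-sample randomness: governed by the cohort seed
  maybe_seed(seed)
  subtype <- ifelse(runif(n_samples) < prop_high, "high", "low")
  comp <- subtype_composition(types)
  alpha_scale <- concentration * n_types
  fr <- matrix(0, n_samples, n_types, dimnames = list(samples, types))
  for (s in c("high", "low")) {
    idx <- which(subtype == s)
    if (length(idx))
      fr[idx, ] <- rdirichlet(length(idx), alpha_scale * comp[[s]])
  }

  # marker-gene block: signature mixed by the true fractions
  marker_expr <- signature %*% t(fr)

  # background block with planted DE genes (alternating direction in the
  # immune-rich subtype)
  bg_expr <- matrix(baseline, n_bg_genes, n_samples,
                    dimnames = list(bg_genes, samples))
  is_high <- subtype == "high"
  if (any(lfc != 0))
    bg_expr[, is_high] <- bg_expr[, is_high] * 2^lfc

  expr <- rbind(marker_expr, bg_expr)
  if (noise_sd > 0)
    expr <- expr * exp(matrix(rnorm(length(expr), 0, noise_sd), nrow(expr)))
  expr <- pmax(expr, 0)
  expr <- expression_matrix(expr, scale_tag = "linear")

  # survival: latent risk 1 for the immune-poor subtype, so "high" survives
  # longer at hazard ratio hr
  z <- as.numeric(!is_high)
  beta <- log(hr)
  surv <- simulate_survival(z, baseline_rate = baseline_rate, beta = beta,
                            censor_rate = censor_rate, seed = NULL)

  # mutations
  panel <- mutation_panel()
  mut_n <- rpois(n_samples, ifelse(is_high, mut_mean_high, mut_mean_low))
  purity <- runif(n_samples, 0.35, 0.95)
  w_high <- w_low <- panel$weight
  names(w_high) <- names(w_low) <- panel$gene
  w_high[c("FGFR3", "KDM6A", "ELF3")] <- w_high[c("FGFR3", "KDM6A", "ELF3")] * 2
  w_low[c("TP53", "RB1")] <- w_low[c("TP53", "RB1")] * 2
  vaf_shift <- c("RB1", "KDM6A", "TP53", "PIK3CA", "KMT2D")
  maf_rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    k <- mut_n[i]
    if (k == 0L) next
    w <- if (is_high[i]) w_high else w_low
    genes <- sample(panel$gene, k, replace = TRUE, prob = w)
    shifted <- genes %in% vaf_shift
    vaf <- rbeta(k, 2, 2)
    if (is_high[i]) vaf[shifted] <- rbeta(sum(shifted), 3.5, 2)
    else vaf[shifted] <- rbeta(sum(shifted), 2, 3.5)
    vaf <- vaf * purity[i]
    depth <- rpois(k, 80) + 20L
    alt <- pmax(1L, rbinom(k, depth, vaf))
    maf_rows[[i]] <- data.frame(
      Tumor_Sample_Barcode = samples[i], Hugo_Symbol = genes,
      Variant_Classification = sample(names(variant_class_probs), k,
                                      replace = TRUE,
                                      prob = variant_class_probs),
      t_alt_count = alt, t_depth = depth, stringsAsFactors = FALSE)
  }
  maf <- validate_maf(do.call(rbind, maf_rows))

  # immunotherapy response driven by immune composition, weakly by
  # mutation count
  imm <- fr[, "T cells CD8"] + fr[, "T cells follicular helper"] +
    fr[, "Dendritic cells activated"] - fr[, "Macrophages M0"]
  lin <- as.numeric(scale(imm)) + 0.15 * as.numeric(scale(mut_n))
  responder <- rbinom(n_samples, 1L, stats::plogis(0.9 * lin - 0.1))
  response_score <- -0.8 * as.numeric(scale(imm)) + rnorm(n_samples, 0, 0.6)
  msi <- ifelse(runif(n_samples) < ifelse(is_high, 0.18, 0.06), "MSI-H",
                ifelse(runif(n_samples) < 0.25, "MSI-L", "MSS"))
  stage <- sample(c("I", "II", "III", "IV"), n_samples, replace = TRUE,
                  prob = c(0.005, 0.32, 0.345, 0.33))

  clinical <- validate_clinical(data.frame(
    sample_id = samples, os_time = surv$os_time, os_event = surv$os_event,
    stage = stage, msi_status = msi, response_score = response_score,
    responder = responder, stringsAsFactors = FALSE))

  truth <- list(
    true_fractions = fr, true_subtype = setNames(subtype, samples),
    true_de_genes = lfc[lfc != 0], true_beta = beta,
    latent_risk = setNames(z, samples),
    responder = setNames(responder, samples),
    mutation_counts = setNames(mut_n, samples),
    purity = setNames(purity, samples))

  structure(list(expression = expr, clinical = clinical, maf = maf,
                 signature = signature, truth = truth),
            class = "tme_cohort")
}

#' @export
print.tme_cohort <- function(x, ...) {
  cat(sprintf("Synthetic TME cohort: %d samples, %d genes (%d markers), %d mutations\n",
              ncol(x$expression), nrow(x$expression), nrow(x$signature),
              nrow(x$maf)))
  tab <- table(x$truth$true_subtype)
  cat(sprintf("Planted subtypes: high = %d, low = %d; hazard ratio = %.3g\n",
              tab[["high"]], tab[["low"]], exp(x$truth$true_beta)))
  invisible(x)
}
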