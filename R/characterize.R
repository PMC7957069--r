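# Subtype characterization: the cell-cell correlation network with per-cell
# survival direction, rank-sum group comparisons (TIDE-like response score,
# MSI), tumor mutation burden, per-gene mutation-frequency Fisher tests,
# variant-allele-fraction comparisons, and paired ROC comparison of two
# biomarkers (DeLong test).

#' Build the immune-cell interaction network
#'
#' Nodes are cell types annotated with their hierarchical cell cluster
#' (A--D) and their overall-survival association (univariate Cox on the
#' fraction: `favorable` if beta < 0 and p < 0.05, `risk` if beta > 0 and
#' p < 0.05, otherwise `ns`). Edges are cell-type pairs with
#' `|Pearson r| >= r_min`; all pairwise correlations are returned alongside
#' the filtered edge list.
#'
#' @param fractions Fraction matrix (samples x cell types).
#' @param clinical Clinical table covering the samples.
#' @param r_min Display threshold on |r| for the edge list (default 0.2).
#' @param n_cell_clusters Hierarchical cell clusters (default 4).
#' @return A list of class `"tme_cell_network"` with `nodes`, `edges`
#'   (i < j unique pairs), and `correlations` (full r/p matrices).
#' @export
build_cell_network <- function(fractions, clinical, r_min = 0.2,
                               n_cell_clusters = 4L) {
  clinical <- validate_clinical(clinical)
  idx <- match(rownames(fractions), clinical$sample_id)
  if (anyNA(idx))
    stop_typed("tme_value_error", "fraction samples missing from clinical")
  cl <- clinical[idx, ]
  clusters <- hierarchical_cluster_cells(fractions, n_cell_clusters)
  cors <- fraction_correlations(fractions)

  nodes <- do.call(rbind, lapply(colnames(fractions), function(ct) {
    v <- fractions[, ct]
    if (var(v) == 0)
      return(data.frame(cell_type = ct, cell_cluster = clusters[[ct]],
                        os_beta = NA_real_, os_p = NA_real_,
                        os_direction = "ns"))
    fit <- cox_univariate(cl$os_time, cl$os_event, v)
    dir <- if (fit$p < 0.05) {
      if (fit$beta < 0) "favorable" else "risk"
    } else "ns"
    data.frame(cell_type = ct, cell_cluster = clusters[[ct]],
               os_beta = fit$beta, os_p = fit$p, os_direction = dir)
  }))

  pairs <- which(upper.tri(cors$r), arr.ind = TRUE)
  edges <- data.frame(
    type_i = colnames(fractions)[pairs[, 1L]],
    type_j = colnames(fractions)[pairs[, 2L]],
    pearson_r = cors$r[pairs], p = cors$p[pairs],
    stringsAsFactors = FALSE)
  edges <- edges[!is.na(edges$pearson_r) & abs(edges$pearson_r) >= r_min, ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, correlations = cors,
                 r_min = r_min),
            class = "tme_cell_network")
}

#' @export
print.tme_cell_network <- function(x, ...) {
  cat(sprintf("Cell network: %d nodes, %d edges at |r| >= %.2f\n",
              nrow(x$nodes), nrow(x$edges), x$r_min))
  sig <- x$nodes[x$nodes$os_direction != "ns", ]
  if (nrow(sig))
    cat("OS-associated:",
        paste(sprintf("%s (%s)", sig$cell_type, sig$os_direction),
              collapse = ", "), "\n")
  invisible(x)
}

#' Two-group rank-sum comparison
#'
#' Two-sided Wilcoxon rank-sum test: exact enumeration when the combined
#' size is at most 20 and there are no ties, otherwise the tie-corrected
#' normal approximation (no continuity correction, so identical groups give
#' p = 1).
#'
#' @param values Numeric vector.
#' @param groups Binary labels (two non-empty levels).
#' @return A list with `w`, `p`, `medians` (named by group), `exact`.
#' @export
group_compare <- function(values, groups) {
  f <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (nlevels(f) != 2L)
    stop_typed("tme_value_error", "need exactly two non-empty groups")
  a <- values[f == levels(f)[1L]]
  b <- values[f == levels(f)[2L]]
  exact <- (length(a) + length(b) <= 20L) &&
    !anyDuplicated(c(a, b))
  ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = FALSE))
  p <- ht$p.value
  if (!is.finite(p)) p <- 1  # degenerate all-tied data carries no evidence
  list(w = unname(ht$statistic), p = p,
       medians = setNames(c(median(a), median(b)), levels(f)),
       exact = exact)
}

#' Tumor mutation burden per sample
#'
#' Mutation count (restricted to non-silent variant classifications when
#' `nonsyn_only`) divided by the exome size in megabases. Samples absent
#' from the MAF receive TMB 0 and are flagged.
#'
#' @param maf MAF-like data.frame (see [read_maf()]).
#' @param samples Sample ids to report (defaults to those in the MAF).
#' @param exome_mb Exome size in Mb (default 38).
#' @param nonsyn_only Count only non-silent classes (default TRUE).
#' @param nonsilent_classes Variant classes counted as non-silent.
#' @return Data frame with `sample_id`, `n_mutations`, `tmb`,
#'   `in_maf` (flag).
#' @export
compute_tmb <- function(maf, samples = NULL, exome_mb = 38,
                        nonsyn_only = TRUE,
                        nonsilent_classes = NONSILENT_CLASSES) {
  if (exome_mb <= 0) stop_typed("tme_value_error", "need exome_mb > 0")
  if (is.null(samples)) samples <- unique(maf$Tumor_Sample_Barcode)
  use <- if (nonsyn_only)
    maf[maf$Variant_Classification %in% nonsilent_classes, , drop = FALSE]
  else maf
  counts <- table(factor(use$Tumor_Sample_Barcode, levels = samples))
  data.frame(sample_id = samples, n_mutations = as.integer(counts),
             tmb = as.numeric(counts) / exome_mb,
             in_maf = samples %in% maf$Tumor_Sample_Barcode,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene mutation-frequency comparison between subtypes
#'
#' For each gene, a 2x2 table of mutated/wild-type samples by subtype is
#' tested with the two-sided Fisher exact test (a sample counts as mutated
#' once per gene regardless of mutation multiplicity).
#'
#' @param maf MAF-like data.frame.
#' @param subtypes Named character vector (sample id -> subtype, two
#'   levels); samples absent from the MAF count as wild-type.
#' @return Data frame with per-gene mutated counts by subtype, group
#'   sizes, `fisher_p`, and BH-adjusted `fisher_p_adj`, sorted by p.
#' @export
mutation_frequency_test <- function(maf, subtypes) {
  lv <- sort(unique(subtypes))
  if (length(lv) != 2L)
    stop_typed("tme_value_error", "need exactly two subtypes")
  samples <- names(subtypes)
  n1 <- sum(subtypes == lv[1L]); n2 <- sum(subtypes == lv[2L])
  maf <- maf[maf$Tumor_Sample_Barcode %in% samples, , drop = FALSE]
  mut <- unique(maf[, c("Hugo_Symbol", "Tumor_Sample_Barcode")])
  mut$subtype <- subtypes[mut$Tumor_Sample_Barcode]
  genes <- sort(unique(mut$Hugo_Symbol))
  rows <- lapply(genes, function(g) {
    m <- mut[mut$Hugo_Symbol == g, ]
    m1 <- sum(m$subtype == lv[1L]); m2 <- sum(m$subtype == lv[2L])
    p <- fisher.test(matrix(c(m1, n1 - m1, m2, n2 - m2), 2L))$p.value
    data.frame(gene = g, n_mut_a = m1, n_mut_b = m2,
               n_a = n1, n_b = n2, fisher_p = p)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("n_mut_", make.names(lv)),
                       paste0("n_", make.names(lv)))
  out$fisher_p_adj <- adjust_bh(out$fisher_p)
  out[order(out$fisher_p), ]
}

#' Compare variant allele fractions between subtypes per gene
#'
#' For each requested gene with at least one mutation in each subtype, the
#' per-mutation VAF values are compared with [group_compare()]; genes
#' absent from a subtype are skipped and flagged.
#'
#' @param maf MAF-like data.frame (with `vaf`).
#' @param subtypes Named character vector (sample id -> subtype).
#' @param genes Genes to test (default: all mutated genes).
#' @return Data frame with per-gene median VAF by subtype, `p`, and
#'   `skipped` flag.
#' @export
vaf_compare <- function(maf, subtypes, genes = NULL) {
  lv <- sort(unique(subtypes))
  if (length(lv) != 2L)
    stop_typed("tme_value_error", "need exactly two subtypes")
  maf <- maf[maf$Tumor_Sample_Barcode %in% names(subtypes), , drop = FALSE]
  maf$subtype <- subtypes[maf$Tumor_Sample_Barcode]
  if (is.null(genes)) genes <- sort(unique(maf$Hugo_Symbol))
  rows <- lapply(genes, function(g) {
    m <- maf[maf$Hugo_Symbol == g, ]
    va <- m$vaf[m$subtype == lv[1L]]
    vb <- m$vaf[m$subtype == lv[2L]]
    if (!length(va) || !length(vb))
      return(data.frame(gene = g, median_vaf_a = NA_real_,
                        median_vaf_b = NA_real_, p = NA_real_,
                        skipped = TRUE))
    gc <- group_compare(m$vaf, m$subtype)
    data.frame(gene = g, median_vaf_a = median(va), median_vaf_b = median(vb),
               p = gc$p, skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("median_vaf_", make.names(lv))
  out
}

#' ROC comparison of two paired biomarkers
#'
#' AUC via the rank / Mann-Whitney identity with ties counted one half
#' (computed through a fixed-direction ROC so that `AUC(score) +
#' AUC(-score) = 1`); the paired AUC difference is tested with DeLong's
#' structural-components variance, two-sided.
#'
#' @param score_a,score_b Numeric scores on the same samples.
#' @param labels Binary outcome (1 = positive class).
#' @return A list of class `"tme_roc_compare"` with elements `roc_a` and
#'   `roc_b` (each `thresholds`, `tpr`, `fpr`, `auc`), `delta_auc`, and
#'   `delong_p`.
#' @export
roc_compare <- function(score_a, score_b, labels) {
  if (!is_binary01(labels))
    stop_typed("tme_value_error", "labels must be 0/1")
  if (length(unique(labels)) != 2L)
    stop_typed("tme_value_error", "both outcome classes must be present")
  if (length(score_a) != length(labels) || length(score_b) != length(labels))
    stop_typed("tme_value_error", "scores and labels must be paired")
  mk <- function(s) {
    r <- pROC::roc(response = labels, predictor = s, direction = "<",
                   levels = c(0, 1), quiet = TRUE)
    list(thresholds = r$thresholds, tpr = r$sensitivities,
         fpr = 1 - r$specificities, auc = as.numeric(r$auc), roc = r)
  }
  a <- mk(score_a); b <- mk(score_b)
  delong_p <- if (isTRUE(all.equal(score_a, score_b))) 1 else {
    ht <- tryCatch(pROC::roc.test(a$roc, b$roc, method = "delong",
                                  paired = TRUE),
                   error = function(e) NULL)
    if (is.null(ht) || is.na(ht$p.value)) 1 else ht$p.value
  }
  structure(list(roc_a = a[c("thresholds", "tpr", "fpr", "auc")],
                 roc_b = b[c("thresholds", "tpr", "fpr", "auc")],
                 delta_auc = a$auc - b$auc, delong_p = delong_p),
            class = "tme_roc_compare")
}

#' @export
print.tme_roc_compare <- function(x, ...) {
  cat(sprintf("AUC(a) = %.4f, AUC(b) = %.4f, delta = %.4f, DeLong p = %.3g\n",
              x$roc_a$auc, x$roc_b$auc, x$delta_auc, x$delong_p))
  invisible(x)
}

#' Characterize fitted subtypes against genomic and response data
#'
#' Convenience wrapper running the cell network, fraction comparisons,
#' response-score and MSI comparisons, TMB, mutation-frequency and VAF
#' tests, and the TME score vs TMB ROC comparison, given a fitted model and
#' the cohort tables.
#'
#' @param model A fitted `"tme_model"` (with training score table).
#' @param maf Optional MAF-like data.frame.
#' @param clinical Clinical table (defaults to the training table).
#' @param fractions Fraction matrix (defaults to the training fractions).
#' @return A list with the individual result tables (elements are `NULL`
#'   when their inputs are unavailable).
#' @export
characterize_subtypes <- function(model, maf = NULL, clinical = NULL,
                                  fractions = NULL) {
  clinical <- validate_clinical(clinical %||% model$clinical)
  fractions <- fractions %||% model$fractions
  st <- model$score_table
  cl <- clinical[match(st$sample_id, clinical$sample_id), ]
  subtypes <- setNames(st$subtype, st$sample_id)
  out <- list()

  out$network <- build_cell_network(fractions, clinical)
  out$fraction_tests <- do.call(rbind, lapply(colnames(fractions),
    function(ct) {
      gc <- group_compare(fractions[st$sample_id, ct], st$subtype)
      data.frame(cell_type = ct, median_high = gc$medians[["TMEscore-high"]],
                 median_low = gc$medians[["TMEscore-low"]], p = gc$p)
    }))
  out$fraction_tests$p_adj <- adjust_bh(out$fraction_tests$p)

  if (!is.null(cl$response_score) && any(!is.na(cl$response_score))) {
    gc <- group_compare(cl$response_score, st$subtype)
    out$response_score <- data.frame(
      median_high = gc$medians[["TMEscore-high"]],
      median_low = gc$medians[["TMEscore-low"]], p = gc$p)
  }
  if (!is.null(cl$msi_status) && any(!is.na(cl$msi_status))) {
    # MSI-L and MSS collapse into one comparison group
    grp <- ifelse(cl$msi_status == "MSI-H", "MSI-H", "MSI-L/MSS")
    gc <- group_compare(st$tmescore, grp)
    out$msi <- data.frame(median_msi_h = gc$medians[["MSI-H"]],
                          median_msi_l_mss = gc$medians[["MSI-L/MSS"]],
                          p = gc$p)
  }
  if (!is.null(maf)) {
    out$tmb <- compute_tmb(maf, samples = st$sample_id)
    out$mutation_tests <- mutation_frequency_test(maf, subtypes)
    top <- head(out$mutation_tests$gene[
      order(-(out$mutation_tests[[2L]] + out$mutation_tests[[3L]]))], 10L)
    out$vaf <- vaf_compare(maf, subtypes, genes = top)
    if (!is.null(cl$responder) && length(unique(cl$responder)) == 2L) {
      tmb <- out$tmb$tmb[match(st$sample_id, out$tmb$sample_id)]
      out$roc <- roc_compare(st$tmescore, tmb, cl$responder)
    }
  }
  out
}
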