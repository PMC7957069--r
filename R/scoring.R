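# The score construction: random-forest reduction of DEGs to cluster
# signature genes, orientation of each gene by the sign of its univariate
# Cox coefficient, the per-sample TME score, and dichotomization at the
# maxstat survival cutpoint.
#
# Score orientation: the score ADDS log2(x + 1) expression over genes whose
# Cox coefficient is negative (hazard-decreasing, "favorable") and SUBTRACTS
# the same sum over genes with a positive coefficient ("risk"), so a higher
# score always means a more favorable immune context and the score-high
# subtype is the better-prognosis one, matching the reported behavior of
# the subtypes it reproduces (see the methods vignette).

#' Reduce differentially expressed genes to cluster signature genes
#'
#' Trains a random-forest classifier of the sample classes on DEG
#' expression (log2 scale) and ranks genes by permutation importance.
#' Under the default `"decoy"` rule a second forest is trained on
#' shuffled class labels and genes are retained when their importance
#' exceeds `mean + 1 sd` of the decoy importances; `"top_n"` retains the
#' `n_top` highest-importance genes. Exact duplicate expression rows among
#' the retained genes are collapsed to the first occurrence.
#'
#' @param expr Expression matrix restricted to candidate genes
#'   (genes x samples).
#' @param classes Class labels (>= 2 classes), one per sample.
#' @param n_trees Trees per forest (default 1000).
#' @param retain_rule `"decoy"` (default) or `"top_n"`.
#' @param n_top Number of genes for `"top_n"`.
#' @param seed Integer seed (optional).
#' @return Character vector of retained gene ids (importance order
#'   preserved as in the input gene order).
#' @export
derive_cluster_signature <- function(expr, classes, n_trees = 1000L,
                                     retain_rule = c("decoy", "top_n"),
                                     n_top = 50L, seed = NULL) {
  retain_rule <- match.arg(retain_rule)
  maybe_seed(seed)
  f <- if (is.factor(classes)) droplevels(classes) else factor(classes)
  if (nlevels(f) < 2L)
    stop_typed("tme_value_error", "need >= 2 classes")
  if (length(f) != ncol(expr))
    stop_typed("tme_value_error", "one class label per sample required")
  t0 <- as.numeric(Sys.time())
  x <- t(as_log2p1(expr))
  colnames(x) <- rownames(expr)
  rf <- randomForest::randomForest(x = x, y = f, ntree = n_trees,
                                   importance = TRUE)
  # raw (unscaled) permutation importance: the decoy spread below is the
  # reference scale, so the per-gene normalization must not erase it
  imp <- randomForest::importance(rf, type = 1L, scale = FALSE)[, 1L]
  keep <- if (retain_rule == "top_n") {
    names(sort(imp, decreasing = TRUE))[seq_len(min(n_top, length(imp)))]
  } else {
    rf0 <- randomForest::randomForest(x = x, y = sample(f), ntree = n_trees,
                                      importance = TRUE)
    imp0 <- randomForest::importance(rf0, type = 1L, scale = FALSE)[, 1L]
    names(imp)[imp > mean(imp0) + sd(imp0)]
  }
  keep <- rownames(expr)[rownames(expr) %in% keep]
  # collapse exact duplicate expression profiles among retained genes
  if (length(keep) > 1L) {
    dup <- duplicated(as.data.frame(t(x[, keep, drop = FALSE])))
    keep <- keep[!dup]
  }
  log_stage("signature", dim(expr), length(keep), t0)
  keep
}

#' Split signature genes by the sign of their Cox coefficient
#'
#' Fits a univariate Cox model per gene on `log2(x + 1)` expression.
#' Genes with `beta > 0` are hazard-increasing (`risk`); genes with
#' `beta < 0` are hazard-decreasing (`favorable`). Genes with exactly
#' zero coefficient, a non-convergent fit, or (when `p_max < 1`) a Wald p
#' above `p_max` are excluded and logged.
#'
#' @param expr Expression matrix (genes x samples).
#' @param clinical Clinical table with `sample_id`, `os_time`, `os_event`.
#' @param signature_genes Genes to screen (must have positive variance).
#' @param p_max Optional Wald-p ceiling (default 1: keep all).
#' @return A list with data.frames `favorable` and `risk` (columns `gene`,
#'   `beta`, `p`, `low_confidence` flagging p > 0.05), and `excluded`.
#' @export
split_by_cox_sign <- function(expr, clinical, signature_genes, p_max = 1) {
  clinical <- validate_clinical(clinical)
  idx <- match(clinical$sample_id, colnames(expr))
  if (anyNA(idx))
    stop_typed("tme_value_error", "clinical samples missing from expression")
  x <- as_log2p1(expr)[, idx, drop = FALSE]
  miss <- setdiff(signature_genes, rownames(x))
  if (length(miss))
    stop_typed("tme_value_error", "signature gene(s) absent from expression: %s",
               paste(head(miss, 5L), collapse = ", "))
  rows <- lapply(signature_genes, function(g) {
    v <- x[g, ]
    if (var(v) == 0)
      return(data.frame(gene = g, beta = NA_real_, p = NA_real_,
                        status = "zero_variance"))
    fit <- tryCatch(cox_univariate(clinical$os_time, clinical$os_event, v),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
      return(data.frame(gene = g, beta = NA_real_, p = NA_real_,
                        status = "not_converged"))
    data.frame(gene = g, beta = fit$beta, p = fit$p, status = "ok")
  })
  tab <- do.call(rbind, rows)
  ok <- tab$status == "ok" & !is.na(tab$beta) & tab$beta != 0 &
    (p_max >= 1 | (!is.na(tab$p) & tab$p <= p_max))
  excluded <- tab[!ok, , drop = FALSE]
  if (nrow(excluded))
    tme_log("cox_split", sprintf("excluded %d gene(s): %s", nrow(excluded),
                                 paste(head(excluded$gene, 5L),
                                       collapse = ", ")))
  kept <- tab[ok, , drop = FALSE]
  kept$low_confidence <- kept$p > 0.05
  list(favorable = kept[kept$beta < 0,
                        c("gene", "beta", "p", "low_confidence")],
       risk = kept[kept$beta > 0, c("gene", "beta", "p", "low_confidence")],
       excluded = excluded)
}

#' Compute the per-sample TME score
#'
#' `score = sum over favorable genes of log2(x + 1) - sum over risk genes
#' of log2(x + 1)`. Model genes absent from the matrix are dropped with a
#' warning; an empty favorable or risk set after dropping is an error.
#'
#' @param expr Expression matrix (linear or log2p1 scale).
#' @param model A `"tme_model"` or any list with character vectors
#'   `favorable_genes` and `risk_genes`.
#' @return Named numeric vector of scores (one per sample).
#' @export
compute_tmescore <- function(expr, model) {
  fav <- model$favorable_genes
  rsk <- model$risk_genes
  x <- as_log2p1(expr)
  fav_in <- intersect(fav, rownames(x))
  rsk_in <- intersect(rsk, rownames(x))
  if (length(fav_in) < length(fav) || length(rsk_in) < length(rsk))
    warn_typed("tme_missing_gene_warning",
               "dropping %d favorable and %d risk gene(s) absent from matrix",
               length(fav) - length(fav_in), length(rsk) - length(rsk_in))
  if (!length(fav_in) || !length(rsk_in))
    stop_typed("tme_value_error",
               "need >= 1 favorable and >= 1 risk gene present")
  colSums(x[fav_in, , drop = FALSE]) - colSums(x[rsk_in, , drop = FALSE])
}

#' Dichotomize TME scores at the optimal survival cutpoint
#'
#' The cutpoint comes from [maxstat_cutpoint()]; samples with
#' `score > cutpoint` are labeled `TMEscore-high`, the rest
#' `TMEscore-low`.
#'
#' @param scores Named numeric scores (names = sample ids).
#' @param clinical Clinical table covering the scored samples.
#' @param minprop Minimum group fraction for the cutpoint search.
#' @param n_perm Permutations for the cutpoint p-value (default 0).
#' @param seed Integer seed (optional).
#' @return A list with `cutpoint` (a `"tme_cutpoint"`) and `score_table`
#'   (data.frame `sample_id`, `tmescore`, `subtype`).
#' @export
dichotomize <- function(scores, clinical, minprop = 0.1, n_perm = 0L,
                        seed = NULL) {
  clinical <- validate_clinical(clinical)
  idx <- match(names(scores), clinical$sample_id)
  if (anyNA(idx))
    stop_typed("tme_value_error", "scored samples missing from clinical table")
  cl <- clinical[idx, ]
  cp <- maxstat_cutpoint(cl$os_time, cl$os_event, as.numeric(scores),
                         minprop = minprop, n_perm = n_perm, seed = seed)
  list(cutpoint = cp,
       score_table = data.frame(
         sample_id = names(scores), tmescore = as.numeric(scores),
         subtype = unname(ifelse(scores > cp$cutpoint, "TMEscore-high",
                                 "TMEscore-low")),
         row.names = NULL, stringsAsFactors = FALSE))
}
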