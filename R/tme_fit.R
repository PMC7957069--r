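# The central fitting routine: from bulk expression + clinical follow-up to
# a fitted TME subtype/score model, following the construction sequence
# deconvolution -> consensus clustering of cell fractions -> DEGs between
# TME clusters -> consensus re-clustering on DEGs -> random-forest signature
# reduction -> Cox-sign split -> TME score -> maxstat dichotomization.

#' Control parameters for [tme_fit()]
#'
#' @param deconv_method Deconvolution solver (`"nu-svr"` or `"nnls"`).
#' @param k_range Candidate cluster counts for both consensus steps.
#' @param n_reps Consensus subsampling repetitions.
#' @param subsample Consensus subsampling fraction.
#' @param inner_restarts K-means restarts inside consensus repetitions.
#' @param pac_tol PAC tie tolerance for K selection.
#' @param p_adj_max,lfc_min DEG thresholds (adjusted p and |log2FC|).
#' @param n_trees Random-forest trees for signature reduction.
#' @param retain_rule Signature retention rule (`"decoy"` or `"top_n"`).
#' @param n_top Gene count for `retain_rule = "top_n"`.
#' @param cox_p_max Optional Wald-p ceiling for the Cox-sign split.
#' @param minprop Minimum group fraction for the maxstat cutpoint.
#' @param n_perm Permutations for the cutpoint p-value (0 = skip).
#' @return A named list of validated control parameters.
#' @export
tme_control <- function(deconv_method = "nu-svr", k_range = 2:5,
                        n_reps = 100L, subsample = 0.8, inner_restarts = 5L,
                        pac_tol = 0.01, p_adj_max = 0.05,
                        lfc_min = log2(1.5), n_trees = 1000L,
                        retain_rule = "decoy", n_top = 50L, cox_p_max = 1,
                        minprop = 0.1, n_perm = 0L) {
  list(deconv_method = match.arg(deconv_method, c("nu-svr", "nnls")),
       k_range = as.integer(k_range), n_reps = as.integer(n_reps),
       subsample = subsample, inner_restarts = as.integer(inner_restarts),
       pac_tol = pac_tol, p_adj_max = p_adj_max, lfc_min = lfc_min,
       n_trees = as.integer(n_trees),
       retain_rule = match.arg(retain_rule, c("decoy", "top_n")),
       n_top = as.integer(n_top), cox_p_max = cox_p_max, minprop = minprop,
       n_perm = as.integer(n_perm))
}

#' Fit the TME subtype and score model
#'
#' @param expr Expression matrix (genes x samples, linear scale).
#' @param clinical Clinical table covering the expression samples
#'   (`sample_id`, `os_time`, `os_event`, optional extras).
#' @param signature Marker signature matrix for deconvolution (required
#'   unless `fractions` is supplied).
#' @param fractions Optional precomputed fraction matrix (samples x cell
#'   types); skips the deconvolution stage.
#' @param control See [tme_control()].
#' @param seed Integer seed governing every stochastic stage.
#' @return An object of class `"tme_model"`; see [predict.tme_model()],
#'   [compute_tmescore()], [write_tme_model()].
#' @export
tme_fit <- function(expr, clinical, signature = NULL, fractions = NULL,
                    control = tme_control(), seed = 1L) {
  t0 <- as.numeric(Sys.time())
  clinical <- validate_clinical(clinical)
  idx <- match(clinical$sample_id, colnames(expr))
  if (anyNA(idx))
    stop_typed("tme_value_error",
               "clinical sample(s) missing from expression: %s",
               paste(head(clinical$sample_id[is.na(idx)], 5L),
                     collapse = ", "))
  expr <- expr[, idx, drop = FALSE]
  attr(expr, "scale_tag") <- attr(expr, "scale_tag") %||% "linear"
  maybe_seed(seed)

  # 1. immune-cell fractions
  if (is.null(fractions)) {
    if (is.null(signature))
      stop_typed("tme_value_error", "need a signature matrix or fractions")
    fractions <- estimate_fractions(expr, signature,
                                    method = control$deconv_method)
  } else {
    fractions <- validate_fractions(as.matrix(fractions))
    fractions <- fractions[match(clinical$sample_id, rownames(fractions)), ,
                           drop = FALSE]
  }

  # 2. TME patterns: consensus K selection on fractions, then K-means
  cons_fr <- consensus_cluster(fractions, k_values = control$k_range,
                               n_reps = control$n_reps,
                               subsample = control$subsample,
                               inner_restarts = control$inner_restarts)
  sse_fr <- sse_curve(fractions, control$k_range, n_restarts = 10L)
  k_tme <- select_k(cons_fr, sse = sse_fr, pac_tol = control$pac_tol)$k
  tme_clusters <- tme_kmeans(fractions, k_tme, n_restarts = 25L)$labels
  names(tme_clusters) <- rownames(fractions)
  tme_log("tme_clusters", sprintf("K = %d (PAC %s)", k_tme,
          paste(sprintf("%.3f", cons_fr$pac), collapse = "/")))

  # 3. DEGs between TME clusters (one-vs-rest union when K > 2)
  degs <- union_degs(expr, tme_clusters, control$p_adj_max, control$lfc_min)
  if (length(degs) < 2L)
    stop_typed("tme_value_error",
               "fewer than 2 DEGs at the configured thresholds")

  # 4. re-cluster samples on DEG expression (genes z-scored on log2 scale)
  deg_mat <- scale(t(as_log2p1(expr)[degs, , drop = FALSE]))
  deg_mat[is.na(deg_mat)] <- 0
  cons_deg <- consensus_cluster(deg_mat, k_values = control$k_range,
                                n_reps = control$n_reps,
                                subsample = control$subsample,
                                inner_restarts = control$inner_restarts)
  k_classes <- select_k(cons_deg, pac_tol = control$pac_tol)$k
  classes <- tme_kmeans(deg_mat, k_classes, n_restarts = 25L)$labels
  names(classes) <- rownames(deg_mat)

  # 5. signature genes by random-forest importance
  signature_genes <- derive_cluster_signature(
    expr[degs, , drop = FALSE], classes, n_trees = control$n_trees,
    retain_rule = control$retain_rule, n_top = control$n_top)
  if (length(signature_genes) < 2L)
    stop_typed("tme_value_error", "signature reduction retained < 2 genes")

  # 6. Cox-sign split
  split <- split_by_cox_sign(expr, clinical, signature_genes,
                             p_max = control$cox_p_max)
  if (!nrow(split$favorable) || !nrow(split$risk))
    stop_typed("tme_value_error",
               "Cox screen produced an empty favorable or risk set")

  model <- structure(list(
    favorable = split$favorable, risk = split$risk,
    favorable_genes = split$favorable$gene, risk_genes = split$risk$gene,
    signature_genes = signature_genes, degs = degs,
    k_tme = k_tme, k_classes = k_classes,
    pac_fractions = cons_fr$pac, pac_degs = cons_deg$pac,
    sse_fractions = sse_fr,
    cutpoint = NA_real_, minprop = control$minprop,
    control = control, seed = seed,
    trained_on = list(n_samples = ncol(expr), n_genes = nrow(expr))),
    class = "tme_model")

  # 7. score + maxstat dichotomization
  scores <- compute_tmescore(expr, model)
  cut <- dichotomize(scores, clinical, minprop = control$minprop,
                     n_perm = control$n_perm)
  model$cutpoint <- cut$cutpoint$cutpoint
  model$cutpoint_detail <- cut$cutpoint
  model$score_table <- cut$score_table
  model$tme_clusters <- tme_clusters
  model$classes <- classes
  model$fractions <- fractions
  model$clinical <- clinical
  lr <- logrank_test(clinical$os_time, clinical$os_event,
                     cut$score_table$subtype)
  model$logrank <- lr
  log_stage("tme_fit", dim(expr), length(scores), t0)
  model
}

# one-vs-rest union of DEG sets (identity contrast when K = 2)
union_degs <- function(expr, clusters, p_adj_max, lfc_min) {
  f <- factor(clusters)
  if (nlevels(f) == 2L) {
    de <- moderated_de_test(expr, f)
    return(filter_degs(de, p_adj_max, lfc_min))
  }
  out <- character(0)
  for (lev in levels(f)) {
    g <- factor(ifelse(f == lev, "this", "rest"), levels = c("this", "rest"))
    de <- moderated_de_test(expr, g)
    out <- union(out, filter_degs(de, p_adj_max, lfc_min))
  }
  rownames(expr)[rownames(expr) %in% out]
}

#' Apply a frozen TME model to a new expression matrix
#'
#' Scores are computed with the frozen gene sets and labels with the frozen
#' cutpoint; at least 50% of each gene set must be present (overlap is
#' logged). With `recut = TRUE` and a clinical table, the cutpoint is
#' re-estimated on the new cohort instead.
#'
#' @param expr_new New expression matrix (linear or log2p1 scale).
#' @param model A fitted `"tme_model"` (or one read back from JSON).
#' @param clinical Optional clinical table (required for `recut`).
#' @param recut Re-estimate the cutpoint on the new cohort (default FALSE).
#' @return Data frame with `sample_id`, `tmescore`, `subtype`.
#' @export
apply_model <- function(expr_new, model, clinical = NULL, recut = FALSE) {
  fav_in <- mean(model$favorable_genes %in% rownames(expr_new))
  rsk_in <- mean(model$risk_genes %in% rownames(expr_new))
  tme_log("apply_model", sprintf(
    "gene-set overlap: favorable %.0f%%, risk %.0f%%",
    100 * fav_in, 100 * rsk_in))
  if (fav_in < 0.5 || rsk_in < 0.5)
    stop_typed("tme_value_error",
               "less than 50%% of a model gene set present in the new matrix")
  scores <- suppressWarnings(compute_tmescore(expr_new, model))
  if (recut) {
    if (is.null(clinical))
      stop_typed("tme_value_error", "recut requires a clinical table")
    return(dichotomize(scores, clinical, minprop = model$minprop)$score_table)
  }
  data.frame(sample_id = names(scores), tmescore = as.numeric(scores),
             subtype = ifelse(scores > model$cutpoint, "TMEscore-high",
                              "TMEscore-low"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.tme_model <- function(x, ...) {
  cat("TME subtype/score model\n")
  cat(sprintf("  TME clusters (fractions): K = %d; DEG classes: K = %d\n",
              x$k_tme, x$k_classes))
  cat(sprintf("  DEGs: %d; signature genes: %d (favorable %d / risk %d)\n",
              length(x$degs), length(x$signature_genes),
              length(x$favorable_genes), length(x$risk_genes)))
  cat(sprintf("  Score cutpoint: %.4f\n", x$cutpoint))
  if (!is.null(x$score_table)) {
    tab <- table(x$score_table$subtype)
    cat(sprintf("  Subtypes: %s\n",
                paste(sprintf("%s n = %d", names(tab), tab),
                      collapse = ", ")))
  }
  if (!is.null(x$logrank))
    cat(sprintf("  Log-rank high vs low: chi2 = %.2f, p = %.3g\n",
                x$logrank$chi_square, x$logrank$p))
  invisible(x)
}

#' @export
summary.tme_model <- function(object, ...) {
  print(object)
  cat("\nPAC by K (fraction clustering):\n")
  print(round(object$pac_fractions, 4))
  cat("PAC by K (DEG re-clustering):\n")
  print(round(object$pac_degs, 4))
  cat("\nTop favorable genes (most negative Cox beta):\n")
  fav <- object$favorable[order(object$favorable$beta), ]
  print(head(fav, 5L), row.names = FALSE)
  cat("Top risk genes (most positive Cox beta):\n")
  rsk <- object$risk[order(-object$risk$beta), ]
  print(head(rsk, 5L), row.names = FALSE)
  invisible(object)
}

#' @export
coef.tme_model <- function(object, ...) {
  both <- rbind(object$favorable, object$risk)
  setNames(both$beta, both$gene)
}

#' @export
predict.tme_model <- function(object, newdata, clinical = NULL,
                              recut = FALSE, ...) {
  apply_model(newdata, object, clinical = clinical, recut = recut)
}

#' @export
plot.tme_model <- function(x, ...) {
  if (is.null(x$score_table) || is.null(x$clinical))
    stop_typed("tme_value_error", "model carries no training cohort to plot")
  st <- x$score_table
  cl <- x$clinical[match(st$sample_id, x$clinical$sample_id), ]
  hi <- st$subtype == "TMEscore-high"
  km_hi <- km_estimate(cl$os_time[hi], cl$os_event[hi])
  km_lo <- km_estimate(cl$os_time[!hi], cl$os_event[!hi])
  plot(stats::stepfun(km_hi$time, c(1, km_hi$survival)), do.points = FALSE,
       xlim = c(0, max(cl$os_time)), ylim = c(0, 1), col = "#2166ac",
       xlab = "Time (days)", ylab = "Overall survival",
       main = "TME score subtypes", ...)
  lines(stats::stepfun(km_lo$time, c(1, km_lo$survival)), do.points = FALSE,
        col = "#b2182b")
  legend("bottomleft", lwd = 2, col = c("#2166ac", "#b2182b"), bty = "n",
         legend = c(sprintf("TMEscore-high (n = %d)", sum(hi)),
                    sprintf("TMEscore-low (n = %d)", sum(!hi))))
  invisible(x)
}

#' Serialize a fitted TME model to JSON
#'
#' Numbers are written at full precision so that a write/read round trip
#' reproduces scores bit-exactly.
#'
#' @param model A `"tme_model"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tme_model <- function(model, path) {
  payload <- list(
    favorable = model$favorable, risk = model$risk,
    signature_genes = model$signature_genes,
    cutpoint = model$cutpoint, minprop = model$minprop,
    k_tme = model$k_tme, k_classes = model$k_classes,
    seed = model$seed, trained_on = model$trained_on)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized TME model
#' @param path JSON path written by [write_tme_model()].
#' @return A `"tme_model"` (sufficient for scoring and prediction).
#' @export
read_tme_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    favorable = as.data.frame(p$favorable), risk = as.data.frame(p$risk),
    favorable_genes = as.character(p$favorable$gene),
    risk_genes = as.character(p$risk$gene),
    signature_genes = as.character(p$signature_genes),
    cutpoint = p$cutpoint, minprop = p$minprop,
    k_tme = p$k_tme, k_classes = p$k_classes, seed = p$seed,
    trained_on = p$trained_on), class = "tme_model")
}
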