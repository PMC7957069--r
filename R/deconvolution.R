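# Signature-based immune-cell deconvolution: estimates relative fractions of
# the 22 leukocyte types in each bulk sample by regressing the sample's
# marker-gene vector on the signature columns. Two solvers: nu-support-vector
# regression (the published algorithm's core, with the nu grid and z-score
# standardization) and non-negative least squares (dependency-light exact
# fallback). Negative coefficients are clipped at zero and fractions are
# renormalized to the simplex, i.e. relative mode; no permutation p-values.

#' Estimate immune-cell fractions from bulk expression
#'
#' @param bulk Expression matrix (genes x samples, linear scale).
#' @param signature Signature matrix (marker genes x cell types, linear
#'   scale). Signature genes absent from `bulk` are dropped with a log line;
#'   fewer than 50% surviving markers is an error.
#' @param method `"nu-svr"` (default): linear nu-SVR on z-scored marker
#'   vectors, with nu chosen from \{0.25, 0.5, 0.75\} by lowest
#'   reconstruction RMSE; or `"nnls"`: Lawson--Hanson non-negative least
#'   squares on raw linear values.
#' @return Fraction matrix (samples x cell types); each row is on the
#'   simplex.
#' @export
estimate_fractions <- function(bulk, signature,
                               method = c("nu-svr", "nnls")) {
  method <- match.arg(method)
  t0 <- as.numeric(Sys.time())
  if (expr_scale(bulk) != "linear")
    stop_typed("tme_value_error", "bulk expression must be on the linear scale")
  common <- intersect(rownames(signature), rownames(bulk))
  if (length(common) < 0.5 * nrow(signature))
    stop_typed("tme_value_error",
               "only %d/%d signature genes present in bulk (< 50%%)",
               length(common), nrow(signature))
  dropped <- setdiff(rownames(signature), common)
  if (length(dropped))
    tme_log("deconvolve", sprintf("dropped %d signature gene(s) absent from bulk",
                                  length(dropped)))
  sig <- signature[common, , drop = FALSE]
  x <- bulk[common, , drop = FALSE]
  zero <- colSums(x) == 0
  if (any(zero))
    stop_typed("tme_value_error", "all-zero marker profile for sample(s): %s",
               paste(colnames(x)[zero], collapse = ", "))

  coefs <- switch(method,
    "nnls" = apply(x, 2L, function(y) pracma::lsqnonneg(sig, y)$x),
    "nu-svr" = apply(x, 2L, function(y) svr_deconvolve(sig, y)))
  coefs <- pmax(coefs, 0)
  fr <- t(coefs) / colSums(coefs)
  dimnames(fr) <- list(colnames(x), colnames(sig))
  log_stage("deconvolve", dim(bulk), dim(fr), t0)
  validate_fractions(fr)
}

# One-sample nu-SVR deconvolution: z-score the signature columns and the
# mixture jointly, fit a linear nu-regression for each nu on the grid, keep
# the weight vector with the lowest reconstruction RMSE (negative weights
# clipped before reconstruction, as in relative mode).
svr_deconvolve <- function(sig, y, nu_grid = c(0.25, 0.5, 0.75)) {
  xs <- scale(sig)
  ys <- as.numeric(scale(y))
  best <- NULL
  best_rmse <- Inf
  for (nu in nu_grid) {
    fit <- e1071::svm(x = xs, y = ys, type = "nu-regression",
                      kernel = "linear", nu = nu, scale = FALSE)
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    w <- pmax(w, 0)
    if (sum(w) == 0) next
    rmse <- sqrt(mean((ys - xs %*% w)^2))
    if (rmse < best_rmse) {
      best <- w
      best_rmse <- rmse
    }
  }
  if (is.null(best))
    stop_typed("tme_value_error", "nu-SVR produced no usable weight vector")
  best
}

#' Pairwise Pearson correlations between cell-type fractions
#'
#' @param fractions Fraction matrix (samples x cell types), >= 3 samples.
#' @return A list with symmetric matrices `r` and `p` (two-sided, from the
#'   t-distribution transform of r) and a logical vector `zero_variance`
#'   flagging cell types whose correlations are undefined (recorded as
#'   `NA`, not 0).
#' @export
fraction_correlations <- function(fractions) {
  n <- nrow(fractions)
  if (n < 3L)
    stop_typed("tme_value_error", "need >= 3 samples for correlations")
  sds <- apply(fractions, 2L, sd)
  zv <- sds == 0
  r <- suppressWarnings(cor(fractions))
  r[zv, ] <- NA_real_
  r[, zv] <- NA_real_
  diag(r) <- ifelse(zv, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_  # self-correlation has no meaningful test
  list(r = r, p = p, zero_variance = zv)
}
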