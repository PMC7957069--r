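# Two-group differential expression with an empirical-Bayes moderated
# t-statistic: per-gene residual variances are shrunk toward a pooled prior
# whose scale and degrees of freedom are estimated by moment matching on the
# marginal distribution of log sample variances, and the moderated t is
# referred to a t distribution with augmented degrees of freedom.
# Benjamini-Hochberg adjustment across all tested genes; the canonical
# screening thresholds are adjusted p < 0.05 and |log2FC| > log2(1.5).

# Newton inversion of the trigamma function (for the prior df estimate).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

# Moment-matched scaled-F prior for sample variances: if s^2 ~ s0^2 F(d, d0),
# then var(log s^2) = trigamma(d/2) + trigamma(d0/2) and
# E(log s^2) = log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2).
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  if (sum(ok) < 2L) return(list(df_prior = 0, s2_prior = mean(s2)))
  z <- log(s2[ok])
  evar <- var(z) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  }
  list(df_prior = d0, s2_prior = s02)
}

#' Moderated two-group differential expression test
#'
#' Expression is transformed to `log2(x + 1)` internally when on the linear
#' scale. Per gene, ordinary two-sample t ingredients are computed with a
#' pooled variance, the variance is shrunk toward the empirical-Bayes prior,
#' and the moderated t is tested on `df_residual + df_prior` degrees of
#' freedom. Genes with zero variance in both groups and zero mean difference
#' are reported with `p = 1` and flagged.
#'
#' @param expr Expression matrix (genes x samples).
#' @param groups Binary labels (two levels), one per sample; the log2 fold
#'   change is `first level - second level` in the sorted unique order
#'   unless `groups` is a factor, whose level order is respected.
#' @return A data.frame of class `"tme_de_result"`: `gene`, `mean_a`,
#'   `mean_b`, `log2fc`, `t_moderated`, `p`, `p_adj`, `zero_variance`, plus
#'   attributes `df_prior` and `s2_prior`.
#' @export
moderated_de_test <- function(expr, groups) {
  t0 <- as.numeric(Sys.time())
  if (length(groups) != ncol(expr))
    stop_typed("tme_value_error", "one group label per sample required")
  f <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (nlevels(f) != 2L)
    stop_typed("tme_value_error", "exactly two groups required, got %d",
               nlevels(f))
  a <- f == levels(f)[1L]
  b <- f == levels(f)[2L]
  n1 <- sum(a); n2 <- sum(b)
  if (n1 < 2L || n2 < 2L)
    stop_typed("tme_value_error", "each group needs >= 2 samples")
  x <- as_log2p1(expr)
  m1 <- rowMeans(x[, a, drop = FALSE])
  m2 <- rowMeans(x[, b, drop = FALSE])
  v1 <- apply(x[, a, drop = FALSE], 1L, var)
  v2 <- apply(x[, b, drop = FALSE], 1L, var)
  df <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df
  prior <- fit_variance_prior(s2, df)
  s2_post <- if (is.finite(prior$df_prior))
    (prior$df_prior * prior$s2_prior + df * s2) / (prior$df_prior + df)
  else rep(prior$s2_prior, length(s2))
  df_total <- df + prior$df_prior
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  lfc <- m1 - m2
  tmod <- lfc / se
  p <- 2 * pt(abs(tmod), df = df_total, lower.tail = FALSE)
  zv <- s2 == 0
  flat <- zv & lfc == 0
  p[flat] <- 1
  tmod[flat] <- 0
  out <- data.frame(gene = rownames(expr), mean_a = m1, mean_b = m2,
                    log2fc = lfc, t_moderated = tmod, p = p,
                    p_adj = adjust_bh(p), zero_variance = zv,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "df_prior") <- prior$df_prior
  attr(out, "s2_prior") <- prior$s2_prior
  class(out) <- c("tme_de_result", "data.frame")
  log_stage("diffexpr", dim(expr), dim(out), t0)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_typed("tme_value_error", "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Filter differentially expressed features
#'
#' Keeps features with `p_adj < p_adj_max` and `|log2fc| > lfc_min`, both
#' strict inequalities. `lfc_min = 0` reduces to the adjusted-p screen
#' alone (the miRNA-style setting).
#'
#' @param de A `"tme_de_result"` (or data.frame with `gene`, `p_adj`,
#'   `log2fc`).
#' @param p_adj_max Adjusted-p ceiling (default 0.05).
#' @param lfc_min Absolute log2 fold-change floor (default `log2(1.5)`).
#' @return Character vector of surviving feature ids.
#' @export
filter_degs <- function(de, p_adj_max = 0.05, lfc_min = log2(1.5)) {
  if (p_adj_max <= 0)
    stop_typed("tme_value_error", "p_adj_max must be positive")
  if (lfc_min < 0)
    stop_typed("tme_value_error", "lfc_min must be >= 0")
  de$gene[de$p_adj < p_adj_max & abs(de$log2fc) > lfc_min]
}
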