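# Clustering stack: K-means with k-means++ seeding, average-linkage
# hierarchical clustering of cell types on correlation distance, consensus
# clustering over subsampled K-means runs, and K selection by the proportion
# of ambiguous clustering (PAC) with a largest-K tie rule. The elbow (SSE)
# curve is computed for diagnostics but never drives the decision.

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers by
# sampling points proportional to squared distance from the chosen set.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - matrix(x[i, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' K-means clustering with k-means++ initialization
#'
#' Lloyd iterations from k-means++ seeds, keeping the lowest
#' within-cluster sum of squares over `n_restarts` restarts.
#'
#' @param x Numeric matrix, observations in rows.
#' @param k Number of clusters (requires at least `k` distinct rows).
#' @param n_restarts Restarts (default 25).
#' @param max_iter Lloyd iteration cap (default 300).
#' @param seed Integer seed (optional).
#' @return A list with `labels` (integer vector), `centers`, and `sse`
#'   (total within-cluster sum of squared errors).
#' @export
tme_kmeans <- function(x, k, n_restarts = 25L, max_iter = 300L, seed = NULL) {
  maybe_seed(seed)
  x <- as.matrix(x)
  n_distinct <- nrow(unique(x))
  if (k > n_distinct)
    stop_typed("tme_value_error", "k = %d exceeds %d distinct points",
               k, n_distinct)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_centers(x, k)
    centers <- unique(centers)
    fit <- if (nrow(centers) < k) {
      # duplicated seeds (possible with duplicated rows): fall back to
      # sampling distinct rows
      suppressWarnings(kmeans(x, centers = unique(x)[sample.int(n_distinct, k),
                                                     , drop = FALSE],
                              iter.max = max_iter, algorithm = "Lloyd"))
    } else {
      suppressWarnings(kmeans(x, centers = centers, iter.max = max_iter,
                              algorithm = "Lloyd"))
    }
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  list(labels = as.integer(best$cluster), centers = best$centers,
       sse = best$tot.withinss)
}

#' Hierarchical clustering of cell types on correlation distance
#'
#' Average-linkage agglomeration on distance `1 - Pearson r` between
#' cell-type fraction profiles, cut into `n_clusters` groups labeled
#' `A`, `B`, ... by decreasing size.
#'
#' @param fractions Fraction matrix (samples x cell types).
#' @param n_clusters Number of cell clusters (default 4).
#' @return Named character vector mapping cell type to cluster label.
#' @export
hierarchical_cluster_cells <- function(fractions, n_clusters = 4L) {
  if (ncol(fractions) < n_clusters)
    stop_typed("tme_value_error", "need >= n_clusters cell types")
  r <- suppressWarnings(cor(fractions))
  if (anyNA(r)) {
    warn_typed("tme_degenerate_warning",
               "zero-variance cell type(s); undefined correlations treated as distance 0")
    r[is.na(r)] <- 1
  }
  d <- as.dist(1 - r)
  hc <- hclust(d, method = "average")
  raw <- cutree(hc, k = n_clusters)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- setNames(LETTERS[seq_along(sizes)], names(sizes))
  setNames(unname(relabel[as.character(raw)]), colnames(fractions))
}

#' Within-cluster SSE curve over a range of K
#'
#' @param x Numeric matrix, observations in rows.
#' @param k_values Integer vector of cluster counts.
#' @param n_restarts Restarts per K (default 25).
#' @param seed Integer seed (optional).
#' @return Data frame with columns `k` and `sse`; `sse` is non-increasing
#'   in `k` (best-of-restarts).
#' @export
sse_curve <- function(x, k_values, n_restarts = 25L, seed = NULL) {
  maybe_seed(seed)
  data.frame(k = k_values,
             sse = vapply(k_values, function(k)
               tme_kmeans(x, k, n_restarts = n_restarts)$sse, numeric(1)))
}

#' Consensus clustering over subsampled K-means runs
#'
#' For each K and repetition, a fraction `subsample` of the samples is drawn
#' without replacement (features kept) and clustered by K-means; the
#' consensus matrix is the ratio of co-clustering to co-sampling counts.
#' Final labels per K come from cutting an average-linkage tree on
#' `1 - consensus`. PAC (proportion of ambiguous clustering) is
#' `CDF(u2) - CDF(u1)` of the off-diagonal upper-triangle consensus
#' entries, defaults `(0.1, 0.9)`.
#'
#' @param x Numeric matrix, samples in rows.
#' @param k_values Integer K values (each >= 2).
#' @param n_reps Subsampling repetitions (>= 20; default 100).
#' @param subsample Subsampling fraction in `[0.5, 1)` (default 0.8).
#' @param inner_restarts K-means restarts inside each repetition (default 5).
#' @param pac_limits Lower/upper CDF evaluation points for PAC.
#' @param seed Integer seed (optional).
#' @return A list of class `"consensus_result"`: `k_values`,
#'   `consensus_matrices`, `cdf` (ecdf closures), `pac` (named numeric),
#'   and `labels` (matrix, samples x K values).
#' @export
consensus_cluster <- function(x, k_values = 2:5, n_reps = 100L,
                              subsample = 0.8, inner_restarts = 5L,
                              pac_limits = c(0.1, 0.9), seed = NULL) {
  maybe_seed(seed)
  if (n_reps < 20L) stop_typed("tme_value_error", "need n_reps >= 20")
  if (subsample < 0.5 || subsample >= 1)
    stop_typed("tme_value_error", "need 0.5 <= subsample < 1")
  if (any(k_values < 2L)) stop_typed("tme_value_error", "k values must be >= 2")
  x <- as.matrix(x)
  n <- nrow(x)
  m <- max(2L, floor(subsample * n))
  t0 <- as.numeric(Sys.time())

  cons <- vector("list", length(k_values))
  names(cons) <- as.character(k_values)
  labels <- matrix(NA_integer_, n, length(k_values),
                   dimnames = list(rownames(x), as.character(k_values)))
  pac <- setNames(numeric(length(k_values)), as.character(k_values))
  cdfs <- vector("list", length(k_values))
  names(cdfs) <- as.character(k_values)

  for (j in seq_along(k_values)) {
    k <- k_values[j]
    co_cluster <- matrix(0, n, n)
    co_sampled <- matrix(0, n, n)
    for (rep in seq_len(n_reps)) {
      idx <- sort(sample.int(n, m))
      fit <- tme_kmeans(x[idx, , drop = FALSE], k,
                        n_restarts = inner_restarts)
      ind <- outer(fit$labels, fit$labels, "==")
      co_cluster[idx, idx] <- co_cluster[idx, idx] + ind
      co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
    }
    if (any(co_sampled == 0))
      stop_typed("tme_value_error",
                 "some sample pairs were never co-sampled; increase n_reps")
    cm <- co_cluster / co_sampled
    diag(cm) <- 1
    dimnames(cm) <- list(rownames(x), rownames(x))
    cons[[j]] <- cm
    hc <- hclust(as.dist(1 - cm), method = "average")
    labels[, j] <- cutree(hc, k = k)
    off <- cm[upper.tri(cm)]
    cdfs[[j]] <- stats::ecdf(off)
    pac[j] <- cdfs[[j]](pac_limits[2L]) - cdfs[[j]](pac_limits[1L])
  }
  log_stage("consensus_cluster", dim(x), c(n, length(k_values)), t0)
  structure(list(k_values = as.integer(k_values),
                 consensus_matrices = cons, cdf = cdfs, pac = pac,
                 labels = labels, pac_limits = pac_limits),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering over K =",
      paste(x$k_values, collapse = ", "), "\n")
  cat("PAC:", paste(sprintf("K=%s %.4f", names(x$pac), x$pac),
                    collapse = "; "), "\n")
  invisible(x)
}

#' Select the number of clusters from PAC values
#'
#' Candidates are all K whose PAC lies within `pac_tol` of the minimum;
#' among candidates the largest K is returned (grouping as detailed as the
#' evidence allows). The SSE curve, when supplied, is attached to the
#' result for diagnostics only.
#'
#' @param consensus A `"consensus_result"` (or a named numeric vector of
#'   PAC values keyed by K).
#' @param sse Optional SSE curve data frame from [sse_curve()].
#' @param pac_tol PAC tie tolerance (default 0.01).
#' @return A list with `k` (chosen K), `pac`, `candidates`, and `sse`.
#' @export
select_k <- function(consensus, sse = NULL, pac_tol = 0.01) {
  pac <- if (inherits(consensus, "consensus_result")) consensus$pac
         else consensus
  if (length(pac) < 2L)
    stop_typed("tme_value_error", "need PAC for >= 2 values of K")
  ks <- as.integer(names(pac))
  cand <- ks[pac <= min(pac) + pac_tol]
  list(k = max(cand), pac = pac, candidates = cand, sse = sse)
}
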