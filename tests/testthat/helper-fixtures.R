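options(tmescore.log_level = "quiet")

# adjusted Rand index (hand-rolled so clustering tests do not depend on the
# package under test)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# tiny expression matrix builder
toy_expr <- function(values, genes = NULL, samples = NULL,
                     scale_tag = "linear") {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  expression_matrix(m, scale_tag = scale_tag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_maf <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  validate_maf(df)
}

toy_clinical <- function(n, times = NULL, events = NULL, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             os_time = times %||% rexp(n, 1 / 500),
             os_event = events %||% rbinom(n, 1, 0.6),
             stringsAsFactors = FALSE)
}

# end-to-end fixture shared by the fit/acceptance tests, built once per run
.e2e_cache <- new.env(parent = emptyenv())
e2e_fixture <- function() {
  if (is.null(.e2e_cache$fit)) {
    cohort <- simulate_cohort(seed = 7L)
    model <- tme_fit(cohort$expression, cohort$clinical,
                     signature = cohort$signature, seed = 11L)
    .e2e_cache$fit <- list(cohort = cohort, model = model)
  }
  .e2e_cache$fit
}
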