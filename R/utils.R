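# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_typed <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "tmescore_error", "error", "condition")))
}

warn_typed <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c(class, "tmescore_warning", "warning",
                                     "condition")))
}

# One structured log line per pipeline stage; silenced via
# options(tmescore.log_level = "quiet").
tme_log <- function(stage, msg, level = "info") {
  rank <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  opt <- getOption("tmescore.log_level", "info")
  if (rank[[level]] >= rank[[opt]]) {
    message(sprintf("[tmescore] %s: %s", stage, msg))
  }
  invisible(NULL)
}

log_stage <- function(stage, in_shape, out_shape, t0) {
  tme_log(stage, sprintf(
    "in=%s out=%s elapsed=%.2fs",
    paste(in_shape, collapse = "x"), paste(out_shape, collapse = "x"),
    as.numeric(Sys.time()) - t0))
}

revcumsum <- function(x) rev(cumsum(rev(x)))

# set.seed only when a seed is supplied; keeps every stochastic entry point
# reproducible without touching the caller's RNG stream otherwise
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Dirichlet draws via normalized gammas; rows on the simplex.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n), rate = 1), nrow = n)
  g / rowSums(g)
}

is_binary01 <- function(x) all(x %in% c(0, 1))
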