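# Survival core implemented from the defining formulas: product-limit
# estimator, Mantel-Haenszel log-rank test with hypergeometric variance,
# univariate Cox proportional hazards by Newton-Raphson on the partial
# likelihood with Efron tie handling, and maximally selected rank statistics
# for survival cutpoints (permutation p-value).

check_surv_input <- function(times, events) {
  if (length(times) == 0L)
    stop_typed("tme_value_error", "empty survival input")
  if (length(times) != length(events))
    stop_typed("tme_value_error", "times and events differ in length")
  if (any(!is.finite(times)) || any(times < 0))
    stop_typed("tme_value_error", "times must be finite and >= 0")
  if (!is_binary01(events))
    stop_typed("tme_value_error", "events must be 0/1")
  invisible(NULL)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times Follow-up times (>= 0).
#' @param events Event indicators (1 = event, 0 = censored). Censored-only
#'   times reduce the at-risk count without producing a step.
#' @return An object of class `"tme_km"`: a data.frame with `time` (distinct
#'   event times, ascending), `n_risk`, `n_event`, `survival`
#'   (`prod(1 - d_i/n_i)`), plus attributes `n` and `surv_fun` (a right-
#'   continuous step function with `S(0) = 1`).
#' @export
km_estimate <- function(times, events) {
  check_surv_input(times, events)
  o <- order(times)
  t_s <- times[o]; e_s <- events[o]
  ut <- unique(t_s[e_s == 1])
  n <- length(times)
  n_risk <- n - findInterval(ut, t_s, left.open = TRUE)  # t_i >= ut
  n_event <- vapply(ut, function(tau) sum(e_s[t_s == tau]), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  df <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                   survival = surv)
  sf <- if (nrow(df)) stats::stepfun(df$time, c(1, df$survival),
                                     right = FALSE)
        else function(t) rep(1, length(t))
  structure(df, n = n, surv_fun = sf, class = c("tme_km", "data.frame"))
}

#' @export
print.tme_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d event times\n",
              attr(x, "n"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

# shared tabulation over distinct event times for two-group tests:
# returns per event time the totals (Y, d) and group-1 quantities (Y1, d1)
logrank_tables <- function(times, events, group1) {
  o <- order(times)
  t_s <- times[o]; e_s <- events[o]; g_s <- group1[o]
  ut <- unique(t_s[e_s == 1])
  if (!length(ut))
    stop_typed("tme_value_error", "no events: log-rank statistic undefined")
  n <- length(times)
  below <- findInterval(ut, t_s, left.open = TRUE)
  Y <- n - below
  cg <- c(0, cumsum(g_s))
  Y1 <- sum(g_s) - cg[below + 1L]
  d <- vapply(ut, function(tau) sum(e_s[t_s == tau]), numeric(1))
  d1 <- vapply(ut, function(tau) sum(e_s[t_s == tau & g_s]), numeric(1))
  list(time = ut, Y = Y, Y1 = Y1, d = d, d1 = d1)
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' Observed-minus-expected deaths summed over the 2x2 table at each distinct
#' event time, with the hypergeometric variance; chi-square on 1 df.
#'
#' @param times,events Survival data (see [km_estimate()]).
#' @param group Binary group labels (two non-empty levels).
#' @return A list with `chi_square`, `p`, `observed`, `expected` (group-1
#'   totals), and `var`.
#' @export
logrank_test <- function(times, events, group) {
  check_surv_input(times, events)
  f <- if (is.factor(group)) droplevels(group) else factor(group)
  if (nlevels(f) != 2L)
    stop_typed("tme_value_error", "log-rank needs exactly two non-empty groups")
  g1 <- f == levels(f)[1L]
  tab <- logrank_tables(times, events, g1)
  E1 <- tab$d * tab$Y1 / tab$Y
  vterm <- ifelse(tab$Y > 1,
                  tab$d * (tab$Y1 / tab$Y) * (1 - tab$Y1 / tab$Y) *
                    (tab$Y - tab$d) / (tab$Y - 1), 0)
  O1 <- sum(tab$d1); E <- sum(E1); V <- sum(vterm)
  chi <- if (V > 0) (O1 - E)^2 / V else 0
  list(chi_square = chi, p = pchisq(chi, df = 1L, lower.tail = FALSE),
       observed = O1, expected = E, var = V)
}

#' Univariate Cox proportional-hazards regression
#'
#' Newton-Raphson maximization of the partial likelihood with Efron's
#' correction for tied event times; convergence at `|delta beta| < 1e-8` or
#' 50 iterations; standard error from the observed information. The score
#' test at `beta = 0` is also reported (for a binary covariate and untied
#' times it equals the log-rank chi-square).
#'
#' @param times,events Survival data.
#' @param covariate Numeric covariate with positive variance.
#' @return An object of class `"tme_cox"`: list with `beta`, `se`, `hr`,
#'   `z`, `p` (two-sided Wald), `score_chisq`, `score_p`, `loglik`,
#'   `converged`, `n`, `n_events`, `iterations`.
#' @export
cox_univariate <- function(times, events, covariate) {
  check_surv_input(times, events)
  if (length(covariate) != length(times))
    stop_typed("tme_value_error", "covariate length mismatch")
  if (sum(events) < 1L)
    stop_typed("tme_value_error", "at least one event required")
  if (var(covariate) == 0)
    stop_typed("tme_value_error", "zero-variance covariate")

  o <- order(times)
  t_s <- times[o]; e_s <- events[o]; x_s <- covariate[o]
  n <- length(t_s)
  ut <- unique(t_s[e_s == 1])
  first_ge <- findInterval(ut, t_s, left.open = TRUE) + 1L
  ev_group <- match(t_s, ut)           # NA for times that are not event times
  is_death <- e_s == 1 & !is.na(ev_group)
  dg <- ev_group[is_death]

  efron_pass <- function(beta) {
    w <- exp(beta * x_s)
    cw <- revcumsum(w); cwx <- revcumsum(w * x_s); cwx2 <- revcumsum(w * x_s^2)
    S0 <- cw[first_ge]; S1 <- cwx[first_ge]; S2 <- cwx2[first_ge]
    wd <- w[is_death]; xd <- x_s[is_death]
    s0 <- as.numeric(rowsum(wd, dg))
    s1 <- as.numeric(rowsum(wd * xd, dg))
    s2 <- as.numeric(rowsum(wd * xd^2, dg))
    dct <- as.numeric(rowsum(rep(1, sum(is_death)), dg))
    ll <- sum(beta * xd); U <- sum(xd); I <- 0
    for (j in seq_along(ut)) {
      dj <- dct[j]
      a <- (seq_len(dj) - 1) / dj
      S0l <- S0[j] - a * s0[j]
      S1l <- S1[j] - a * s1[j]
      S2l <- S2[j] - a * s2[j]
      ll <- ll - sum(log(S0l))
      U <- U - sum(S1l / S0l)
      I <- I + sum(S2l / S0l - (S1l / S0l)^2)
    }
    list(ll = ll, U = U, I = I)
  }

  p0 <- efron_pass(0)
  score_chisq <- if (p0$I > 0) p0$U^2 / p0$I else 0
  beta <- 0; converged <- FALSE; iter <- 0L; pass <- p0
  for (iter in seq_len(50L)) {
    if (pass$I <= 0) break
    step <- pass$U / pass$I
    beta <- beta + step
    pass <- efron_pass(beta)
    if (abs(step) < 1e-8) { converged <- TRUE; break }
    if (abs(beta) > 20) break  # monotone likelihood / separation
  }
  se <- if (pass$I > 0) 1 / sqrt(pass$I) else NA_real_
  z <- beta / se
  structure(list(beta = beta, se = se, hr = exp(beta), z = z,
                 p = 2 * pnorm(abs(z), lower.tail = FALSE),
                 score_chisq = score_chisq,
                 score_p = pchisq(score_chisq, 1L, lower.tail = FALSE),
                 loglik = pass$ll, converged = converged, n = n,
                 n_events = sum(events), iterations = iter),
            class = "tme_cox")
}

#' @export
print.tme_cox <- function(x, ...) {
  cat(sprintf(
    "Cox PH (Efron ties): beta = %.4f (se %.4f), HR = %.4f, p = %.3g%s\n",
    x$beta, x$se, x$hr, x$p,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Maximally selected rank statistic survival cutpoint
#'
#' Candidate cutpoints are midpoints between consecutive distinct score
#' values whose induced splits leave at least `ceiling(minprop * n)` samples
#' on each side. Each candidate is scored by the standardized log-rank
#' statistic of the induced two-group split; the cutpoint with the maximal
#' absolute standardized statistic is returned (ties broken toward the
#' lower cutpoint). The p-value approximation permutes the score vector.
#'
#' @param times,events Survival data.
#' @param score Continuous per-sample score (non-constant).
#' @param minprop Minimum fraction of samples on each side (default 0.1).
#' @param n_perm Permutations for the p-value (default 1000; 0 skips it).
#' @param seed Integer seed for the permutation (optional).
#' @return An object of class `"tme_cutpoint"`: list with `cutpoint`,
#'   `statistic` (max |standardized log-rank|), `candidates` (data.frame of
#'   `cutpoint`, `statistic`), `p_approx` (or `NA`), `n_perm`.
#' @export
maxstat_cutpoint <- function(times, events, score, minprop = 0.1,
                             n_perm = 1000L, seed = NULL) {
  check_surv_input(times, events)
  n <- length(times)
  if (n < 1 / minprop)
    stop_typed("tme_value_error", "need at least 1/minprop samples")
  if (length(unique(score)) < 2L)
    stop_typed("tme_value_error", "constant score: no admissible cutpoint")
  if (sum(events) < 1L)
    stop_typed("tme_value_error", "no events: statistic undefined")
  maybe_seed(seed)

  # event-time structure (fixed under score permutation)
  o <- order(times)
  t_s <- times[o]; e_s <- events[o]
  ut <- unique(t_s[e_s == 1])
  K <- length(ut)
  Y <- n - findInterval(ut, t_s, left.open = TRUE)
  d <- vapply(ut, function(tau) sum(e_s[t_s == tau]), numeric(1))
  c1 <- d / Y
  g <- ifelse(Y > 1, d * (Y - d) / (Y^2 * (Y - 1)), 0)
  # at-risk indicator per (sample, event time), rows in time order
  A <- outer(t_s, ut, ">=") * 1
  ev <- e_s

  # admissible split sizes from the distinct-score structure
  s_sorted <- sort(score)
  su <- unique(s_sorted)
  n_left <- cumsum(tabulate(match(s_sorted, su), nbins = length(su)))
  lo <- ceiling(minprop * n)
  keep <- which(n_left >= lo & (n - n_left) >= lo &
                  seq_along(su) < length(su))
  if (!length(keep))
    stop_typed("tme_value_error", "no admissible cutpoint under minprop")
  cut_rows <- n_left[keep]
  cutpoints <- (su[keep] + su[keep + 1L]) / 2

  # standardized log-rank statistic for every admissible split of a score
  # ordering; `ord` maps time-ordered rows into score order
  split_stats <- function(ord) {
    Y1 <- apply(A[ord, , drop = FALSE], 2L, cumsum)[cut_rows, , drop = FALSE]
    O <- cumsum(ev[ord])[cut_rows]
    E <- as.numeric(Y1 %*% c1)
    V <- as.numeric((Y1 * (matrix(Y, length(cut_rows), K, byrow = TRUE) -
                             Y1)) %*% g)
    ifelse(V > 0, (O - E) / sqrt(V), 0)
  }

  score_t <- score[o]                       # scores in time order
  obs <- split_stats(order(score_t))
  best <- which.max(abs(obs))               # ties -> lower cutpoint
  stat <- abs(obs)[best]

  p_approx <- NA_real_
  if (n_perm > 0L) {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      if (max(abs(split_stats(order(score_t[perm])))) >= stat)
        exceed <- exceed + 1L
    }
    p_approx <- (1L + exceed) / (n_perm + 1L)
  }
  structure(list(cutpoint = cutpoints[best], statistic = stat,
                 candidates = data.frame(cutpoint = cutpoints,
                                         statistic = abs(obs)),
                 p_approx = p_approx, n_perm = n_perm, minprop = minprop),
            class = "tme_cutpoint")
}

#' @export
print.tme_cutpoint <- function(x, ...) {
  cat(sprintf(
    "Maxstat cutpoint: %.4f (standardized log-rank %.3f, %d candidates%s)\n",
    x$cutpoint, x$statistic, nrow(x$candidates),
    if (is.na(x$p_approx)) "" else sprintf(", permutation p = %.3g",
                                           x$p_approx)))
  invisible(x)
}
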