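test_that("product-limit estimate matches hand computation with ties", {
  km <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km$survival, c(0.5, 0))

  # all censored: no steps
  km2 <- km_estimate(c(3, 5, 8), c(0, 0, 0))
  expect_identical(nrow(km2), 0L)
  expect_equal(attr(km2, "surv_fun")(10), 1)

  # 10 subjects with ties and censoring, against the hand product-limit
  times <- c(1, 1, 2, 3, 3, 4, 5, 6, 6, 7)
  events <- c(1, 0, 1, 1, 1, 0, 1, 0, 1, 0)
  km3 <- km_estimate(times, events)
  # t=1: 10 at risk, 1 death; t=2: 8, 1; t=3: 7, 2; t=5: 4, 1; t=6: 3, 1
  hand <- cumprod(c(1 - 1/10, 1 - 1/8, 1 - 2/7, 1 - 1/4, 1 - 1/3))
  expect_equal(km3$time, c(1, 2, 3, 5, 6))
  expect_equal(km3$n_risk, c(10, 8, 7, 4, 3))
  expect_equal(km3$survival, hand)

  expect_error(km_estimate(numeric(0), numeric(0)),
               class = "tme_value_error")
})

test_that("KM equals one minus the empirical CDF without censoring", {
  set.seed(1)
  t <- rexp(80)
  km <- km_estimate(t, rep(1, 80))
  sf <- attr(km, "surv_fun")
  grid <- sort(t)
  expect_equal(sf(grid), 1 - stats::ecdf(grid)(grid) + 0, tolerance = 1e-12)
})

test_that("log-rank test matches brute-force tabulation and survdiff", {
  # identical groups: O = E by symmetry
  t <- c(2, 4, 6, 8, 10, 12)
  lr0 <- logrank_test(c(t, t), rep(1, 12), rep(c("a", "b"), each = 6))
  expect_equal(lr0$chi_square, 0)
  expect_equal(lr0$p, 1)

  set.seed(2)
  times <- c(rexp(6, 1), rexp(6, 3))
  events <- rbinom(12, 1, 0.8)
  grp <- rep(c("a", "b"), each = 6)
  lr <- logrank_test(times, events, grp)

  # brute-force summation over the 2x2 table at each event time
  ut <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (tau in ut) {
    at <- times >= tau
    Y <- sum(at); Y1 <- sum(at & grp == "a")
    d <- sum(events == 1 & times == tau)
    d1 <- sum(events == 1 & times == tau & grp == "a")
    O <- O + d1
    E <- E + d * Y1 / Y
    if (Y > 1) V <- V + d * (Y1 / Y) * (1 - Y1 / Y) * (Y - d) / (Y - 1)
  }
  expect_equal(lr$chi_square, (O - E)^2 / V)

  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  expect_equal(lr$chi_square, sd$chisq, tolerance = 1e-10)

  expect_error(logrank_test(times, rep(0, 12), grp),
               class = "tme_value_error")
})

test_that("log-rank rejection rate is calibrated under the null", {
  set.seed(3)
  rej <- 0
  for (i in 1:300) {
    t <- rexp(40)
    e <- rbinom(40, 1, 0.7)
    g <- rep(c(0, 1), 20)
    if (logrank_test(t, e, g)$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 300, 0.02)
  expect_lte(rej / 300, 0.08)
})

test_that("Cox regression recovers null and planted effects", {
  x <- rnorm(1000)
  s <- simulate_survival(x, beta = 0, censor_rate = 0.3, seed = 11)
  fit <- cox_univariate(s$os_time, s$os_event, x)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta), 3 * fit$se)

  set.seed(12)
  x2 <- rnorm(2000)
  s2 <- simulate_survival(x2, beta = log(2), censor_rate = 0.3, seed = 13)
  fit2 <- cox_univariate(s2$os_time, s2$os_event, x2)
  expect_lt(abs(fit2$beta - log(2)), 3 * fit2$se)

  expect_error(cox_univariate(s$os_time, s$os_event, rep(1, 1000)),
               class = "tme_value_error")
})

test_that("Cox matches the reference implementation under Efron ties", {
  skip_if_not_installed("survival")
  set.seed(14)
  x <- rnorm(150)
  s <- simulate_survival(x, beta = 0.6, censor_rate = 0.4, seed = 15)
  tt <- round(s$os_time / 50)  # heavy ties
  fit <- cox_univariate(tt, s$os_event, x)
  ref <- survival::coxph(survival::Surv(tt, s$os_event) ~ x, ties = "efron")
  expect_equal(fit$beta, unname(stats::coef(ref)), tolerance = 1e-7)
  expect_equal(fit$se, sqrt(ref$var[1, 1]), tolerance = 1e-7)
})

test_that("score test at beta = 0 equals the log-rank chi-square", {
  set.seed(16)
  x <- rbinom(120, 1, 0.5)
  s <- simulate_survival(x, beta = 0.4, censor_rate = 0.3, seed = 17)
  fit <- cox_univariate(s$os_time, s$os_event, x)
  lr <- logrank_test(s$os_time, s$os_event, x)
  expect_lt(abs(fit$score_chisq - lr$chi_square), 1e-6)
})

test_that("affine rescaling of the covariate rescales beta, keeps p", {
  set.seed(18)
  x <- rnorm(300)
  s <- simulate_survival(x, beta = 0.5, censor_rate = 0.2, seed = 19)
  f1 <- cox_univariate(s$os_time, s$os_event, x)
  f2 <- cox_univariate(s$os_time, s$os_event, 4 * x + 2)
  expect_equal(f2$beta, f1$beta / 4, tolerance = 1e-6)
  expect_equal(f2$p, f1$p, tolerance = 1e-6)
})

test_that("maxstat equals an exhaustive scan over admissible splits", {
  for (seed in 1:5) {
    set.seed(seed)
    tt <- rexp(30)
    ee <- rbinom(30, 1, 0.7)
    if (sum(ee) == 0) ee[1] <- 1
    sc <- rnorm(30)
    cp <- maxstat_cutpoint(tt, ee, sc, n_perm = 0)
    su <- sort(unique(sc))
    lo <- ceiling(0.1 * 30)
    best <- -Inf; bestc <- NA
    for (i in seq_len(length(su) - 1)) {
      nl <- sum(sc <= su[i])
      if (nl < lo || 30 - nl < lo) next
      z <- sqrt(logrank_test(tt, ee, sc <= su[i])$chi_square)
      if (z > best) { best <- z; bestc <- (su[i] + su[i + 1]) / 2 }
    }
    expect_equal(cp$cutpoint, bestc)
    expect_equal(cp$statistic, best, tolerance = 1e-10)
  }
})

test_that("maxstat respects minprop and orders a clean gap correctly", {
  # minprop = 0.4 on n = 10: only splits 4/6, 5/5, 6/4 admissible
  tt <- 1:10; ee <- rep(1, 10); sc <- 1:10
  cp <- maxstat_cutpoint(tt, ee, sc, minprop = 0.4, n_perm = 0)
  expect_identical(nrow(cp$candidates), 3L)
  expect_equal(cp$candidates$cutpoint, c(4.5, 5.5, 6.5))

  # low scores die first, clear gap: cutpoint in the gap, statistic equals
  # the log-rank at that split
  set.seed(20)
  sc2 <- c(runif(15, 0, 1), runif(15, 3, 4))
  tt2 <- c(rexp(15, 1), rexp(15, 1 / 8))
  ee2 <- rep(1, 30)
  cp2 <- maxstat_cutpoint(tt2, ee2, sc2, n_perm = 200, seed = 21)
  expect_gt(cp2$cutpoint, 1)
  expect_lt(cp2$cutpoint, 3)
  lrz <- sqrt(logrank_test(tt2, ee2, sc2 <= cp2$cutpoint)$chi_square)
  expect_equal(cp2$statistic, lrz, tolerance = 1e-10)
  expect_lt(cp2$p_approx, 0.05)

  expect_error(maxstat_cutpoint(tt, ee, rep(1, 10)),
               class = "tme_value_error")
})

test_that("maxstat statistic is invariant under monotone score transforms", {
  set.seed(22)
  tt <- rexp(40); ee <- rbinom(40, 1, 0.8); sc <- rnorm(40)
  a <- maxstat_cutpoint(tt, ee, sc, n_perm = 0)
  b <- maxstat_cutpoint(tt, ee, exp(sc), n_perm = 0)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-10)
  expect_equal(sort(a$candidates$statistic), sort(b$candidates$statistic),
               tolerance = 1e-10)
})
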