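test_that("signature matrix honors the marker enrichment construction", {
  sig <- generate_signature_matrix(5, 3, fold = 4, seed = 1)
  expect_identical(dim(sig), c(15L, 3L))
  for (k in 1:3) {
    rows <- ((k - 1) * 5 + 1):(k * 5)
    own <- sig[rows, k]
    other <- apply(sig[rows, -k, drop = FALSE], 1, max)
    expect_true(all(own > 4 * other))
  }
  expect_identical(sig, generate_signature_matrix(5, 3, fold = 4, seed = 1))
  expect_error(generate_signature_matrix(5, 3, fold = 1),
               class = "tme_value_error")
  expect_error(generate_signature_matrix(3, 3, fold = 4),
               class = "tme_value_error")
  full <- generate_signature_matrix(seed = 2)
  expect_identical(colnames(full)[4], "T cells CD8")
  expect_identical(qr(full)$rank, 22L)
})

test_that("cohort generation is deterministic and records simplex truth", {
  a <- simulate_cohort(n_samples = 60, n_bg_genes = 100, n_de_genes = 20,
                       seed = 5)
  b <- simulate_cohort(n_samples = 60, n_bg_genes = 100, n_de_genes = 20,
                       seed = 5)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$maf, b$maf)
  expect_true(all(abs(rowSums(a$truth$true_fractions) - 1) < 1e-9))
  expect_true(all(a$truth$true_fractions >= 0))
  expect_setequal(unique(a$truth$true_subtype), c("high", "low"))
  expect_identical(length(a$truth$true_de_genes), 20L)
  expect_error(simulate_cohort(n_samples = 10, n_bg_genes = 5,
                               n_de_genes = 10),
               class = "tme_value_error")
})

test_that("zero-noise marker expression equals signature times fractions", {
  co <- simulate_cohort(n_samples = 30, n_bg_genes = 50, n_de_genes = 0,
                        noise_sd = 0, seed = 3)
  markers <- rownames(co$signature)
  expected <- co$signature %*% t(co$truth$true_fractions)
  expect_equal(unclass(co$expression[markers, ]), expected,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("survival simulation matches its exponential closed forms", {
  # null: score-independent event times (two-sample KS)
  s <- simulate_survival(rep(c(0, 1), each = 500), beta = 0,
                         censor_rate = 0, seed = 11)
  ks <- suppressWarnings(
    stats::ks.test(s$os_time[1:500], s$os_time[501:1000]))
  expect_gt(ks$p.value, 0.01)

  # censor_rate = 0 forces all events
  expect_true(all(s$os_event == 1))

  # beta = 1, scores {0, 1}: mean event-time ratio ~ e
  s2 <- simulate_survival(rep(c(0, 1), each = 5000), beta = 1,
                          censor_rate = 0, seed = 12)
  ratio <- mean(s2$os_time[1:5000]) / mean(s2$os_time[5001:10000])
  expect_lt(abs(ratio - exp(1)) / exp(1), 0.1)

  # realized censoring fraction near target at n >= 200
  s3 <- simulate_survival(rnorm(400), beta = 0.5, censor_rate = 0.4,
                          seed = 13)
  expect_lt(abs(mean(1 - s3$os_event) - 0.4), 0.1)

  expect_error(simulate_survival(1:5, baseline_rate = 0),
               class = "tme_value_error")
  expect_error(simulate_survival(1:5, censor_rate = 1),
               class = "tme_value_error")
})

test_that("planted hazard ratio is recovered by Cox regression on the truth", {
  co <- simulate_cohort(n_samples = 400, n_bg_genes = 10, n_de_genes = 0,
                        hr = 2.5, seed = 21)
  fit <- cox_univariate(co$clinical$os_time, co$clinical$os_event,
                        co$truth$latent_risk)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta - log(2.5)), 3 * fit$se)
})

test_that("null cohort shows no survival separation between true subtypes", {
  co <- simulate_cohort(n_samples = 300, n_bg_genes = 10, n_de_genes = 0,
                        hr = 1, seed = 31)
  lr <- logrank_test(co$clinical$os_time, co$clinical$os_event,
                     co$truth$true_subtype)
  expect_gt(lr$p, 0.01)
})
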