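toy_model <- function(fav, rsk, cutpoint = 0) {
  structure(list(favorable_genes = fav, risk_genes = rsk,
                 cutpoint = cutpoint, minprop = 0.1),
            class = "tme_model")
}

test_that("the TME score evaluates its defining sum exactly", {
  x <- toy_expr(matrix(c(3, 1), 2, 1), genes = c("F", "R"))
  m <- toy_model("F", "R")
  expect_equal(unname(compute_tmescore(x, m)), log2(4) - log2(2))  # = 1

  zeros <- toy_expr(matrix(0, 2, 3), genes = c("F", "R"))
  expect_equal(unname(compute_tmescore(zeros, m)), rep(0, 3))

  x2 <- toy_expr(matrix(c(1, 3, 0, 1), 4, 1),
                 genes = c("F1", "F2", "R1", "R2"))
  m2 <- toy_model(c("F1", "F2"), c("R1", "R2"))
  expect_equal(unname(compute_tmescore(x2, m2)), (1 + 2) - (0 + 1))  # = 2

  # missing genes: dropped with a warning; empty set is an error
  x3 <- toy_expr(matrix(c(3, 1, 2), 3, 1), genes = c("F1", "F2", "R1"))
  m3 <- toy_model(c("F1", "F2", "FX"), "R1")
  expect_warning(s3 <- compute_tmescore(x3, m3),
                 class = "tme_missing_gene_warning")
  expect_equal(unname(s3), log2(4) + log2(2) - log2(3))
  expect_error(suppressWarnings(compute_tmescore(x3, toy_model("FX", "R1"))),
               class = "tme_value_error")
})

test_that("score is monotone in favorable-up and risk-down directions", {
  set.seed(1)
  genes <- sprintf("g%02d", 1:20)
  m <- toy_model(genes[1:10], genes[11:20])
  x <- toy_expr(matrix(2^rnorm(20 * 5, 4), 20, 5), genes = genes)
  base <- compute_tmescore(x, m)
  for (i in 1:50) {
    g <- sample(20, 1)
    s <- sample(5, 1)
    y <- unclass(x)
    y[g, s] <- y[g, s] + runif(1, 0.5, 5)
    pert <- compute_tmescore(toy_expr(y, genes = genes), m)
    if (g <= 10) expect_gt(pert[s], base[s]) else expect_lt(pert[s], base[s])
    expect_equal(pert[-s], base[-s])
  }
})

test_that("Cox-sign split assigns planted hazard directions", {
  set.seed(2)
  n <- 600
  risk_expr <- 2^rnorm(n, 4, 1)    # high expression -> high hazard
  fav_expr <- 2^rnorm(n, 4, 1)     # high expression -> low hazard
  noise <- 2^rnorm(n, 4, 1)
  lin <- scale(log2(risk_expr + 1)) - scale(log2(fav_expr + 1))
  s <- simulate_survival(as.numeric(lin), beta = log(2), censor_rate = 0.3,
                         seed = 3)
  expr <- toy_expr(rbind(risk_expr, fav_expr, noise),
                   genes = c("RISKY", "PROTECT", "NOISE"),
                   samples = sprintf("s%03d", 1:n))
  cl <- data.frame(sample_id = colnames(expr), os_time = s$os_time,
                   os_event = s$os_event)
  split <- split_by_cox_sign(expr, cl, c("RISKY", "PROTECT", "NOISE"))
  expect_true("RISKY" %in% split$risk$gene)
  expect_true("PROTECT" %in% split$favorable$gene)
  # the uninformative gene lands somewhere by its near-zero beta but is
  # flagged low-confidence
  noise_row <- rbind(split$favorable, split$risk)
  expect_true(noise_row$low_confidence[noise_row$gene == "NOISE"])

  # constant gene is excluded, not assigned
  expr2 <- toy_expr(rbind(risk_expr, rep(5, n)),
                    genes = c("RISKY", "FLAT"),
                    samples = sprintf("s%03d", 1:n))
  split2 <- split_by_cox_sign(expr2, cl, c("RISKY", "FLAT"))
  expect_identical(split2$excluded$gene, "FLAT")
})

test_that("random-forest reduction keeps informative genes, drops decoys", {
  set.seed(13)
  n <- 120
  classes <- rep(1:2, each = n / 2)
  informative <- t(sapply(1:10, function(i)
    2^(rnorm(n, 4, 0.4) + ifelse(classes == 1, 1, 0))))
  noise <- matrix(2^rnorm(90 * n, 4, 0.6), 90)
  expr <- toy_expr(rbind(informative, noise),
                   genes = c(sprintf("inf%02d", 1:10),
                             sprintf("noise%02d", 1:90)),
                   samples = sprintf("s%03d", 1:n))
  keep <- derive_cluster_signature(expr, classes, n_trees = 500, seed = 13)
  expect_true(all(sprintf("inf%02d", 1:10) %in% keep))
  expect_lte(sum(grepl("^noise", keep)), 5)

  top <- derive_cluster_signature(expr, classes, n_trees = 300,
                                  retain_rule = "top_n", n_top = 5,
                                  seed = 14)
  expect_identical(length(top), 5L)

  # duplicated expression rows collapse to one retained gene
  dup <- toy_expr(rbind(informative, informative[1, , drop = FALSE]),
                  genes = c(sprintf("inf%02d", 1:10), "inf01_copy"),
                  samples = sprintf("s%03d", 1:n))
  keep2 <- derive_cluster_signature(dup, classes, n_trees = 300, seed = 15)
  expect_false(all(c("inf01", "inf01_copy") %in% keep2))
  expect_lte(length(keep2), nrow(dup))

  expect_error(derive_cluster_signature(expr, rep(1, n)),
               class = "tme_value_error")
})

test_that("dichotomization finds the planted break and labels by score", {
  # events only below score 5.5: cutpoint must land in (5, 6)
  sc <- setNames(as.numeric(1:10), sprintf("s%02d", 1:10))
  cl <- data.frame(sample_id = names(sc),
                   os_time = c(1, 2, 1.5, 2.5, 1.2, 30, 28, 25, 33, 31),
                   os_event = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  out <- dichotomize(sc, cl, minprop = 0.2)
  expect_gt(out$cutpoint$cutpoint, 5)
  expect_lt(out$cutpoint$cutpoint, 6)
  expect_identical(
    out$score_table$subtype,
    unname(ifelse(sc > out$cutpoint$cutpoint, "TMEscore-high",
                  "TMEscore-low")))

  # bimodal scores, low mode planted at 2.5x hazard -> high group survives
  set.seed(5)
  n <- 200
  sc2 <- c(rnorm(n / 2, -2, 0.4), rnorm(n / 2, 2, 0.4))
  names(sc2) <- sprintf("t%03d", 1:n)
  s <- simulate_survival(as.numeric(sc2 < 0), beta = log(2.5),
                         censor_rate = 0.3, seed = 6)
  cl2 <- data.frame(sample_id = names(sc2), os_time = s$os_time,
                    os_event = s$os_event)
  out2 <- dichotomize(sc2, cl2)
  expect_gt(out2$cutpoint$cutpoint, -1.5)
  expect_lt(out2$cutpoint$cutpoint, 1.5)
  lr <- logrank_test(cl2$os_time, cl2$os_event, out2$score_table$subtype)
  expect_lt(lr$p, 0.01)
  km_hi <- km_estimate(cl2$os_time[out2$score_table$subtype == "TMEscore-high"],
                       cl2$os_event[out2$score_table$subtype == "TMEscore-high"])
  km_lo <- km_estimate(cl2$os_time[out2$score_table$subtype == "TMEscore-low"],
                       cl2$os_event[out2$score_table$subtype == "TMEscore-low"])
  mid <- median(cl2$os_time)
  expect_gt(attr(km_hi, "surv_fun")(mid), attr(km_lo, "surv_fun")(mid))
})

test_that("model JSON serialization round-trips scores bit-exactly", {
  set.seed(7)
  genes <- sprintf("g%02d", 1:12)
  m <- toy_model(genes[1:6], genes[7:12], cutpoint = 1.2345678901234567)
  m$favorable <- data.frame(gene = genes[1:6], beta = -runif(6), p = runif(6))
  m$risk <- data.frame(gene = genes[7:12], beta = runif(6), p = runif(6))
  m$signature_genes <- genes
  x <- toy_expr(matrix(2^rnorm(12 * 8, 4), 12, 8), genes = genes)
  f <- withr::local_tempfile(fileext = ".json")
  write_tme_model(m, f)
  m2 <- read_tme_model(f)
  expect_identical(compute_tmescore(x, m), compute_tmescore(x, m2))
  expect_identical(m$cutpoint, m2$cutpoint)
  expect_identical(m$favorable_genes, m2$favorable_genes)
})
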