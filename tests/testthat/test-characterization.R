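test_that("Fisher mutation-frequency test matches hypergeometric enumeration", {
  subtypes <- setNames(rep(c("high", "low"), each = 5), sprintf("s%02d", 1:10))
  maf <- toy_maf(
    Tumor_Sample_Barcode = c("s01", "s02", "s03", "s01", "s06"),
    Hugo_Symbol = c("TP53", "TP53", "TP53", "TP53", "KRAS"),
    Variant_Classification = "Missense_Mutation",
    t_alt_count = 4L, t_depth = 10L)
  out <- mutation_frequency_test(maf, subtypes)
  # TP53: mutated 3/5 high vs 0/5 low (s01 counted once despite 2 rows)
  tp53 <- out[out$gene == "TP53", ]
  expect_identical(tp53$n_mut_high, 3L)
  expect_identical(tp53$n_mut_low, 0L)
  expect_equal(tp53$fisher_p, 1 / 6, tolerance = 1e-10)
  # equal rates in equal groups -> p = 1
  maf2 <- toy_maf(
    Tumor_Sample_Barcode = c("s01", "s06"),
    Hugo_Symbol = "EGFR", Variant_Classification = "Missense_Mutation",
    t_alt_count = 4L, t_depth = 10L)
  expect_equal(mutation_frequency_test(maf2, subtypes)$fisher_p, 1)
})

test_that("rank-sum comparison uses exact enumeration for small groups", {
  gc <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_true(gc$exact)
  expect_equal(gc$p, 0.1)
  # identical groups: p = 1 (tie-corrected normal, no continuity shift)
  gc2 <- group_compare(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(gc2$p, 1)
  expect_error(group_compare(1:5, rep("a", 5)), class = "tme_value_error")
})

test_that("exact and asymptotic rank-sum p-values agree at n = 10 + 10", {
  worst <- 0
  for (seed in 1:20) {
    set.seed(seed)
    v <- rnorm(20)
    g <- rep(c("a", "b"), each = 10)
    p_exact <- group_compare(v, g)$p
    p_asym <- suppressWarnings(
      wilcox.test(v[1:10], v[11:20], exact = FALSE)$p.value)
    worst <- max(worst, abs(p_exact - p_asym))
  }
  expect_lt(worst, 0.02)
})

test_that("TMB counts non-silent mutations per megabase", {
  maf <- toy_maf(
    Tumor_Sample_Barcode = c(rep("s1", 9), "s2"),
    Hugo_Symbol = sprintf("G%d", 1:10),
    Variant_Classification = c(rep("Missense_Mutation", 8), "Silent",
                               "Silent"),
    t_alt_count = 3L, t_depth = 10L)
  tmb <- compute_tmb(maf, samples = c("s1", "s2", "s3"))
  expect_equal(tmb$tmb[tmb$sample_id == "s1"], 8 / 38, tolerance = 1e-12)
  expect_equal(tmb$tmb[tmb$sample_id == "s2"], 0)  # silent-only sample
  expect_equal(tmb$tmb[tmb$sample_id == "s3"], 0)
  expect_false(tmb$in_maf[tmb$sample_id == "s3"])
  # brute-force filter oracle
  want <- sum(maf$Tumor_Sample_Barcode == "s1" &
                maf$Variant_Classification %in%
                  c("Missense_Mutation", "Nonsense_Mutation",
                    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del",
                    "In_Frame_Ins", "Splice_Site", "Translation_Start_Site",
                    "Nonstop_Mutation"))
  expect_identical(tmb$n_mutations[tmb$sample_id == "s1"], want)
  # silent included when nonsyn_only is off
  expect_equal(compute_tmb(maf, "s1", nonsyn_only = FALSE)$n_mutations, 9L)
})

test_that("VAF comparison splits by subtype and skips one-sided genes", {
  subtypes <- setNames(rep(c("high", "low"), each = 30),
                       sprintf("s%02d", 1:60))
  set.seed(4)
  maf <- toy_maf(
    Tumor_Sample_Barcode = c(sprintf("s%02d", 1:30), sprintf("s%02d", 31:60),
                             "s01", "s31", "s02"),
    Hugo_Symbol = c(rep("SHIFTED", 60), "RARE", "RARE", "ONESIDED"),
    Variant_Classification = "Missense_Mutation",
    t_alt_count = c(round(rbeta(30, 8, 2) * 100), round(rbeta(30, 2, 8) * 100),
                    40L, 60L, 50L),
    t_depth = 100L)
  out <- vaf_compare(maf, subtypes)
  shifted <- out[out$gene == "SHIFTED", ]
  expect_lt(shifted$p, 0.001)
  expect_gt(shifted$median_vaf_high, shifted$median_vaf_low)
  # single mutation per group: exact test over 2 ranks
  expect_equal(out$p[out$gene == "RARE"], 1)
  expect_true(out$skipped[out$gene == "ONESIDED"])
})

test_that("ROC/AUC equals pair counting with the tie convention", {
  lab <- c(0, 0, 0, 0, 1, 1, 1, 1)
  perfect <- c(1, 2, 3, 4, 5, 6, 7, 8)
  rc <- roc_compare(perfect, rep(1, 8), lab)
  expect_equal(rc$roc_a$auc, 1)
  expect_equal(rc$roc_b$auc, 0.5)  # constant score: all ties

  set.seed(5)
  s <- c(3, 1, 4, 1, 5, 9, 2, 6)
  rc2 <- roc_compare(s, -s, lab)
  # exhaustive pair counting: (concordant + ties/2) / (n1 * n0)
  pos <- s[lab == 1]; neg <- s[lab == 0]
  conc <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
  expect_equal(rc2$roc_a$auc, conc / 16)
  expect_equal(rc2$roc_a$auc + rc2$roc_b$auc, 1)  # AUC(s) + AUC(-s) = 1

  # DeLong self-comparison is degenerate at p = 1
  expect_equal(roc_compare(s, s, lab)$delong_p, 1)
  expect_error(roc_compare(s, s, rep(1, 8)), class = "tme_value_error")
})

test_that("cell network recovers a planted protective cell type", {
  set.seed(6)
  n <- 500
  fr <- matrix(rgamma(n * 5, 2), n)
  fr <- fr / rowSums(fr)
  dimnames(fr) <- list(sprintf("s%03d", 1:n), sprintf("ct%d", 1:5))
  s <- simulate_survival(as.numeric(scale(fr[, "ct1"])), beta = -1,
                         censor_rate = 0.3, seed = 7)
  cl <- data.frame(sample_id = rownames(fr), os_time = s$os_time,
                   os_event = s$os_event)
  net <- build_cell_network(fr, cl, n_cell_clusters = 2)
  expect_identical(nrow(net$nodes), 5L)  # node count = cell-type count
  expect_identical(
    net$nodes$os_direction[net$nodes$cell_type == "ct1"], "favorable")
  expect_true(all(net$nodes$os_direction[net$nodes$os_p >= 0.05] == "ns"))
  # display threshold above 1 empties the edge list, correlations remain
  net2 <- build_cell_network(fr, cl, r_min = 1.01, n_cell_clusters = 2)
  expect_identical(nrow(net2$edges), 0L)
  expect_identical(dim(net2$correlations$r), c(5L, 5L))
})
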