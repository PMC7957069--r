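# Run configuration and the end-to-end pipeline driver: validated config
# (serializable to YAML; a config plus fixed inputs fully determines a
# run), stage orchestration with per-stage logging, and a summary JSON of
# the headline counts.

#' Build a validated run configuration
#'
#' @param expression,clinical,maf,signature,fractions Input table paths
#'   (TSV; MAF for mutations). `maf`, `signature` and `fractions` are
#'   optional; `expression` and `clinical` are required unless `simulate`
#'   is enabled.
#' @param simulate `FALSE` (default), `TRUE` (simulate with defaults), or a
#'   named list of [simulate_cohort()] arguments.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed for the whole run.
#' @param characterize Run the characterization stage (default TRUE).
#' @param ... Tunables forwarded to [tme_control()].
#' @return A list of class `"tme_config"`.
#' @export
tme_config <- function(expression = NULL, clinical = NULL, maf = NULL,
                       signature = NULL, fractions = NULL, simulate = FALSE,
                       outdir = tempfile("tmescore_run_"), seed = 1L,
                       characterize = TRUE, ...) {
  control <- tme_control(...)
  cfg <- list(inputs = list(expression = expression, clinical = clinical,
                            maf = maf, signature = signature,
                            fractions = fractions),
              simulate = simulate, outdir = outdir, seed = as.integer(seed),
              characterize = isTRUE(characterize), control = control)
  class(cfg) <- "tme_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  sim_on <- !identical(cfg$simulate, FALSE)
  if (!sim_on) {
    if (is.null(cfg$inputs$expression))
      stop_typed("tme_config_error",
                 "expression input required unless simulate is enabled")
    if (is.null(cfg$inputs$clinical))
      stop_typed("tme_config_error",
                 "clinical table required for the survival stages")
    for (f in Filter(Negate(is.null), cfg$inputs))
      if (!file.exists(f))
        stop_typed("tme_config_error", "input not found: %s", f)
    if (is.null(cfg$inputs$signature) && is.null(cfg$inputs$fractions))
      stop_typed("tme_config_error",
                 "need a signature matrix or precomputed fractions")
  }
  cfg
}

#' Read / write a run configuration as YAML
#' @param path YAML path.
#' @return For `read_config`, a validated `"tme_config"`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  ctl <- y$control %||% list()
  do.call(tme_config, c(
    y$inputs %||% list(),
    list(simulate = y$simulate %||% FALSE,
         outdir = y$outdir %||% tempfile("tmescore_run_"),
         seed = y$seed %||% 1L,
         characterize = y$characterize %||% TRUE),
    ctl))
}

#' @rdname read_config
#' @param cfg A `"tme_config"`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_typed("tme_stage_error", "stage '%s' failed: %s", name,
               conditionMessage(e))
  })
}

#' Run the full TME subtyping pipeline
#'
#' Simulates or loads the cohort, fits the TME model (deconvolution,
#' consensus clustering, differential expression, signature reduction,
#' score, cutpoint), optionally characterizes the subtypes, writes every
#' stage table under `config$outdir`, and writes a `summary.json` with the
#' headline counts. Deterministic given (inputs, config, seed): two runs
#' with the same config produce byte-identical summaries.
#'
#' @param config A `"tme_config"` from [tme_config()] or [read_config()].
#' @return Invisibly, a list with `model`, `characterization`, `summary`,
#'   and `cohort` (when simulated).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  maybe_seed(config$seed)
  sim_on <- !identical(config$simulate, FALSE)

  cohort <- NULL
  if (sim_on) {
    args <- if (is.list(config$simulate)) config$simulate else list()
    if (is.null(args$seed)) args$seed <- config$seed
    cohort <- run_stage("simulate", do.call(simulate_cohort, args))
    expr <- cohort$expression
    clinical <- cohort$clinical
    maf <- cohort$maf
    signature <- cohort$signature
    fractions <- NULL
    run_stage("simulate", {
      write_expression(expr, file.path(config$outdir, "expression.tsv"))
      write_tsv(clinical, file.path(config$outdir, "clinical.tsv"))
      write_tsv(maf, file.path(config$outdir, "mutations.maf.tsv"))
      write_fractions(cohort$truth$true_fractions,
                      file.path(config$outdir, "truth_fractions.tsv"))
      write_tsv(data.frame(sample_id = names(cohort$truth$true_subtype),
                           true_subtype = cohort$truth$true_subtype),
                file.path(config$outdir, "truth_subtype.tsv"))
    })
  } else {
    expr <- run_stage("read_inputs",
                      read_expression(config$inputs$expression))
    clinical <- run_stage("read_inputs", read_clinical(config$inputs$clinical))
    maf <- if (!is.null(config$inputs$maf))
      run_stage("read_inputs", read_maf(config$inputs$maf)) else NULL
    signature <- if (!is.null(config$inputs$signature))
      run_stage("read_inputs", {
        s <- read_expression(config$inputs$signature)
        attr(s, "scale_tag") <- NULL
        s
      }) else NULL
    fractions <- if (!is.null(config$inputs$fractions))
      run_stage("read_inputs", read_fractions(config$inputs$fractions))
    else NULL
  }

  model <- run_stage("fit", tme_fit(expr, clinical, signature = signature,
                                    fractions = fractions,
                                    control = config$control,
                                    seed = config$seed))
  run_stage("fit", {
    write_fractions(model$fractions, file.path(config$outdir, "fractions.tsv"))
    write_tsv(data.frame(sample_id = names(model$tme_clusters),
                         tme_cluster = model$tme_clusters,
                         deg_class = model$classes),
              file.path(config$outdir, "clusters.tsv"))
    write_tsv(data.frame(gene = model$degs),
              file.path(config$outdir, "degs.tsv"))
    write_tsv(model$score_table, file.path(config$outdir, "scores.tsv"))
    write_tme_model(model, file.path(config$outdir, "model.json"))
  })

  char <- NULL
  if (config$characterize) {
    char <- run_stage("characterize",
                      characterize_subtypes(model, maf = maf))
    run_stage("characterize", {
      write_tsv(char$network$nodes,
                file.path(config$outdir, "network_nodes.tsv"))
      write_tsv(char$network$edges,
                file.path(config$outdir, "network_edges.tsv"))
      write_tsv(char$fraction_tests,
                file.path(config$outdir, "fraction_tests.tsv"))
      if (!is.null(char$tmb))
        write_tsv(char$tmb, file.path(config$outdir, "tmb.tsv"))
      if (!is.null(char$mutation_tests))
        write_tsv(char$mutation_tests,
                  file.path(config$outdir, "mutation_tests.tsv"))
      if (!is.null(char$vaf))
        write_tsv(char$vaf, file.path(config$outdir, "vaf_tests.tsv"))
    })
  }

  summary <- list(
    n_samples = ncol(expr), n_genes = nrow(expr),
    k_tme = model$k_tme, k_classes = model$k_classes,
    n_degs = length(model$degs),
    n_signature_genes = length(model$signature_genes),
    n_favorable = length(model$favorable_genes),
    n_risk = length(model$risk_genes),
    cutpoint = model$cutpoint,
    n_high = sum(model$score_table$subtype == "TMEscore-high"),
    n_low = sum(model$score_table$subtype == "TMEscore-low"),
    logrank_chi_square = model$logrank$chi_square,
    logrank_p = model$logrank$p)
  if (!is.null(char$roc)) {
    summary$auc_tmescore <- char$roc$roc_a$auc
    summary$auc_tmb <- char$roc$roc_b$auc
    summary$delong_p <- char$roc$delong_p
  }
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model = model, characterization = char, summary = summary,
                 cohort = cohort))
}
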