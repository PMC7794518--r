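# End-to-end orchestration: simulate -> filter -> tumor fraction -> TMB ->
# copy number -> concordance, as one reproducible run with a resolved
# configuration, a log, and machine-readable outputs.

RUN_STAGES <- c("filter", "tumor_fraction", "tmb", "copy_number",
                "concordance")

#' Pipeline run configuration
#'
#' Collects every stage parameter with defaults matching the calling and
#' estimation thresholds the package implements: 8 mutant reads, 1%/8%
#' VAF floors, 3x gDNA ratio, mapping quality above 30, read-end
#' proximity above 25, a 95% binomial quantile adjustment, subclonality
#' below 25% of tumor fraction, and ctDNA detection above 1%.
#'
#' @param sim a [sim_config()] for the synthetic cohort stage.
#' @param thresholds a [somatic_thresholds()] list.
#' @param quantile confidence level for [adjusted_vaf()].
#' @param detection_tf ctDNA detection threshold (tumor fraction scale).
#' @param subclonal_fraction clonality threshold as a fraction of TF.
#' @param amplification_threshold copies at which a gene is amplified.
#' @param ci_level copy-number confidence level.
#' @param strict_chip exclude (rather than only flag) variants under
#'   clonal hematopoiesis review.
#' @param include_silent_tmb count silent mutations in TMB.
#' @param stages subset of analysis stages to run (dependency order is
#'   enforced internally).
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       thresholds = somatic_thresholds(),
                       quantile = 0.95,
                       detection_tf = 0.01,
                       subclonal_fraction = 0.25,
                       amplification_threshold = 5,
                       ci_level = 0.95,
                       strict_chip = FALSE,
                       include_silent_tmb = FALSE,
                       stages = RUN_STAGES) {
  config <- list(sim = sim, thresholds = thresholds, quantile = quantile,
                 detection_tf = detection_tf,
                 subclonal_fraction = subclonal_fraction,
                 amplification_threshold = amplification_threshold,
                 ci_level = ci_level, strict_chip = strict_chip,
                 include_silent_tmb = include_silent_tmb, stages = stages)
  class(config) <- "run_config"
  errors <- validate_config(config)
  if (length(errors)) stop("invalid run_config:\n  ",
                           paste(errors, collapse = "\n  "))
  config
}

#' Validate a pipeline configuration
#'
#' @param config a `run_config` (or plain list with the same fields).
#' @return Character vector of error messages; empty when valid.
#' @export
validate_config <- function(config) {
  errors <- character()
  known <- c("sim", "thresholds", "quantile", "detection_tf",
             "subclonal_fraction", "amplification_threshold", "ci_level",
             "strict_chip", "include_silent_tmb", "stages")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    errors <- c(errors, paste("unknown field(s):",
                              paste(unknown, collapse = ", ")))
  th <- config$thresholds
  if (!is.null(th)) {
    if (!is.null(th$min_alt_reads) && th$min_alt_reads < 1)
      errors <- c(errors, "thresholds$min_alt_reads must be >= 1")
    for (f in c("min_vaf_cfdna", "min_vaf_tissue"))
      if (!is.null(th[[f]]) && (th[[f]] < 0 || th[[f]] > 1))
        errors <- c(errors, paste0("thresholds$", f, " must be in [0, 1]"))
    if (!is.null(th$gdna_ratio) && th$gdna_ratio < 0)
      errors <- c(errors, "thresholds$gdna_ratio must be >= 0")
    for (f in c("min_mapq", "min_end_distance"))
      if (!is.null(th[[f]]) && th[[f]] < 0)
        errors <- c(errors, paste0("thresholds$", f, " must be >= 0"))
  }
  for (f in c("quantile", "detection_tf", "subclonal_fraction", "ci_level"))
    if (!is.null(config[[f]]) &&
        (!is.numeric(config[[f]]) || config[[f]] < 0 || config[[f]] > 1))
      errors <- c(errors, paste0(f, " must be in [0, 1]"))
  for (f in c("quantile", "ci_level"))
    if (!is.null(config[[f]]) && config[[f]] %in% c(0, 1))
      errors <- c(errors, paste0(f, " of ", config[[f]],
                                 " gives a degenerate bound"))
  if (!is.null(config$amplification_threshold) &&
      config$amplification_threshold < 0)
    errors <- c(errors, "amplification_threshold must be >= 0")
  if (!is.null(config$stages) &&
      length(setdiff(config$stages, RUN_STAGES)))
    errors <- c(errors, paste("unknown stage(s):",
                              paste(setdiff(config$stages, RUN_STAGES),
                                    collapse = ", ")))
  if (!is.null(config$sim)) {
    sim_err <- tryCatch({ validate_sim_config(config$sim); character() },
                        error = function(e) conditionMessage(e))
    errors <- c(errors, sim_err)
  }
  errors
}

stage_error <- function(stage, sample, e) {
  stop(structure(class = c("pipeline_error", "error", "condition"),
                 list(message = sprintf("stage '%s' failed for %s: %s",
                                        stage, sample, conditionMessage(e)),
                      call = NULL, stage = stage, sample = sample)))
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) a cohort, then executes the enabled stages in
#' dependency order, writing every intermediate and a cohort summary to
#' `out_dir`: the cohort files, kept-variant and audit TSVs, per-sample
#' tumor fractions, TMB and copy-number tables, the concordance report,
#' a `summary.json`, the resolved configuration (`config.yaml`) and a run
#' log. Tumor-fraction estimation is two-pass: if the variant backing a
#' sample's estimate lies in a gene the copy-number stage calls amplified
#' in that sample, the estimate is redone excluding that gene.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param cohort optional pre-built `ctdna_cohort`; by default one is
#'   simulated from `config$sim`.
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `kept`, `audit`, `tf`, `tmb`, `copy_number`, `concordance`,
#'   `summary`).
#' @export
run_pipeline <- function(config, out_dir, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  errors <- validate_config(config)
  if (length(errors)) stop("invalid config: ", paste(errors, collapse = "; "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(..., "\n", sep = "", file = log_path,
                                append = TRUE)
  cat("", file = log_path)
  log_line("ctdnapipe ", as.character(utils::packageVersion("ctdnapipe")),
           " | seed ", config$sim$seed)

  if (is.null(cohort)) cohort <- simulate_cohort(config$sim)
  write_cohort(cohort, file.path(out_dir, "cohort"))
  log_line("cohort: ", length(cohort$truth), " patients, ",
           nrow(cohort$manifest), " samples")

  results <- list(cohort = cohort)
  stages <- config$stages

  if ("filter" %in% stages) {
    fr <- tryCatch(filter_cohort(cohort, config$thresholds,
                                 strict_chip = config$strict_chip),
                   error = function(e) stage_error("filter", "cohort", e))
    results$kept <- fr$kept
    results$audit <- fr$audit
    write_tsv(fr$kept, file.path(out_dir, "kept_variants.tsv"))
    write_tsv(fr$audit, file.path(out_dir, "filter_audit.tsv"))
    log_line("filter: kept ", nrow(fr$kept), " of ", nrow(fr$audit),
             " candidate observations")
  }

  if ("tumor_fraction" %in% stages) {
    tf <- tryCatch(
      cohort_tumor_fractions(results$kept, cohort$manifest,
                             config$quantile, config$detection_tf),
      error = function(e) stage_error("tumor_fraction", "cohort", e))
    results$tf <- tf
  }

  if ("copy_number" %in% stages) {
    cn <- tryCatch(
      cohort_copy_numbers(cohort$coverage, results$tf,
                          config$amplification_threshold, config$ci_level),
      error = function(e) stage_error("copy_number", "cohort", e))
    # second pass: re-estimate TF where the source variant proved amplified
    if ("tumor_fraction" %in% stages) {
      tf <- results$tf
      for (i in seq_len(nrow(tf))) {
        if (is.na(tf$source_variant[i])) next
        src <- results$kept[tf$sample_id[i] == results$kept$sample_id &
                              variant_key(results$kept$chrom,
                                          results$kept$pos,
                                          results$kept$ref,
                                          results$kept$alt) ==
                              tf$source_variant[i], ]
        amp_genes <- cn$gene[cn$sample_id == tf$sample_id[i] & cn$amplified]
        if (nrow(src) && src$gene[1] %in% amp_genes) {
          est <- estimate_tumor_fraction(
            results$kept[results$kept$sample_id == tf$sample_id[i], ],
            tf$compartment[i], config$quantile, config$detection_tf,
            exclude_genes = amp_genes)
          tf$tumor_fraction[i] <- est$tumor_fraction
          tf$adjusted_vaf[i] <- est$adjusted_vaf
          tf$raw_max_vaf[i] <- est$raw_max_vaf
          tf$source_variant[i] <- est$source_variant
          tf$detected[i] <- est$detected
          log_line("tumor_fraction: re-estimated ", tf$sample_id[i],
                   " excluding amplified gene(s)")
        }
      }
      results$tf <- tf
      cn <- cohort_copy_numbers(cohort$coverage, results$tf,
                                config$amplification_threshold,
                                config$ci_level)
    }
    results$copy_number <- cn
    write_tsv(cn, file.path(out_dir, "copy_number.tsv"))
    log_line("copy_number: ", sum(cn$amplified), " amplification call(s)")
  }

  if ("tumor_fraction" %in% stages) {
    write_tsv(results$tf, file.path(out_dir, "tumor_fractions.tsv"))
    log_line("tumor_fraction: ", sum(results$tf$detected),
             " of ", nrow(results$tf), " tumor samples detected")
  }

  if ("tmb" %in% stages) {
    tmb <- tryCatch(
      cohort_tmb(results$kept, cohort$depth, cohort$manifest,
                 config$include_silent_tmb),
      error = function(e) stage_error("tmb", "cohort", e))
    results$tmb <- tmb
    write_tsv(tmb, file.path(out_dir, "tmb.tsv"))
    log_line("tmb: median ", signif(stats::median(tmb$tmb_per_mb), 3),
             " mutations/Mb")
  }

  if ("concordance" %in% stages) {
    conc <- tryCatch(
      cohort_concordance_report(results$kept, results$tf, cohort$manifest,
                                cohort$variants, config$subclonal_fraction),
      error = function(e) stage_error("concordance", "cohort", e))
    results$concordance <- conc
    if (is.null(conc$reason)) {
      write_tsv(conc$pairs, file.path(out_dir, "concordance_pairs.tsv"))
      write_tsv(conc$variants, file.path(out_dir, "concordance_variants.tsv"))
      write_tsv(conc$serial, file.path(out_dir, "serial_concordance.tsv"))
      cont <- if (!is.null(conc$contingency))
        list(table = conc$contingency$table,
             odds_ratio = conc$contingency$odds_ratio,
             p_two_sided = conc$contingency$p_two_sided)
      else list(note = "stratified table degenerate; test not applicable")
      jsonlite::write_json(cont, file.path(out_dir, "contingency.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      log_line("concordance: ", conc$totals$n_shared, "/",
               conc$totals$n_mutations, " mutations shared across ",
               conc$totals$n_pairs, " pairs")
    } else log_line("concordance: ", conc$reason)
  }

  summary <- pipeline_summary(results, config)
  results$summary <- summary
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  yaml::write_yaml(resolve_config_for_yaml(config),
                   file.path(out_dir, "config.yaml"))
  invisible(results)
}

resolve_config_for_yaml <- function(config) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  out$sim$amplified_genes <- as.list(out$sim$amplified_genes)
  out$sim$depth_mean <- as.list(out$sim$depth_mean)
  out$thresholds$background_rate <-
    if (is.null(out$thresholds$background_rate)) "disabled"
    else out$thresholds$background_rate
  out
}

pipeline_summary <- function(results, config) {
  tf <- results$tf
  s <- list(
    schema_version = 1L,
    seed = config$sim$seed,
    n_patients = length(results$cohort$truth),
    n_samples = nrow(results$cohort$manifest))
  if (!is.null(tf)) {
    cf <- tf[tf$compartment == "cfDNA", ]
    ti <- tf[tf$compartment == "tissue", ]
    s$tumor_fraction <- list(
      median_cfdna = stats::median(cf$tumor_fraction),
      median_tissue = stats::median(ti$tumor_fraction),
      ctdna_detection_rate = mean(cf$detected),
      evaluable_rate_cfdna = mean(cf$evaluable))
  }
  if (!is.null(results$tmb))
    s$tmb <- list(median_per_mb = stats::median(results$tmb$tmb_per_mb))
  if (!is.null(results$copy_number))
    s$copy_number <- list(n_amplified = sum(results$copy_number$amplified))
  conc <- results$concordance
  if (!is.null(conc) && is.null(conc$reason)) {
    s$concordance <- list(
      n_pairs = conc$totals$n_pairs,
      fraction_shared = conc$totals$fraction_shared,
      fisher_p = if (!is.null(conc$contingency))
        conc$contingency$p_two_sided else NA)
    for (cmp in c("cfDNA", "tissue")) {
      v <- conc$serial$concordance[conc$serial$compartment == cmp]
      s$concordance[[paste0("median_serial_", cmp)]] <-
        if (length(v)) stats::median(v, na.rm = TRUE) else NA
    }
  }
  s
}
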