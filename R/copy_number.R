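# Per-gene absolute copy number from normalized coverage log-ratios with
# purity correction. The observed coverage ratio of a gene is modeled as a
# mixture of tumor cells at copy number CN and diploid normal cells:
#   ratio = (tf * CN + 2 * (1 - tf)) / 2
# so CN = (2 * 2^log_ratio - 2 * (1 - tf)) / tf, floored at zero.
# Confidence intervals come from the per-gene spread of log-ratios among
# samples with no evidence of cancer (tumor fraction 0), computed on the
# log scale and transformed through the same model.

#' Coverage log-ratio for one gene
#'
#' @param gene_coverage normalized coverage of the gene in the sample.
#' @param baseline_coverage expected normalized coverage of the same gene
#'   in cancer-free samples.
#' @return `log2(gene_coverage / baseline_coverage)`.
#' @export
gene_log_ratio <- function(gene_coverage, baseline_coverage) {
  if (any(gene_coverage <= 0) || any(baseline_coverage <= 0))
    stop("gene_log_ratio: coverages must be > 0")
  log2(gene_coverage / baseline_coverage)
}

#' Purity-corrected absolute gene copy number
#'
#' Inverts the tumor/normal mixture model at the sample's tumor fraction.
#' High-level amplifications remain detectable at low tumor fractions
#' because the correction divides the coverage excess by `tf`. Negative
#' solutions (coverage below what pure normal DNA would give) are floored
#' at 0.
#'
#' @param log_ratio log2 coverage ratio(s).
#' @param tumor_fraction sample tumor fraction in `(0, 1]`; copy number is
#'   unidentifiable at `tf = 0`.
#' @return Estimated copies (>= 0); equals `2 * 2^log_ratio` at `tf = 1`
#'   and 2 whenever `log_ratio = 0`.
#' @export
gene_copy_number <- function(log_ratio, tumor_fraction) {
  if (any(tumor_fraction <= 0))
    stop("gene_copy_number: tumor_fraction must be > 0 (copy number is ",
         "unidentifiable in a sample without tumor DNA)")
  if (any(tumor_fraction > 1)) stop("tumor_fraction must be <= 1")
  pmax(0, (2 * 2 ^ log_ratio - 2 * (1 - tumor_fraction)) / tumor_fraction)
}

#' Baseline per-gene log-ratio dispersion from cancer-free samples
#'
#' Estimates, for each gene, the standard deviation of the coverage
#' log-ratio among samples with tumor fraction 0, which calibrates the
#' copy-number confidence intervals. At least three such samples are
#' required.
#'
#' @param baseline_coverage data.frame (`sample_id`, `gene`, `coverage`)
#'   restricted to zero-tumor-fraction samples.
#' @return data.frame: gene, baseline_mean (linear scale), baseline_sd
#'   (log2 scale), n.
#' @export
estimate_baseline_sd <- function(baseline_coverage) {
  n_samp <- length(unique(baseline_coverage$sample_id))
  if (n_samp < 3)
    stop("estimate_baseline_sd: need >= 3 cancer-free baseline samples, got ",
         n_samp)
  sp <- split(baseline_coverage, baseline_coverage$gene)
  out <- do.call(rbind, lapply(sp, function(g) {
    lr <- log2(g$coverage)
    data.frame(gene = g$gene[1],
               baseline_mean = 2 ^ mean(lr),
               baseline_sd = stats::sd(lr),
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Confidence interval for a gene copy number
#'
#' Propagates `log_ratio +/- z * baseline_sd` through
#' [gene_copy_number()]; the interval is computed on the log-ratio scale
#' and transformed, then floored at 0 copies.
#'
#' @param log_ratio observed log2 coverage ratio.
#' @param tumor_fraction sample tumor fraction in `(0, 1]`.
#' @param baseline_sd per-gene log-ratio standard deviation among
#'   zero-tumor-fraction samples.
#' @param level confidence level (default 0.95).
#' @return Named numeric `c(ci_low, ci_high)` in copies.
#' @export
copy_number_ci <- function(log_ratio, tumor_fraction, baseline_sd,
                           level = 0.95) {
  if (any(baseline_sd < 0)) stop("baseline_sd must be >= 0")
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(ci_low = gene_copy_number(log_ratio - z * baseline_sd, tumor_fraction),
    ci_high = gene_copy_number(log_ratio + z * baseline_sd, tumor_fraction))
}

#' Amplification call
#'
#' @param copies estimated copy number(s) (>= 0).
#' @param threshold minimum copies to call an amplification; the default
#'   of 5 is configurable and boundary-inclusive.
#' @return Logical.
#' @export
call_amplification <- function(copies, threshold = 5) {
  if (any(copies < 0)) stop("copies must be >= 0")
  copies >= threshold
}

#' Gene copy-number calls for every evaluable tumor sample of a cohort
#'
#' The baseline is derived from samples whose estimated tumor fraction is
#' 0 (typically the matched germline samples plus any tumor-negative
#' specimens); per-gene baseline mean and log-ratio sd calibrate the
#' estimates and intervals. Samples with tumor fraction 0 are skipped,
#' since copy number is unidentifiable there.
#'
#' @param coverage cohort coverage table (`sample_id`, `gene`,
#'   `coverage`).
#' @param tf_table data.frame with `sample_id` and `tumor_fraction` for
#'   tumor samples; samples absent from it (e.g. gDNA) are treated as
#'   tumor fraction 0 and contribute to the baseline.
#' @param amplification_threshold copies at or above which a gene is
#'   called amplified.
#' @param level confidence level for intervals.
#' @return data.frame: sample_id, gene, log_ratio, copy_number, ci_low,
#'   ci_high, amplified.
#' @export
cohort_copy_numbers <- function(coverage, tf_table,
                                amplification_threshold = 5, level = 0.95) {
  tf <- tf_table$tumor_fraction[match(coverage$sample_id,
                                      tf_table$sample_id)]
  tf[is.na(tf)] <- 0
  baseline <- estimate_baseline_sd(coverage[tf == 0, , drop = FALSE])
  tumor <- coverage[tf > 0, , drop = FALSE]
  tft <- tf[tf > 0]
  b <- match(tumor$gene, baseline$gene)
  lr <- gene_log_ratio(tumor$coverage, baseline$baseline_mean[b])
  cn <- gene_copy_number(lr, tft)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- gene_copy_number(lr - z * baseline$baseline_sd[b], tft)
  hi <- gene_copy_number(lr + z * baseline$baseline_sd[b], tft)
  out <- data.frame(sample_id = tumor$sample_id, gene = tumor$gene,
                    log_ratio = lr, copy_number = cn,
                    ci_low = lo, ci_high = hi,
                    amplified = cn >= amplification_threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
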