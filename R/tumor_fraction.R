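# Conservative tumor-fraction estimation from the highest somatic VAF.
# Observed mutant read counts are treated as binomial draws; the highest
# observed VAF is deflated to the value it would have if it were a 95%
# quantile outlier (an exact one-sided lower confidence bound), then
# transformed to a tumor fraction under a loss-of-heterozygosity
# assumption: TF = 2 / (1/VAF + 1).

#' Conservative binomial adjustment of an observed VAF
#'
#' Given `k` mutant reads of `n` total, returns the largest allele
#' fraction `p` such that observing `k` or more mutant reads still has
#' probability at most `1 - quantile` under Binomial(n, p) - i.e. the
#' exact one-sided lower confidence bound at level `quantile` (the
#' Clopper-Pearson construction, computed through the Beta quantile
#' identity). This deflates the highest observed VAF to guard against it
#' being a high quantile outlier of its sampling distribution.
#'
#' @param alt_reads mutant read count `k >= 0` (vectorized).
#' @param depth total read count `n >= k`.
#' @param quantile confidence level of the bound, default 0.95.
#' @return Adjusted VAF in `[0, 1]`; 0 where `alt_reads = 0`.
#' @export
adjusted_vaf <- function(alt_reads, depth, quantile = 0.95) {
  if (any(depth < 1)) stop("adjusted_vaf: depth must be >= 1")
  if (any(alt_reads < 0)) stop("adjusted_vaf: alt_reads must be >= 0")
  if (any(alt_reads > depth)) stop("adjusted_vaf: alt_reads must be <= depth")
  if (quantile <= 0 || quantile >= 1)
    stop("adjusted_vaf: quantile must be in (0, 1)")
  n <- max(length(alt_reads), length(depth))
  k <- rep_len(alt_reads, n); d <- rep_len(depth, n)
  out <- numeric(n)
  pos <- k > 0
  out[pos] <- stats::qbeta(1 - quantile, k[pos], d[pos] - k[pos] + 1)
  out
}

#' Tumor fraction from a somatic VAF under loss of heterozygosity
#'
#' `TF = 2 / (1/VAF + 1) = 2 VAF / (1 + VAF)`. Assuming the selected
#' mutation sits on a region of loss of heterozygosity is conservative:
#' any residual reference copy in tumor cells would only make the true
#' tumor fraction larger than this estimate. The calling floors of 1%
#' (cfDNA) and 8% (tissue) map to detection limits of about 2% and 15%
#' tumor fraction respectively.
#'
#' @param vaf variant allele fraction(s) in `[0, 1]`.
#' @return Tumor fraction(s) in `[0, 1]`.
#' @seealso [vaf_from_tumor_fraction()] for the inverse.
#' @export
tumor_fraction_from_vaf <- function(vaf) {
  if (any(vaf < 0 | vaf > 1)) stop("vaf must be in [0, 1]")
  2 * vaf / (1 + vaf)
}

#' Inverse of [tumor_fraction_from_vaf()]
#'
#' @param tf tumor fraction(s) in `[0, 1]`.
#' @return The VAF `tf / (2 - tf)` a truncal LOH mutation would show.
#' @export
vaf_from_tumor_fraction <- function(tf) {
  if (any(tf < 0 | tf > 1)) stop("tf must be in [0, 1]")
  tf / (2 - tf)
}

#' Select the variant used for tumor-fraction estimation
#'
#' Among filtered somatic variants, the highest-VAF autosomal variant is
#' used, after excluding chromosome 9 mutations (frequent copy-neutral
#' LOH), TERT promoter mutations (low depth), mutations in copy-number
#' amplified regions, and anything on sex or mitochondrial contigs. Ties
#' at the maximum VAF are broken by lexicographic (chrom, pos, alt) order.
#'
#' @param kept_variants data.frame of filtered variant observations.
#' @param exclude_genes additional genes to exclude (e.g. genes called
#'   amplified by the copy-number stage in a second pass).
#' @return The selected one-row data.frame, or `NULL` when none eligible.
#' @export
select_tf_variant <- function(kept_variants, exclude_genes = NULL) {
  v <- kept_variants
  if (is.null(v) || nrow(v) == 0) return(NULL)
  eligible <- v$region_flag == "autosome" & is_autosome(v$chrom)
  if (!is.null(exclude_genes)) eligible <- eligible & !(v$gene %in% exclude_genes)
  v <- v[eligible, , drop = FALSE]
  if (nrow(v) == 0) return(NULL)
  vaf <- ifelse(v$depth > 0, v$alt_reads / v$depth, 0)
  top <- which(vaf == max(vaf))
  if (length(top) > 1)
    top <- top[order(v$chrom[top], v$pos[top], v$alt[top])][1]
  v[top, , drop = FALSE]
}

#' Estimate the tumor fraction of a filtered sample
#'
#' Applies [adjusted_vaf()] to the read counts of the variant chosen by
#' [select_tf_variant()], then [tumor_fraction_from_vaf()]. A cfDNA sample
#' is called ctDNA-detected when the estimated fraction exceeds 1%; a
#' sample is evaluable for genomic characterization when at least one
#' protein-altering somatic mutation was kept.
#'
#' @param kept_variants data.frame of filtered variant observations for
#'   one sample.
#' @param compartment `"cfDNA"` or `"tissue"`.
#' @param quantile confidence level for the binomial adjustment.
#' @param detection_tf detection threshold on the tumor fraction scale.
#' @param exclude_genes passed to [select_tf_variant()].
#' @return A `tf_estimate`: list with `tumor_fraction`, `adjusted_vaf`,
#'   `raw_max_vaf`, `source_variant` (key or `NA`), `detected`,
#'   `evaluable`.
#' @export
estimate_tumor_fraction <- function(kept_variants,
                                    compartment = c("cfDNA", "tissue"),
                                    quantile = 0.95, detection_tf = 0.01,
                                    exclude_genes = NULL) {
  compartment <- match.arg(compartment)
  evaluable <- !is.null(kept_variants) && nrow(kept_variants) > 0 &&
    any(kept_variants$effect == "protein_altering")
  sel <- select_tf_variant(kept_variants, exclude_genes)
  if (is.null(sel)) {
    est <- list(tumor_fraction = 0, adjusted_vaf = 0, raw_max_vaf = 0,
                source_variant = NA_character_, detected = FALSE,
                evaluable = evaluable)
    class(est) <- "tf_estimate"
    return(est)
  }
  av <- adjusted_vaf(sel$alt_reads, sel$depth, quantile)
  tf <- tumor_fraction_from_vaf(av)
  est <- list(tumor_fraction = tf, adjusted_vaf = av,
              raw_max_vaf = sel$alt_reads / sel$depth,
              source_variant = variant_key(sel$chrom, sel$pos, sel$ref,
                                           sel$alt),
              detected = tf > detection_tf,
              evaluable = evaluable)
  class(est) <- "tf_estimate"
  est
}

#' @export
print.tf_estimate <- function(x, ...) {
  cat(sprintf(
    "tumor fraction %.4f (adjusted VAF %.4f, raw max %.4f) %s%s\n",
    x$tumor_fraction, x$adjusted_vaf, x$raw_max_vaf,
    if (x$detected) "detected" else "not detected",
    if (x$evaluable) ", evaluable" else ", not evaluable"))
  invisible(x)
}

#' Purity-normalized VAF
#'
#' @param vaf observed VAF in `[0, 1]`.
#' @param tf sample tumor fraction in `(0, 1]`.
#' @return `vaf / tf` (multiply by 100 for the percent scale used in
#'   reports); ratios above 1 typically indicate amplified loci.
#' @export
normalized_vaf <- function(vaf, tf) {
  if (any(tf <= 0)) stop("normalized_vaf: tf must be > 0")
  if (any(vaf < 0 | vaf > 1)) stop("vaf must be in [0, 1]")
  vaf / tf
}

#' Clonality classification of a mutation
#'
#' A mutation is classified subclonal when its VAF is strictly below 25%
#' of the sample tumor fraction, a deliberately conservative cut given
#' that targeted panels do not support allele-specific copy number and
#' ploidy modeling; otherwise clonal.
#'
#' @param vaf observed VAF(s).
#' @param tf sample tumor fraction in `(0, 1]`.
#' @param subclonal_fraction the threshold as a fraction of `tf`.
#' @return Character vector, `"clonal"` or `"subclonal"`.
#' @export
classify_clonality <- function(vaf, tf, subclonal_fraction = 0.25) {
  if (any(tf <= 0)) stop("classify_clonality: tf must be > 0")
  ifelse(vaf < subclonal_fraction * tf, "subclonal", "clonal")
}

#' Tumor fraction for every tumor sample of a cohort
#'
#' @param kept data.frame of filtered observations (all samples).
#' @param manifest cohort manifest.
#' @param quantile,detection_tf see [estimate_tumor_fraction()].
#' @param exclude_genes optional per-call amplified-gene exclusion.
#' @return data.frame with one row per tumor sample: sample_id,
#'   patient_id, compartment, tumor_fraction, adjusted_vaf, raw_max_vaf,
#'   source_variant, detected, evaluable.
#' @export
cohort_tumor_fractions <- function(kept, manifest, quantile = 0.95,
                                   detection_tf = 0.01,
                                   exclude_genes = NULL) {
  tumor <- manifest[manifest$compartment != "gDNA", ]
  rows <- lapply(seq_len(nrow(tumor)), function(i) {
    sid <- tumor$sample_id[i]
    est <- estimate_tumor_fraction(kept[kept$sample_id == sid, , drop = FALSE],
                                   tumor$compartment[i], quantile,
                                   detection_tf, exclude_genes)
    data.frame(sample_id = sid, patient_id = tumor$patient_id[i],
               compartment = tumor$compartment[i],
               timepoint_days = tumor$timepoint_days[i],
               tumor_fraction = est$tumor_fraction,
               adjusted_vaf = est$adjusted_vaf,
               raw_max_vaf = est$raw_max_vaf,
               source_variant = est$source_variant,
               detected = est$detected, evaluable = est$evaluable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
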