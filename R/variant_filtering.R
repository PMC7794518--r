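# Somatic mutation calling filters for targeted cfDNA/tissue panels with a
# matched germline, plus the stricter silent-mutation rules used for
# whole-exome data. Every candidate variant gets an audit record listing
# exactly which rules it failed.

#' Somatic filter thresholds
#'
#' Default thresholds for targeted-panel somatic calling: at least eight
#' mutant-allele reads, minimum VAF 1% in cfDNA and 8% in tissue, VAF more
#' than 3x that of the matched gDNA, mean mapping quality of
#' mutation-supporting reads strictly above 30, and a read-end proximity
#' score strictly above 25 bases. Ties at exactly 30 / exactly 25 fail.
#'
#' @param min_alt_reads minimum mutant-allele read count.
#' @param min_vaf_cfdna,min_vaf_tissue compartment VAF floors.
#' @param gdna_ratio required ratio of tumor VAF to matched gDNA VAF.
#' @param min_mapq mapping-quality gate (strict inequality).
#' @param min_end_distance read-end proximity gate in bases (strict).
#' @param background_rate optional per-site background error rate for an
#'   additional one-sided binomial test of the mutant read count; `NULL`
#'   (the default) disables the test.
#' @param background_alpha significance level for the background test.
#' @return A named list of thresholds.
#' @export
somatic_thresholds <- function(min_alt_reads = 8L,
                               min_vaf_cfdna = 0.01,
                               min_vaf_tissue = 0.08,
                               gdna_ratio = 3,
                               min_mapq = 30,
                               min_end_distance = 25,
                               background_rate = NULL,
                               background_alpha = 0.01) {
  list(min_alt_reads = min_alt_reads, min_vaf_cfdna = min_vaf_cfdna,
       min_vaf_tissue = min_vaf_tissue, gdna_ratio = gdna_ratio,
       min_mapq = min_mapq, min_end_distance = min_end_distance,
       background_rate = background_rate,
       background_alpha = background_alpha)
}

#' Read-end proximity score
#'
#' Mean distance of the mutant allele from the nearest read end, among the
#' reads supporting the mutation. Low scores indicate alignment or FFPE
#' artifacts clustered at fragment ends.
#'
#' @param end_distances distances in bases, one per supporting read.
#' @return The arithmetic mean in bases.
#' @export
read_end_proximity <- function(end_distances) {
  if (length(end_distances) == 0)
    stop("read_end_proximity: empty distance list")
  if (any(end_distances < 0))
    stop("read_end_proximity: distances must be >= 0")
  mean(end_distances)
}

filter_codes <- c("MIN_ALT_READS", "MIN_VAF", "GDNA_RATIO", "MAPQ",
                  "END_PROXIMITY", "BACKGROUND", "WES_MIN_VAF",
                  "WES_BACKGROUND", "WES_NORMAL_RATIO", "CHIP_GENE_REVIEW")

collapse_reasons <- function(fail_matrix) {
  apply(fail_matrix, 1, function(r)
    paste(colnames(fail_matrix)[r], collapse = ","))
}

# Vectorized rule evaluation over a variant observation data.frame.
# gdna_vaf must be aligned with obs rows (0 where no matched observation).
somatic_rule_matrix <- function(obs, gdna_vaf, compartment, thresholds) {
  min_vaf <- switch(compartment, cfDNA = thresholds$min_vaf_cfdna,
                    tissue = thresholds$min_vaf_tissue,
                    stop("compartment must be cfDNA or tissue"))
  vaf <- ifelse(obs$depth > 0, obs$alt_reads / obs$depth, 0)
  fails <- cbind(
    MIN_ALT_READS = obs$alt_reads < thresholds$min_alt_reads,
    MIN_VAF = vaf < min_vaf,
    GDNA_RATIO = !(vaf > thresholds$gdna_ratio * gdna_vaf),
    MAPQ = !(obs$mean_mapq_alt > thresholds$min_mapq),
    END_PROXIMITY = !(obs$mean_end_distance_alt > thresholds$min_end_distance))
  if (!is.null(thresholds$background_rate)) {
    # one-sided binomial test: mutant support must exceed what the site
    # error rate alone would plausibly produce
    p <- stats::pbinom(obs$alt_reads - 1L, obs$depth,
                       thresholds$background_rate, lower.tail = FALSE)
    fails <- cbind(fails, BACKGROUND = p > thresholds$background_alpha)
  }
  fails
}

#' Apply the targeted-panel somatic filters to one observation
#'
#' A candidate passes when it has at least `min_alt_reads` mutant reads,
#' meets the compartment VAF floor, has a VAF more than `gdna_ratio` times
#' the matched gDNA VAF (taken as 0 when the gDNA has no observation or no
#' mutant reads, in which case the decision is annotated `GDNA_MISSING`),
#' and clears the mapping-quality and read-end proximity gates.
#'
#' @param obs a one-row variant observation (data.frame or list with
#'   fields chrom, pos, ref, alt, depth, alt_reads, mean_mapq_alt,
#'   mean_end_distance_alt).
#' @param gdna_obs matched germline observation at the same locus, or
#'   `NULL` when the locus was not covered in gDNA.
#' @param compartment `"cfDNA"` or `"tissue"`.
#' @param thresholds a [somatic_thresholds()] list.
#' @return A `filter_decision`: list with `passed`, `reasons` (character
#'   vector of failed rule codes) and `notes`.
#' @export
passes_somatic_filters <- function(obs, gdna_obs = NULL,
                                   compartment = c("cfDNA", "tissue"),
                                   thresholds = somatic_thresholds()) {
  compartment <- match.arg(compartment)
  obs <- as.data.frame(obs)
  notes <- character()
  gdna_vaf <- 0
  if (!is.null(gdna_obs)) {
    gdna_obs <- as.data.frame(gdna_obs)
    if (!identical(unname(c(obs$chrom, obs$pos, obs$ref, obs$alt)),
                   unname(c(gdna_obs$chrom, gdna_obs$pos, gdna_obs$ref,
                            gdna_obs$alt))))
      stop("passes_somatic_filters: gDNA observation is for a different locus")
    if (gdna_obs$depth > 0) gdna_vaf <- gdna_obs$alt_reads / gdna_obs$depth
    else notes <- "GDNA_MISSING"
  } else notes <- "GDNA_MISSING"
  fails <- somatic_rule_matrix(obs, gdna_vaf, compartment, thresholds)
  reasons <- colnames(fails)[fails[1, ]]
  structure(list(passed = length(reasons) == 0, reasons = reasons,
                 notes = notes), class = "filter_decision")
}

#' Apply the whole-exome silent-mutation filters
#'
#' Silent calls from exome data are held to a stricter standard: VAF of at
#' least 10%, at least 50x the same-locus background error rate, at least
#' 10x the VAF in the matched normal, plus the shared mapping-quality and
#' read-end proximity gates.
#'
#' @param obs a one-row variant observation.
#' @param site_background_rate per-site background error rate in `[0, 1]`.
#' @param normal_obs matched normal observation at the same locus.
#' @param thresholds a [somatic_thresholds()] list (mapq/proximity gates).
#' @return A `filter_decision`.
#' @export
passes_wes_silent_filters <- function(obs, site_background_rate, normal_obs,
                                      thresholds = somatic_thresholds()) {
  obs <- as.data.frame(obs)
  normal_obs <- as.data.frame(normal_obs)
  if (site_background_rate < 0 || site_background_rate > 1)
    stop("site_background_rate must be in [0, 1]")
  if (!identical(unname(c(obs$chrom, obs$pos, obs$ref, obs$alt)),
                 unname(c(normal_obs$chrom, normal_obs$pos, normal_obs$ref,
                          normal_obs$alt))))
    stop("passes_wes_silent_filters: normal observation is for a different locus")
  vaf <- if (obs$depth > 0) obs$alt_reads / obs$depth else 0
  normal_vaf <- if (normal_obs$depth > 0)
    normal_obs$alt_reads / normal_obs$depth else 0
  fails <- c(
    WES_MIN_VAF = vaf < 0.10,
    WES_BACKGROUND = vaf < 50 * site_background_rate,
    WES_NORMAL_RATIO = vaf < 10 * normal_vaf,
    MAPQ = !(obs$mean_mapq_alt > thresholds$min_mapq),
    END_PROXIMITY = !(obs$mean_end_distance_alt > thresholds$min_end_distance))
  reasons <- names(fails)[fails]
  structure(list(passed = length(reasons) == 0, reasons = reasons,
                 notes = character()), class = "filter_decision")
}

#' @export
print.filter_decision <- function(x, ...) {
  cat(if (x$passed) "PASS" else paste("FAIL:",
                                      paste(x$reasons, collapse = ",")),
      if (length(x$notes)) paste0(" [", paste(x$notes, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Filter all candidate variants of one sample against its matched gDNA
#'
#' Applies [passes_somatic_filters()] to every candidate observation,
#' matching germline observations by (chrom, pos, ref, alt). Variants in
#' clonal hematopoiesis genes with any mutant read support in gDNA are
#' flagged `CHIP_GENE_REVIEW`; in advisory mode (the default) the flag is
#' informational, in strict mode such variants are excluded.
#'
#' @param sample_variants data.frame of candidate observations for one
#'   tumor sample (cfDNA or tissue).
#' @param gdna_variants data.frame of matched germline observations for
#'   the same patient.
#' @param compartment `"cfDNA"` or `"tissue"`.
#' @param thresholds a [somatic_thresholds()] list.
#' @param chip_genes genes subject to clonal hematopoiesis review.
#' @param strict_chip if `TRUE`, flagged CHIP-gene variants are excluded.
#' @return list with `kept` (passing observations) and `audit` (one row
#'   per input with per-rule outcomes, `passed`, `reasons`, `notes`).
#' @export
filter_sample <- function(sample_variants, gdna_variants,
                          compartment = c("cfDNA", "tissue"),
                          thresholds = somatic_thresholds(),
                          chip_genes = chip_gene_list(),
                          strict_chip = FALSE) {
  compartment <- match.arg(compartment)
  obs <- sample_variants
  if (nrow(obs) == 0) {
    return(list(kept = obs,
                audit = cbind(obs, data.frame(passed = logical(),
                                              reasons = character(),
                                              notes = character()))))
  }
  key <- variant_key(obs$chrom, obs$pos, obs$ref, obs$alt)
  gkey <- variant_key(gdna_variants$chrom, gdna_variants$pos,
                      gdna_variants$ref, gdna_variants$alt)
  m <- match(key, gkey)
  gdna_depth <- ifelse(is.na(m), 0L, gdna_variants$depth[m])
  gdna_alt <- ifelse(is.na(m), 0L, gdna_variants$alt_reads[m])
  gdna_vaf <- ifelse(gdna_depth > 0, gdna_alt / gdna_depth, 0)
  fails <- somatic_rule_matrix(obs, gdna_vaf, compartment, thresholds)
  chip_flag <- obs$gene %in% chip_genes & gdna_alt >= 1
  if (strict_chip) fails <- cbind(fails, CHIP_GENE_REVIEW = chip_flag)
  passed <- rowSums(fails) == 0
  audit <- cbind(obs[, intersect(DIALECT_COLS, names(obs))],
                 as.data.frame(fails),
                 data.frame(
                   chip_review = chip_flag,
                   passed = passed,
                   reasons = collapse_reasons(fails),
                   notes = ifelse(gdna_depth == 0, "GDNA_MISSING", ""),
                   stringsAsFactors = FALSE))
  rownames(audit) <- NULL
  list(kept = obs[passed, , drop = FALSE], audit = audit)
}

#' Filter every tumor sample in a cohort
#'
#' @param cohort a `ctdna_cohort` (or any list with `manifest` and
#'   `variants` in the package dialect).
#' @param thresholds a [somatic_thresholds()] list.
#' @param chip_genes,strict_chip see [filter_sample()].
#' @return list with `kept` and `audit` data.frames stacked over samples.
#' @export
filter_cohort <- function(cohort, thresholds = somatic_thresholds(),
                          chip_genes = chip_gene_list(),
                          strict_chip = FALSE) {
  man <- cohort$manifest
  kept_list <- list(); audit_list <- list()
  for (pid in unique(man$patient_id)) {
    pman <- man[man$patient_id == pid, ]
    gdna_id <- pman$sample_id[pman$compartment == "gDNA"]
    if (length(gdna_id) != 1)
      stop("patient ", pid, " must have exactly one gDNA sample")
    gdna <- cohort$variants[cohort$variants$sample_id == gdna_id, ]
    for (i in which(pman$compartment != "gDNA")) {
      sid <- pman$sample_id[i]
      sv <- cohort$variants[cohort$variants$sample_id == sid, ]
      res <- filter_sample(sv, gdna, pman$compartment[i], thresholds,
                           chip_genes, strict_chip)
      kept_list[[sid]] <- res$kept
      audit_list[[sid]] <- res$audit
    }
  }
  kept <- do.call(rbind, kept_list)
  audit <- do.call(rbind, audit_list)
  rownames(kept) <- rownames(audit) <- NULL
  list(kept = kept, audit = audit)
}
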