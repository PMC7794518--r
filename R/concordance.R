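# Mutation-level agreement between paired tissue and ctDNA samples and
# across serial same-compartment samples: shared/exclusive accounting,
# coverage-explained discordance flags, clonality-stratified contingency
# tests, and serial concordance fractions.

#' Partition two variant sets into shared and exclusive calls
#'
#' Variants are matched exactly on (chrom, pos, ref, alt).
#'
#' @param a,b data.frames of called variants from the same patient (or
#'   character vectors of [variant_key()] strings).
#' @return list with `shared`, `exclusive_a`, `exclusive_b` (key vectors)
#'   and `fraction_shared` = shared / union. A warning is raised when two
#'   non-empty sets share nothing, which in practice indicates a sample
#'   pairing problem.
#' @export
match_variants <- function(a, b) {
  keyify <- function(x) {
    if (is.character(x)) x
    else variant_key(x$chrom, x$pos, x$ref, x$alt)
  }
  ka <- unique(keyify(a)); kb <- unique(keyify(b))
  shared <- intersect(ka, kb)
  ex_a <- setdiff(ka, kb); ex_b <- setdiff(kb, ka)
  union_n <- length(shared) + length(ex_a) + length(ex_b)
  if (length(shared) == 0 && length(ka) > 0 && length(kb) > 0)
    warning("variant sets share no mutation; check sample pairing")
  list(shared = shared, exclusive_a = ex_a, exclusive_b = ex_b,
       fraction_shared = if (union_n > 0) length(shared) / union_n else NA_real_)
}

#' Could higher depth explain an exclusive call?
#'
#' An exclusive mutation is flagged coverage-explained when the paired
#' sample already shows at least three unique mutant-allele reads at the
#' locus, indicating that deeper sequencing would likely have called it
#' independently.
#'
#' @param paired_alt_reads mutant read count(s) at the locus in the paired
#'   sample; `NA` when no pileup data is available.
#' @param min_reads threshold (default 3).
#' @return Logical (NA propagates as unknown, not `FALSE`).
#' @export
coverage_explained <- function(paired_alt_reads, min_reads = 3) {
  ifelse(is.na(paired_alt_reads), NA, paired_alt_reads >= min_reads)
}

#' Is a paired sample deep enough to detect truncal mutations?
#'
#' Under a diploid heterozygous truncal model the expected VAF is `tf/2`,
#' so the expected mutant read count is `depth * tf / 2`; the paired
#' sample is considered sufficient when this meets the eight-read calling
#' minimum.
#'
#' @param paired_depth read depth at the locus (or gene median).
#' @param paired_tf tumor fraction of the paired sample.
#' @param min_alt_reads calling minimum (default 8).
#' @return Logical.
#' @export
depth_sufficiency <- function(paired_depth, paired_tf, min_alt_reads = 8) {
  paired_depth * paired_tf / 2 >= min_alt_reads
}

#' Serial sample concordance
#'
#' Fraction of unique mutations detected in every sample among those
#' detected in any sample, across two or more same-patient,
#' same-compartment samples. Invariant to sample ordering.
#'
#' @param call_sets list (length >= 2) of called variant sets, each a
#'   data.frame or a vector of variant keys.
#' @return Fraction in `[0, 1]` (`NA` when no mutation was called in any
#'   sample).
#' @export
serial_concordance <- function(call_sets) {
  if (length(call_sets) < 2)
    stop("serial_concordance: need >= 2 samples")
  keys <- lapply(call_sets, function(x) {
    if (is.character(x)) unique(x)
    else unique(variant_key(x$chrom, x$pos, x$ref, x$alt))
  })
  all_of <- Reduce(intersect, keys)
  any_of <- Reduce(union, keys)
  if (length(any_of) == 0) return(NA_real_)
  length(all_of) / length(any_of)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value using the point-probability definition (the
#' sum of the probabilities of all tables, with margins fixed, no more
#' likely than the observed one), and the sample odds ratio
#' `(a d)/(b c)` with the usual infinity conventions.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A `contingency_result`: list with `table`, `odds_ratio`,
#'   `p_two_sided`.
#' @export
fisher_exact_two_sided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("table must contain non-negative integers")
  if (sum(table) == 0) stop("all-zero table")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  p <- stats::fisher.test(table)$p.value
  structure(list(table = table, odds_ratio = or, p_two_sided = min(1, p)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Fisher exact two-sided p = %.4g, odds ratio = %.3g\n",
              x$p_two_sided, x$odds_ratio))
  invisible(x)
}

# Select the evaluation pair for one patient: highest tumor-fraction cfDNA
# sample and most recent tissue sample, among evaluable samples. Ties are
# broken by sample_id order.
select_pair <- function(tf_patient) {
  cf <- tf_patient[tf_patient$compartment == "cfDNA" & tf_patient$evaluable, ]
  ti <- tf_patient[tf_patient$compartment == "tissue" & tf_patient$evaluable, ]
  if (nrow(cf) == 0 || nrow(ti) == 0) return(NULL)
  cf <- cf[order(-cf$tumor_fraction, cf$sample_id), ][1, ]
  ti <- ti[order(-ti$timepoint_days, ti$sample_id), ][1, ]
  list(ctdna = cf, tissue = ti)
}

#' Cohort-wide tissue versus ctDNA concordance report
#'
#' For every patient with at least one evaluable cfDNA and one evaluable
#' tissue sample, evaluates the highest ctDNA-fraction sample against the
#' most recent tissue sample: shared/exclusive protein-altering mutation
#' accounting, coverage-explained flags for exclusive calls (>= 3 mutant
#' reads in the paired sample), a clonality-stratified 2x2 contingency
#' table with Fisher's exact test, and serial concordance per patient and
#' compartment.
#'
#' @param kept filtered observations (all samples).
#' @param tf_table output of [cohort_tumor_fractions()].
#' @param manifest cohort manifest.
#' @param all_variants full candidate observation table (used for paired
#'   read lookups at exclusive loci).
#' @param subclonal_fraction clonality threshold as a fraction of the
#'   tumor fraction (default 0.25).
#' @return A `concordance_report`: list with `pairs`, `variants`,
#'   `serial` data.frames, `contingency` (or `NULL` when the stratified
#'   table is degenerate), `totals`, and `reason` when empty.
#' @export
cohort_concordance_report <- function(kept, tf_table, manifest, all_variants,
                                      subclonal_fraction = 0.25) {
  pair_rows <- list(); var_rows <- list()
  for (pid in unique(tf_table$patient_id)) {
    pair <- select_pair(tf_table[tf_table$patient_id == pid, ])
    if (is.null(pair)) next
    get_calls <- function(sid)
      kept[kept$sample_id == sid & kept$effect == "protein_altering", ,
           drop = FALSE]
    cf_calls <- get_calls(pair$ctdna$sample_id)
    ti_calls <- get_calls(pair$tissue$sample_id)
    m <- withCallingHandlers(
      match_variants(cf_calls, ti_calls),
      warning = function(w) invokeRestart("muffleWarning"))
    all_keys <- c(m$shared, m$exclusive_a, m$exclusive_b)
    if (length(all_keys) == 0) next
    cf_key <- variant_key(cf_calls$chrom, cf_calls$pos, cf_calls$ref,
                          cf_calls$alt)
    ti_key <- variant_key(ti_calls$chrom, ti_calls$pos, ti_calls$ref,
                          ti_calls$alt)
    lookup_vaf <- function(keys, calls, key_index) {
      i <- match(keys, key_index)
      ifelse(is.na(i), NA_real_, calls$vaf[i])
    }
    vaf_cf <- lookup_vaf(all_keys, cf_calls, cf_key)
    vaf_ti <- lookup_vaf(all_keys, ti_calls, ti_key)
    # clonality from the compartment where the mutation was called,
    # preferring ctDNA; purity-normalized against that sample's TF
    clon <- rep(NA_character_, length(all_keys))
    ok_cf <- !is.na(vaf_cf) & pair$ctdna$tumor_fraction > 0
    if (any(ok_cf))
      clon[ok_cf] <- classify_clonality(vaf_cf[ok_cf],
                                        pair$ctdna$tumor_fraction,
                                        subclonal_fraction)
    ok_ti <- is.na(vaf_cf) & !is.na(vaf_ti) & pair$tissue$tumor_fraction > 0
    if (any(ok_ti))
      clon[ok_ti] <- classify_clonality(vaf_ti[ok_ti],
                                        pair$tissue$tumor_fraction,
                                        subclonal_fraction)
    # paired-sample mutant reads for exclusive calls
    paired_alt <- rep(NA_integer_, length(all_keys))
    pk <- all_variants[all_variants$sample_id %in%
                         c(pair$ctdna$sample_id, pair$tissue$sample_id), ]
    pk_key <- variant_key(pk$chrom, pk$pos, pk$ref, pk$alt)
    for (k in seq_along(all_keys)) {
      key <- all_keys[k]
      if (key %in% m$shared) next
      other <- if (key %in% m$exclusive_a) pair$tissue$sample_id
               else pair$ctdna$sample_id
      hit <- which(pk_key == key & pk$sample_id == other)
      if (length(hit)) paired_alt[k] <- pk$alt_reads[hit[1]]
    }
    shared_flag <- all_keys %in% m$shared
    var_rows[[pid]] <- data.frame(
      patient_id = pid, variant = all_keys, shared = shared_flag,
      detected_in = ifelse(shared_flag, "both",
                           ifelse(all_keys %in% m$exclusive_a, "ctDNA_only",
                                  "tissue_only")),
      vaf_ctdna = vaf_cf, vaf_tissue = vaf_ti, clonality = clon,
      paired_alt_reads = paired_alt,
      coverage_explained = ifelse(shared_flag, NA,
                                  coverage_explained(paired_alt)),
      stringsAsFactors = FALSE)
    pair_rows[[pid]] <- data.frame(
      patient_id = pid,
      ctdna_sample = pair$ctdna$sample_id,
      tissue_sample = pair$tissue$sample_id,
      n_shared = length(m$shared),
      n_ctdna_only = length(m$exclusive_a),
      n_tissue_only = length(m$exclusive_b),
      fraction_shared = m$fraction_shared,
      stringsAsFactors = FALSE)
  }

  # serial concordance per patient and compartment (all evaluable samples)
  serial_rows <- list()
  for (pid in unique(tf_table$patient_id)) {
    for (cmp in c("cfDNA", "tissue")) {
      sids <- tf_table$sample_id[tf_table$patient_id == pid &
                                   tf_table$compartment == cmp &
                                   tf_table$evaluable]
      if (length(sids) < 2) next
      sets <- lapply(sids, function(sid)
        kept[kept$sample_id == sid & kept$effect == "protein_altering", ])
      frac <- serial_concordance(sets)
      serial_rows[[paste(pid, cmp)]] <- data.frame(
        patient_id = pid, compartment = cmp, n_samples = length(sids),
        concordance = frac, stringsAsFactors = FALSE)
    }
  }
  serial <- if (length(serial_rows)) do.call(rbind, serial_rows)
            else data.frame(patient_id = character(),
                            compartment = character(),
                            n_samples = integer(), concordance = numeric())
  rownames(serial) <- NULL

  if (length(pair_rows) == 0) {
    rep <- list(pairs = NULL, variants = NULL, serial = serial,
                contingency = NULL, totals = NULL,
                reason = "no patient had an evaluable tissue-ctDNA pair")
    class(rep) <- "concordance_report"
    return(rep)
  }
  pairs <- do.call(rbind, pair_rows)
  variants <- do.call(rbind, var_rows)
  rownames(pairs) <- rownames(variants) <- NULL

  # clonality-stratified sharing table: rows subclonal/clonal,
  # columns shared/exclusive
  cl <- variants$clonality
  tab <- rbind(
    subclonal = c(shared = sum(variants$shared & cl == "subclonal",
                               na.rm = TRUE),
                  exclusive = sum(!variants$shared & cl == "subclonal",
                                  na.rm = TRUE)),
    clonal = c(shared = sum(variants$shared & cl == "clonal", na.rm = TRUE),
               exclusive = sum(!variants$shared & cl == "clonal",
                               na.rm = TRUE)))
  contingency <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
    fisher_exact_two_sided(tab) else NULL

  n_total <- nrow(variants)
  n_excl <- sum(!variants$shared)
  totals <- list(
    n_pairs = nrow(pairs),
    n_mutations = n_total,
    n_shared = sum(variants$shared),
    fraction_shared = sum(variants$shared) / n_total,
    n_exclusive = n_excl,
    n_coverage_explained = sum(variants$coverage_explained, na.rm = TRUE),
    fraction_exclusive_coverage_explained =
      if (n_excl > 0) sum(variants$coverage_explained, na.rm = TRUE) / n_excl
      else NA_real_)
  rep <- list(pairs = pairs, variants = variants, serial = serial,
              contingency = contingency, totals = totals, reason = NULL)
  class(rep) <- "concordance_report"
  rep
}

#' @export
print.concordance_report <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat("concordance_report: empty (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "concordance_report: %d pairs, %d/%d mutations shared (%.1f%%)\n",
    x$totals$n_pairs, x$totals$n_shared, x$totals$n_mutations,
    100 * x$totals$fraction_shared))
  if (!is.null(x$contingency))
    cat(sprintf("  clonal/subclonal sharing Fisher p = %.4g\n",
                x$contingency$p_two_sided))
  if (nrow(x$serial))
    for (cmp in unique(x$serial$compartment))
      cat(sprintf("  median serial %s concordance: %.2f (%d patients)\n",
                  cmp, stats::median(
                    x$serial$concordance[x$serial$compartment == cmp],
                    na.rm = TRUE),
                  sum(x$serial$compartment == cmp)))
  invisible(x)
}
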