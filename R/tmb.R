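# Depth-aware tumor mutational burden extrapolation from a targeted panel.
# Each detected mutation m contributes 1/B_m, where B_m is the number of
# panel sites deep enough to have detected a mutation at the same VAF
# (at least 8 mutant reads expected). Summing the reciprocals corrects
# for the reduced detectability of low-VAF mutations under non-uniform
# coverage; the per-site sum is scaled to mutations per megabase.

#' Depth required to detect a mutation at a given VAF
#'
#' The minimum sequencing depth at which a mutation with allele fraction
#' `vaf` would be expected to yield the eight mutant reads required by the
#' somatic calling filters: `ceiling(8 / vaf)`.
#'
#' @param vaf observed allele fraction(s) in `(0, 1]`.
#' @param min_alt_reads mutant-read requirement (default 8).
#' @return Integer depth(s).
#' @export
required_depth <- function(vaf, min_alt_reads = 8) {
  if (any(vaf <= 0)) stop("required_depth: vaf must be > 0")
  if (any(vaf > 1)) stop("required_depth: vaf must be <= 1")
  as.integer(ceiling(min_alt_reads / vaf))
}

#' Build/validate a depth profile
#'
#' @param histogram data.frame with columns `depth_bin` (reads) and
#'   `n_sites` (count of panel sites at that depth).
#' @return A `depth_profile` data.frame with a `footprint` attribute
#'   (total sites).
#' @export
depth_profile <- function(histogram) {
  stopifnot(all(c("depth_bin", "n_sites") %in% names(histogram)))
  if (nrow(histogram) == 0) stop("depth_profile: empty histogram")
  if (any(histogram$depth_bin < 0) || any(histogram$n_sites < 0))
    stop("depth_profile: bins must be non-negative")
  out <- histogram[, c("depth_bin", "n_sites")]
  attr(out, "footprint") <- sum(out$n_sites)
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' Number of panel sites able to detect a mutation at a given VAF
#'
#' `B_m`: the count of sites whose depth is at least
#' [required_depth()]`(vaf)`. Monotone non-increasing as `vaf` decreases.
#'
#' @param profile a [depth_profile()] (or raw histogram data.frame).
#' @param vaf allele fraction in `(0, 1]`.
#' @param min_alt_reads mutant-read requirement.
#' @return Number of sites (0 when no bin is deep enough).
#' @export
detectability_count <- function(profile, vaf, min_alt_reads = 8) {
  profile <- depth_profile(profile)
  need <- required_depth(vaf, min_alt_reads)
  vapply(need, function(d)
    sum(profile$n_sites[profile$depth_bin >= d]), numeric(1))
}

#' Extrapolate tumor mutational burden from panel mutations
#'
#' `TMB = 1e6 * sum_m 1/B_m` over the retained mutations (mutations per
#' megabase). Mutations whose VAF is undetectable at every covered site
#' (`B_m = 0`) cannot be extrapolated and are excluded with a warning.
#'
#' @param mutations data.frame of kept somatic variant observations with
#'   `chrom, pos, ref, alt, effect, depth, alt_reads`.
#' @param profile a [depth_profile()] for the same sample.
#' @param include_silent count silent mutations too (off by default,
#'   matching the protein-altering scope of targeted-panel calling).
#' @param min_alt_reads mutant-read requirement behind `B_m`.
#' @return A `tmb_estimate`: list with `tmb_per_mb`, `contributions`
#'   (variant key, vaf, required_depth, B, weight = 1/B) and `excluded`.
#' @export
tmb_estimate <- function(mutations, profile, include_silent = FALSE,
                         min_alt_reads = 8) {
  profile <- depth_profile(profile)
  if (!include_silent && nrow(mutations))
    mutations <- mutations[mutations$effect == "protein_altering", ,
                           drop = FALSE]
  if (nrow(mutations) == 0) {
    est <- list(tmb_per_mb = 0,
                contributions = data.frame(variant = character(),
                                           vaf = numeric(),
                                           required_depth = integer(),
                                           B = numeric(), weight = numeric()),
                excluded = character())
    class(est) <- "tmb_estimate"
    return(est)
  }
  vaf <- mutations$alt_reads / mutations$depth
  need <- required_depth(vaf, min_alt_reads)
  B <- detectability_count(profile, vaf, min_alt_reads)
  key <- variant_key(mutations$chrom, mutations$pos, mutations$ref,
                     mutations$alt)
  contrib <- data.frame(variant = key, vaf = vaf, required_depth = need,
                        B = B, weight = ifelse(B > 0, 1 / B, NA_real_),
                        stringsAsFactors = FALSE)
  excluded <- contrib$variant[contrib$B == 0]
  if (length(excluded))
    warning(length(excluded),
            " mutation(s) undetectable at any covered site excluded from TMB")
  kept <- contrib[contrib$B > 0, , drop = FALSE]
  est <- list(tmb_per_mb = 1e6 * sum(kept$weight),
              contributions = kept, excluded = excluded)
  class(est) <- "tmb_estimate"
  est
}

#' @export
print.tmb_estimate <- function(x, ...) {
  cat(sprintf("TMB %.2f mutations/Mb from %d mutation(s)%s\n",
              x$tmb_per_mb, nrow(x$contributions),
              if (length(x$excluded))
                paste0(" (", length(x$excluded), " excluded)") else ""))
  invisible(x)
}

#' TMB for every tumor sample of a cohort
#'
#' @param kept filtered observations (all samples).
#' @param depth long depth table (`sample_id`, `depth_bin`, `n_sites`).
#' @param manifest cohort manifest.
#' @param include_silent see [tmb_estimate()].
#' @return data.frame: sample_id, tmb_per_mb, n_mutations, n_excluded.
#' @export
cohort_tmb <- function(kept, depth, manifest, include_silent = FALSE) {
  tumor <- manifest[manifest$compartment != "gDNA", ]
  rows <- lapply(tumor$sample_id, function(sid) {
    est <- tmb_estimate(kept[kept$sample_id == sid, , drop = FALSE],
                        depth[depth$sample_id == sid,
                              c("depth_bin", "n_sites")],
                        include_silent)
    data.frame(sample_id = sid, tmb_per_mb = est$tmb_per_mb,
               n_mutations = nrow(est$contributions),
               n_excluded = length(est$excluded),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
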