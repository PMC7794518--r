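# Internal helpers shared across modules.

AUTOSOMES <- paste0("chr", 1:22)

#' Variant identity key
#'
#' Variants are matched exactly on (chrom, pos, ref, alt); no fuzzy indel
#' matching is attempted.
#'
#' @param chrom,pos,ref,alt vectors describing one variant per element.
#' @return Character vector of `chrom:pos:ref>alt` keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  if (length(chrom) == 0) return(character(0))
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

is_autosome <- function(chrom) chrom %in% AUTOSOMES

#' Derive a per-patient random seed from a global seed
#'
#' One global integer seed drives cohort generation; per-patient streams are
#' split off deterministically so patients can be regenerated in isolation.
#' The multiplier is a large prime; results are kept below 2^31.
#'
#' @param seed global integer seed.
#' @param index 1-based stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index), index >= 1)
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647L)
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = colClasses, check.names = FALSE)
}
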