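# In-code fixtures shared across test files.

# Minimal one-row variant observation in the package dialect.
make_obs <- function(chrom = "chr5", pos = 100L, ref = "A", alt = "T",
                     gene = "TP53", effect = "protein_altering",
                     depth = 1000L, alt_reads = 100L, mapq = 60,
                     end_distance = 40, region_flag = "autosome",
                     sample_id = "S1") {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, gene = gene, effect = effect, depth = depth,
             alt_reads = alt_reads, mean_mapq_alt = mapq,
             mean_end_distance_alt = end_distance,
             region_flag = region_flag, vaf = alt_reads / depth,
             stringsAsFactors = FALSE)
}

# A small but fully featured cohort used by several test files.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(sim_config(n_patients = 6,
                                           panel_footprint = 20000,
                                           seed = 42))
    cache
  }
})
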