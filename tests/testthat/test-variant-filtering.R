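# Somatic calling filters: rule-by-rule behavior, audit bookkeeping,
# boundary strictness, idempotence and monotonicity.

test_that("read_end_proximity is the mean supporting-read distance", {
  expect_equal(read_end_proximity(c(30, 25, 35)), 30)
  expect_equal(read_end_proximity(c(10, 10, 10)), 10)
  # a score of exactly 25 fails the strict > 25 gate
  obs <- make_obs(end_distance = read_end_proximity(25))
  dec <- passes_somatic_filters(obs, compartment = "cfDNA")
  expect_false(dec$passed)
  expect_true("END_PROXIMITY" %in% dec$reasons)
  expect_error(read_end_proximity(numeric()), "empty")
})

test_that("targeted somatic filters apply the calling thresholds", {
  gdna0 <- make_obs(depth = 300L, alt_reads = 0L)
  # 1% VAF cfDNA call with clean support passes
  dec <- passes_somatic_filters(make_obs(depth = 1000L, alt_reads = 10L),
                                gdna0, "cfDNA")
  expect_true(dec$passed)
  expect_length(dec$reasons, 0)
  # seven mutant reads fail the eight-read minimum
  dec <- passes_somatic_filters(make_obs(depth = 100L, alt_reads = 7L),
                                gdna0, "cfDNA")
  expect_false(dec$passed)
  expect_true("MIN_ALT_READS" %in% dec$reasons)
  # tissue at 6% VAF with gDNA at 2.5%: fails both floor and gDNA ratio
  dec <- passes_somatic_filters(
    make_obs(depth = 1000L, alt_reads = 60L),
    make_obs(depth = 1000L, alt_reads = 25L, sample_id = "G"), "tissue")
  expect_false(dec$passed)
  expect_setequal(dec$reasons, c("MIN_VAF", "GDNA_RATIO"))
  # mapping quality of exactly 30 fails the strict gate
  dec <- passes_somatic_filters(make_obs(mapq = 30), gdna0, "cfDNA")
  expect_true("MAPQ" %in% dec$reasons)
  # absent or uncovered gDNA: ratio passes but decision carries a note
  dec <- passes_somatic_filters(make_obs(), NULL, "cfDNA")
  expect_true(dec$passed)
  expect_equal(dec$notes, "GDNA_MISSING")
  expect_error(
    passes_somatic_filters(make_obs(), make_obs(pos = 999L), "cfDNA"),
    "different locus")
})

test_that("germline heterozygous variants are removed by the gDNA ratio", {
  dec <- passes_somatic_filters(
    make_obs(depth = 1000L, alt_reads = 500L),
    make_obs(depth = 300L, alt_reads = 150L, sample_id = "G"), "cfDNA")
  expect_false(dec$passed)
  expect_equal(dec$reasons, "GDNA_RATIO")
})

test_that("WES silent-mutation rules are stricter", {
  normal0 <- make_obs(depth = 200L, alt_reads = 1L)
  ok <- make_obs(depth = 1000L, alt_reads = 120L, mapq = 50)
  dec <- passes_wes_silent_filters(ok, 0.001, normal0)
  expect_true(dec$passed)   # 12% VAF, 120x background, 24x normal
  dec <- passes_wes_silent_filters(make_obs(depth = 1000L, alt_reads = 90L),
                                   0.001, normal0)
  expect_false(dec$passed)
  expect_true("WES_MIN_VAF" %in% dec$reasons)
  dec <- passes_wes_silent_filters(
    make_obs(depth = 1000L, alt_reads = 150L), 0.001,
    make_obs(depth = 1000L, alt_reads = 20L, sample_id = "N"))
  expect_false(dec$passed)
  expect_equal(dec$reasons, "WES_NORMAL_RATIO")
  expect_error(passes_wes_silent_filters(ok, 1.5, normal0),
               "site_background_rate")
})

test_that("filter_sample audits every input and flags CHIP-gene variants", {
  obs <- rbind(make_obs(pos = 1L, alt_reads = 100L),
               make_obs(pos = 2L, alt_reads = 7L, depth = 100L),
               make_obs(pos = 3L, gene = "DNMT3A", alt_reads = 40L,
                        depth = 1000L))
  gdna <- rbind(make_obs(pos = 1L, depth = 300L, alt_reads = 0L,
                         sample_id = "G"),
                make_obs(pos = 3L, gene = "DNMT3A", depth = 300L,
                         alt_reads = 2L, sample_id = "G"))
  res <- filter_sample(obs, gdna, "cfDNA")
  expect_equal(nrow(res$audit), 3)
  expect_equal(nrow(res$kept), 2)        # advisory mode keeps the CHIP call
  expect_true(res$audit$chip_review[3])
  strict <- filter_sample(obs, gdna, "cfDNA", strict_chip = TRUE)
  expect_equal(nrow(strict$kept), 1)
  expect_true(grepl("CHIP_GENE_REVIEW", strict$audit$reasons[3]))
})

test_that("filtering is idempotent and kept VAFs respect the floor", {
  cohort <- small_cohort()
  res <- filter_cohort(cohort)
  gdna_ids <- cohort$manifest$sample_id[cohort$manifest$compartment == "gDNA"]
  for (sid in unique(res$kept$sample_id)) {
    cmp <- cohort$manifest$compartment[cohort$manifest$sample_id == sid]
    pid <- cohort$manifest$patient_id[cohort$manifest$sample_id == sid]
    gdna <- cohort$variants[cohort$variants$sample_id ==
                              intersect(gdna_ids, paste0(pid, "-gDNA")), ]
    kept <- res$kept[res$kept$sample_id == sid, ]
    again <- filter_sample(kept, gdna, cmp)
    expect_equal(again$kept, kept)
    floor <- if (cmp == "cfDNA") 0.01 else 0.08
    expect_true(all(kept$vaf >= floor))
  }
})

test_that("raising any threshold never enlarges the kept set", {
  cohort <- small_cohort()
  base <- filter_cohort(cohort)$kept
  base_keys <- paste(base$sample_id,
                     variant_key(base$chrom, base$pos, base$ref, base$alt))
  stricter <- list(
    somatic_thresholds(min_alt_reads = 12),
    somatic_thresholds(min_vaf_cfdna = 0.05, min_vaf_tissue = 0.20),
    somatic_thresholds(gdna_ratio = 6),
    somatic_thresholds(min_mapq = 45),
    somatic_thresholds(min_end_distance = 40))
  for (th in stricter) {
    kept <- filter_cohort(cohort, th)$kept
    keys <- paste(kept$sample_id,
                  variant_key(kept$chrom, kept$pos, kept$ref, kept$alt))
    expect_true(all(keys %in% base_keys))
  }
})

test_that("the optional background-rate test removes error-level support", {
  th <- somatic_thresholds(background_rate = 0.001)
  # 9 mutant reads of 6000 is compatible with a 0.1% error rate
  dec <- passes_somatic_filters(make_obs(depth = 6000L, alt_reads = 9L),
                                NULL, "cfDNA", th)
  expect_true("BACKGROUND" %in% dec$reasons)
  dec <- passes_somatic_filters(make_obs(depth = 1000L, alt_reads = 100L),
                                NULL, "cfDNA", th)
  expect_true(dec$passed)
})

test_that("FFPE artifacts are caught by the read-end proximity gate", {
  cohort <- small_cohort()
  classes <- truth_class_lookup(cohort)
  res <- filter_cohort(cohort)
  audit <- res$audit
  key <- variant_key(audit$chrom, audit$pos, audit$ref, audit$alt)
  art_keys <- classes$variant_id[classes$class == "ffpe_artifact"]
  tissue_ids <- cohort$manifest$sample_id[
    cohort$manifest$compartment == "tissue"]
  art_rows <- audit[key %in% art_keys & audit$sample_id %in% tissue_ids &
                      audit$alt_reads > 0 &
                      audit$mean_end_distance_alt <= 25, ]
  expect_gt(nrow(art_rows), 0)
  expect_true(all(!art_rows$passed))
})
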