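# Generator: expected VAFs, read-support sampling, truth structure,
# confounder labels, determinism and on-disk round trip.

test_that("expected_vaf follows the purity/copy mixture model", {
  expect_equal(expected_vaf(1, 1, 2, 1), 0.5)
  expect_equal(expected_vaf(1, 0.5, 2, 1), 0.25)
  # truncal LOH: inverting through the tumor-fraction transform recovers tf
  v <- expected_vaf(1, 0.5, 1, 1)
  expect_equal(v, 0.5 / 1.5)
  expect_equal(tumor_fraction_from_vaf(v), 0.5)
  expect_equal(expected_vaf(1, 0, 2, 1), 0)
  expect_error(expected_vaf(1, -0.1, 2, 1), "negative")
  expect_error(expected_vaf(1, 0.5, 1, 2), "mutant_copies")
})

test_that("simulate_read_support is binomial with the right moments", {
  expect_equal(simulate_read_support(0, 1000)$alt_reads, 0)
  expect_equal(simulate_read_support(1, 50)$alt_reads, 50)
  set.seed(11)
  reps <- simulate_read_support(rep(0.1, 10000), 1000)
  expect_true(all(reps$alt_reads <= reps$depth))
  se <- sqrt(1000 * 0.1 * 0.9) / sqrt(10000)
  expect_lt(abs(mean(reps$alt_reads) - 100), 3 * sqrt(90))
  expect_lt(abs(mean(reps$alt_reads) - 100), 4 * se)
})

test_that("clone tree truth respects CCF ordering and truncal fixation", {
  cohort <- small_cohort()
  for (t in cohort$truth) {
    ccf <- as.matrix(t$ccf[, -1])
    tumor_cols <- names(t$tumor_fraction)[t$tumor_fraction > 0]
    expect_true(all(ccf[1, tumor_cols] == 1))
    for (k in which(!is.na(t$clones$parent_id)))
      expect_true(all(ccf[k, ] <= ccf[t$clones$parent_id[k], ] + 1e-12))
    # every mutation belongs to exactly one clone or confounder class
    som <- t$mutations[t$mutations$class == "somatic", ]
    expect_true(all(som$clone_id %in% t$clones$clone_id))
  }
})

test_that("confounder truth labels behave as constructed", {
  config <- sim_config(n_patients = 1, chip_count = 3,
                       chip_vaf_range = c(0.05, 0.10),
                       panel_footprint = 5000, seed = 3)
  pat <- simulate_patient(config, "P1", derive_seed(3, 1))
  truth <- pat$truth
  chip <- truth$mutations[truth$mutations$class == "chip", ]
  expect_equal(nrow(chip), 3)
  gdna_id <- pat$manifest$sample_id[pat$manifest$compartment == "gDNA"]
  gdna_obs <- pat$variants[pat$variants$sample_id == gdna_id, ]
  gk <- variant_key(gdna_obs$chrom, gdna_obs$pos, gdna_obs$ref, gdna_obs$alt)
  expect_true(all(gdna_obs$alt_reads[match(chip$mutation_id, gk)] > 0))
  # chip truth: present in gDNA and cfDNA, absent from tissue
  tv <- truth$true_vaf
  cf_col <- grep("cfDNA", names(tv), value = TRUE)[1]
  ti_col <- grep("tissue", names(tv), value = TRUE)[1]
  chip_rows <- tv$variant_id %in% chip$mutation_id
  expect_true(all(tv[chip_rows, cf_col] > 0))
  expect_true(all(tv[chip_rows, ti_col] == 0))
  # germline truth VAF is 0.5 in every compartment
  germ_rows <- tv$variant_id %in%
    truth$mutations$mutation_id[truth$mutations$class == "germline"]
  for (col in setdiff(names(tv), "variant_id"))
    expect_true(all(tv[germ_rows, col] == 0.5))
})

test_that("germline variants show balanced gDNA allele fractions", {
  cohort <- small_cohort()
  classes <- truth_class_lookup(cohort)
  gdna_ids <- cohort$manifest$sample_id[cohort$manifest$compartment == "gDNA"]
  obs <- cohort$variants[cohort$variants$sample_id %in% gdna_ids, ]
  key <- variant_key(obs$chrom, obs$pos, obs$ref, obs$alt)
  germ <- obs[key %in% classes$variant_id[classes$class == "germline"] &
                obs$depth >= 200, ]
  expect_gt(nrow(germ), 50)
  expect_gte(mean(germ$vaf >= 0.3 & germ$vaf <= 0.7), 0.99)
})

test_that("without subclones, serial samples share all somatic truth", {
  config <- sim_config(n_patients = 1, n_subclonal = 0, drift_prob = 1,
                       panel_footprint = 5000, seed = 5)
  truth <- simulate_patient(config, "P1", 99L)$truth
  tv <- truth$true_vaf
  som <- tv$variant_id %in%
    truth$mutations$mutation_id[truth$mutations$class == "somatic"]
  tumor_cols <- names(truth$tumor_fraction)[truth$tumor_fraction > 0]
  for (col in tumor_cols) expect_true(all(tv[som, col] > 0))
})

test_that("mean resimulated VAF matches truth within binomial error", {
  config <- sim_config(n_patients = 1, panel_footprint = 5000, seed = 8)
  pat <- simulate_patient(config, "P1", 17L)
  tv <- pat$truth$true_vaf
  sample_ids <- pat$manifest$sample_id[pat$manifest$compartment == "cfDNA"]
  sid <- sample_ids[1]
  set.seed(21)
  picked <- which(tv[[sid]] > 0)[1:5]
  for (i in picked) {
    v <- tv[[sid]][i]
    depth <- 1000L
    sims <- simulate_read_support(rep(v, 1000), depth)
    se <- sqrt(v * (1 - v) / depth) / sqrt(1000)
    expect_lt(abs(mean(sims$alt_reads / sims$depth) - v), 3 * se + 1e-12)
  }
})

test_that("identical config and seed give byte-identical cohort files", {
  config <- sim_config(n_patients = 2, panel_footprint = 5000, seed = 31)
  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  write_cohort(simulate_cohort(config), d1)
  write_cohort(simulate_cohort(config), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) > 5)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cohorts round-trip losslessly through the TSV/JSON writers", {
  cohort <- simulate_cohort(sim_config(n_patients = 2,
                                       panel_footprint = 5000, seed = 13))
  dir <- file.path(tempdir(), "roundtrip")
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(back$manifest, cohort$manifest)
  cols <- c("sample_id", "chrom", "pos", "ref", "alt", "gene", "effect",
            "depth", "alt_reads", "mean_mapq_alt", "mean_end_distance_alt",
            "region_flag", "vaf")
  expect_equal(back$variants[, cols], cohort$variants[, cols])
  expect_equal(back$depth[, c("depth_bin", "n_sites", "sample_id")],
               cohort$depth[, c("depth_bin", "n_sites", "sample_id")])
  for (pid in names(cohort$truth)) {
    expect_equal(back$truth[[pid]]$tumor_fraction,
                 cohort$truth[[pid]]$tumor_fraction)
    expect_equal(back$truth[[pid]]$mutations, cohort$truth[[pid]]$mutations)
  }
  unlink(dir, recursive = TRUE)
})

test_that("samples with no variants still write and read valid files", {
  config <- sim_config(n_patients = 1, n_truncal = 0, n_subclonal = 0,
                       germline_het_count = 0, chip_count = 0,
                       ffpe_noise_rate = 0, panel_footprint = 5000,
                       seed = 2)
  cohort <- simulate_cohort(config)
  expect_equal(nrow(cohort$variants), 0)
  dir <- file.path(tempdir(), "empty_cohort")
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$variants), 0)
  expect_equal(back$manifest, cohort$manifest)
  unlink(dir, recursive = TRUE)
})

test_that("invalid configurations are rejected with clear messages", {
  expect_error(sim_config(drift_prob = 1.5), "drift_prob")
  expect_error(sim_config(panel_footprint = 0), "panel_footprint")
  expect_error(sim_config(tf_range = list(cfDNA = c(0.5, 0.1),
                                          tissue = c(0.1, 0.9))),
               "tf_range")
  expect_error(sim_config(depth_mean = c(cfDNA = -1, tissue = 370,
                                         gDNA = 300)), "depth")
})
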