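# Tissue/ctDNA and serial concordance: set partitioning, coverage
# explanations, Fisher tests, pairing rules.

test_that("match_variants partitions the union of two call sets", {
  m <- match_variants(c("A", "B", "C"), c("B", "C", "D"))
  expect_setequal(m$shared, c("B", "C"))
  expect_equal(m$exclusive_a, "A")
  expect_equal(m$exclusive_b, "D")
  expect_equal(m$fraction_shared, 0.5)
  expect_equal(match_variants(c("A", "B"), c("A", "B"))$fraction_shared, 1)
  expect_warning(m <- match_variants("A", "B"), "no mutation")
  expect_equal(m$fraction_shared, 0)
  # partition conservation
  expect_equal(length(m$shared) + length(m$exclusive_a) +
                 length(m$exclusive_b), 2)
})

test_that("coverage_explained needs three mutant reads in the pair", {
  expect_true(coverage_explained(3))
  expect_false(coverage_explained(2))
  expect_false(coverage_explained(0))
  expect_true(is.na(coverage_explained(NA)))
})

test_that("depth sufficiency reflects expected truncal read support", {
  expect_true(depth_sufficiency(1000, 0.2))    # expect 100 reads
  expect_false(depth_sufficiency(100, 0.05))   # expect 2.5 reads
  expect_false(depth_sufficiency(1000, 0))
})

test_that("serial concordance is order-invariant and bounded by pairs", {
  expect_equal(serial_concordance(list(c("A", "B"), c("A", "B"),
                                       c("A", "B"))), 1)
  expect_equal(serial_concordance(list(c("A", "B"), "A")), 0.5)
  expect_error(serial_concordance(list("A")), ">= 2")
  set.seed(4)
  pool <- replicate(20, paste0("v", sample(50, sample(5:20, 1))),
                    simplify = FALSE)
  for (i in 1:10) {
    sets <- pool[sample(20, 3)]
    frac <- serial_concordance(sets)
    expect_equal(frac, serial_concordance(rev(sets)))
    pairwise <- c(match_variants(sets[[1]], sets[[2]])$fraction_shared,
                  match_variants(sets[[1]], sets[[3]])$fraction_shared,
                  match_variants(sets[[2]], sets[[3]])$fraction_shared)
    expect_lte(frac, min(pairwise) + 1e-12)
  }
})

test_that("Fisher test matches the enumeration oracle and is symmetric", {
  expect_equal(fisher_exact_two_sided(matrix(c(1, 1, 1, 1), 2))$p_two_sided,
               1)
  set.seed(9)
  for (i in 1:25) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_two_sided(tab)$p_two_sided
    expect_equal(p, fisher_enum_p(tab), tolerance = 1e-10)
    expect_equal(p, fisher_exact_two_sided(t(tab))$p_two_sided,
                 tolerance = 1e-12)
    expect_equal(p, fisher_exact_two_sided(tab[2:1, 2:1])$p_two_sided,
                 tolerance = 1e-12)
  }
  expect_equal(fisher_exact_two_sided(matrix(c(10, 0, 0, 10), 2))$odds_ratio,
               Inf)
  expect_error(fisher_exact_two_sided(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher_exact_two_sided(matrix(c(-1, 1, 1, 1), 2)),
               "non-negative")
})

test_that("pairing picks the highest-TF cfDNA and latest tissue sample", {
  cohort <- small_cohort()
  kept <- filter_cohort(cohort)$kept
  tf <- cohort_tumor_fractions(kept, cohort$manifest)
  rep <- cohort_concordance_report(kept, tf, cohort$manifest,
                                   cohort$variants)
  expect_null(rep$reason)
  for (i in seq_len(nrow(rep$pairs))) {
    pid <- rep$pairs$patient_id[i]
    cf <- tf[tf$patient_id == pid & tf$compartment == "cfDNA" &
               tf$evaluable, ]
    expect_equal(rep$pairs$ctdna_sample[i],
                 cf$sample_id[which.max(cf$tumor_fraction)])
    ti <- tf[tf$patient_id == pid & tf$compartment == "tissue" &
               tf$evaluable, ]
    expect_equal(rep$pairs$tissue_sample[i],
                 ti$sample_id[which.max(ti$timepoint_days)])
  }
  # per-pair accounting sums to the variant table
  expect_equal(sum(rep$pairs$n_shared + rep$pairs$n_ctdna_only +
                     rep$pairs$n_tissue_only), nrow(rep$variants))
  expect_equal(rep$totals$fraction_shared,
               sum(rep$variants$shared) / nrow(rep$variants))
})

test_that("compartment-private subclones depress subclonal sharing", {
  config <- sim_config(n_patients = 25, n_truncal = 4, n_subclonal = 6,
                       subclone_private_prob = 0.6, drift_prob = 0,
                       serial_timepoints = 1,
                       tf_range = list(cfDNA = c(0.4, 0.6),
                                       tissue = c(0.5, 0.9)),
                       ffpe_noise_rate = 0, panel_footprint = 2000,
                       seed = 77)
  cohort <- simulate_cohort(config)
  kept <- filter_cohort(cohort)$kept
  tf <- cohort_tumor_fractions(kept, cohort$manifest)
  rep <- cohort_concordance_report(kept, tf, cohort$manifest,
                                   cohort$variants)
  v <- rep$variants[!is.na(rep$variants$clonality), ]
  share_rate <- tapply(v$shared, v$clonality, mean)
  expect_gt(share_rate[["clonal"]], share_rate[["subclonal"]])
})

test_that("an empty cohort yields an explained empty report", {
  manifest <- data.frame(patient_id = "P1", sample_id = "P1-gDNA",
                         compartment = "gDNA", assay = "targeted-panel",
                         timepoint_days = 0,
                         treatment_context = "baseline")
  tf <- data.frame(sample_id = character(), patient_id = character(),
                   compartment = character(), timepoint_days = numeric(),
                   tumor_fraction = numeric(), adjusted_vaf = numeric(),
                   raw_max_vaf = numeric(), source_variant = character(),
                   detected = logical(), evaluable = logical())
  rep <- cohort_concordance_report(make_obs()[0, ], tf, manifest,
                                   make_obs()[0, ])
  expect_match(rep$reason, "no patient")
})
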