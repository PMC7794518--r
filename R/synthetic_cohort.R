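# Synthetic cohort generator: paired cfDNA / tissue / germline samples with
# known ground truth, emulating targeted-panel sequencing of a metastatic
# urothelial carcinoma cohort. Every downstream stage (filtering, tumor
# fraction, TMB, copy number, concordance) is testable against the truth
# labels this module records.

#' Simulation configuration
#'
#' Builds and validates the configuration driving [simulate_cohort()].
#' Defaults describe the study conditions the generator emulates: deep
#' targeted sequencing of cfDNA (about 1040x unique depth) with shallower
#' archival tissue (about 370x) and matched leukocyte gDNA, truncal and
#' subclonal somatic mutations, germline heterozygous variants, clonal
#' hematopoiesis (CHIP) variants shared between gDNA and cfDNA, FFPE
#' artifacts restricted to tissue, amplified oncogenes, and serial samples
#' whose subclones can drift out between timepoints.
#'
#' @param n_patients number of patients to simulate.
#' @param tf_range named list with elements `cfDNA` and `tissue`, each a
#'   length-2 vector giving the uniform sampling interval for the true
#'   tumor fraction of that compartment.
#' @param depth_mean named numeric vector of mean unique read depth per
#'   compartment (`cfDNA`, `tissue`, `gDNA`).
#' @param depth_dispersion negative-binomial size parameter for per-site
#'   depth around the compartment mean; smaller values give more
#'   non-uniform coverage.
#' @param panel_footprint number of targeted bases (sites) on the panel.
#' @param n_truncal,n_subclonal somatic mutations assigned to the truncal
#'   clone and to subclones, per patient.
#' @param germline_het_count germline heterozygous variants per patient.
#' @param chip_count clonal hematopoiesis variants per patient, placed in
#'   [chip_gene_list()] genes with correlated gDNA/cfDNA allele fractions.
#' @param chip_vaf_range uniform sampling interval for CHIP gDNA VAF.
#' @param ffpe_noise_rate Poisson mean of FFPE artifact variants injected
#'   per tissue sample (low VAF, short read-end distances).
#' @param serial_timepoints number of serial timepoints per compartment.
#' @param drift_prob probability that a subclone is absent from later
#'   timepoints of the compartments in `drift_compartments`.
#' @param drift_compartments compartments subject to clonal drift; the
#'   default restricts drift to tissue, reflecting the temporal stability
#'   of ctDNA relative to serial primary-site tissue.
#' @param subclone_private_prob probability that a subclone is restricted
#'   to a single tumor compartment (cfDNA or tissue, chosen at random).
#' @param silent_fraction fraction of somatic mutations that are silent.
#' @param amplified_genes data.frame with columns `gene` and `copy_number`
#'   giving focally amplified oncogenes (tumor copies).
#' @param cn_noise_sd standard deviation (log2 scale) of per-gene coverage
#'   noise used when emitting normalized gene coverages.
#' @param seed global integer seed; per-patient streams are derived with
#'   [derive_seed()].
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 20,
                       tf_range = list(cfDNA = c(0.05, 0.60),
                                       tissue = c(0.15, 0.90)),
                       depth_mean = c(cfDNA = 1040, tissue = 370, gDNA = 300),
                       depth_dispersion = 8,
                       panel_footprint = 350000L,
                       n_truncal = 4L,
                       n_subclonal = 3L,
                       germline_het_count = 25L,
                       chip_count = 2L,
                       chip_vaf_range = c(0.005, 0.05),
                       ffpe_noise_rate = 3,
                       serial_timepoints = 2L,
                       drift_prob = 0.4,
                       drift_compartments = "tissue",
                       subclone_private_prob = 0,
                       silent_fraction = 0.15,
                       amplified_genes = data.frame(gene = "ERBB2",
                                                    copy_number = 20),
                       cn_noise_sd = 0.08,
                       seed = 1L) {
  config <- list(n_patients = as.integer(n_patients), tf_range = tf_range,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 panel_footprint = as.integer(panel_footprint),
                 n_truncal = as.integer(n_truncal),
                 n_subclonal = as.integer(n_subclonal),
                 germline_het_count = as.integer(germline_het_count),
                 chip_count = as.integer(chip_count),
                 chip_vaf_range = chip_vaf_range,
                 ffpe_noise_rate = ffpe_noise_rate,
                 serial_timepoints = as.integer(serial_timepoints),
                 drift_prob = drift_prob,
                 drift_compartments = drift_compartments,
                 subclone_private_prob = subclone_private_prob,
                 silent_fraction = silent_fraction,
                 amplified_genes = amplified_genes,
                 cn_noise_sd = cn_noise_sd,
                 seed = as.integer(seed))
  class(config) <- "sim_config"
  validate_sim_config(config)
  config
}

validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_patients < 1) stop("n_patients must be >= 1")
  for (cmp in c("cfDNA", "tissue")) {
    r <- config$tf_range[[cmp]]
    if (is.null(r) || length(r) != 2 || any(r < 0) || any(r > 1) || r[1] > r[2])
      stop("tf_range$", cmp, " must be an interval inside [0, 1]")
  }
  if (any(config$depth_mean < 0)) stop("depths must be >= 0")
  if (!all(c("cfDNA", "tissue", "gDNA") %in% names(config$depth_mean)))
    stop("depth_mean must name cfDNA, tissue and gDNA")
  if (config$panel_footprint <= 0) stop("panel_footprint must be > 0")
  if (config$depth_dispersion <= 0) stop("depth_dispersion must be > 0")
  for (p in c("drift_prob", "subclone_private_prob", "silent_fraction"))
    stop_if_not_scalar_prob(config[[p]], p)
  r <- config$chip_vaf_range
  if (length(r) != 2 || any(r < 0) || any(r > 1) || r[1] > r[2])
    stop("chip_vaf_range must be an interval inside [0, 1]")
  if (config$serial_timepoints < 1) stop("serial_timepoints must be >= 1")
  if (config$ffpe_noise_rate < 0) stop("ffpe_noise_rate must be >= 0")
  if (!all(config$drift_compartments %in% c("cfDNA", "tissue")))
    stop("drift_compartments must be a subset of cfDNA/tissue")
  ag <- config$amplified_genes
  if (!is.null(ag) && nrow(ag) > 0) {
    stopifnot(all(c("gene", "copy_number") %in% names(ag)))
    if (any(ag$copy_number < 0)) stop("amplified copy numbers must be >= 0")
  }
  invisible(config)
}

#' Expected variant allele fraction under the purity/copy mixture model
#'
#' The expected VAF of a somatic mutation carried by a fraction `ccf` of
#' cancer cells, in a sample with the given tumor fraction, when the
#' mutated locus has `total_copies` in tumor cells of which
#' `mutant_copies` carry the mutant allele (normal cells contribute two
#' reference copies):
#' \deqn{VAF = \frac{tf \cdot ccf \cdot m}{tf \cdot c + (1 - tf) \cdot 2}}
#' A truncal mutation under loss of heterozygosity (`total_copies = 1`,
#' `mutant_copies = 1`, `ccf = 1`) gives `VAF = tf / (2 - tf)`, the
#' inverse of the conservative tumor-fraction transform.
#'
#' @param ccf cancer cell fraction in `[0, 1]`.
#' @param tumor_fraction sample tumor fraction in `[0, 1]`.
#' @param total_copies tumor copy number at the locus (integer >= 0).
#' @param mutant_copies mutant-allele copies, `<= total_copies`.
#' @return Expected VAF in `[0, 1]`; 0 when `tumor_fraction = 0`.
#' @export
expected_vaf <- function(ccf, tumor_fraction, total_copies, mutant_copies) {
  if (any(c(ccf, tumor_fraction, total_copies, mutant_copies) < 0))
    stop("expected_vaf: negative inputs are not allowed")
  if (any(ccf > 1) || any(tumor_fraction > 1))
    stop("expected_vaf: ccf and tumor_fraction must be <= 1")
  if (any(mutant_copies > total_copies))
    stop("expected_vaf: mutant_copies must be <= total_copies")
  denom <- tumor_fraction * total_copies + (1 - tumor_fraction) * 2
  ifelse(denom <= 0, 0, tumor_fraction * ccf * mutant_copies / denom)
}

#' Binomial read-support sampling
#'
#' Draws the mutant read count for a variant at a given true VAF and total
#' depth from a binomial distribution, the read-count noise model under
#' which the conservative tumor-fraction adjustment is derived. Uses the
#' current R random number stream; results are deterministic under
#' `set.seed()`.
#'
#' @param true_vaf true variant allele fraction(s) in `[0, 1]`.
#' @param depth total read depth(s), integer `>= 0`; recycled with
#'   `true_vaf`.
#' @return data.frame with columns `alt_reads` and `depth`.
#' @export
simulate_read_support <- function(true_vaf, depth) {
  if (any(true_vaf < 0 | true_vaf > 1)) stop("true_vaf must be in [0, 1]")
  if (any(depth < 0)) stop("depth must be >= 0")
  n <- max(length(true_vaf), length(depth))
  true_vaf <- rep_len(true_vaf, n)
  depth <- rep_len(as.integer(depth), n)
  data.frame(alt_reads = stats::rbinom(n, depth, true_vaf), depth = depth)
}

# ---- internal generation machinery -----------------------------------------

sample_bases <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  data.frame(ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
}

region_flag_for <- function(gene, chrom, amplified) {
  ifelse(gene == "TERT", "TERT_promoter",
         ifelse(chrom == "chr9", "chr9",
                ifelse(gene %in% amplified, "amplified", "autosome")))
}

# Place n variants on panel genes with unique loci within the patient.
place_variants <- function(n, genes, used_keys, amplified) {
  if (n == 0)
    return(data.frame(gene = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      region_flag = character(), stringsAsFactors = FALSE))
  rows <- genes[sample.int(nrow(genes), n, replace = TRUE), , drop = FALSE]
  pos <- rows$start + sample.int(8000L, n, replace = TRUE)
  ba <- sample_bases(n)
  out <- data.frame(gene = rows$gene, chrom = rows$chrom, pos = pos,
                    ref = ba$ref, alt = ba$alt, stringsAsFactors = FALSE)
  # resample any locus collisions (rare)
  repeat {
    keys <- variant_key(out$chrom, out$pos, out$ref, out$alt)
    dup <- duplicated(keys) | keys %in% used_keys
    if (!any(dup)) break
    out$pos[dup] <- out$pos[dup] + sample.int(50L, sum(dup), replace = TRUE)
  }
  out$region_flag <- region_flag_for(out$gene, out$chrom, amplified)
  out
}

#' Simulate one patient with ground truth
#'
#' Generates one matched germline sample plus `serial_timepoints` cfDNA and
#' tissue samples, with a patient-level clone tree, somatic mutations with
#' binomially sampled read support, germline heterozygous variants, CHIP
#' variants shared between gDNA and cfDNA, and tissue-restricted FFPE
#' artifacts. Every truth variant is emitted as a candidate observation in
#' every sample of the patient (possibly with zero mutant reads), so that
#' paired-sample read lookups are always possible downstream.
#'
#' @param config a [sim_config()].
#' @param patient_id patient identifier string.
#' @param patient_seed integer seed for this patient's stream.
#' @return list with elements `manifest`, `variants`, `depth`, `coverage`
#'   (data.frames) and `truth` (the patient TruthModel: tumor fractions,
#'   clone tree with per-sample CCFs, mutation table, per-variant class
#'   labels and true VAF matrix).
#' @export
simulate_patient <- function(config, patient_id, patient_seed) {
  validate_sim_config(config)
  with_seed(patient_seed, simulate_patient_impl(config, patient_id))
}

simulate_patient_impl <- function(config, patient_id) {
  panel <- panel_genes()
  somatic_genes <- panel[panel$role %in% c("driver", "tert_promoter"), ]
  chip_genes <- panel[panel$role == "chip", ]
  amplified <- if (nrow(config$amplified_genes)) config$amplified_genes$gene
               else character()

  # ---- samples and tumor fractions
  tp <- seq_len(config$serial_timepoints)
  manifest <- rbind(
    data.frame(patient_id = patient_id,
               sample_id = sprintf("%s-gDNA", patient_id),
               compartment = "gDNA", assay = "targeted-panel",
               timepoint_days = 0L, treatment_context = "baseline",
               stringsAsFactors = FALSE),
    data.frame(patient_id = patient_id,
               sample_id = sprintf("%s-cfDNA-t%d", patient_id, tp),
               compartment = "cfDNA", assay = "targeted-panel",
               timepoint_days = (tp - 1L) * 90L,
               treatment_context = ifelse(tp == 1, "pre_treatment",
                                          "on_treatment"),
               stringsAsFactors = FALSE),
    data.frame(patient_id = patient_id,
               sample_id = sprintf("%s-tissue-t%d", patient_id, tp),
               compartment = "tissue", assay = "targeted-panel",
               timepoint_days = (tp - 1L) * 180L,
               treatment_context = "archival",
               stringsAsFactors = FALSE))
  n_samp <- nrow(manifest)
  tf <- numeric(n_samp)
  names(tf) <- manifest$sample_id
  for (i in seq_len(n_samp)) {
    cmp <- manifest$compartment[i]
    tf[i] <- if (cmp == "gDNA") 0 else stats::runif(1,
      config$tf_range[[cmp]][1], config$tf_range[[cmp]][2])
  }

  # ---- clone tree: truncal clone 1 plus subclones, child CCF <= parent
  n_clones <- 1L + config$n_subclonal
  clones <- data.frame(clone_id = seq_len(n_clones),
                       parent_id = NA_integer_, base_ccf = 1,
                       private_compartment = NA_character_,
                       drifted = FALSE, stringsAsFactors = FALSE)
  if (n_clones > 1) for (k in 2:n_clones) {
    parent <- sample.int(k - 1L, 1)
    clones$parent_id[k] <- parent
    clones$base_ccf[k] <- stats::runif(1, 0, clones$base_ccf[parent])
    if (stats::runif(1) < config$subclone_private_prob)
      clones$private_compartment[k] <- sample(c("cfDNA", "tissue"), 1)
    clones$drifted[k] <- stats::runif(1) < config$drift_prob
  }
  timepoint_index <- stats::ave(seq_len(n_samp), manifest$compartment,
                                FUN = seq_along)
  ccf <- matrix(0, n_clones, n_samp,
                dimnames = list(NULL, manifest$sample_id))
  for (j in seq_len(n_samp)) {
    cmp <- manifest$compartment[j]
    if (cmp == "gDNA") next
    for (k in seq_len(n_clones)) {
      v <- clones$base_ccf[k]
      if (!is.na(clones$private_compartment[k]) &&
          clones$private_compartment[k] != cmp) v <- 0
      if (clones$drifted[k] && cmp %in% config$drift_compartments &&
          timepoint_index[j] > 1) v <- 0
      if (!is.na(clones$parent_id[k])) v <- min(v, ccf[clones$parent_id[k], j])
      ccf[k, j] <- v
    }
  }

  # ---- somatic mutations (truncal modeled under LOH, subclonal diploid het)
  used <- character()
  n_som <- config$n_truncal + config$n_subclonal
  som <- place_variants(n_som, somatic_genes, used, amplified)
  used <- c(used, variant_key(som$chrom, som$pos, som$ref, som$alt))
  som$clone_id <- c(rep(1L, config$n_truncal),
                    if (config$n_subclonal > 0)
                      sample(2:n_clones, config$n_subclonal, replace = TRUE))
  som$total_copies <- ifelse(som$clone_id == 1L, 1L, 2L)
  amp_idx <- som$gene %in% amplified
  if (any(amp_idx))
    som$total_copies[amp_idx] <- config$amplified_genes$copy_number[
      match(som$gene[amp_idx], config$amplified_genes$gene)]
  som$mutant_copies <- rep(1L, nrow(som))
  som$effect <- ifelse(som$gene == "TERT", "silent",
    ifelse(stats::runif(n_som) < config$silent_fraction, "silent",
           "protein_altering"))
  som$class <- rep("somatic", nrow(som))

  # ---- germline heterozygous variants
  germ <- place_variants(config$germline_het_count, panel, used, amplified)
  used <- c(used, variant_key(germ$chrom, germ$pos, germ$ref, germ$alt))
  if (nrow(germ)) {
    germ$clone_id <- NA_integer_
    germ$total_copies <- 2L; germ$mutant_copies <- 1L
    germ$effect <- ifelse(stats::runif(nrow(germ)) < 0.5, "silent",
                          "protein_altering")
    germ$class <- "germline"
  }

  # ---- CHIP variants: present in gDNA and cfDNA, absent from tissue truth
  chip <- place_variants(config$chip_count, chip_genes, used, amplified)
  used <- c(used, variant_key(chip$chrom, chip$pos, chip$ref, chip$alt))
  if (nrow(chip)) {
    chip$clone_id <- NA_integer_
    chip$total_copies <- 2L; chip$mutant_copies <- 1L
    chip$effect <- "protein_altering"
    chip$class <- "chip"
  }
  chip_gdna_vaf <- if (nrow(chip)) stats::runif(nrow(chip),
    config$chip_vaf_range[1], config$chip_vaf_range[2]) else numeric()

  # ---- FFPE artifacts: tissue-sample-specific, low VAF, short end distance
  tissue_ids <- manifest$sample_id[manifest$compartment == "tissue"]
  art_list <- list()
  for (sid in tissue_ids) {
    n_art <- stats::rpois(1, config$ffpe_noise_rate)
    if (n_art == 0) next
    a <- place_variants(n_art, somatic_genes, used, amplified)
    used <- c(used, variant_key(a$chrom, a$pos, a$ref, a$alt))
    a$clone_id <- NA_integer_
    a$total_copies <- 2L; a$mutant_copies <- 1L
    a$effect <- "protein_altering"
    a$class <- "ffpe_artifact"
    a$artifact_sample <- sid
    a$artifact_vaf <- stats::runif(n_art, 0.005, 0.05)
    a$artifact_end_distance <- stats::runif(n_art, 5, 15)
    art_list[[sid]] <- a
  }
  art <- if (length(art_list)) do.call(rbind, art_list) else NULL

  vars <- rbind(som[, c("gene", "chrom", "pos", "ref", "alt", "region_flag",
                        "clone_id", "total_copies", "mutant_copies",
                        "effect", "class")],
                if (nrow(germ)) germ[, c("gene", "chrom", "pos", "ref", "alt",
                                         "region_flag", "clone_id",
                                         "total_copies", "mutant_copies",
                                         "effect", "class")],
                if (nrow(chip)) chip[, c("gene", "chrom", "pos", "ref", "alt",
                                         "region_flag", "clone_id",
                                         "total_copies", "mutant_copies",
                                         "effect", "class")],
                if (!is.null(art)) art[, c("gene", "chrom", "pos", "ref",
                                           "alt", "region_flag", "clone_id",
                                           "total_copies", "mutant_copies",
                                           "effect", "class")])
  rownames(vars) <- NULL
  vars$variant_id <- variant_key(vars$chrom, vars$pos, vars$ref, vars$alt)

  # ---- true VAF per variant per sample
  true_vaf <- matrix(0, nrow(vars), n_samp,
                     dimnames = list(vars$variant_id, manifest$sample_id))
  for (j in seq_len(n_samp)) {
    cmp <- manifest$compartment[j]
    for (i in seq_len(nrow(vars))) {
      cls <- vars$class[i]
      if (cls == "somatic") {
        if (cmp == "gDNA") next
        true_vaf[i, j] <- expected_vaf(ccf[vars$clone_id[i], j], tf[j],
                                       vars$total_copies[i],
                                       vars$mutant_copies[i])
      } else if (cls == "germline") {
        true_vaf[i, j] <- 0.5
      } else if (cls == "chip") {
        ci <- which(chip$gene == vars$gene[i] & chip$pos == vars$pos[i])[1]
        if (cmp == "gDNA") true_vaf[i, j] <- chip_gdna_vaf[ci]
        else if (cmp == "cfDNA")
          true_vaf[i, j] <- min(1, chip_gdna_vaf[ci] *
                                   exp(stats::rnorm(1, 0, 0.15)))
      } else if (cls == "ffpe_artifact") {
        ai <- which(art$pos == vars$pos[i] & art$chrom == vars$chrom[i])[1]
        if (manifest$sample_id[j] == art$artifact_sample[ai])
          true_vaf[i, j] <- art$artifact_vaf[ai]
      }
    }
  }

  # ---- observations: every truth variant in every sample
  obs_list <- vector("list", n_samp)
  for (j in seq_len(n_samp)) {
    cmp <- manifest$compartment[j]
    nv <- nrow(vars)
    depth <- stats::rnbinom(nv, size = config$depth_dispersion,
                            mu = config$depth_mean[[cmp]])
    alt <- stats::rbinom(nv, depth, true_vaf[, j])
    end_dist <- round(stats::runif(nv, 30, 70), 1)
    if (!is.null(art)) {
      for (ai in seq_len(nrow(art))) {
        if (manifest$sample_id[j] == art$artifact_sample[ai]) {
          vi <- match(variant_key(art$chrom[ai], art$pos[ai], art$ref[ai],
                                  art$alt[ai]), vars$variant_id)
          end_dist[vi] <- round(art$artifact_end_distance[ai], 1)
        }
      }
    }
    obs_list[[j]] <- data.frame(
      sample_id = rep(manifest$sample_id[j], nv),
      chrom = vars$chrom, pos = vars$pos, ref = vars$ref, alt = vars$alt,
      gene = vars$gene, effect = vars$effect,
      depth = depth, alt_reads = alt,
      mean_mapq_alt = round(pmin(60, pmax(20, stats::rnorm(nv, 58, 2))), 1),
      mean_end_distance_alt = end_dist,
      region_flag = vars$region_flag,
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, obs_list)
  variants$vaf <- ifelse(variants$depth > 0,
                         variants$alt_reads / variants$depth, 0)

  # ---- per-site depth histograms
  depth_list <- vector("list", n_samp)
  for (j in seq_len(n_samp)) {
    cmp <- manifest$compartment[j]
    d <- stats::rnbinom(config$panel_footprint,
                        size = config$depth_dispersion,
                        mu = config$depth_mean[[cmp]])
    tb <- table(d)
    depth_list[[j]] <- data.frame(sample_id = manifest$sample_id[j],
                                  depth_bin = as.integer(names(tb)),
                                  n_sites = as.integer(tb),
                                  stringsAsFactors = FALSE)
  }
  depth <- do.call(rbind, depth_list)

  # ---- normalized per-gene coverage (mixture of tumor CN and diploid normal)
  cov_list <- vector("list", n_samp)
  for (j in seq_len(n_samp)) {
    cn_g <- rep(2, nrow(panel))
    if (length(amplified))
      cn_g[match(amplified, panel$gene)] <- config$amplified_genes$copy_number
    ratio <- (tf[j] * cn_g + 2 * (1 - tf[j])) / 2
    cov_list[[j]] <- data.frame(
      sample_id = manifest$sample_id[j], gene = panel$gene,
      coverage = ratio * 2 ^ stats::rnorm(nrow(panel), 0, config$cn_noise_sd),
      stringsAsFactors = FALSE)
  }
  coverage <- do.call(rbind, cov_list)

  truth <- list(
    patient_id = patient_id,
    tumor_fraction = tf,
    clones = data.frame(clone_id = clones$clone_id,
                        parent_id = clones$parent_id,
                        stringsAsFactors = FALSE),
    ccf = cbind(data.frame(clone_id = clones$clone_id),
                as.data.frame(ccf)),
    mutations = cbind(data.frame(mutation_id = vars$variant_id),
                      vars[, c("clone_id", "chrom", "pos", "ref", "alt",
                               "gene", "effect", "total_copies",
                               "mutant_copies", "class")]),
    true_vaf = cbind(data.frame(variant_id = vars$variant_id),
                     as.data.frame(true_vaf)))
  rownames(truth$mutations) <- rownames(truth$true_vaf) <- NULL

  list(manifest = manifest, variants = variants, depth = depth,
       coverage = coverage, truth = truth)
}

#' Simulate a full synthetic cohort
#'
#' @param config a [sim_config()].
#' @return An object of class `ctdna_cohort`: list with data.frames
#'   `manifest`, `variants`, `depth`, `coverage`, a per-patient `truth`
#'   list, and the `config` used.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  pats <- lapply(seq_len(config$n_patients), function(i) {
    simulate_patient(config, sprintf("P%03d", i),
                     derive_seed(config$seed, i))
  })
  cohort <- list(
    manifest = do.call(rbind, lapply(pats, `[[`, "manifest")),
    variants = do.call(rbind, lapply(pats, `[[`, "variants")),
    depth = do.call(rbind, lapply(pats, `[[`, "depth")),
    coverage = do.call(rbind, lapply(pats, `[[`, "coverage")),
    truth = lapply(pats, `[[`, "truth"),
    config = config)
  rownames(cohort$manifest) <- rownames(cohort$variants) <-
    rownames(cohort$depth) <- rownames(cohort$coverage) <- NULL
  names(cohort$truth) <- vapply(cohort$truth, `[[`, "", "patient_id")
  class(cohort) <- "ctdna_cohort"
  cohort
}

#' @export
print.ctdna_cohort <- function(x, ...) {
  cat("ctdna_cohort:", length(x$truth), "patients,",
      nrow(x$manifest), "samples,",
      nrow(x$variants), "candidate variant observations\n")
  invisible(x)
}

# ---- on-disk round trip ----------------------------------------------------

DIALECT_COLS <- c("sample_id", "chrom", "pos", "ref", "alt", "gene", "effect",
                  "depth", "alt_reads", "mean_mapq_alt",
                  "mean_end_distance_alt", "region_flag")

#' Write a cohort to disk
#'
#' Emits one variant TSV per sample (the package's tab-separated dialect,
#' 1-based positions), one depth-histogram TSV per sample, a normalized
#' gene coverage TSV, a cohort manifest TSV, and the full truth model as
#' JSON. Files round-trip losslessly through [read_cohort()].
#'
#' @param cohort a `ctdna_cohort`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "ctdna_cohort"))
  if (nrow(cohort$manifest) == 0) stop("empty cohort")
  dir.create(file.path(out_dir, "variants"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "depth"), showWarnings = FALSE)
  write_tsv(cohort$manifest, file.path(out_dir, "manifest.tsv"))
  write_tsv(cohort$coverage, file.path(out_dir, "coverage.tsv"))
  for (sid in cohort$manifest$sample_id) {
    v <- cohort$variants[cohort$variants$sample_id == sid, DIALECT_COLS]
    write_tsv(v, file.path(out_dir, "variants",
                           paste0(sid, ".variants.tsv")))
    d <- cohort$depth[cohort$depth$sample_id == sid,
                      c("depth_bin", "n_sites")]
    write_tsv(d, file.path(out_dir, "depth", paste0(sid, ".depth.tsv")))
  }
  truth <- cohort$truth
  for (i in seq_along(truth))
    truth[[i]]$tumor_fraction <- as.list(truth[[i]]$tumor_fraction)
  jsonlite::write_json(
    list(config = unclass(cohort$config), truth = truth),
    file.path(out_dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(out_dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory produced by [write_cohort()].
#' @return A `ctdna_cohort` with observed VAFs recomputed from counts.
#' @export
read_cohort <- function(dir) {
  manifest <- read_tsv(file.path(dir, "manifest.tsv"))
  coverage <- read_tsv(file.path(dir, "coverage.tsv"))
  vlist <- list(); dlist <- list()
  for (sid in manifest$sample_id) {
    v <- read_tsv(file.path(dir, "variants", paste0(sid, ".variants.tsv")),
                  colClasses = c(chrom = "character", ref = "character",
                                 alt = "character"))
    vlist[[sid]] <- v
    d <- read_tsv(file.path(dir, "depth", paste0(sid, ".depth.tsv")))
    if (nrow(d)) d$sample_id <- sid
    dlist[[sid]] <- d
  }
  variants <- do.call(rbind, vlist)
  rownames(variants) <- NULL
  variants$vaf <- ifelse(variants$depth > 0,
                         variants$alt_reads / variants$depth, 0)
  j <- jsonlite::read_json(file.path(dir, "truth.json"),
                           simplifyVector = TRUE, simplifyDataFrame = TRUE)
  truth <- j$truth
  for (i in seq_along(truth))
    truth[[i]]$tumor_fraction <- unlist(truth[[i]]$tumor_fraction)
  cohort <- list(manifest = manifest, variants = variants,
                 depth = do.call(rbind, dlist), coverage = coverage,
                 truth = truth, config = j$config)
  rownames(cohort$depth) <- NULL
  class(cohort) <- "ctdna_cohort"
  cohort
}
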