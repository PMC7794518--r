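---
title: "Methods: ctDNA variant filtering, tumor fraction, TMB and concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ctDNA variant filtering, tumor fraction, TMB and concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnapipe)
```

# Scope

`ctdnapipe` implements a targeted-panel liquid-biopsy analysis for
metastatic urothelial carcinoma and similar settings: somatic variant
filtering against a matched germline, conservative estimation of the
circulating tumor DNA (ctDNA) fraction, depth-aware tumor mutational
burden (TMB) extrapolation, purity-corrected gene copy number, and
mutation-level concordance between tumor tissue and plasma and across
serial samples. Because the clinical sequencing data such analyses are
developed on is controlled-access, the package ships a synthetic cohort
generator with fully recorded ground truth; every stage is validated
against that truth rather than against inaccessible patient data.

# Somatic variant filtering

Candidate variants carry read counts, a mean mapping quality over
mutation-supporting reads, and a read-end proximity score (the mean
distance of the mutant allele from the nearest read end among supporting
reads; artifacts cluster near fragment ends). A call is retained when all
of the following hold:

* at least 8 mutant-allele reads;
* VAF at least 1% in cfDNA or 8% in tissue;
* VAF strictly greater than 3x the matched germline (gDNA) VAF — this one
  rule removes both germline heterozygous variants (VAF near 50% in both
  compartments) and most clonal hematopoiesis (CHIP) variants, which are
  present in the white-blood-cell compartment;
* mean mapping quality strictly above 30 and read-end proximity strictly
  above 25 bases. Ties at exactly 30 or exactly 25 fail: the gates are
  quoted as strict inequalities and we keep them that way.

When the germline has no coverage at a locus the ratio rule passes with a
`GDNA_MISSING` annotation rather than silently failing: filtering against
the matched normal is only meaningful where normal data exists.

Because cfDNA is sequenced much deeper than gDNA, low-VAF CHIP variants
can survive the ratio rule. Variants in a configurable CHIP gene list
(default DNMT3A, TET2, ASXL1) with any mutant support in gDNA are flagged
`CHIP_GENE_REVIEW`; the flag is advisory by default (mirroring a manual
review step) and exclusionary in strict mode.

Exome-derived silent calls are held to stricter rules (VAF >= 10%,
>= 50x the site background error rate, >= 10x the matched normal VAF)
via `passes_wes_silent_filters()`.

Targeted-panel calling in principle also filters against a background
error rate, but no error model or magnitude is standardized; we expose it
as an optional one-sided binomial test of the mutant read count against a
configurable per-site error rate (default 0.1%, alpha = 0.01), disabled
by default so it cannot silently change results.

# Tumor fraction

The ctDNA fraction is estimated from the highest VAF among eligible
somatic mutations. Three exclusions precede selection: chromosome 9
mutations (frequent copy-neutral loss of heterozygosity distorts VAFs),
TERT promoter mutations (systematically low depth), and mutations in
copy-number amplified regions; selection is restricted to autosomes. Ties
at the maximum VAF break by lexicographic (chrom, pos, alt) order so runs
are reproducible.

Two corrections are applied to the selected variant:

1. **Binomial quantile adjustment.** The observed mutant count `k` of `n`
   is treated as a binomial draw, and we conservatively ask what the true
   VAF would be if the observation were a 95% quantile outlier: the
   largest `p` with `P(X >= k | Binomial(n, p)) <= 0.05`. This is the
   exact one-sided lower confidence bound (Clopper-Pearson), computed via
   the Beta identity `qbeta(0.05, k, n - k + 1)`; the test suite checks
   it against an independent bisection of the binomial survival function
   for every `(k, n)` with `n <= 200`. The adjustment is applied to the
   single selected variant without a max-of-m multiplicity correction:
   whether the published procedure conditioned on the maximum of several
   mutations is not stated, and the uncorrected per-variant bound is the
   more conservative, simpler choice. The `quantile` argument is exposed
   for sensitivity analysis.
2. **LOH transform.** `TF = 2 VAF / (1 + VAF)`, i.e. assuming the variant
   sits on a region of loss of heterozygosity. This is conservative: any
   retained reference copy in tumor cells would imply a higher tumor
   fraction. The transform is a strictly increasing bijection of [0, 1];
   its inverse `VAF = TF / (2 - TF)` round-trips to 1e-12 in the tests.
   The calling floors imply detection limits of `2*0.01/1.01 = 2.0%`
   tumor fraction in cfDNA and `2*0.08/1.08 = 14.8%` in tissue.

A cfDNA sample is "detected" when the estimated fraction exceeds 1%, and
"evaluable" when at least one protein-altering somatic mutation was kept.
The pipeline applies the amplified-region exclusion in two passes: flags
provided with the input are honored immediately, and if the selected
variant's gene is subsequently called amplified by the copy-number stage,
the estimate is redone excluding it. Clonality is classified per mutation
as subclonal when `VAF < 0.25 * TF` (strictly; the boundary is clonal), a
deliberately conservative cut because targeted panels do not support
allele-specific copy number modeling.

# TMB extrapolation

Genome-wide TMB is extrapolated from the panel with a per-mutation
detectability correction. A mutation at observed VAF `v` needs depth
`ceiling(8 / v)` to be expected to clear the eight-read minimum; `B_m` is
the number of panel sites at or above that depth, read off the sample's
depth histogram. Then

$$TMB = 10^6 \sum_m 1/B_m \quad \text{mutations/Mb}.$$

Low-VAF mutations are detectable on fewer sites and so carry larger
weights, compensating for their depressed detection under non-uniform
coverage. With uniformly adequate depth this reduces exactly to mutation
count / footprint x 1e6. Mutations with `B_m = 0` cannot be extrapolated
and are excluded with a warning. The observed VAF (not the
purity-normalized one) drives `required_depth`, since detectability
depends on the allele fraction actually present in the library. Silent
calls are excluded by default, matching the protein-altering scope of the
targeted calling; `include_silent = TRUE` covers exome-style inputs.

# Gene copy number

Observed normalized coverage of a gene is modeled as a mixture of tumor
cells at copy number `CN` and diploid normal cells:
`ratio = (tf * CN + 2 (1 - tf)) / 2`, inverted as
`CN = (2 * 2^lr - 2 (1 - tf)) / tf` where `lr` is the log2 coverage
ratio against the per-gene baseline. Division by `tf` is what keeps
high-level amplifications visible at low ctDNA fractions. Negative
solutions are floored at 0 copies. Copy number is unidentifiable at
`tf = 0`, so such samples are never called; instead they define the
baseline: per-gene mean coverage and log-ratio standard deviation are
estimated from samples with no evidence of cancer (at least three
required). Confidence intervals are formed on the log-ratio scale
(`lr +/- 1.96 sd`) and transformed through the same model — the log scale
is where baseline noise is approximately symmetric, and the transform
preserves interval ordering. Amplification is called at >= 5 copies
(boundary inclusive); no standard threshold exists, so it is explicit and
configurable.

# Concordance

Tissue-vs-plasma comparison selects, per patient, the highest
ctDNA-fraction cfDNA sample and the most recent tissue sample, among
samples evaluable for protein-altering mutations (ties break by sample
id, logged in the outputs). Variants match exactly on (chrom, pos, ref,
alt); no fuzzy indel matching, so discordance is auditable. For each
exclusive call, the paired sample's read support at the locus is checked:
three or more mutant reads flag the discordance as coverage-explained
(deeper sequencing would likely have recovered it); missing pileup data
yields unknown, never false. Depth sufficiency for truncal detection uses
the expected mutant count `depth * tf / 2 >= 8` under a diploid
heterozygous truncal model.

Sharing is stratified by clonality into a 2x2 table tested with a
two-sided Fisher exact test using the point-probability definition (sum
of all no-more-likely tables), the convention of the mainstream
implementations; the p-value is delegated to `stats::fisher.test` and
verified in the tests against a brute-force hypergeometric enumeration on
all tables with margins up to 10. The reported odds ratio is the sample
odds ratio `ad/bc`. Serial concordance is the fraction of unique
mutations called in every sample among those called in any sample of a
patient-compartment series; it is order-invariant and bounded above by
the minimum pairwise shared fraction.

# The synthetic cohort generator

The generator emulates the study conditions downstream stages were built
for: per patient one gDNA sample, and serial cfDNA and tissue samples at
mean unique depths of 1040x, 370x and 300x (gDNA), negative-binomially
dispersed per site (size 8, a visibly non-uniform but not pathological
coverage profile) over a 350 kb panel footprint modeled on a 50-60 gene
exonic design. Default mutation load is 4 truncal plus 3 subclonal
somatic mutations per patient (about 6 protein-altering at the default
15% silent fraction), placing panel mutation densities in the
interquartile range reported for urothelial tumors on comparably sized
panels.

Ground truth is a clone tree: the truncal clone has cancer cell fraction
(CCF) 1 in every tumor-bearing sample, subclone CCFs are drawn uniformly
subject to child <= parent (the simplest null model). Truncal mutations
are simulated under LOH (one mutant copy of one total) so that the
ground truth is self-consistent with the estimator's conservative LOH
assumption and true tumor fractions are recoverable; subclonal mutations
are diploid heterozygous. Expected VAFs come from the standard
purity/copy mixture, and observed counts are binomial draws at
negative-binomial depths. Confounders are injected with truth labels:

* germline heterozygous variants (true VAF 0.5 everywhere);
* CHIP variants in DNMT3A/TET2/ASXL1 with correlated gDNA/cfDNA VAFs
  (default 0.5-5%, the range where germline-depth asymmetry makes them
  dangerous) and absent from tissue;
* FFPE artifacts restricted to single tissue samples, VAF 0.5-5%, with
  short read-end distances (mean 5-15 bases) so the proximity gate is
  exercised;
* amplified oncogenes (default ERBB2 at 20 copies) affecting both the
  coverage tables and the VAFs of co-located mutations.

Serial drift removes a subclone from later timepoints with probability
`drift_prob`; drift is restricted to tissue by default
(`drift_compartments = "tissue"`), reflecting the temporal stability of
ctDNA relative to archival primary-site tissue, and is configurable for
experiments that need drift elsewhere. `subclone_private_prob` restricts
a subclone to one tumor compartment, which is how the tests construct
cohorts with depressed subclonal tissue/plasma sharing. One global seed
drives everything; per-patient streams are split deterministically
(`derive_seed`) so identical configurations produce byte-identical
cohort files.

What the generator does *not* emulate: read-level errors and alignment
artifacts beyond the configured classes, tri-nucleotide mutational
signatures, segment-level copy number, sample contamination, and any
empirical background-error profile (none is published; the background
filter is therefore off by default). Passing tests demonstrate internal
consistency of the estimators under binomial read sampling with known
truth — not performance on real cfDNA, where error modes are richer.

# Numerical choices and degenerate inputs

* `adjusted_vaf(0, n)` is 0; `adjusted_vaf(n, n)` has the closed form
  `0.05^(1/n)`, used as a test anchor.
* Zero-depth observations get VAF 0 rather than NA so rule evaluation is
  total; they fail the read-count floor anyway.
* `gene_copy_number` rejects `tf = 0` instead of returning arbitrary
  values; interval endpoints and estimates are floored at 0 copies.
* Empty variant files are valid (header only) and round-trip.
* Fisher's test rejects all-zero tables; the degenerate stratified table
  in a cohort where everything is shared is reported as not applicable
  rather than as p = 1 from a forced call.

# Problem sizes used by the test suite

Simulation-backed checks run at deliberately compact scales chosen to
keep Monte-Carlo error well inside the asserted tolerances: 100
single-patient replicate cohorts for TMB density recovery (mean within
10%), 200 replicates per level for tumor-fraction recovery at depths of
1000x (median within 0.05), 100 patients for the serial-drift contrast,
500 replicates for copy-number interval calibration, and 5-6 patient
cohorts for pipeline smoke and determinism contracts. Panel footprints
in these simulations are scaled to 2-20 kb, which leaves the per-site
depth distribution (the quantity TMB and detectability depend on)
unchanged while keeping histogram generation cheap.

# Known limitations

* The tumor-fraction estimator inherits the LOH assumption's downward
  bias when the true architecture is diploid heterozygous; this is by
  design (conservatism) and visible in the generator if truncal
  mutations are configured diploid.
* TMB extrapolation corrects for depth-driven missingness only; mutations
  with VAFs below the calling floor are invisible and uncorrectable, so
  panel TMB underestimates the burden of highly subclonal tumors.
* The copy-number model is single-clone and gene-level; subclonal and
  segment-level events are out of scope.
* Concordance operates on called variant sets; it cannot distinguish
  biological absence from borderline detection except through the
  coverage-explained flag.
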