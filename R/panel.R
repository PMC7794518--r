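# Built-in gene panel used by the synthetic cohort generator. Loosely modeled
# on targeted bladder-cancer driver panels: chromatin modifiers, cell-cycle
# regulators, PI3K pathway members, the TERT promoter, and the genes most
# often used to flag clonal hematopoiesis (DNMT3A, TET2, ASXL1). Coordinates
# are synthetic stand-ins, not genome-build positions; only chromosome
# assignment and interval width matter to the simulation.

#' Default targeted gene panel for simulation
#'
#' Returns the gene table used by [simulate_cohort()]: symbol, chromosome,
#' a synthetic exonic interval, and a role used when placing variants
#' (`driver`, `chip`, or `tert_promoter`). CDKN2A and TSC1 sit on chr9 so
#' the chromosome 9 exclusion in tumor-fraction estimation is exercised;
#' KDM6A and STAG2 sit on chrX to exercise the autosome restriction.
#'
#' @return A data.frame with columns gene, chrom, start, end, role.
#' @export
panel_genes <- function() {
  g <- function(gene, chrom, start, role = "driver")
    data.frame(gene = gene, chrom = chrom, start = start,
               end = start + 8000L, role = role,
               stringsAsFactors = FALSE)
  rbind(
    g("TP53",   "chr17",  7565097L),
    g("RB1",    "chr13", 48877883L),
    g("PIK3CA", "chr3", 178866311L),
    g("FGFR3",  "chr4",   1795039L),
    g("ERBB2",  "chr17", 37844393L),
    g("ERCC2",  "chr19", 45854919L),
    g("ARID1A", "chr1",  27022524L),
    g("KMT2D",  "chr12", 49412758L),
    g("CREBBP", "chr16",  3775055L),
    g("EP300",  "chr22", 41488614L),
    g("ATM",    "chr11", 108093211L),
    g("BRCA2",  "chr13", 32889611L),
    g("FBXW7",  "chr4", 153242410L),
    g("ELF3",   "chr1", 201979689L),
    g("CDKN1A", "chr6",  36644236L),
    g("CCND1",  "chr11", 69455873L),
    g("MDM2",   "chr12", 69201956L),
    g("E2F3",   "chr6",  20402137L),
    g("CDKN2A", "chr9",  21967751L),
    g("TSC1",   "chr9", 135766735L),
    g("KDM6A",  "chrX",  44732423L),
    g("STAG2",  "chrX", 123094475L),
    g("TERT",   "chr5",   1253287L, role = "tert_promoter"),
    g("DNMT3A", "chr2",  25455845L, role = "chip"),
    g("TET2",   "chr4", 106067032L, role = "chip"),
    g("ASXL1",  "chr20", 30946134L, role = "chip")
  )
}

#' Default clonal hematopoiesis review gene list
#'
#' Genes linked to hematopoietic stem cell clonal expansion; variants in
#' these genes with any mutant read support in matched germline DNA are
#' flagged for review during filtering.
#'
#' @return Character vector of gene symbols.
#' @export
chip_gene_list <- function() c("DNMT3A", "TET2", "ASXL1")
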