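# Accessors for the packaged example data: the 19 Sanger-confirmed
# candidate SNPs with their codon annotations, the 16-gene colour-gene
# list they fall in, and the 102-animal genotyping cohort.

wc_extdata <- function(name) {
  path <- system.file("extdata", name, package = "whitecoat")
  if (!nzchar(path)) abort(paste0("packaged fixture not found: ", name))
  path
}

#' Packaged candidate SNP table
#'
#' The nineteen Sanger-confirmed non-synonymous candidate SNPs that
#' survived the recessive trio filter in the fallow-deer coat-colour
#' study, with bovine-reference coordinates, genomic ref/alt alleles, CDS
#' position, capitalised-codon strings and the printed amino-acid
#' substitutions. Feed to [verify_codon_annotations()] to recompute and check every
#' annotation.
#'
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `accession`, `cdna_pos`, `codon_ref`, `codon_alt`, `aa_sub`.
#' @export
wc_candidate_snps <- function() {
  readr::read_tsv(
    wc_extdata("candidate_snps.tsv"),
    col_types = readr::cols(
      chrom = "c", pos = "i", ref = "c", alt = "c", gene = "c",
      accession = "c", cdna_pos = "i", codon_ref = "c", codon_alt = "c",
      aa_sub = "c"
    )
  )
}

#' Packaged colour-gene list
#'
#' The sixteen pigmentation genes represented among the candidate SNPs.
#'
#' @return Character vector of gene symbols.
#' @export
wc_colour_genes <- function() {
  read_gene_list(wc_extdata("colour_genes.txt"))
}

#' Packaged genotyping cohort
#'
#' The 102-animal fallow-deer cohort (80 pigmented, 22 white, 12
#' locations) genotyped at the MC1R c.143T>C site (variant key
#' `"18:14705518:T:C"`): 69 TT and 11 TC pigmented animals, 22 CC white
#' animals. Location-level splits are reconstructed to be consistent with
#' the cohort totals.
#'
#' @return Panel tibble (see [read_panel()]).
#' @export
wc_cohort_panel <- function() {
  read_panel(wc_extdata("cohort_panel.tsv"))
}

#' Variant key of the MC1R dilution SNP
#'
#' @return The `"chrom:pos:ref:alt"` key of MC1R c.143T>C on the bovine
#'   reference.
#' @export
wc_mc1r_key <- function() {
  variant_key("18", 14705518L, "T", "C")
}
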