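# In-code fixtures: tiny gene models and VCFs built at test time.

# Plus-strand single-segment model with "ctg" (Leu) at codon `leu_codon`,
# "aaa" elsewhere; genomic segment starts at `start`.
make_leu_model <- function(leu_codon = 48, n_codons = 60, start = 1000L,
                           chrom = "18", symbol = "MC1R") {
  codons <- rep("aaa", n_codons)
  codons[1] <- "atg"
  codons[leu_codon] <- "ctg"
  codons[n_codons] <- "taa"
  seq <- paste(codons, collapse = "")
  tibble::tibble(
    symbol = symbol, accession = "SYN_TEST.1", chrom = chrom, strand = "+",
    cds_segments = list(tibble::tibble(
      start = start, end = start + nchar(seq) - 1L
    )),
    cds_seq = seq
  )
}

# Minus-strand single-segment model carrying `codon` at position `at_codon`.
make_minus_model <- function(codon = "gat", at_codon = 525, n_codons = 540,
                             start = 50000L, chrom = "13",
                             symbol = "ATRN") {
  codons <- rep("aaa", n_codons)
  codons[1] <- "atg"
  codons[at_codon] <- codon
  codons[n_codons] <- "taa"
  seq <- paste(codons, collapse = "")
  tibble::tibble(
    symbol = symbol, accession = "SYN_TEST.2", chrom = chrom, strand = "-",
    cds_segments = list(tibble::tibble(
      start = start, end = start + nchar(seq) - 1L
    )),
    cds_seq = seq
  )
}

write_test_vcf <- function(records, samples = c("DAM", "CALF")) {
  path <- withr::local_tempfile(
    fileext = ".vcf", .local_envir = parent.frame()
  )
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records
  ), path)
  path
}

# Closed-form two-sided Fisher tail for a 2x2 table via the hypergeometric
# mass, independent of the enumeration implementation.
fisher_2x2_oracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  a <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A panel tibble in the shape read_panel() returns.
make_panel <- function(phenotypes, gts, key = "18:14705518:T:C") {
  parsed <- parse_variant_key(key)
  p <- tibble::tibble(
    animal_id = sprintf("P%03d", seq_along(phenotypes)),
    location = "LOC01", origin = "G",
    phenotype = phenotypes
  )
  p[[key]] <- allele_string(gts, parsed$ref, parsed$alt)
  attr(p, "variant_cols") <- key
  p
}
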