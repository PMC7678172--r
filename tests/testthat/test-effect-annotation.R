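test_that("cds_position walks segments in transcription order", {
  plus <- tibble::tibble(
    symbol = "P", accession = "x", chrom = "1", strand = "+",
    cds_segments = list(tibble::tibble(start = 1000L, end = 1999L)),
    cds_seq = strrep("a", 1000)
  )
  expect_equal(cds_position(plus, "1", 1000), 1L)
  expect_equal(cds_position(plus, "1", 1999), 1000L)
  expect_true(is.na(cds_position(plus, "1", 999)))
  expect_true(is.na(cds_position(plus, "2", 1000)))

  minus <- plus
  minus$strand <- "-"
  expect_equal(cds_position(minus, "1", 1999), 1L)
  expect_equal(cds_position(minus, "1", 1000), 1000L)

  two <- tibble::tibble(
    symbol = "T2", accession = "x", chrom = "1", strand = "+",
    cds_segments = list(tibble::tibble(
      start = c(100L, 300L), end = c(199L, 399L)
    )),
    cds_seq = strrep("a", 200)
  )
  expect_equal(cds_position(two, "1", 300), 101L)

  # brute-force walk oracle: count bases over segments one by one
  walk <- integer(0)
  for (seg in seq_len(2)) {
    rng <- seq(two$cds_segments[[1]]$start[seg], two$cds_segments[[1]]$end[seg])
    walk <- c(walk, rng)
  }
  for (k in seq_along(walk)) {
    expect_equal(cds_position(two, "1", walk[k]), k)
  }
})

test_that("genomic_position inverts cds_position on both strands", {
  set.seed(42)
  for (strand in c("+", "-")) {
    model <- tibble::tibble(
      symbol = "INV", accession = "x", chrom = "3", strand = strand,
      cds_segments = list(if (strand == "+") {
        tibble::tibble(start = c(500L, 801L), end = c(650L, 949L))
      } else {
        tibble::tibble(start = c(801L, 500L), end = c(949L, 650L))
      }),
      cds_seq = strrep("a", 300)
    )
    for (cdna in sample(300, 25)) {
      g <- genomic_position(model, cdna)
      expect_equal(cds_position(model, "3", g), cdna)
    }
  }
})

test_that("codon arithmetic maps CDS coordinates to residues and offsets", {
  expect_equal(codon_arithmetic(143)$codon_index, 48L)
  expect_equal(codon_arithmetic(143)$codon_offset, 2L)
  expect_equal(codon_arithmetic(1)$codon_index, 1L)
  expect_equal(codon_arithmetic(1)$codon_offset, 1L)
  expect_equal(codon_arithmetic(9260)$codon_index, 3087L)
  expect_equal(codon_arithmetic(9260)$codon_offset, 2L)
  expect_error(codon_arithmetic(0), "positive")

  # reconstruction is exact for every CDS coordinate
  ca <- codon_arithmetic(1:300)
  expect_equal(3L * (ca$codon_index - 1L) + ca$codon_offset, 1:300)
})

test_that("translation agrees with an independent 64-codon lookup", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  expect_length(codons, 64L)
  ref <- as.character(Biostrings::GENETIC_CODE[codons])
  expect_equal(translate_codon(codons), ref)
})

test_that("infer_strand reads the capitalised-codon notation", {
  expect_equal(infer_strand("T", "C", "cTg", "cCg", 2), "+")
  expect_equal(infer_strand("C", "T", "Gat", "Aat", 1), "-")
  expect_equal(infer_strand("G", "T", "gCc", "gAc", 2), "-")
  expect_error(infer_strand("A", "C", "gGa", "gTa", 2), "neither")
  expect_error(infer_strand("T", "C", "Ctg", "cCg", 2), "capital")
})

test_that("annotate_variant reproduces the dilution-allele annotation", {
  model <- make_leu_model()
  pos143 <- genomic_position(model, 143L)
  eff <- annotate_variant(
    list(chrom = "18", pos = pos143, ref = "T", alt = "C"), model
  )
  expect_equal(eff$cdna_pos, 143L)
  expect_equal(eff$codon_index, 48L)
  expect_equal(eff$codon_ref, "cTg")
  expect_equal(eff$codon_alt, "cCg")
  expect_equal(eff$hgvs_p, "p.L48P")
  expect_equal(eff$effect_class, "missense")

  # third codon base CTG -> CTA is silent
  pos144 <- genomic_position(model, 144L)
  syn <- annotate_variant(
    list(chrom = "18", pos = pos144, ref = "G", alt = "A"), model
  )
  expect_equal(syn$effect_class, "synonymous")
  expect_equal(syn$hgvs_p, "p.L48=")

  # non-coding position
  expect_null(annotate_variant(
    list(chrom = "18", pos = 1L, ref = "A", alt = "C"), model
  ))

  # CDS sequence disagreeing with the claimed reference allele
  expect_error(
    annotate_variant(list(chrom = "18", pos = pos143, ref = "G", alt = "C"),
                     model),
    "reference mismatch"
  )
})

test_that("minus-strand annotation complements the genomic alleles", {
  model <- make_minus_model(codon = "gat", at_codon = 525)
  pos <- genomic_position(model, 1573L) # G of "gat" on the coding strand
  eff <- annotate_variant(
    list(chrom = "13", pos = pos, ref = "C", alt = "T"), model
  )
  expect_equal(eff$cdna_pos, 1573L)
  expect_equal(eff$codon_ref, "Gat")
  expect_equal(eff$codon_alt, "Aat")
  expect_equal(eff$hgvs_p, "p.D525N")
  expect_equal(eff$effect_class, "missense")
})

test_that("annotation is strand-symmetric on random gene models", {
  set.seed(7)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:20) {
    n_codons <- sample(5:20, 1)
    seq <- whitecoat:::random_cds(n_codons)
    s <- 10000L; e <- s + nchar(seq) - 1L
    plus <- tibble::tibble(
      symbol = "SYM", accession = "x", chrom = "9", strand = "+",
      cds_segments = list(tibble::tibble(start = s, end = e)),
      cds_seq = seq
    )
    minus <- plus
    minus$strand <- "-"
    cdna <- sample(nchar(seq), 1)
    ref_nt <- toupper(substr(seq, cdna, cdna))
    alt_nt <- sample(setdiff(bases, ref_nt), 1)
    eff_plus <- annotate_variant(
      list(chrom = "9", pos = s + cdna - 1L, ref = ref_nt, alt = alt_nt),
      plus
    )
    eff_minus <- annotate_variant(
      list(chrom = "9", pos = e - cdna + 1L,
           ref = complement_base(ref_nt), alt = complement_base(alt_nt)),
      minus
    )
    expect_equal(eff_minus, eff_plus)
  }
})

test_that("verify_codon_annotations recomputes and matches the printed annotations", {
  snps <- wc_candidate_snps()
  v <- verify_codon_annotations(snps)
  expect_equal(sum(v$match), 19L)
  expect_equal(sum(v$strand == "-"), 10L) # minus-strand rows in the table

  one <- verify_codon_annotations(snps[snps$gene == "MC1R", ])
  expect_equal(sum(one$match), 1L)
  expect_equal(one$strand, "+")

  corrupted <- snps[snps$gene == "MC1R", ]
  corrupted$aa_sub <- "p.L48A"
  expect_equal(sum(verify_codon_annotations(corrupted)$match), 0L)
})
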