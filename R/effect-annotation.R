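# Strand-aware coding-effect annotation: genomic position -> CDS coordinate,
# codon arithmetic, translation under the standard genetic code, and the
# capitalised-codon notation used in the candidate tables.

# Standard genetic code, 64 entries, stop = "*".
GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' Translate codons under the standard genetic code
#'
#' @param codon Character vector of 3-letter codons (case-insensitive).
#' @return One-letter amino acids, `"*"` for stop.
#' @export
#' @examples
#' translate_codon(c("CTG", "ccg", "TGA"))
translate_codon <- function(codon) {
  aa <- unname(GENETIC_CODE_TABLE[toupper(codon)])
  if (anyNA(aa)) {
    abort(paste0("not a codon: ", codon[is.na(aa)][1]))
  }
  aa
}

#' Watson-Crick complement
#'
#' @param x Character vector of nucleotide strings.
#' @return The complement (not reversed), case preserved.
#' @export
complement_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of nucleotide strings.
#' @return Reverse complements.
#' @export
reverse_complement <- function(x) {
  purrr::map_chr(x, function(s) {
    paste(rev(strsplit(complement_base(s), "", fixed = TRUE)[[1]]),
          collapse = "")
  })
}

#' Map a genomic position to its CDS coordinate
#'
#' Counts bases along `cds_segments` in transcription order: ascending
#' within a segment for `+` strand genes, descending for `-` strand genes
#' (so for `-` strand the highest genomic coordinate of the first segment is
#' c.1).
#'
#' @param model One gene model (a one-row tibble or a list with fields
#'   `chrom`, `strand`, `cds_segments`).
#' @param chrom Chromosome of the query position.
#' @param pos 1-based genomic position.
#' @return The 1-based CDS coordinate, or `NA` if `pos` lies outside all
#'   segments (or on another chromosome).
#' @export
cds_position <- function(model, chrom, pos) {
  model <- as_model_row(model)
  if (as.character(chrom) != model$chrom) return(NA_integer_)
  seg <- model$cds_segments
  offset <- 0L
  for (i in seq_len(nrow(seg))) {
    s <- seg$start[i]; e <- seg$end[i]
    if (pos >= s && pos <= e) {
      within <- if (model$strand == "+") pos - s + 1L else e - pos + 1L
      return(offset + within)
    }
    offset <- offset + (e - s + 1L)
  }
  NA_integer_
}

#' Map a CDS coordinate back to its genomic position
#'
#' Inverse of [cds_position()].
#'
#' @inheritParams cds_position
#' @param cdna_pos 1-based CDS coordinate.
#' @return The genomic position, or `NA` if `cdna_pos` exceeds the CDS.
#' @export
genomic_position <- function(model, cdna_pos) {
  model <- as_model_row(model)
  seg <- model$cds_segments
  remaining <- as.integer(cdna_pos)
  if (remaining < 1L) abort("cdna_pos must be >= 1")
  for (i in seq_len(nrow(seg))) {
    len <- seg$end[i] - seg$start[i] + 1L
    if (remaining <= len) {
      return(if (model$strand == "+") seg$start[i] + remaining - 1L
             else seg$end[i] - remaining + 1L)
    }
    remaining <- remaining - len
  }
  NA_integer_
}

as_model_row <- function(model) {
  if (is_tibble(model)) {
    if (nrow(model) != 1L) abort("expected exactly one gene model")
    list(
      symbol = model$symbol, accession = model$accession,
      chrom = as.character(model$chrom), strand = model$strand,
      cds_segments = model$cds_segments[[1]], cds_seq = model$cds_seq
    )
  } else {
    model
  }
}

#' Codon arithmetic for a CDS coordinate
#'
#' The residue index is `ceiling(cdna_pos / 3)`; the within-codon offset is
#' `((cdna_pos - 1) %% 3) + 1`.
#'
#' @param cdna_pos 1-based CDS coordinate(s).
#' @return Tibble with `cdna_pos`, `codon_index`, `codon_offset`.
#' @export
#' @examples
#' codon_arithmetic(143) # residue 48, middle base
codon_arithmetic <- function(cdna_pos) {
  cdna_pos <- as.integer(cdna_pos)
  if (any(is.na(cdna_pos)) || any(cdna_pos < 1L)) {
    abort("cdna_pos must be a positive integer")
  }
  tibble(
    cdna_pos = cdna_pos,
    codon_index = as.integer(ceiling(cdna_pos / 3)),
    codon_offset = ((cdna_pos - 1L) %% 3L) + 1L
  )
}

capital_at <- function(codon) {
  caps <- which(strsplit(codon, "", fixed = TRUE)[[1]] %in% LETTERS)
  if (length(caps) != 1L) {
    abort(paste0("codon '", codon, "' must carry exactly one capital letter"))
  }
  caps
}

#' Infer transcript strand from genomic alleles and codon notation
#'
#' In the capitalised-codon notation the single capital letter marks the
#' variant base on the coding strand. The gene lies on `+` when the capitals
#' equal the genomic ref/alt, on `-` when they equal their Watson-Crick
#' complements; anything else is an annotation inconsistency.
#'
#' @param genomic_ref,genomic_alt Genomic alleles (single letters).
#' @param codon_ref,codon_alt Codon strings with the variant base
#'   capitalised (e.g. `"cTg"`, `"cCg"`).
#' @param codon_offset Expected position of the capital within the codon
#'   (1-3).
#' @return `"+"` or `"-"`.
#' @export
#' @examples
#' infer_strand("T", "C", "cTg", "cCg", 2) # "+"
#' infer_strand("C", "T", "Gat", "Aat", 1) # "-"
infer_strand <- function(genomic_ref, genomic_alt, codon_ref, codon_alt,
                         codon_offset) {
  pr <- capital_at(codon_ref)
  pa <- capital_at(codon_alt)
  if (pr != codon_offset || pa != codon_offset) {
    abort(sprintf(
      "capital letter at position %d/%d, expected %d (%s/%s)",
      pr, pa, codon_offset, codon_ref, codon_alt
    ))
  }
  cr <- toupper(substr(codon_ref, pr, pr))
  ca <- toupper(substr(codon_alt, pa, pa))
  gr <- toupper(genomic_ref); ga <- toupper(genomic_alt)
  if (cr == gr && ca == ga) return("+")
  if (cr == complement_base(gr) && ca == complement_base(ga)) return("-")
  abort(sprintf(
    "codon capitals %s>%s match neither %s>%s nor its complement",
    cr, ca, gr, ga
  ))
}

render_codon <- function(codon_lower, offset, base_upper) {
  out <- tolower(codon_lower)
  substr(out, offset, offset) <- toupper(base_upper)
  out
}

classify_effect <- function(aa_ref, aa_alt, codon_index) {
  if (aa_ref == aa_alt) return("synonymous")
  if (aa_alt == "*") return("nonsense")
  if (codon_index == 1L && aa_ref == "M") return("start-lost")
  "missense"
}

#' Annotate a single SNV against a gene model
#'
#' Maps the genomic position into the CDS, complements the alleles for `-`
#' strand genes, extracts the reference codon from `cds_seq`, substitutes
#' the variant base, translates both codons, and classifies the effect.
#' The returned codon strings follow the convention of a lowercase codon
#' with the variant base capitalised.
#'
#' @param variant A one-row tibble or list with `chrom`, `pos`, `ref`,
#'   `alt` (single-nucleotide alleles).
#' @param model A gene model (one row).
#' @return A one-row tibble (`cdna_pos`, `ref_nt`, `alt_nt`, `codon_index`,
#'   `codon_offset`, `codon_ref`, `codon_alt`, `aa_ref`, `aa_alt`,
#'   `effect_class`, `hgvs_c`, `hgvs_p`), or `NULL` when the position is
#'   non-coding for this model.
#' @export
annotate_variant <- function(variant, model) {
  model <- as_model_row(model)
  v <- if (is_tibble(variant)) as.list(variant[1, ]) else variant
  if (nchar(v$ref) != 1L || nchar(v$alt) != 1L) {
    abort("annotate_variant expects a single-nucleotide variant")
  }
  cdna <- cds_position(model, v$chrom, v$pos)
  if (is.na(cdna)) return(NULL)

  ref_nt <- toupper(v$ref); alt_nt <- toupper(v$alt)
  if (model$strand == "-") {
    ref_nt <- complement_base(ref_nt)
    alt_nt <- complement_base(alt_nt)
  }
  seq_ref <- toupper(substr(model$cds_seq, cdna, cdna))
  if (seq_ref != ref_nt) {
    abort(sprintf(
      "reference mismatch in %s at c.%d: CDS has %s, variant ref implies %s",
      model$symbol, cdna, seq_ref, ref_nt
    ))
  }
  ca <- codon_arithmetic(cdna)
  ci <- ca$codon_index; off <- ca$codon_offset
  codon0 <- substr(model$cds_seq, 3L * (ci - 1L) + 1L, 3L * ci)
  codon_alt_plain <- codon0
  substr(codon_alt_plain, off, off) <- tolower(alt_nt)
  aa_ref <- translate_codon(codon0)
  aa_alt <- translate_codon(codon_alt_plain)
  eff <- classify_effect(aa_ref, aa_alt, ci)
  tibble(
    gene = model$symbol,
    accession = model$accession,
    cdna_pos = cdna,
    ref_nt = ref_nt, alt_nt = alt_nt,
    codon_index = ci, codon_offset = off,
    codon_ref = render_codon(codon0, off, ref_nt),
    codon_alt = render_codon(codon_alt_plain, off, alt_nt),
    aa_ref = aa_ref, aa_alt = aa_alt,
    effect_class = eff,
    hgvs_c = sprintf("c.%d%s>%s", cdna, ref_nt, alt_nt),
    hgvs_p = if (eff == "synonymous") sprintf("p.%s%d=", aa_ref, ci)
             else sprintf("p.%s%d%s", aa_ref, ci, aa_alt)
  )
}

#' Annotate a variant table against a set of gene models
#'
#' Each SNV is matched to the gene models on its chromosome whose CDS
#' segments contain its position; indels and non-coding positions get `NA`
#' effect columns. Positions hitting more than one model are annotated
#' against the first matching model (one model per gene is assumed).
#'
#' @param variants Variant tibble (as from [read_vcf()]).
#' @param gene_models Gene-model tibble.
#' @return `variants` with annotation columns appended.
#' @export
annotate_variants <- function(variants, gene_models) {
  eff_cols <- tibble(
    gene = NA_character_, accession = NA_character_,
    cdna_pos = NA_integer_, ref_nt = NA_character_, alt_nt = NA_character_,
    codon_index = NA_integer_, codon_offset = NA_integer_,
    codon_ref = NA_character_, codon_alt = NA_character_,
    aa_ref = NA_character_, aa_alt = NA_character_,
    effect_class = NA_character_, hgvs_c = NA_character_,
    hgvs_p = NA_character_
  )
  if (nrow(variants) == 0L) {
    out <- dplyr::bind_cols(variants, eff_cols[0, ])
    attr(out, "samples") <- attr(variants, "samples")
    return(out)
  }
  ann <- purrr::map(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (v$vclass != "SNV") return(eff_cols)
    on_chrom <- gene_models[gene_models$chrom == v$chrom, ]
    for (j in seq_len(nrow(on_chrom))) {
      hit <- annotate_variant(v, on_chrom[j, ])
      if (!is.null(hit)) return(hit)
    }
    eff_cols
  })
  out <- dplyr::bind_cols(variants, bind_rows(ann))
  attr(out, "samples") <- attr(variants, "samples")
  out
}

parse_aa_sub <- function(aa_sub) {
  m <- stringr::str_match(aa_sub, "^p\\.([A-Z\\*])(\\d+)([A-Z\\*])$")
  if (anyNA(m[, 1])) {
    abort(paste0("cannot parse amino-acid substitution: ",
                 aa_sub[is.na(m[, 1])][1]))
  }
  tibble(aa_ref = m[, 2], codon_index = as.integer(m[, 3]), aa_alt = m[, 4])
}

#' Re-derive and check printed candidate annotations
#'
#' For each row of a candidate table (genomic ref/alt, CDS position, codon
#' strings with the variant base capitalised, and a printed `p.` amino-acid
#' substitution), recomputes the residue index and codon offset from the
#' CDS position, infers the strand from the allele/codon pair, translates
#' both codon strings, and compares everything against the printed
#' substitution.
#'
#' @param rows Tibble with columns `ref`, `alt`, `cdna_pos`, `codon_ref`,
#'   `codon_alt`, `aa_sub` (e.g. `"p.L48P"`).
#' @return `rows` with appended columns `codon_index`, `codon_offset`,
#'   `strand`, `aa_ref_calc`, `aa_alt_calc`, `match` (logical). The number
#'   of matching rows is `sum(out$match)`.
#' @export
verify_codon_annotations <- function(rows) {
  printed <- parse_aa_sub(rows$aa_sub)
  out <- purrr::map(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    ca <- codon_arithmetic(r$cdna_pos)
    res <- tibble(
      codon_index = ca$codon_index,
      codon_offset = ca$codon_offset,
      strand = NA_character_,
      aa_ref_calc = NA_character_,
      aa_alt_calc = NA_character_,
      match = FALSE
    )
    ok <- tryCatch({
      res$strand <- infer_strand(r$ref, r$alt, r$codon_ref, r$codon_alt,
                                 ca$codon_offset)
      res$aa_ref_calc <- translate_codon(r$codon_ref)
      res$aa_alt_calc <- translate_codon(r$codon_alt)
      TRUE
    }, error = function(e) FALSE)
    if (ok) {
      res$match <- res$codon_index == printed$codon_index[i] &&
        res$aa_ref_calc == printed$aa_ref[i] &&
        res$aa_alt_calc == printed$aa_alt[i] &&
        res$aa_ref_calc != res$aa_alt_calc
    }
    res
  })
  dplyr::bind_cols(rows, bind_rows(out))
}
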