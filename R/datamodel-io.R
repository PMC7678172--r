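# Domain tables and readers/writers for the minimal formats the pipeline
# consumes: a strict biallelic VCF dialect, gene-model TSVs, candidate-gene
# lists, and phenotype/genotyping panel TSVs.

#' Build a variant key
#'
#' A variant key is the canonical `"chrom:pos:ref:alt"` string used to match
#' variants between the VCF, panel columns, and reports.
#'
#' @param chrom Chromosome label.
#' @param pos 1-based genomic position.
#' @param ref,alt Reference and alternative allele strings.
#' @return A character vector of keys.
#' @export
#' @examples
#' variant_key("18", 14705518, "T", "C")
variant_key <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d:%s:%s", as.character(chrom), as.integer(pos),
          toupper(ref), toupper(alt))
}

#' Split variant keys back into their fields
#'
#' @param key Character vector of `"chrom:pos:ref:alt"` keys.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
parse_variant_key <- function(key) {
  parts <- stringr::str_split_fixed(key, stringr::fixed(":"), 4)
  bad <- parts[, 4] == "" | parts[, 3] == ""
  if (any(bad)) {
    abort(paste0("malformed variant key: ", key[bad][1]))
  }
  tibble(
    chrom = parts[, 1],
    pos = as.integer(parts[, 2]),
    ref = toupper(parts[, 3]),
    alt = toupper(parts[, 4])
  )
}

#' Classify variants as SNV or indel
#'
#' A site is an SNV exactly when both alleles are single nucleotides;
#' anything else (length difference or multi-base substitution) is treated
#' as an indel-class site for the proximity filter.
#'
#' @param ref,alt Allele strings.
#' @return Character vector, `"SNV"` or `"INDEL"`.
#' @export
variant_class <- function(ref, alt) {
  if_else(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "INDEL")
}

gt_from_allele_string <- function(allele_string, ref, alt) {
  a <- toupper(allele_string)
  # accept both orders for heterozygotes ("TC" and "CT")
  dplyr::case_when(
    is.na(a) | a %in% c("", ".", "./.", "..") ~ NA_character_,
    a == paste0(ref, ref) ~ "HOM_REF",
    a == paste0(ref, alt) | a == paste0(alt, ref) ~ "HET",
    a == paste0(alt, alt) ~ "HOM_ALT",
    TRUE ~ "BAD"
  )
}

#' Render a genotype code as its two-allele string
#'
#' @param gt Genotype codes (`"HOM_REF"`, `"HET"`, `"HOM_ALT"`, or `NA`).
#' @param ref,alt Allele letters of the site.
#' @return Character vector such as `"TT"`, `"TC"`, `"CC"`; `NA` passes
#'   through.
#' @export
#' @examples
#' allele_string(c("HOM_REF", "HET", "HOM_ALT"), "T", "C")
allele_string <- function(gt, ref, alt) {
  dplyr::case_when(
    is.na(gt) ~ NA_character_,
    gt == "HOM_REF" ~ paste0(ref, ref),
    gt == "HET" ~ paste0(ref, alt),
    gt == "HOM_ALT" ~ paste0(alt, alt),
    TRUE ~ NA_character_
  )
}

gt_from_vcf_field <- function(field, line_no) {
  gt <- sub(":.*$", "", field)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  if (gt %in% c("./.", ".", ".|.")) {
    return(NA_character_)
  }
  alleles <- strsplit(gt, "/", fixed = TRUE)[[1]]
  if (length(alleles) != 2L || !all(alleles %in% c("0", "1"))) {
    if (any(suppressWarnings(as.integer(alleles)) > 1L, na.rm = TRUE)) {
      abort(sprintf(
        "unsupported multi-allelic genotype '%s' at line %d", gt, line_no
      ))
    }
    abort(sprintf("malformed genotype '%s' at line %d", gt, line_no))
  }
  n_alt <- sum(alleles == "1")
  GT_LEVELS[n_alt + 1L]
}

#' Read a minimal biallelic VCF
#'
#' Parses the strict dialect the pipeline uses: VCFv4.2-style headers, one
#' biallelic SNV or indel per record, `GT` as the first `FORMAT` key.
#' Phased separators (`|`) are normalised to unphased; `./.` becomes a
#' missing genotype. Multi-allelic records (comma in `ALT` or allele index
#' above 1) are rejected.
#'
#' @param path Path to the VCF file.
#' @return A tibble with one row per variant: `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `vclass`, `key`, and one genotype column per sample (values
#'   `"HOM_REF"`/`"HET"`/`"HOM_ALT"`/`NA`). Sample names are recorded in the
#'   `"samples"` attribute.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  header_idx <- which(startsWith(lines, "#CHROM"))
  if (length(header_idx) != 1L) {
    abort("VCF must contain exactly one #CHROM header line")
  }
  header <- strsplit(lines[header_idx], "\t", fixed = TRUE)[[1]]
  if (length(header) < 10L) {
    abort("VCF header declares no samples")
  }
  samples <- header[10:length(header)]

  body_idx <- setdiff(seq_along(lines), seq_len(header_idx))
  body_idx <- body_idx[!startsWith(lines[body_idx], "#") &
                         nzchar(trimws(lines[body_idx]))]

  empty <- tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), qual = double(), vclass = character(),
    key = character()
  )
  for (s in samples) empty[[s]] <- character()
  if (length(body_idx) == 0L) {
    attr(empty, "samples") <- samples
    return(empty)
  }

  rows <- purrr::map(body_idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L + length(samples)) {
      abort(sprintf("malformed VCF record at line %d: %d fields", i, length(f)))
    }
    if (grepl(",", f[5], fixed = TRUE)) {
      abort(sprintf("unsupported multi-allelic record at line %d", i))
    }
    pos <- suppressWarnings(as.integer(f[2]))
    qual <- suppressWarnings(as.numeric(f[6]))
    if (is.na(pos) || pos < 1L) {
      abort(sprintf("malformed POS at line %d: '%s'", i, f[2]))
    }
    if (is.na(qual) || qual < 0) {
      abort(sprintf("malformed QUAL at line %d: '%s'", i, f[6]))
    }
    if (!startsWith(f[9], "GT")) {
      abort(sprintf("FORMAT must begin with GT at line %d", i))
    }
    ref <- toupper(f[4]); alt <- toupper(f[5])
    if (ref == alt) abort(sprintf("REF equals ALT at line %d", i))
    gts <- purrr::map_chr(f[10:(9 + length(samples))], gt_from_vcf_field, i)
    out <- tibble(
      chrom = f[1], pos = pos, ref = ref, alt = alt, qual = qual,
      vclass = variant_class(ref, alt),
      key = variant_key(f[1], pos, ref, alt)
    )
    for (k in seq_along(samples)) out[[samples[k]]] <- gts[k]
    out
  })
  out <- bind_rows(rows)
  attr(out, "samples") <- samples
  out
}

#' Write the minimal VCF dialect
#'
#' Inverse of [read_vcf()]: `read_vcf(write_vcf(x, path))` reproduces `x`
#' for the supported dialect.
#'
#' @param variants Tibble as returned by [read_vcf()] (genotype columns
#'   named by sample).
#' @param path Output path.
#' @param samples Sample column names; defaults to the `"samples"` attribute.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, samples = NULL) {
  samples <- samples %||% attr(variants, "samples")
  if (is.null(samples)) {
    samples <- setdiff(
      names(variants),
      c("chrom", "pos", "ref", "alt", "qual", "vclass", "key")
    )
  }
  missing_cols <- setdiff(samples, names(variants))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "inconsistent sample columns; missing: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  gt_code <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- purrr::map_chr(seq_len(nrow(variants)), function(i) {
    gts <- purrr::map_chr(samples, function(s) {
      g <- variants[[s]][i]
      if (is.na(g)) "./." else gt_code[[g]]
    })
    paste(c(
      variants$chrom[i], format(variants$pos[i], scientific = FALSE), ".",
      variants$ref[i], variants$alt[i],
      format(variants$qual[i], scientific = FALSE, trim = TRUE),
      ".", ".", "GT", gts
    ), collapse = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a candidate-gene list
#'
#' One gene symbol per line; `#` starts a comment. Symbols are upper-cased
#' and de-duplicated.
#'
#' @param path Path to the list file.
#' @return Character vector of unique upper-case symbols, in first-seen
#'   order.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  syms <- unique(toupper(lines[nzchar(lines)]))
  if (length(syms) == 0L) {
    warn(paste0("gene list is empty: ", path))
  }
  syms
}

parse_segments <- function(txt) {
  purrr::map(txt, function(s) {
    pieces <- strsplit(s, ";", fixed = TRUE)[[1]]
    m <- stringr::str_split_fixed(pieces, stringr::fixed("-"), 2)
    tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  })
}

format_segments <- function(segments) {
  purrr::map_chr(segments, function(seg) {
    paste(sprintf("%d-%d", seg$start, seg$end), collapse = ";")
  })
}

#' Validate a gene-model table
#'
#' Checks, per model: segments are 1-based with `start <= end`, mutually
#' non-overlapping, their total length equals `nchar(cds_seq)`, and the CDS
#' length is divisible by 3.
#'
#' @param models Gene-model tibble (see [read_gene_models()]).
#' @return `models`, invisibly; aborts with the offending gene on failure.
#' @export
validate_gene_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    seg <- models$cds_segments[[i]]
    sym <- models$symbol[i]
    if (any(seg$end < seg$start) || any(seg$start < 1L)) {
      abort(paste0("bad CDS segment bounds in gene ", sym))
    }
    ord <- seg[order(seg$start), , drop = FALSE]
    if (nrow(ord) > 1L && any(ord$start[-1] <= ord$end[-nrow(ord)])) {
      abort(paste0("overlapping CDS segments in gene ", sym))
    }
    total <- sum(seg$end - seg$start + 1L)
    if (total != nchar(models$cds_seq[i])) {
      abort(sprintf(
        "gene %s: segment span %d != CDS length %d",
        sym, total, nchar(models$cds_seq[i])
      ))
    }
    if (total %% 3L != 0L) {
      abort(sprintf("gene %s: CDS length %d not divisible by 3", sym, total))
    }
  }
  invisible(models)
}

#' Read a gene-model TSV
#'
#' Expected columns: `symbol`, `accession`, `chrom`, `strand` (`+`/`-`),
#' `cds_segments` (semicolon-joined `start-end` 1-based inclusive intervals,
#' in transcription order), `cds_seq` (coding-strand sequence).
#'
#' @param path Path to the TSV.
#' @return A tibble with `cds_segments` parsed into a list-column of
#'   `start`/`end` tibbles.
#' @export
read_gene_models <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("symbol", "accession", "chrom", "strand", "cds_segments", "cds_seq")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("gene-model TSV lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(raw$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  models <- tibble(
    symbol = toupper(raw$symbol),
    accession = raw$accession,
    chrom = raw$chrom,
    strand = raw$strand,
    cds_segments = parse_segments(raw$cds_segments),
    cds_seq = tolower(raw$cds_seq)
  )
  validate_gene_models(models)
}

#' Write a gene-model table as TSV
#'
#' @param models Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  out <- tibble(
    symbol = models$symbol,
    accession = models$accession,
    chrom = models$chrom,
    strand = models$strand,
    cds_segments = format_segments(models$cds_segments),
    cds_seq = models$cds_seq
  )
  readr::write_tsv(out, path)
  invisible(path)
}

PHENOTYPE_MAP <- c(
  "white" = "WHITE",
  "wt" = "PIGMENTED",
  "wildtype" = "PIGMENTED",
  "wildtype brown" = "PIGMENTED",
  "brown" = "PIGMENTED",
  "pigmented" = "PIGMENTED",
  "dark pigmented" = "PIGMENTED",
  "wt/dark pigmented" = "PIGMENTED"
)

#' Read a phenotype/genotyping panel TSV
#'
#' Expected columns: `animal_id`, `location`, `origin` (`G` game park, `H`
#' hunting ground), `phenotype`, then one column per variant key
#' (`"chrom:pos:ref:alt"`) holding two-letter genotypes such as `"TT"`,
#' `"TC"`, `"CC"` (empty or `.` = missing). Phenotype labels are mapped to
#' the binary `PIGMENTED`/`WHITE` coding: wildtype brown and dark pigmented
#' animals are both `PIGMENTED`.
#'
#' @param path Path to the TSV.
#' @return A tibble, one row per animal, with genotype columns kept as
#'   allele strings; variant-key columns are listed in the
#'   `"variant_cols"` attribute.
#' @export
read_panel <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("animal_id", "location", "origin", "phenotype")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("panel TSV lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  phen <- unname(PHENOTYPE_MAP[tolower(trimws(raw$phenotype))])
  if (anyNA(phen)) {
    bad <- which(is.na(phen))
    abort(sprintf(
      "unknown phenotype '%s' in panel row %d (animal %s)",
      raw$phenotype[bad[1]], bad[1], raw$animal_id[bad[1]]
    ))
  }
  out <- raw
  out$phenotype <- phen
  variant_cols <- setdiff(names(out), need)
  attr(out, "variant_cols") <- variant_cols
  out
}

#' Long genotype calls from a panel
#'
#' Converts a panel's allele-string columns into one row per animal and
#' variant, with genotype codes derived from the variant key's ref/alt
#' letters. Unparseable strings raise an error naming the animal.
#'
#' @param panel Panel tibble from [read_panel()] (or one shaped like it).
#' @param variant_cols Variant-key columns; defaults to the attribute set by
#'   [read_panel()], else all columns beyond the four fixed ones.
#' @return Tibble with `animal_id`, `phenotype`, `variant_key`,
#'   `allele_string`, `gt` (`NA` when missing).
#' @export
panel_genotypes <- function(panel, variant_cols = NULL) {
  variant_cols <- variant_cols %||% attr(panel, "variant_cols") %||%
    setdiff(names(panel), c("animal_id", "location", "origin", "phenotype"))
  if (length(variant_cols) == 0L) {
    return(tibble(
      animal_id = character(), phenotype = character(),
      variant_key = character(), allele_string = character(),
      gt = character()
    ))
  }
  long <- tidyr::pivot_longer(
    panel[, c("animal_id", "phenotype", variant_cols)],
    cols = all_of(variant_cols),
    names_to = "variant_key", values_to = "allele_string"
  )
  keys <- parse_variant_key(long$variant_key)
  long$gt <- gt_from_allele_string(long$allele_string, keys$ref, keys$alt)
  bad <- which(long$gt == "BAD")
  if (length(bad) > 0) {
    abort(sprintf(
      "genotype '%s' for animal %s is not consistent with %s",
      long$allele_string[bad[1]], long$animal_id[bad[1]],
      long$variant_key[bad[1]]
    ))
  }
  long
}

`%||%` <- function(x, y) if (is.null(x)) y else x
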