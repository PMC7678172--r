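# The candidate filtering cascade: indel-proximity/QUAL quality control,
# candidate-gene subsetting, non-synonymous restriction, recessive trio
# filter, and staged validation-panel refinement, with a per-stage audit.

#' Remove SNVs shadowed by nearby, better-supported indels
#'
#' An SNV is dropped exactly when some indel on the same chromosome lies
#' within `window` base pairs of it (distance between POS fields, inclusive)
#' and the SNV's QUAL is strictly lower than that indel's QUAL. Indels are
#' never removed by this rule.
#'
#' @param variants Variant tibble with `chrom`, `pos`, `qual`, `vclass`.
#' @param window Proximity window in bp (default 3).
#' @return The filtered tibble.
#' @export
filter_near_indels <- function(variants, window = 3) {
  if (nrow(variants) == 0L) return(variants)
  indels <- variants[variants$vclass == "INDEL",
                     c("chrom", "pos", "qual"), drop = FALSE]
  if (nrow(indels) == 0L) return(variants)
  drop <- purrr::map_lgl(seq_len(nrow(variants)), function(i) {
    if (variants$vclass[i] != "SNV") return(FALSE)
    near <- indels$chrom == variants$chrom[i] &
      abs(indels$pos - variants$pos[i]) <= window
    any(near & variants$qual[i] < indels$qual)
  })
  out <- variants[!drop, , drop = FALSE]
  attr(out, "samples") <- attr(variants, "samples")
  out
}

#' Keep variants inside listed candidate genes
#'
#' A variant is retained when its position falls inside a CDS segment of a
#' gene model whose symbol is on the candidate list. Listed genes without a
#' model produce a warning and are skipped.
#'
#' @param variants Variant tibble.
#' @param gene_models Gene-model tibble.
#' @param gene_list Character vector of gene symbols (case-insensitive).
#' @return The retained variants with a `gene` column giving the matched
#'   symbol.
#' @export
subset_to_genes <- function(variants, gene_models, gene_list) {
  gene_list <- toupper(gene_list)
  absent <- setdiff(gene_list, gene_models$symbol)
  if (length(absent) > 0) {
    warn(paste0("no gene model for listed gene(s): ",
                paste(absent, collapse = ", ")))
  }
  models <- gene_models[gene_models$symbol %in% gene_list, , drop = FALSE]
  hit_gene <- purrr::map_chr(seq_len(nrow(variants)), function(i) {
    on_chrom <- models[models$chrom == variants$chrom[i], , drop = FALSE]
    for (j in seq_len(nrow(on_chrom))) {
      seg <- on_chrom$cds_segments[[j]]
      if (any(variants$pos[i] >= seg$start & variants$pos[i] <= seg$end)) {
        return(on_chrom$symbol[j])
      }
    }
    NA_character_
  })
  out <- variants[!is.na(hit_gene), , drop = FALSE]
  out$gene <- hit_gene[!is.na(hit_gene)]
  attr(out, "samples") <- attr(variants, "samples")
  out
}

#' Keep amino-acid-changing variants
#'
#' Retains effect classes `missense`, `nonsense`, `start-lost`; drops
#' synonymous and unannotated (non-coding or indel) rows.
#'
#' @param annotated Variant tibble carrying an `effect_class` column (see
#'   [annotate_variants()]).
#' @return The filtered tibble.
#' @export
nonsynonymous_only <- function(annotated) {
  keep <- !is.na(annotated$effect_class) &
    annotated$effect_class %in% c("missense", "nonsense", "start-lost")
  out <- annotated[keep, , drop = FALSE]
  attr(out, "samples") <- attr(annotated, "samples")
  out
}

#' Recessive trio filter
#'
#' Under a fully penetrant recessive model the affected animal must be
#' homozygous for the alternative allele and its unaffected first-degree
#' relative (the obligate carrier) heterozygous. A variant is retained only
#' for the genotype pair (`HOM_ALT`, `HET`); a missing genotype in either
#' sample removes it.
#'
#' @param variants Variant tibble with genotype columns.
#' @param affected_id,carrier_id Names of the genotype columns for the
#'   affected and carrier samples.
#' @return The retained variants.
#' @export
recessive_trio_filter <- function(variants, affected_id, carrier_id) {
  for (s in c(affected_id, carrier_id)) {
    if (!s %in% names(variants)) {
      abort(paste0("sample column not found: ", s))
    }
  }
  keep <- !is.na(variants[[affected_id]]) & !is.na(variants[[carrier_id]]) &
    variants[[affected_id]] == "HOM_ALT" & variants[[carrier_id]] == "HET"
  out <- variants[keep, , drop = FALSE]
  attr(out, "samples") <- attr(variants, "samples")
  out
}

#' Refine candidates against a genotyped validation panel
#'
#' A candidate survives when every genotyped WHITE animal in the panel is
#' `HOM_ALT` and every genotyped PIGMENTED animal is not (`HOM_REF` or
#' `HET`) — exact concordance under the recessive model. Missing genotypes
#' never disqualify a candidate; they are counted in `n_missing`.
#'
#' @param candidates Variant tibble with a `key` column.
#' @param panel Panel tibble (see [read_panel()]); variant columns matching
#'   candidate keys are used, candidates without a panel column pass
#'   through untested.
#' @return The surviving candidates with an `n_missing` column giving the
#'   number of panel animals lacking a genotype at the site.
#' @export
refine_with_panel <- function(candidates, panel) {
  if (nrow(candidates) == 0L || nrow(panel) == 0L) {
    candidates$n_missing <- rep(0L, nrow(candidates))
    return(candidates)
  }
  gts <- panel_genotypes(panel)
  verdict <- purrr::map(candidates$key, function(k) {
    g <- gts[gts$variant_key == k, , drop = FALSE]
    if (nrow(g) == 0L) return(list(ok = TRUE, n_missing = 0L))
    n_missing <- sum(is.na(g$gt))
    g <- g[!is.na(g$gt), , drop = FALSE]
    ok <- all(g$gt[g$phenotype == "WHITE"] == "HOM_ALT") &&
      all(g$gt[g$phenotype == "PIGMENTED"] != "HOM_ALT")
    list(ok = ok, n_missing = n_missing)
  })
  keep <- purrr::map_lgl(verdict, "ok")
  out <- candidates[keep, , drop = FALSE]
  out$n_missing <- purrr::map_int(verdict, "n_missing")[keep]
  attr(out, "samples") <- attr(candidates, "samples")
  out
}

n_genes_of <- function(variants) {
  if ("gene" %in% names(variants)) {
    dplyr::n_distinct(variants$gene, na.rm = TRUE)
  } else {
    NA_integer_
  }
}

#' Run the full candidate filtering cascade
#'
#' Applies, in order: indel-proximity/QUAL control, candidate-gene
#' subsetting, coding-effect annotation with restriction to amino-acid
#' changing variants, the recessive trio filter, and one refinement pass
#' per validation panel. Stage-by-stage counts are recorded.
#'
#' @param variants Variant tibble with genotype columns (as from
#'   [read_vcf()]), or a path to a VCF file.
#' @param gene_models Gene-model tibble.
#' @param gene_list Character vector of candidate gene symbols.
#' @param affected_id,carrier_id Sample names of the affected animal and
#'   its obligate carrier.
#' @param panels Ordered list of validation panels (each as from
#'   [read_panel()]); may be empty.
#' @param window Indel-proximity window in bp.
#' @return A `cascade_report` object: list with `stages` (tibble of
#'   `stage`, `n_in`, `n_out`, `n_genes`) and `candidates` (the surviving
#'   variant tibble).
#' @export
run_cascade <- function(variants, gene_models, gene_list,
                        affected_id, carrier_id,
                        panels = list(), window = 3) {
  if (is.character(variants) && length(variants) == 1L) {
    variants <- read_vcf(variants)
  }
  samples <- attr(variants, "samples") %||%
    setdiff(names(variants),
            c("chrom", "pos", "ref", "alt", "qual", "vclass", "key"))
  for (s in c(affected_id, carrier_id)) {
    if (!s %in% samples) {
      abort(paste0("sample '", s, "' is not in the call set (",
                   paste(samples, collapse = ", "), ")"))
    }
  }
  stages <- list()
  log_stage <- function(name, n_in, after) {
    stages[[length(stages) + 1L]] <<- tibble(
      stage = name, n_in = n_in, n_out = nrow(after),
      n_genes = n_genes_of(after)
    )
    after
  }
  cur <- variants
  cur <- log_stage("indel_proximity_qc", nrow(variants),
                   filter_near_indels(cur, window = window))
  cur <- log_stage("candidate_gene_subset", nrow(cur),
                   subset_to_genes(cur, gene_models, gene_list))
  ann <- annotate_variants(cur[, setdiff(names(cur), "gene"), drop = FALSE],
                           gene_models)
  cur <- log_stage("nonsynonymous", nrow(cur), nonsynonymous_only(ann))
  cur <- log_stage("recessive_trio", nrow(cur),
                   recessive_trio_filter(cur, affected_id, carrier_id))
  for (i in seq_along(panels)) {
    nm <- names(panels)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("panel_", i)
    cur <- log_stage(nm, nrow(cur), refine_with_panel(cur, panels[[i]]))
  }
  structure(
    list(stages = bind_rows(stages), candidates = cur),
    class = "cascade_report"
  )
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Candidate filtering cascade\n")
  print(x$stages)
  cat("final candidates:", nrow(x$candidates), "\n")
  if (nrow(x$candidates) > 0 && "hgvs_p" %in% names(x$candidates)) {
    shown <- head(x$candidates, 10)
    cat(paste0("  ", shown$gene, " ", shown$hgvs_c, " (", shown$hgvs_p, ")",
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @rdname run_cascade
#' @param x A `cascade_report`.
#' @param ... Unused.
#' @method tidy cascade_report
#' @export
tidy.cascade_report <- function(x, ...) {
  x$stages
}

#' @rdname run_cascade
#' @method glance cascade_report
#' @export
glance.cascade_report <- function(x, ...) {
  tibble(
    n_input = x$stages$n_in[1],
    n_candidates = nrow(x$candidates),
    n_stages = nrow(x$stages),
    n_genes_final = n_genes_of(x$candidates)
  )
}

#' @rdname run_cascade
#' @param object A `cascade_report`.
#' @method autoplot cascade_report
#' @export
autoplot.cascade_report <- function(object, ...) {
  d <- object$stages
  d$stage <- factor(d$stage, levels = rev(d$stage))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_out, y = .data$stage)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), hjust = -0.2) +
    ggplot2::labs(
      x = "variants surviving the stage", y = NULL,
      title = "Candidate filtering cascade"
    ) +
    ggplot2::theme_minimal()
}
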