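# Exact genotype-phenotype association on the full cohort: 2x3 contingency
# table, Fisher's exact r x c test by margin-constrained enumeration in log
# space, carrier frequency, recessive-model concordance, cohort accounting.

#' Build the phenotype-by-genotype contingency table
#'
#' Counts genotyped animals into a 2x3 table with rows
#' (`PIGMENTED`, `WHITE`) and columns (hom-ref, het, hom-alt) labelled with
#' the site's allele letters (e.g. `TT`/`TC`/`CC`). Animals with a missing
#' genotype are excluded from the counts and reported in `n_missing`.
#'
#' @param panel Panel tibble (see [read_panel()]).
#' @param variant_key `"chrom:pos:ref:alt"` key naming the genotype column.
#' @return A `genotype_table`: an integer matrix with attributes
#'   `variant_key`, `n_missing`, and `gt_levels` (the genotype code of each
#'   column).
#' @export
build_table <- function(panel, variant_key) {
  key <- parse_variant_key(variant_key)
  labels <- allele_string(GT_LEVELS, key$ref, key$alt)
  m <- matrix(0L, nrow = 2, ncol = 3,
              dimnames = list(c("PIGMENTED", "WHITE"), labels))
  n_missing <- 0L
  if (variant_key %in% names(panel)) {
    gts <- panel_genotypes(panel, variant_cols = variant_key)
    n_missing <- sum(is.na(gts$gt))
    obs <- gts[!is.na(gts$gt), , drop = FALSE]
    if (nrow(obs) > 0) {
      tab <- table(factor(obs$phenotype, levels = c("PIGMENTED", "WHITE")),
                   factor(obs$gt, levels = GT_LEVELS))
      m[] <- as.integer(tab)
    }
  } else {
    n_missing <- nrow(panel)
  }
  structure(m, variant_key = variant_key, n_missing = n_missing,
            gt_levels = GT_LEVELS, class = c("genotype_table", "matrix"))
}

as_count_matrix <- function(table) {
  m <- unclass(table)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  if (!is.matrix(m)) abort("expected a contingency table (matrix)")
  if (any(m < 0) || any(m != round(m))) {
    abort("contingency table must hold non-negative integer counts")
  }
  storage.mode(m) <- "double"
  m
}

# All compositions of `total` into length(caps) parts with part j <= caps[j].
row_compositions <- function(total, caps) {
  if (length(caps) == 1L) {
    if (total <= caps[1]) return(list(total)) else return(list())
  }
  out <- list()
  for (v in 0:min(total, caps[1])) {
    for (rest in row_compositions(total - v, caps[-1])) {
      out[[length(out) + 1L]] <- c(v, rest)
    }
  }
  out
}

# Enumerate all tables sharing the margins of `m`; returns their log
# hypergeometric probabilities. Rows are filled in turn; the last row is
# forced by the remaining column margins.
enumerate_log_probs <- function(m) {
  rm <- rowSums(m); cm <- colSums(m); n <- sum(m)
  const <- sum(lgamma(rm + 1)) + sum(lgamma(cm + 1)) - lgamma(n + 1)
  r <- nrow(m)
  acc <- new.env(parent = emptyenv())
  acc$lp <- numeric(0)
  fill_row <- function(i, col_left, lfact_acc) {
    if (i == r) {
      acc$lp[length(acc$lp) + 1L] <-
        const - (lfact_acc + sum(lgamma(col_left + 1)))
      return(invisible())
    }
    for (cells in row_compositions(rm[i], col_left)) {
      fill_row(i + 1L, col_left - cells, lfact_acc + sum(lgamma(cells + 1)))
    }
  }
  fill_row(1L, cm, 0)
  acc$lp
}

log_sum_exp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

#' Fisher's exact test for an r x c contingency table
#'
#' Exact conditional two-sided test by complete enumeration of the tables
#' sharing the observed row and column margins. The probability of a table
#' is the multivariate hypergeometric mass
#' `prod(rowmargins!) * prod(colmargins!) / (total! * prod(cells!))`,
#' computed in log space; the p-value sums the probabilities of all tables
#' whose probability does not exceed the observed table's (relative tie
#' tolerance `1e-7`). All-zero rows and columns are dropped first; a table
#' with fewer than two non-empty rows or columns has p = 1.
#'
#' @param table A `genotype_table` or plain count matrix.
#' @param detail If `TRUE`, also return the enumerated log probabilities.
#' @return The p-value, or (with `detail = TRUE`) a list with `p_value`,
#'   `log_probs`, `log_p_obs`, `n_tables`.
#' @export
#' @examples
#' fisher_exact_rxc(matrix(c(3, 0, 0, 3), 2)) # 0.1
fisher_exact_rxc <- function(table, detail = FALSE) {
  m <- as_count_matrix(table)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) {
    if (detail) {
      return(list(p_value = 1, log_probs = 0, log_p_obs = 0, n_tables = 1L))
    }
    return(1)
  }
  rm <- rowSums(m); cm <- colSums(m); n <- sum(m)
  const <- sum(lgamma(rm + 1)) + sum(lgamma(cm + 1)) - lgamma(n + 1)
  lp_obs <- const - sum(lgamma(m + 1))
  lp <- enumerate_log_probs(m)
  p <- exp(log_sum_exp(lp[lp <= lp_obs + 1e-7]))
  p <- min(p, 1)
  if (detail) {
    list(p_value = p, log_probs = lp, log_p_obs = lp_obs,
         n_tables = length(lp))
  } else {
    p
  }
}

#' Collapse a 2x3 genotype table to hom-alt vs the rest
#'
#' @param table A 2x3 `genotype_table` or matrix (columns hom-ref, het,
#'   hom-alt).
#' @return A 2x2 matrix with columns `non-hom-alt`, `hom-alt`.
#' @export
collapse_recessive <- function(table) {
  m <- as_count_matrix(table)
  if (ncol(m) != 3L) abort("expected a 2x3 genotype table")
  out <- cbind(m[, 1] + m[, 2], m[, 3])
  colnames(out) <- c("non-hom-alt", "hom-alt")
  out
}

round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Carrier frequency among unaffected animals
#'
#' The fraction of genotyped PIGMENTED animals that are heterozygous at the
#' tested site, as a percentage. The integer rendering rounds half away
#' from zero.
#'
#' @param table A 2x3 `genotype_table` or matrix (rows PIGMENTED, WHITE;
#'   columns hom-ref, het, hom-alt).
#' @return One-row tibble: `n_het`, `n_pigmented`, `carrier_pct`,
#'   `carrier_pct_int`. With zero genotyped pigmented animals the
#'   percentages are `NA` and a warning is raised.
#' @export
carrier_frequency <- function(table) {
  m <- as_count_matrix(table)
  if (nrow(m) != 2L || ncol(m) != 3L) abort("expected a 2x3 genotype table")
  n_pig <- sum(m[1, ])
  n_het <- m[1, 2]
  if (n_pig == 0) {
    warn("no genotyped pigmented animals: carrier frequency undefined")
    return(tibble(n_het = 0L, n_pigmented = 0L,
                  carrier_pct = NA_real_, carrier_pct_int = NA_real_))
  }
  pct <- 100 * n_het / n_pig
  tibble(
    n_het = as.integer(n_het), n_pigmented = as.integer(n_pig),
    carrier_pct = pct, carrier_pct_int = round_half_away(pct)
  )
}

#' Concordance with the recessive-model prediction
#'
#' Predicts WHITE exactly for hom-alt animals and PIGMENTED otherwise, and
#' reports the percentage of genotyped animals whose observed phenotype
#' matches: hom-ref and het PIGMENTED animals plus hom-alt WHITE animals.
#'
#' @param table A 2x3 `genotype_table` or matrix.
#' @param model Only `"recessive"` is implemented.
#' @return One-row tibble: `n_match`, `n_total`, `concordance_pct`. An
#'   empty table yields `NA` with a warning.
#' @export
concordance <- function(table, model = "recessive") {
  model <- match.arg(model, "recessive")
  m <- as_count_matrix(table)
  if (nrow(m) != 2L || ncol(m) != 3L) abort("expected a 2x3 genotype table")
  n_total <- sum(m)
  if (n_total == 0) {
    warn("empty table: concordance undefined")
    return(tibble(n_match = 0L, n_total = 0L, concordance_pct = NA_real_))
  }
  n_match <- m[1, 1] + m[1, 2] + m[2, 3]
  tibble(
    n_match = as.integer(n_match), n_total = as.integer(n_total),
    concordance_pct = 100 * n_match / n_total
  )
}

#' Cohort accounting
#'
#' Totals, white fraction (one decimal, rounded half away from zero) and
#' per-location composition of a phenotyped cohort.
#'
#' @param panel Panel tibble with `animal_id`, `location`, `origin`,
#'   `phenotype`.
#' @return One-row tibble: `n_total`, `n_pigmented`, `n_white`,
#'   `white_pct`, and a `by_location` list-column holding the per-location
#'   counts. `white_pct` is `NA` for an empty cohort.
#' @export
cohort_summary <- function(panel) {
  n_total <- nrow(panel)
  n_white <- sum(panel$phenotype == "WHITE")
  n_pig <- sum(panel$phenotype == "PIGMENTED")
  white_pct <- if (n_total == 0) NA_real_ else
    round_half_away(100 * n_white / n_total, 1)
  by_loc <- if (n_total == 0) {
    tibble(location = character(), origin = character(),
           n = integer(), n_pigmented = integer(), n_white = integer())
  } else {
    panel %>%
      group_by(.data$location, .data$origin) %>%
      summarise(
        n = dplyr::n(),
        n_pigmented = sum(.data$phenotype == "PIGMENTED"),
        n_white = sum(.data$phenotype == "WHITE"),
        .groups = "drop"
      )
  }
  tibble(
    n_total = n_total, n_pigmented = n_pig, n_white = n_white,
    white_pct = white_pct, by_location = list(by_loc)
  )
}

#' Exact genotype-phenotype association at one site
#'
#' Convenience wrapper: builds the 2x3 table from the panel, runs the exact
#' test (optionally on the hom-alt vs rest collapse), and attaches carrier
#' frequency and recessive-model concordance.
#'
#' @param panel Panel tibble.
#' @param variant_key Site to test.
#' @param collapse If `TRUE`, test the 2x2 hom-alt vs rest collapse instead
#'   of the full 2x3 table.
#' @return A `whitecoat_assoc` object (list with `table`, `p_value`,
#'   `carrier`, `concordance`, `variant_key`, `collapse`).
#' @export
associate <- function(panel, variant_key, collapse = FALSE) {
  tab <- build_table(panel, variant_key)
  p <- fisher_exact_rxc(if (collapse) collapse_recessive(tab) else tab)
  structure(
    list(
      table = tab,
      p_value = p,
      carrier = carrier_frequency(tab),
      concordance = concordance(tab),
      variant_key = variant_key,
      collapse = collapse
    ),
    class = "whitecoat_assoc"
  )
}

#' @export
print.whitecoat_assoc <- function(x, ...) {
  cat("Genotype-phenotype association at", x$variant_key, "\n\n")
  print(unclass(x$table)[, , drop = FALSE])
  cat(sprintf(
    "\nFisher exact p = %.3g%s\nconcordance = %.1f%%  carrier frequency = %.2f%% (%d%%)\n",
    x$p_value, if (x$collapse) " (hom-alt vs rest collapse)" else "",
    x$concordance$concordance_pct, x$carrier$carrier_pct,
    as.integer(x$carrier$carrier_pct_int)
  ))
  invisible(x)
}

#' @rdname associate
#' @param x,object A `whitecoat_assoc` or `genotype_table`.
#' @param ... Unused.
#' @method tidy whitecoat_assoc
#' @export
tidy.whitecoat_assoc <- function(x, ...) {
  tidy.genotype_table(x$table)
}

#' @rdname associate
#' @method glance whitecoat_assoc
#' @export
glance.whitecoat_assoc <- function(x, ...) {
  tibble(
    variant_key = x$variant_key,
    p_value = x$p_value,
    concordance_pct = x$concordance$concordance_pct,
    carrier_pct = x$carrier$carrier_pct,
    n = x$concordance$n_total,
    n_missing = attr(x$table, "n_missing")
  )
}

#' @rdname associate
#' @method tidy genotype_table
#' @export
tidy.genotype_table <- function(x, ...) {
  m <- as_count_matrix(x)
  out <- as_tibble(as.table(m), .name_repair = "minimal")
  names(out) <- c("phenotype", "genotype", "count")
  out$count <- as.integer(out$count)
  as_tibble(out)
}

#' @rdname associate
#' @method autoplot genotype_table
#' @export
autoplot.genotype_table <- function(object, ...) {
  d <- tidy.genotype_table(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$genotype, .data$phenotype)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count), colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#4477aa") +
    ggplot2::labs(
      x = "genotype", y = NULL,
      title = paste0("Phenotype by genotype at ",
                     attr(object, "variant_key") %||% "site")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname associate
#' @method autoplot whitecoat_assoc
#' @export
autoplot.whitecoat_assoc <- function(object, ...) {
  autoplot.genotype_table(object$table) +
    ggplot2::labs(subtitle = sprintf("Fisher exact p = %.3g", object$p_value))
}
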