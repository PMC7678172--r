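# Synthetic study generator: gene models with random coding sequences, a
# Hardy-Weinberg cohort with a fully penetrant recessive white phenotype, a
# sequenced dam/calf pair (affected + obligate carrier), background coding
# variants, and staged validation panels. Gives every pipeline stage a
# self-contained, seed-reproducible input.

SENSE_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]

#' Simulation configuration
#'
#' Defaults mirror the study design the pipeline was built around: a
#' genotyped cohort of 102 animals, a causal allele at population frequency
#' 0.25 under Hardy-Weinberg with full penetrance, 16 candidate genes of
#' 300 codons, and a background of 500 unlinked coding variants with a 10%
#' indel fraction.
#'
#' @param seed Integer seed; all generators derive their randomness from it.
#' @param n_animals Cohort size.
#' @param q Causal allele frequency, in (0, 1).
#' @param n_background Number of background coding variants.
#' @param n_genes Number of synthetic gene models.
#' @param gene_length_codons CDS length per gene, in codons (>= 2).
#' @param indel_rate Fraction of background sites emitted as indels.
#' @param qual_range Range for simulated QUAL scores.
#' @param penetrance Probability that a hom-alt animal is WHITE (default 1).
#' @param error_rate Per-genotype rate of replacing a call with a fresh
#'   Hardy-Weinberg draw (default 0 = perfect genotyping).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_animals = 102L, q = 0.25,
                       n_background = 500L, n_genes = 16L,
                       gene_length_codons = 300L, indel_rate = 0.1,
                       qual_range = c(20, 1000), penetrance = 1,
                       error_rate = 0) {
  if (q <= 0 || q >= 1) abort("q must lie in (0, 1)")
  if (n_genes < 1L) abort("n_genes must be >= 1")
  if (gene_length_codons < 2L) abort("gene_length_codons must be >= 2")
  if (indel_rate < 0 || indel_rate > 1) abort("indel_rate must be in [0, 1]")
  if (penetrance < 0 || penetrance > 1) abort("penetrance must be in [0, 1]")
  structure(
    list(
      seed = as.integer(seed), n_animals = as.integer(n_animals), q = q,
      n_background = as.integer(n_background), n_genes = as.integer(n_genes),
      gene_length_codons = as.integer(gene_length_codons),
      indel_rate = indel_rate, qual_range = qual_range,
      penetrance = penetrance, error_rate = error_rate
    ),
    class = "sim_config"
  )
}

random_cds <- function(n_codons) {
  body <- sample(SENSE_CODONS, n_codons - 2L, replace = TRUE)
  tolower(paste(c("ATG", body, "TAA"), collapse = ""))
}

#' Simulate gene models
#'
#' Generates `n_genes` models with random coding sequences (valid start and
#' stop, no internal stop codons), alternating strands, and 1-3 CDS
#' segments at non-overlapping loci. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @return A gene-model tibble (see [read_gene_models()]).
#' @export
simulate_gene_models <- function(config) {
  set.seed(config$seed + 1L)
  L <- 3L * config$gene_length_codons
  purrr::map(seq_len(config$n_genes), function(i) {
    n_seg <- sample(1:3, 1)
    cuts <- sort(sample(seq_len(L - 1L), n_seg - 1L))
    lens <- diff(c(0L, cuts, L))
    base <- 1000000L * i + sample.int(1000L, 1)
    starts <- integer(n_seg); ends <- integer(n_seg)
    cursor <- base
    for (k in seq_len(n_seg)) {
      starts[k] <- cursor
      ends[k] <- cursor + lens[k] - 1L
      cursor <- ends[k] + 200L # intron
    }
    strand <- if (i %% 2L == 1L) "+" else "-"
    seg <- tibble(start = starts, end = ends)
    if (strand == "-") seg <- seg[rev(seq_len(n_seg)), ]
    tibble(
      symbol = sprintf("GENE%02d", i),
      accession = sprintf("SYN_%06d.1", i),
      chrom = as.character(((i - 1L) %% 5L) + 1L),
      strand = strand,
      cds_segments = list(seg),
      cds_seq = random_cds(config$gene_length_codons)
    )
  }) %>%
    bind_rows() %>%
    validate_gene_models()
}

hw_probs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

draw_hw <- function(n, q) {
  sample(GT_LEVELS, n, replace = TRUE, prob = hw_probs(q))
}

# Mendelian dam -> calf transmission: one maternal allele drawn uniformly
# from the dam's genotype, paternal allele alt with probability q.
transmit_from_dam <- function(dam_gt, q) {
  maternal_alt <- switch(dam_gt,
    HOM_REF = 0L, HET = sample(0:1, 1), HOM_ALT = 1L
  )
  paternal_alt <- rbinom(1L, 1L, q)
  GT_LEVELS[maternal_alt + paternal_alt + 1L]
}

#' Simulate the phenotyped cohort and the sequenced pair
#'
#' Draws each animal's causal genotype from Hardy-Weinberg proportions
#' ((1-q)^2, 2q(1-q), q^2); the phenotype is WHITE for hom-alt animals
#' (with probability `penetrance`, default 1) and PIGMENTED otherwise. One
#' WHITE animal is selected as the sequenced dam (if none arises the first
#' animal is forced hom-alt, with a message) and a PIGMENTED calf is
#' generated by Mendelian transmission — with a hom-alt dam the calf is
#' necessarily heterozygous, the obligate carrier.
#'
#' If fewer than `min_white` white animals arise, pigmented animals are
#' promoted to hom-alt white (with a message) until the staged validation
#' design is feasible — the sampled study this emulates had its white
#' animals by construction.
#'
#' @param config A [sim_config()].
#' @param min_white Minimum number of white animals guaranteed in the
#'   cohort (the sequenced dam plus the validation-stage whites).
#' @return List with `cohort` (tibble: `animal_id`, `location`, `origin`,
#'   `phenotype`, `causal_gt`) and `truth` (list: `dam_id`, `calf_id`,
#'   `calf_gt`, `calf_location`, `dam_forced`).
#' @export
simulate_cohort <- function(config, min_white = 4L) {
  set.seed(config$seed + 2L)
  n <- config$n_animals
  locations <- sprintf("LOC%02d", 1:12)
  origins <- setNames(rep(c("G", "H"), length.out = 12), locations)
  loc <- sample(locations, n, replace = TRUE)
  gt <- draw_hw(n, config$q)
  white <- gt == "HOM_ALT" & rbinom(n, 1L, config$penetrance) == 1L
  cohort <- tibble(
    animal_id = sprintf("A%03d", seq_len(n)),
    location = loc,
    origin = unname(origins[loc]),
    phenotype = if_else(white, "WHITE", "PIGMENTED"),
    causal_gt = gt
  )
  dam_forced <- !any(cohort$phenotype == "WHITE")
  min_white <- min(min_white, n)
  shortfall <- min_white - sum(cohort$phenotype == "WHITE")
  if (shortfall > 0L) {
    message(shortfall, " white animal(s) short of the study design at q = ",
            config$q, "; promoting pigmented animals to hom-alt white")
    idx <- which(cohort$phenotype == "PIGMENTED")[seq_len(shortfall)]
    cohort$causal_gt[idx] <- "HOM_ALT"
    cohort$phenotype[idx] <- "WHITE"
  }
  dam_idx <- which(cohort$phenotype == "WHITE")[1]
  # the study design requires a pigmented calf: with a hom-alt dam the
  # maternal allele is always alt, so a pigmented calf is necessarily HET
  calf_gt <- "HET"
  list(
    cohort = cohort,
    truth = list(
      dam_id = cohort$animal_id[dam_idx],
      calf_id = "CALF01",
      calf_gt = calf_gt,
      calf_location = cohort$location[dam_idx],
      dam_forced = dam_forced
    )
  )
}

pick_missense_site <- function(model) {
  L <- nchar(model$cds_seq)
  for (try in seq_len(1000L)) {
    cdna <- sample(4:(L - 3L), 1) # avoid start and stop codons
    ref_nt <- toupper(substr(model$cds_seq, cdna, cdna))
    alt_nt <- sample(setdiff(c("A", "C", "G", "T"), ref_nt), 1)
    ca <- codon_arithmetic(cdna)
    codon0 <- toupper(substr(model$cds_seq, 3L * (ca$codon_index - 1L) + 1L,
                             3L * ca$codon_index))
    codon1 <- codon0
    substr(codon1, ca$codon_offset, ca$codon_offset) <- alt_nt
    if (translate_codon(codon1) != "*" &&
        translate_codon(codon1) != translate_codon(codon0)) {
      return(list(cdna = cdna, ref_nt = ref_nt, alt_nt = alt_nt))
    }
  }
  abort("could not find a missense site")
}

to_genomic_allele <- function(nt, strand) {
  if (strand == "+") nt else complement_base(nt)
}

#' Simulate the trio variant calls and the cohort genotype matrix
#'
#' Implants one causal SNV (a missense change inside the first gene model;
#' dam hom-alt, calf het) and `n_background` unlinked background sites at
#' distinct positions in the candidate genes. Background genotypes are
#' drawn per animal from Hardy-Weinberg(q), with the calf generated by
#' Mendelian transmission from the dam; `indel_rate` of background sites
#' are emitted as 1-bp insertions. QUAL is uniform over `qual_range`.
#' Background sites are kept more than 3 bp away from the causal site so
#' the implanted call is never shadowed by a simulated indel.
#'
#' @param config A [sim_config()].
#' @param gene_models Gene models from [simulate_gene_models()].
#' @param cohort_sim Output of [simulate_cohort()].
#' @return List with `variants` (tibble with genotype columns for dam and
#'   calf, `"samples"` attribute set), `genotypes` (character matrix,
#'   animals x variant keys, cohort plus calf), and `causal_key`.
#' @export
simulate_variant_calls <- function(config, gene_models, cohort_sim) {
  set.seed(config$seed + 3L)
  cohort <- cohort_sim$cohort
  truth <- cohort_sim$truth
  q <- config$q

  causal_model <- as_model_row(gene_models[1, ])
  site <- pick_missense_site(causal_model)
  causal_pos <- genomic_position(causal_model, site$cdna)
  causal <- tibble(
    chrom = causal_model$chrom,
    pos = causal_pos,
    ref = to_genomic_allele(site$ref_nt, causal_model$strand),
    alt = to_genomic_allele(site$alt_nt, causal_model$strand),
    qual = runif(1, config$qual_range[1], config$qual_range[2])
  )

  # distinct background positions inside CDS segments, clear of the causal
  all_sites <- purrr::map(seq_len(nrow(gene_models)), function(j) {
    model <- as_model_row(gene_models[j, ])
    seg <- model$cds_segments
    tibble(
      model_idx = j,
      chrom = model$chrom,
      pos = unlist(purrr::map2(seg$start, seg$end, seq)),
      strand = model$strand
    )
  }) %>% bind_rows()
  all_sites <- all_sites[!(all_sites$chrom == causal$chrom &
                             abs(all_sites$pos - causal$pos) <= 3L), ]
  if (nrow(all_sites) < config$n_background) {
    abort("gene space too small for the requested background variant count")
  }
  bg <- all_sites[sample.int(nrow(all_sites), config$n_background), ]

  bg_rows <- purrr::map(seq_len(nrow(bg)), function(i) {
    model <- as_model_row(gene_models[bg$model_idx[i], ])
    cdna <- cds_position(model, bg$chrom[i], bg$pos[i])
    coding_ref <- toupper(substr(model$cds_seq, cdna, cdna))
    g_ref <- to_genomic_allele(coding_ref, model$strand)
    is_indel <- runif(1) < config$indel_rate
    if (is_indel) {
      alt <- paste0(g_ref, sample(c("A", "C", "G", "T"), 1))
    } else {
      alt <- sample(setdiff(c("A", "C", "G", "T"), g_ref), 1)
    }
    tibble(chrom = bg$chrom[i], pos = bg$pos[i], ref = g_ref, alt = alt,
           qual = runif(1, config$qual_range[1], config$qual_range[2]))
  }) %>% bind_rows()

  variants <- bind_rows(causal, bg_rows) %>%
    mutate(
      vclass = variant_class(.data$ref, .data$alt),
      key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)
    )
  causal_key <- variants$key[1]
  variants <- variants %>% arrange(.data$chrom, .data$pos)

  # cohort (+ calf) genotype matrix across all sites, drawn once so the
  # trio calls and every panel agree
  animals <- c(cohort$animal_id, truth$calf_id)
  dam_row <- match(truth$dam_id, animals)
  gmat <- matrix(NA_character_, nrow = length(animals),
                 ncol = nrow(variants),
                 dimnames = list(animals, variants$key))
  for (k in seq_len(nrow(variants))) {
    if (variants$key[k] == causal_key) {
      gmat[seq_len(nrow(cohort)), k] <- cohort$causal_gt
      gmat[length(animals), k] <- truth$calf_gt
    } else {
      draws <- draw_hw(nrow(cohort), q)
      gmat[seq_len(nrow(cohort)), k] <- draws
      gmat[length(animals), k] <- transmit_from_dam(draws[dam_row], q)
    }
  }
  if (config$error_rate > 0) {
    flip <- matrix(runif(length(gmat)) < config$error_rate, nrow(gmat))
    flip[, match(causal_key, variants$key)] <- FALSE # phenotype stays consistent
    gmat[flip] <- draw_hw(sum(flip), q)
  }

  variants[[truth$dam_id]] <- unname(gmat[truth$dam_id, variants$key])
  variants[[truth$calf_id]] <- unname(gmat[truth$calf_id, variants$key])
  attr(variants, "samples") <- c(truth$dam_id, truth$calf_id)
  list(variants = variants, genotypes = gmat, causal_key = causal_key)
}

panel_from_ids <- function(cohort, ids, genotypes, variants) {
  rows <- cohort[match(ids, cohort$animal_id),
                 c("animal_id", "location", "origin", "phenotype")]
  for (k in seq_len(nrow(variants))) {
    key <- variants$key[k]
    rows[[key]] <- allele_string(unname(genotypes[ids, key]),
                                 variants$ref[k], variants$alt[k])
  }
  attr(rows, "variant_cols") <- variants$key
  rows
}

#' Simulate staged validation panels
#'
#' Builds an ordered list of genotyping panels mirroring a staged
#' validation design (e.g. 1 white + 1 pigmented, then 3 + 3, then the full
#' cohort). Panels are cumulative by default: each stage extends the
#' previous one, sampling without replacement from the cohort. The
#' sequenced dam is excluded from the intermediate stages (it provides no
#' new information) and enters with the full cohort.
#'
#' @param config A [sim_config()].
#' @param study Output of [simulate_variant_calls()] plus the cohort, i.e. a
#'   list with `cohort`, `truth`, `genotypes`, `variants` (as assembled by
#'   [simulate_study()]).
#' @param stages List of stages; each is `c(n_white, n_pigmented)` or
#'   `"all"` for the whole cohort.
#' @param cumulative If `TRUE` (default) stage k's animals include stage
#'   k-1's.
#' @return Named list of panel tibbles (`stage_1`, `stage_2`, ...).
#' @export
simulate_panels <- function(config, study,
                            stages = list(c(1, 1), c(3, 3), "all"),
                            cumulative = TRUE) {
  set.seed(config$seed + 4L)
  cohort <- study$cohort
  whites <- cohort$animal_id[cohort$phenotype == "WHITE"]
  pigs <- cohort$animal_id[cohort$phenotype == "PIGMENTED"]
  dam <- study$truth$dam_id
  white_order <- c(sample(setdiff(whites, dam)), dam)
  pig_order <- sample(pigs)
  panels <- list()
  prev_ids <- character()
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    if (identical(st, "all")) {
      ids <- cohort$animal_id
    } else {
      if (st[1] > length(whites) || st[2] > length(pigs)) {
        abort(sprintf(
          "stage %d requests %d white + %d pigmented but cohort has %d + %d",
          i, st[1], st[2], length(whites), length(pigs)
        ))
      }
      ids <- c(head(white_order, st[1]), head(pig_order, st[2]))
      if (!cumulative && i > 1L) {
        pool_w <- setdiff(white_order, prev_ids)
        pool_p <- setdiff(pig_order, prev_ids)
        ids <- c(head(pool_w, st[1]), head(pool_p, st[2]))
      }
    }
    panels[[paste0("stage_", i)]] <-
      panel_from_ids(cohort, ids, study$genotypes, study$variants)
    prev_ids <- union(prev_ids, ids)
  }
  panels
}

#' Simulate a complete study
#'
#' One call generating everything the pipeline consumes, mutually
#' consistent and reproducible from the seed: gene models, gene list,
#' phenotyped cohort, the sequenced dam/calf variant calls with one
#' implanted causal missense SNV, the cohort genotype matrix, and staged
#' validation panels.
#'
#' @param config A [sim_config()].
#' @param stages Panel staging passed to [simulate_panels()].
#' @return List: `config`, `gene_models`, `gene_list`, `cohort`, `truth`,
#'   `variants`, `genotypes`, `causal_key`, `panels`.
#' @export
simulate_study <- function(config = sim_config(),
                           stages = list(c(1, 1), c(3, 3), "all")) {
  gene_models <- simulate_gene_models(config)
  cohort_sim <- simulate_cohort(config)
  calls <- simulate_variant_calls(config, gene_models, cohort_sim)
  study <- list(
    config = config,
    gene_models = gene_models,
    gene_list = gene_models$symbol,
    cohort = cohort_sim$cohort,
    truth = cohort_sim$truth,
    variants = calls$variants,
    genotypes = calls$genotypes,
    causal_key = calls$causal_key
  )
  study$panels <- simulate_panels(config, study, stages = stages)
  study
}
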