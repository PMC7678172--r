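make_variants <- function(...) {
  v <- tibble::tribble(...)
  v$vclass <- variant_class(v$ref, v$alt)
  v$key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  v
}

test_that("indel-proximity filter drops only lower-QUAL SNVs within range", {
  base <- function(snv_pos, snv_qual, indel_pos, indel_qual) {
    make_variants(
      ~chrom, ~pos, ~ref, ~alt, ~qual,
      "1", snv_pos, "A", "C", snv_qual,
      "1", indel_pos, "AT", "A", indel_qual
    )
  }
  expect_equal(filter_near_indels(base(100L, 30, 102L, 50))$vclass, "INDEL")
  expect_equal(nrow(filter_near_indels(base(100L, 60, 102L, 50))), 2L)
  expect_equal(nrow(filter_near_indels(base(100L, 30, 104L, 50))), 2L)

  # exhaustive over distances 1..5, both QUAL orders
  for (d in 1:5) {
    lower <- filter_near_indels(base(100L, 30, 100L + d, 50))
    higher <- filter_near_indels(base(100L, 60, 100L + d, 50))
    expect_equal(any(lower$vclass == "SNV"), d > 3)
    expect_equal(nrow(higher), 2L)
  }

  # different chromosome never interacts
  far <- make_variants(
    ~chrom, ~pos, ~ref, ~alt, ~qual,
    "1", 100L, "A", "C", 30,
    "2", 101L, "AT", "A", 50
  )
  expect_equal(nrow(filter_near_indels(far)), 2L)
})

test_that("gene subsetting keeps only variants inside listed gene CDS", {
  model <- make_leu_model() # MC1R-like on chrom 18 from position 1000
  pos <- genomic_position(model, 143L)
  v <- make_variants(
    ~chrom, ~pos, ~ref, ~alt, ~qual,
    "18", pos, "T", "C", 800,
    "18", 50L, "G", "A", 700 # intergenic
  )
  kept <- subset_to_genes(v, model, c("MC1R"))
  expect_equal(kept$key, v$key[1])
  expect_equal(kept$gene, "MC1R")

  expect_warning(none <- subset_to_genes(v, model, c("TYR")), "TYR")
  expect_equal(nrow(none), 0L)
})

test_that("non-synonymous restriction keeps amino-acid-changing classes", {
  ann <- tibble::tibble(
    key = sprintf("1:%d:A:C", 1:6),
    effect_class = c("missense", "synonymous", "nonsense", "synonymous",
                     "synonymous", NA)
  )
  out <- nonsynonymous_only(ann)
  expect_equal(out$effect_class, c("missense", "nonsense"))
})

test_that("the trio filter matches the nine-genotype-pair oracle", {
  pairs <- expand.grid(
    affected = c("HOM_REF", "HET", "HOM_ALT"),
    carrier = c("HOM_REF", "HET", "HOM_ALT"),
    stringsAsFactors = FALSE
  )
  v <- tibble::tibble(
    chrom = "1", pos = seq_len(nrow(pairs)), ref = "A", alt = "C",
    qual = 100, vclass = "SNV",
    key = sprintf("1:%d:A:C", seq_len(nrow(pairs))),
    DAM = pairs$affected, CALF = pairs$carrier
  )
  kept <- recessive_trio_filter(v, "DAM", "CALF")
  oracle <- pairs$affected == "HOM_ALT" & pairs$carrier == "HET"
  expect_equal(kept$key, v$key[oracle])
  expect_equal(nrow(kept), 1L)

  # missing genotype in either sample removes the site
  v$DAM[pairs$affected == "HOM_ALT" & pairs$carrier == "HET"] <- NA
  expect_equal(nrow(recessive_trio_filter(v, "DAM", "CALF")), 0L)

  expect_error(recessive_trio_filter(v, "DAM", "NOPE"), "NOPE")
})

test_that("panel refinement enforces exact recessive concordance", {
  cand <- tibble::tibble(
    chrom = "18", pos = 14705518L, ref = "T", alt = "C", qual = 800,
    vclass = "SNV", key = "18:14705518:T:C"
  )
  good <- make_panel(
    rep(c("WHITE", "PIGMENTED"), each = 3),
    c("HOM_ALT", "HOM_ALT", "HOM_ALT", "HOM_REF", "HET", "HOM_REF")
  )
  expect_equal(nrow(refine_with_panel(cand, good)), 1L)

  bad <- make_panel(
    rep(c("WHITE", "PIGMENTED"), each = 3),
    c("HOM_ALT", "HOM_ALT", "HOM_ALT", "HOM_REF", "HET", "HOM_ALT")
  )
  expect_equal(nrow(refine_with_panel(cand, bad)), 0L)

  white_het <- make_panel(c("WHITE", "PIGMENTED"), c("HET", "HOM_REF"))
  expect_equal(nrow(refine_with_panel(cand, white_het)), 0L)

  # empty panel is vacuous; missing genotypes are reported, not fatal
  expect_equal(nrow(refine_with_panel(cand, good[0, ])), 1L)
  with_missing <- make_panel(
    c("WHITE", "WHITE", "PIGMENTED"),
    c("HOM_ALT", NA, "HET")
  )
  out <- refine_with_panel(cand, with_missing)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_missing, 1L)
})

test_that("the cascade audits every stage and conserves counts", {
  study <- simulate_study(sim_config(seed = 11, n_background = 150))
  rep <- run_cascade(
    study$variants, study$gene_models, study$gene_list,
    study$truth$dam_id, study$truth$calf_id, panels = study$panels
  )
  st <- tidy(rep)
  expect_true(all(diff(st$n_out) <= 0 | st$n_in[-1] == st$n_out[-nrow(st)]))
  expect_true(all(st$n_out <= st$n_in))
  # removals plus survivors account for the input exactly
  expect_equal(st$n_in[1] - st$n_out[nrow(st)], sum(st$n_in - st$n_out))
  expect_true(study$causal_key %in% rep$candidates$key)

  expect_error(
    run_cascade(study$variants, study$gene_models, study$gene_list,
                "NOSUCH", study$truth$calf_id),
    "NOSUCH"
  )
})

test_that("an empty call set yields an all-zero cascade", {
  path <- write_test_vcf(character())
  v <- read_vcf(path)
  rep <- run_cascade(v, make_leu_model(), "MC1R", "DAM", "CALF")
  expect_true(all(tidy(rep)$n_out == 0L))
  expect_equal(nrow(rep$candidates), 0L)
})
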