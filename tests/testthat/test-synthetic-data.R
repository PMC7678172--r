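test_that("generators are reproducible from the seed", {
  cfg <- sim_config(seed = 5, n_background = 60)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_equal(a$variants, b$variants)
  expect_equal(a$cohort, b$cohort)
  expect_equal(a$genotypes, b$genotypes)
  expect_equal(a$panels, b$panels)
  expect_equal(a$causal_key, b$causal_key)
})

test_that("simulated gene models are structurally valid", {
  cfg <- sim_config(seed = 3, n_genes = 4, gene_length_codons = 50)
  models <- simulate_gene_models(cfg)
  expect_equal(nrow(models), 4L)
  expect_equal(models$strand, c("+", "-", "+", "-"))
  expect_true(all(nchar(models$cds_seq) == 150L))
  expect_silent(validate_gene_models(models))
  # no internal stops: the whole CDS translates cleanly
  aas <- purrr::map_chr(models$cds_seq, function(s) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(translate_codon(codons), collapse = "")
  })
  expect_true(all(startsWith(aas, "M")))
  expect_true(all(!grepl("\\*.", aas))) # stop only at the end
})

test_that("cohort genotypes follow Hardy-Weinberg with full penetrance", {
  cfg <- sim_config(seed = 9, n_animals = 10000L, q = 0.3)
  sim <- simulate_cohort(cfg)
  frac <- mean(sim$cohort$causal_gt == "HOM_ALT")
  se <- sqrt(0.09 * 0.91 / 10000)
  expect_lt(abs(frac - 0.09), 3 * se)
  # phenotype is deterministic from genotype
  expect_equal(sim$cohort$phenotype == "WHITE",
               sim$cohort$causal_gt == "HOM_ALT")
  # the calf of a hom-alt dam is the obligate carrier
  expect_equal(sim$truth$calf_gt, "HET")
  dam <- sim$cohort[sim$cohort$animal_id == sim$truth$dam_id, ]
  expect_equal(dam$causal_gt, "HOM_ALT")
})

test_that("a cohort short of whites is topped up with a message", {
  cfg <- sim_config(seed = 2, n_animals = 12L, q = 0.01)
  expect_message(sim <- simulate_cohort(cfg), "promoting")
  expect_equal(sum(sim$cohort$phenotype == "WHITE"), 4L)
  dam <- sim$cohort[sim$cohort$animal_id == sim$truth$dam_id, ]
  expect_equal(dam$causal_gt, "HOM_ALT")
  expect_equal(dam$phenotype, "WHITE")
  # every white animal is hom-alt and vice versa, even after promotion
  expect_equal(sim$cohort$phenotype == "WHITE",
               sim$cohort$causal_gt == "HOM_ALT")
})

test_that("trio calls implant the causal SNV and honour indel_rate", {
  cfg <- sim_config(seed = 13, n_background = 120)
  study <- simulate_study(cfg)
  causal <- study$variants[study$variants$key == study$causal_key, ]
  expect_equal(nrow(causal), 1L)
  expect_equal(causal[[study$truth$dam_id]], "HOM_ALT")
  expect_equal(causal[[study$truth$calf_id]], "HET")
  expect_equal(causal$vclass, "SNV")
  # the implanted change is annotated non-synonymous in its gene
  eff <- annotate_variants(causal, study$gene_models)
  expect_true(eff$effect_class %in% c("missense", "nonsense"))
  expect_gt(sum(study$variants$vclass == "INDEL"), 0L)

  no_indel <- simulate_study(sim_config(seed = 13, n_background = 120,
                                        indel_rate = 0))
  expect_equal(sum(no_indel$variants$vclass == "INDEL"), 0L)
})

test_that("background trio-filter survival tracks q^2(1-q)", {
  q <- 0.2
  cfg <- sim_config(seed = 21, n_background = 2000L, q = q, indel_rate = 0)
  study <- simulate_study(cfg)
  bg <- study$variants[study$variants$key != study$causal_key, ]
  kept <- recessive_trio_filter(bg, study$truth$dam_id, study$truth$calf_id)
  expected <- q^2 * (1 - q)
  se <- sqrt(expected * (1 - expected) / nrow(bg))
  expect_lt(abs(nrow(kept) / nrow(bg) - expected), 3 * se)
})

test_that("staged panels respect sizes, nesting, and truth margins", {
  cfg <- sim_config(seed = 17, n_background = 40)
  study <- simulate_study(cfg)
  p <- study$panels
  expect_equal(nrow(p$stage_1), 2L)
  expect_equal(nrow(p$stage_2), 6L)
  expect_equal(nrow(p$stage_3), cfg$n_animals)
  expect_equal(sum(p$stage_2$phenotype == "WHITE"), 3L)
  # cumulative staging nests the animals
  expect_true(all(p$stage_1$animal_id %in% p$stage_2$animal_id))
  expect_true(all(p$stage_2$animal_id %in% p$stage_3$animal_id))

  # full-cohort table margins equal the simulated truth
  tab <- build_table(p$stage_3, study$causal_key)
  expect_equal(unname(rowSums(unclass(tab))),
               c(sum(study$cohort$phenotype == "PIGMENTED"),
                 sum(study$cohort$phenotype == "WHITE")))
  # and the simulated cohort is perfectly concordant by construction
  expect_equal(concordance(tab)$concordance_pct, 100)

  empty <- simulate_panels(cfg, study, stages = list(c(0, 0)))
  expect_equal(nrow(empty$stage_1), 0L)
  expect_error(
    simulate_panels(cfg, study, stages = list(c(1000, 0))),
    "requests"
  )
})

test_that("an animal's genotype is consistent across panels and the VCF", {
  study <- simulate_study(sim_config(seed = 23, n_background = 30))
  p2 <- study$panels$stage_2
  p3 <- study$panels$stage_3
  shared <- intersect(p2$animal_id, p3$animal_id)
  keys <- attr(p2, "variant_cols")[1:10]
  for (k in keys) {
    expect_equal(p2[[k]][match(shared, p2$animal_id)],
                 p3[[k]][match(shared, p3$animal_id)])
  }
  dam <- study$truth$dam_id
  vcf_gt <- study$variants[[dam]]
  panel_gt <- panel_genotypes(p3[p3$animal_id == dam, ])
  m <- match(study$variants$key, panel_gt$variant_key)
  expect_equal(panel_gt$gt[m], vcf_gt)
})
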