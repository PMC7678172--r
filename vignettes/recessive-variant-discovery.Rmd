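---
title: "Recessive candidate-gene variant discovery: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recessive candidate-gene variant discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whitecoat)
```

## The genetic model

`whitecoat` targets one specific, common study design in coat-colour
genetics: a phenotype that segregates as a fully penetrant autosomal
recessive trait, a sequenced affected individual together with an
unaffected first-degree relative, and a candidate-gene list. For white
fallow deer the affected hind must be homozygous for the causal allele and
her pigmented calf — which received one maternal allele — is an obligate
carrier, hence heterozygous. These two genotype constraints are the
discriminating signal: any coding variant where the pair is not
(hom-alt, het) cannot be the fully penetrant recessive cause.

The model's assumptions, and what breaks when they fail:

* **Full penetrance, no phenocopies.** A hom-alt animal is always white
  and a white animal is always hom-alt. A single discordant animal in a
  validation panel eliminates a true causal variant; the panel refinement
  is deliberately exact rather than statistical because the cohort data
  contain no discordance. A `penetrance` knob exists in the simulator for
  robustness experiments but defaults to 1.
* **Biallelic, well-called sites.** The VCF dialect is restricted to
  biallelic SNVs and indels with GT as the leading FORMAT key;
  multi-allelic records are rejected rather than silently split.
* **One transcript per gene.** Gene models are supplied by the caller as a
  TSV (symbol, accession, chromosome, strand, ordered CDS segments, CDS
  sequence); isoform ambiguity is out of scope.

## The filtering cascade

`run_cascade()` applies, in order, each stage recording in/out counts:

1. `filter_near_indels()` — an SNV is removed iff an indel on the same
   chromosome lies within `window` bp (default 3, measured between POS
   fields, inclusive) *and* the SNV's QUAL is strictly below that indel's.
   The conjunction is read pairwise — the SNV is compared against the
   nearby indel, not a global threshold — which is the closest literal
   reading of the quality-control rule this stage implements; indels
   themselves are never removed.
2. `subset_to_genes()` — position inside a CDS segment of a listed gene.
   Using CDS segments rather than full gene spans means intronic and UTR
   variants leave the cascade here; the non-synonymous restriction would
   drop them anyway, so the stage at which they exit does not change the
   final candidate set.
3. `annotate_variants()` + `nonsynonymous_only()` — see below.
4. `recessive_trio_filter()` — keeps exactly the (hom-alt, het) pair. A
   missing genotype in either sample removes the site: a variant that
   cannot be confirmed to fit the model is not carried forward.
5. `refine_with_panel()`, once per panel in order — a candidate survives
   while every genotyped white animal is hom-alt and no genotyped
   pigmented animal is. Missing panel genotypes are reported but never
   disqualify: completeness of genotyping is an assumption of the design,
   so behaviour under missingness is intentionally conservative.

## Coding-effect annotation

The annotator is self-contained: no external annotation service or
download. For an SNV at genomic position *g* in a gene model,
`cds_position()` counts bases along the CDS segments in transcription
order (descending genomic coordinates for minus-strand genes), giving the
CDS coordinate *n*. Codon arithmetic is exact integer arithmetic:

* residue index = ⌈*n*/3⌉,
* codon offset = ((*n*−1) mod 3) + 1,

and the reconstruction 3·(index−1)+offset = *n* is tested as a property.
For minus-strand genes the genomic alleles are Watson–Crick complemented
before the codon lookup. Codons are rendered lowercase with the variant
base capitalised (`cTg`/`cCg`), the convention used in candidate tables in
this field, and effects are classed synonymous / missense / nonsense /
start-lost; only synonymous changes are dropped by the cascade, the other
three classes all progress.

`infer_strand()` solves the inverse problem — given genomic alleles and
capitalised codon strings, decide the strand — and doubles as a
consistency check: if neither orientation explains the codon capitals, the
annotation is internally inconsistent and the function errors rather than
guessing. `verify_codon_annotations()` uses it to re-derive every field of the
packaged 19-SNP candidate table and compare against the printed
amino-acid substitutions; the packaged table's `c.N X>Y` column carries
the *genomic* ref/alt alleles (matching its `Ref`/`Alt` columns), so
strand inference is what reconciles them with the coding-strand codons on
the ten minus-strand rows.

The genetic code is a hand-authored 64-entry table; the test suite checks
all 64 codons against an independent lookup (`Biostrings::GENETIC_CODE`).

## The exact association test

`fisher_exact_rxc()` is an exact conditional test by complete enumeration.
All tables with the observed row and column margins are generated
recursively (the last row is forced by the remaining column margins); each
table's multivariate hypergeometric probability is computed in log space
from `lgamma` terms, and the two-sided p-value follows the
probability-mass criterion: sum the probabilities of every table whose
probability is at most the observed table's, with a relative tie tolerance
of 1e-7. Degenerate inputs collapse first: all-zero rows and columns are
dropped, and a table with fewer than two non-empty rows or columns has
p = 1 (only one table satisfies such margins).

Enumeration is exhaustive rather than network-optimised because the
tables this pipeline tests are 2×3 with cohort-scale margins — the
packaged cohort's margins admit only 210 tables. Properties tested:
enumeration probabilities sum to 1 (within 1e-9 in log space), the
p-value is invariant under row/column permutation, 2×2 cases match the
closed-form hypergeometric tail on 200 random tables, and 2×3 cases match
an independent exact implementation (`stats::fisher.test`). For the
packaged cohort the observed table is strictly the most extreme of its
margin class, so the p-value equals the observed table's own mass,
1/C(102,22) ≈ 8.4×10⁻²³.

Reported percentages round half away from zero: carrier frequency to an
integer (11/80 → 13.75 → "14%"), cohort white fraction to one decimal
(22/102 → 21.6%). A 2×2 collapse (hom-alt vs rest) is available via
`associate(..., collapse = TRUE)` for the strictly recessive contrast; the
default is the full 2×3 table.

## The synthetic-data generator

`simulate_study()` emulates the study's statistical structure, not its
sequencing: no reads, no coverage model, no reference genome. Defaults
are fixed at the study conditions and are not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `n_animals` | 102 | genotyped cohort size |
| `q` | 0.25 | causal allele frequency (near the cohort allele count 55/204) |
| `n_background` | 500 | unlinked background coding SNVs/indels |
| `n_genes` | 16 | candidate gene models |
| `gene_length_codons` | 300 | CDS length (receptor-gene scale) |
| `indel_rate` | 0.1 | fraction of background sites emitted as indels |
| `qual_range` | [20, 1000] | simulated QUAL |
| `penetrance` | 1 | P(white | hom-alt) |
| `error_rate` | 0 | genotype corruption rate |

Cohort genotypes are Hardy–Weinberg draws; the phenotype is deterministic
from the genotype at default penetrance. The calf receives one maternal
allele (uniform from the dam's two) and a paternal allele that is the
causal allele with probability `q` — sires are not modelled as
individuals. Background sites are unlinked (independent across sites and
animals), which understates the local correlation real linkage would
produce; a real chromosome would carry haplotypes of variants that pass or
fail the trio filter together. Passing tests on this generator therefore
demonstrate the pipeline's logic, not robustness to linkage, batch
effects, or genotyping error.

Two deliberate guarantees keep the generated study well-posed. First, the
implanted causal site is a clean missense call: background sites are kept
more than 3 bp away from it, mirroring the fact that the real causal call
survived quality control. Second, the cohort always contains at least
`min_white = 4` white animals (the sequenced dam plus the three whites the
staged validation needs): when fewer arise from Hardy–Weinberg sampling —
at q = 0.25 a 102-animal cohort falls short of 3 whites in a few percent
of draws — pigmented animals are promoted to hom-alt white with a logged
message. This mirrors how such cohorts are actually assembled: white
animals are collected deliberately, not encountered at population
frequency. The Hardy–Weinberg calibration tests use cohorts large enough
(n = 10,000) that the guarantee never engages.

One cohort × variant genotype matrix is drawn per study, and the trio VCF
and every panel read from it, so an animal's genotype at a site is
identical wherever it appears (nested panels stay consistent). All
randomness derives from the single config seed; small fixed offsets give
each generator stage an independent, reproducible stream.

Analytic calibration: a background variant passes the trio filter iff the
dam is hom-alt (probability q²) and the calf's paternal allele is
reference (probability 1−q); the observed survival fraction is tested
against q²(1−q) within three binomial standard errors.

## Problem sizes and runtime choices

The test suite runs the staged end-to-end recovery on 20 seeds at the
default study conditions (102 animals, 500 background variants) and the
trio-filter calibration at 10,000 background sites; both complete in
about two minutes on one core. These sizes were chosen to give the
binomial checks three-standard-error resolution while keeping the suite
fast; the generator scales to larger cohorts if sharper calibration is
wanted.

## Interfaces and limitations

The package is tidyverse-shaped: readers return tibbles, every pipeline
stage takes and returns a tibble, fitted results (`cascade_report`,
`whitecoat_assoc`, `run_report`) provide `tidy()`/`glance()` and
`autoplot()` methods, and `run_all()` + `write_run_report()` produce a
self-describing JSON report whose embedded config reproduces the run.
R functions and this vignette are the interface; there is no shell
entry point.

Known limitations, all deliberate:

* no BAM/FASTQ handling, no structural variants, and no liftover — the
  pipeline starts at biallelic variant calls against whatever reference
  the caller used;
* no splice-site, UTR, or regulatory annotation: strictly CDS effects;
* no multiple-testing correction or effect-size intervals: the design
  tests a single terminal candidate on the full cohort;
* indel-class sites traverse the cascade untyped (they cannot be the
  answer under this annotator and exit at the non-synonymous stage), so a
  causal indel would be missed — a limitation of the coding-SNV study
  design itself.
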