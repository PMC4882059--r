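---
title: "Genotyping CD177 gene conversion from quantized read dosage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping CD177 gene conversion from quantized read dosage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd177conv)
library(dplyr)
```

## The problem

CD177 is a GPI-anchored neutrophil surface antigen (HNA-2a). Most people
carry a mixture of CD177^hi^ and CD177^neg^ neutrophils; a few percent are
CD177^null^, expressing none, and are at risk of alloimmunisation
(transfusion-related acute lung injury, neonatal alloimmune neutropenia).
The *CD177* gene sits next to a pseudogene, *CD177P1*, homologous to exons
4–9. Because amplicon reads from the homologous exons cannot be assigned to
one locus, a sequencing experiment over this region reports, at every fixed
gene/pseudogene difference (a *paralogous sequence variant*, PSV), the
pooled allele fraction over **four** homologous copies: two gene-locus and
two pseudogene-locus copies.

This package implements the inference that follows from that arithmetic.
The pseudogene's exon 7 carries a premature stop codon (c.787A>T, K263X);
when a gene allele's exon 7 is replaced by the pseudogene homolog through
gene conversion, the chimeric allele is transcribed but truncated. The
variant read fraction at exon-7 PSVs is then quantized:

| gene alleles converted at exon 7 | pseudogene-derived copies | expected variant fraction |
|---|---|---|
| 0 (`ref_hom`) | 2 / 4 | 50% |
| 1 (`ectopic_het`) | 3 / 4 | 75% |
| 2 (`null`) | 4 / 4 | 100% |

`expected_vaf()` is this model; everything else — simulation, calling,
breakpoints, MLPA cross-checks, cohort statistics — is built around it.

## The packaged locus

The locus shipped in `inst/extdata/` is synthetic except where the variant
catalog pins it. The 17 coding variants (9 PSVs in exons 4/5/7, 8 gene
SNPs) fix paired gene-relative (g.) and CDS (c.) coordinates, reference and
variant bases, and the codon contexts needed for consequence annotation
(the exon-7 context makes c.787–789 the lysine codon AAA). Filler bases
were drawn once from a fixed seed at build time, so codon contexts are
stable. Exon boundaries are a design choice: the g./c. pairs fix only the
per-exon coordinate offsets, and we chose compact exons consistent with
every pair.

Two numerical quirks are worth stating plainly:

* The catalogued pair (g.7509, c.798) implies a g.−c. offset one larger
  than the other five exon-7 sites. The coordinate map honors every
  catalogued pair verbatim by mapping exon 7 as two CDS segments separated
  by a one-base alignment gap (g.7502 is unmapped). `g_to_c()` and
  `c_to_g()` therefore round-trip on all catalogued pairs and on every CDS
  position.
* A few catalogued amino-acid labels (`aa_label`) are not reproducible by
  codon arithmetic from the catalogued CDS position (e.g. a third-position
  change cannot produce the labelled missense). The catalog stores those
  labels as historical annotation; `annotate_consequence()` always computes
  the consequence from the packaged sequence. The stop-gain at c.787
  (K263X), the quantity that matters for the null phenotype, computes
  exactly.

```{r}
model <- load_builtin_cd177_model()
annotate_consequence(model, filter(model$sites, site_id == "g.7497")) |>
  select(site_id, c_pos, codon_index, ref_codon, alt_codon, is_stop_gain)
```

## What the simulator emulates — and what it does not

`sim_config()` fixes the study conditions:

* **Cohort structure.** Each gene allele is converted with probability
  `q = 0.16` under random mating, so genotype classes follow Hardy–Weinberg
  ((1−q)², 2q(1−q), q²). The default follows from the observed ~2.6%
  CD177^null^ prevalence: q = √0.026 ≈ 0.16.
* **Conversion tracts.** A heterozygote's single converted allele carries
  the exon-7-only tract. In null genotypes each allele draws its left
  endpoint uniformly from {before exon 5, before exon 7} — the two
  crossover classes observed in CD177^null^ genomes. Tracts are contiguous
  exon runs within 4–9.
* **Reads.** `var_count ~ Binomial(9000, f)` per site, with symmetric
  base-flip error e = 0.005 moving f to f(1−e) + (1−f)e. The study depth
  (>9,000×) is given; the error model and its rate are our choice of a
  typical short-read substitution rate.
* **Pseudogene exon-4 polymorphism.** The exon-4 PSV also varies on the
  pseudogene locus in the population (a *CD177P1* allele carrying the gene
  base, frequency 0.2 by default), producing 25/50/75% exon-4 levels that
  are independent of conversion. This is what lets the site classifier see
  quarter-levels at exon 4 without any exon-4 conversion tract.
* **MLPA.** Noiseless peak height is proportional to target copies
  (gene-only probe: 2; shared probes: 4 regardless of conversion;
  pseudogene-specific probe for exon e: 2 + converted alleles covering e),
  with multiplicative log-normal noise at CV 4% by default.
* **Phenotype.** `pct_hi` is a clipped normal with ordered class means
  (ref_hom 85, ectopic_het 45, SD 10); nulls are fixed at 100% negative.
  The intermediate subset is small (mean 3%) except in an "atypical" mode
  (>20% intermediate, genotype-independent, off by default). Only the
  ordering and the null are published facts; the numbers are a plausible
  rendering of the published dot plots.
* **Germline model.** Saliva profiles are independent binomial draws from
  the same genotype; there is no somatic-mosaicism option, because the
  study found perfect tissue concordance.

Passing tests on this generator show that the inference correctly inverts
the model it assumes — quantized dosage, unlinked noise, complete site
coverage. They do not establish robustness to real-data pathologies the
generator omits: allele-specific amplification bias, coverage dropout,
index hopping, CNVs that change total copy number, or tracts with endpoints
inside exons.

## Calling rules and numerical choices

* **Site quantization** (`call_sites()`): exact Clopper–Pearson intervals
  (via `qbeta`) at 99% two-sided confidence. The configured error rate is
  treated as an *upper bound*: level k predicts a fraction anywhere in the
  band between k/4 and its fully error-shifted value, and a level is
  assigned only when the confidence interval intersects exactly one band;
  otherwise the site is ambiguous. The band form matters at the boundary
  levels: a site with all 9,000 reads variant has CI [0.9994, 1], which
  excludes the point prediction 0.995 but intersects the band [0.995, 1].
* **Genotype call** (`call_genotype()`): at least 4 of the 5 exon-7 PSV
  levels must agree (tolerates one dropout); anything less is `unresolved`.
  By construction miscalls surface as `unresolved` rather than as wrong
  confident classes — at depth 9,000 the three levels are ~25 binomial
  standard deviations apart, so confident errors are vanishingly rare.
* **Copy interpretation.** A variant level of 75/100% at an exon maps to
  1/0 gene-derived copies. A level *below* 50% means a pseudogene-locus
  copy carries the gene base; the gene locus still has its 2 copies, so the
  call keeps `gene_copies = 2` and flags `pseudogene_locus_variation`.
* **Heterozygote phase.** A 75% exon-7 level is attributed to one converted
  gene allele rather than a pseudogene duplication; the MLPA integration
  (`mlpa_integrate()`) is the structural tiebreaker — a duplication of the
  pseudogene-specific exon-7 probe with all shared probes normal is exactly
  the conversion signature, since conversion moves sequence between
  paralogs without changing total copy number.
* **Breakpoints** (`infer_breakpoint()`): the crossover is bracketed
  half-open between the last exon retaining the expected gene copy count
  and the first with a deficit. Copy counts are only assayed at PSV-bearing
  exons (4, 5, 7), so intervals are between assayed exons, not base-precise.
  Non-monotone patterns (deficit then restoration) are reported as flagged
  multi-interval complex events rather than forced into one interval.
* **MLPA normalization**: peak height ÷ mean control-probe height within
  sample, then ÷ the mean of that ratio across ≥3 declared control samples;
  deletion below 0.75, duplication above 1.25 (configurable); copy number
  integerized as `round(ratio × expected_copies)`.
* **Hardy–Weinberg** (`hwe_test()`): 1-df chi-square against expectations
  at the estimated allele frequency, plus the observed/expected
  heterozygosity ratio. The source material quotes a single
  "Hardy-Weinberg ratio (= 0.9998)" without defining the statistic; we
  report both standard quantities rather than guess the formula.
* **Association** (`associate()`): Spearman and Kruskal–Wallis on
  untransformed percentages — the published relation is shown as dot plots
  without a stated model, so rank statistics assume only the ordering.
* **Haplotype enumeration** (`enumerate_haplotypes()`): exhaustive over
  base assignments to the four copies with pseudogene exon-7 slots fixed to
  the divergent base, collapsing configurations equal up to chromosome
  swap. Observed level combinations can be consistent with several
  configurations (e.g. 50%/50% admits four); all are returned.

## Worked example

```{r}
cfg <- sim_config(n_samples = 200, q = 0.16, seed = 7)
truth <- simulate_cohort(cfg)
reads <- simulate_reads(truth, model, cfg)
calls <- call_genotype(reads, model, error_rate = cfg$error_rate)
count(calls, exon7_class)

glance(hwe_test(sum(calls$exon7_class == "ref_hom"),
                sum(calls$exon7_class == "ectopic_het"),
                sum(calls$exon7_class == "null")))

pheno <- simulate_phenotype(truth, cfg)
tidy(associate(inner_join(select(calls, sample_id, exon7_class),
                          select(pheno, -exon7_class), by = "sample_id")))
```

## Problem sizes

The shipped tests exercise the cohort pipeline at 10^4 samples × 17 sites
for genotype recovery, 10^4 replicate probe draws for MLPA state recovery,
10^3 replicate cohorts of 500 for the Hardy–Weinberg null, and 10^5
genotype draws for class-frequency convergence — sizes at which the
binomial standard errors make the assertions sharp while the whole suite
runs in well under a minute of compute.

## Known limitations

* Conversion tracts are modelled at exon granularity; intra-exon breakpoint
  refinement is out of scope (the assay only observes PSV-bearing exons).
* SNP genotypes are an optional overlay (`snp_dosage`) and independent of
  conversion state; linkage between SNP haplotypes and conversion alleles
  is not modelled.
* The VCF export is a flat per-site allele-depth table for interoperability,
  not a phased genotype representation.
* `classify_site()` needs cohort-level quarter-fraction evidence; on a
  cohort where a PSV happens never to deviate from 50% it returns
  `unknown`, by design.
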