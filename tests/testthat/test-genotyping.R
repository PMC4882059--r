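test_that("exact binomial interval matches the binom.test oracle", {
  cases <- expand.grid(x = c(0, 1, 17, 2210, 4500, 6790, 8999, 9000),
                       n = 9000)
  cases <- rbind(cases, data.frame(x = c(0, 3, 7, 10), n = 10))
  cases <- cases[cases$x <= cases$n, ]
  got <- call_site(cases$n - cases$x, cases$x, confidence = 0.99)
  for (i in seq_len(nrow(cases))) {
    oracle <- binom.test(cases$x[i], cases$n[i],
                         conf.level = 0.99)$conf.int
    expect_equal(got$ci_lo[i], oracle[1], tolerance = 1e-12)
    expect_equal(got$ci_hi[i], oracle[2], tolerance = 1e-12)
  }
})

test_that("site quantization assigns the unique level inside the CI", {
  expect_equal(call_site(0, 9000)$level, 100L)
  expect_equal(call_site(4500, 4500)$level, 50L)
  # 6790/9000 = 0.754: CI excludes 50 and 100
  c75 <- call_site(2210, 6790)
  expect_equal(c75$level, 75L)
  expect_false(c75$ambiguous)
  expect_true(c75$ci_lo <= c75$vaf && c75$vaf <= c75$ci_hi)
  # shallow ambiguous site: CI covers several quanta
  amb <- call_site(3, 4)
  expect_true(amb$ambiguous)
  expect_true(is.na(amb$level))
  expect_error(call_site(0, 0), class = "cd177conv_depth_error")
})

test_that("quantized level is monotone in the variant count", {
  n <- 2000L
  lev <- call_sites(tibble::tibble(ref_count = n - (0:n),
                                   var_count = 0:n))$level
  expect_true(all(diff(lev[!is.na(lev)]) >= 0))
  # and in a sparse scan of a deep site
  xs <- seq(0L, 9000L, by = 250L)
  lev2 <- call_sites(tibble::tibble(ref_count = 9000L - xs,
                                    var_count = xs))$level
  expect_true(all(diff(lev2[!is.na(lev2)]) >= 0))
})

test_that("genotype calling maps exon-7 PSV levels to conversion classes", {
  prof <- dplyr::bind_rows(noiseless_profile(ref_hom_gt("a")),
                           noiseless_profile(ectopic_het_gt("b")),
                           noiseless_profile(null_gt("c")))
  calls <- call_genotype(prof, the_model, error_rate = 0)
  got <- setNames(calls$exon7_class, calls$sample_id)
  expect_equal(got[["a"]], "ref_hom")
  expect_equal(got[["b"]], "ectopic_het")
  expect_equal(got[["c"]], "null")
  expect_true(all(calls$exon7_concordant))
  # per-exon gene copies follow the dosage arithmetic
  expect_equal(calls$gene_copies_exon7[calls$sample_id == "a"], 2L)
  expect_equal(calls$gene_copies_exon7[calls$sample_id == "b"], 1L)
  expect_equal(calls$gene_copies_exon7[calls$sample_id == "c"], 0L)
  expect_equal(calls$gene_copies_exon4[calls$sample_id == "c"], 2L)
})

test_that("conflicting exon-7 levels resolve by supermajority or not at
           all", {
  prof <- noiseless_profile(ectopic_het_gt("s"))
  # one dropout site still resolves (4/5 agree)
  drop1 <- dplyr::mutate(prof, var_count = dplyr::if_else(
    site_id == "g.7492", as.integer(round(depth * 0.5)), var_count),
    ref_count = depth - var_count)
  c1 <- call_genotype(drop1, the_model, error_rate = 0)
  expect_equal(c1$exon7_class, "ectopic_het")
  expect_false(c1$exon7_concordant)
  # two conflicting sites -> unresolved, never a wrong confident class
  drop2 <- dplyr::mutate(prof, var_count = dplyr::if_else(
    site_id %in% c("g.7492", "g.7496"), as.integer(round(depth * 0.5)),
    var_count), ref_count = depth - var_count)
  c2 <- call_genotype(drop2, the_model, error_rate = 0)
  expect_equal(c2$exon7_class, "unresolved")
  expect_equal(c2$qc_flags, "exon7_discordant")
  # a profile without exon-7 PSVs is insufficient input
  no7 <- dplyr::filter(prof, !site_id %in% exon7_psv_ids)
  expect_error(call_genotype(no7, the_model),
               class = "cd177conv_input_error")
})

test_that("cohort-scale genotype recovery is near-perfect with unresolved
           as the only failure mode", {
  cfg <- sim_config(n_samples = 2000, q = 0.16, depth = 9000,
                    error_rate = 0.005, seed = 21)
  truth <- simulate_cohort(cfg)
  reads <- simulate_reads(truth, the_model, cfg)
  calls <- call_genotype(reads, the_model, error_rate = cfg$error_rate)
  merged <- dplyr::inner_join(truth, calls, by = "sample_id")
  confident <- merged$exon7_class.y != "unresolved"
  # no confident miscalls at all
  expect_true(all(merged$exon7_class.x[confident] ==
                    merged$exon7_class.y[confident]))
  expect_gte(mean(merged$exon7_class.x == merged$exon7_class.y), 0.999)
})

test_that("site classification separates gene SNPs from paralog
           divergence", {
  cdna <- c("G", "A")  # bases seen in intact-allele transcripts
  e2 <- dplyr::filter(the_model$sites, site_id == "g.242")
  expect_equal(classify_site(e2, cohort_levels = c(0L, 50L), cdna), "SNP")
  e8 <- dplyr::filter(the_model$sites, site_id == "g.7968")
  expect_equal(classify_site(e8, cohort_levels = c(0L, 50L),
                             cdna_bases = c("G", "A")), "SNP")
  e5 <- dplyr::filter(the_model$sites, site_id == "g.2368")
  expect_equal(classify_site(e5, cohort_levels = c(25L, 50L, 75L),
                             cdna_bases = "T"), "PSV")
  # no quarter-level evidence and absent from cDNA -> unknown
  expect_equal(classify_site(e5, cohort_levels = c(0L, 50L),
                             cdna_bases = "T"), "unknown")
  # every catalogued exon-4/5/7 divergence site classifies as PSV on
  # simulated cohort + cDNA evidence; every exon-1/2 site as SNP
  cfg <- sim_config(n_samples = 50, q = 0.3, seed = 22)
  truth <- simulate_cohort(cfg)
  reads <- simulate_reads(truth, the_model, cfg)
  levels_by_site <- call_sites(reads, error_rate = cfg$error_rate) |>
    dplyr::group_by(site_id) |>
    dplyr::summarise(lv = list(level))
  intact_tx <- simulate_transcripts("intact", "intact", "hi", the_model)
  for (i in seq_len(nrow(the_model$sites))) {
    site <- the_model$sites[i, ]
    lv <- levels_by_site$lv[[match(site$site_id, levels_by_site$site_id)]]
    cls <- classify_site(site, lv, intact_tx$bases[[1]][[site$site_id]])
    if (site$site_class == "PSV") expect_equal(cls, "PSV")
    if (site$exon <= 3L) expect_equal(cls, "SNP")
  }
})

test_that("breakpoint intervals bracket the copy-count transition", {
  b1 <- infer_breakpoint(c("4" = 2, "5" = 0, "7" = 0))
  expect_equal(b1$left_exon, 4L)
  expect_equal(b1$right_exon, 5L)
  expect_false(b1$complex)
  b2 <- infer_breakpoint(c("4" = 2, "5" = 2, "7" = 0))
  expect_equal(b2$left_exon, 5L)
  expect_equal(b2$right_exon, 7L)
  b3 <- infer_breakpoint(c("4" = 2, "5" = 2, "7" = 2))
  expect_equal(nrow(b3), 0L)
  # per-allele scope for a heterozygous tract
  b4 <- infer_breakpoint(c("4" = 1, "5" = 1, "7" = 1), expected = 1,
                         scope = "allele")
  expect_equal(nrow(b4), 0L)
  b5 <- infer_breakpoint(c("4" = 2, "5" = 1, "7" = 1), scope = "allele")
  expect_equal(b5$scope, "allele")
  # deficit at the first assayed exon leaves the left bound open
  b6 <- infer_breakpoint(c("4" = 0, "5" = 0, "7" = 0))
  expect_true(is.na(b6$left_exon))
  expect_equal(b6$right_exon, 4L)
  # deficit followed by restoration is complex with entry and exit bounds
  b7 <- infer_breakpoint(c("4" = 2, "5" = 0, "7" = 2))
  expect_true(all(b7$complex))
  expect_equal(b7$boundary, c("entry", "exit"))
  expect_equal(b7$right_exon, c(5L, 7L))
  expect_error(infer_breakpoint(c("4" = 2)),
               class = "cd177conv_input_error")
})

test_that("germline concordance verdicts", {
  cfg <- sim_config(n_samples = 3, q = 0.4, depth = 9000, seed = 23)
  truth <- simulate_cohort(cfg)
  neut <- simulate_reads(truth, the_model, cfg, "neutrophil")
  sal <- simulate_reads(truth, the_model, cfg, "saliva")
  for (s in truth$sample_id) {
    conc <- germline_concordance(dplyr::filter(neut, sample_id == s),
                                 dplyr::filter(sal, sample_id == s),
                                 error_rate = cfg$error_rate)
    expect_equal(conc$verdict, "germline")
    expect_equal(conc$n_agree, conc$n_compared)
  }
  # constructed somatic counterexample: 50 vs 75 at exon 7
  n50 <- dplyr::mutate(noiseless_profile(ref_hom_gt("x")),
                       tissue = "neutrophil")
  s75 <- dplyr::mutate(noiseless_profile(ectopic_het_gt("x")),
                       tissue = "saliva")
  conc2 <- germline_concordance(n50, s75, error_rate = 0)
  expect_equal(conc2$verdict, "somatic_difference")
  expect_true(conc2$somatic_flag)
  # same tissue label on both sides is misuse
  expect_error(germline_concordance(n50, dplyr::mutate(s75, tissue =
                                                         "neutrophil")),
               class = "cd177conv_input_error")
})

test_that("haplotype enumeration agrees with exhaustive assignment search", {
  # independent oracle: loop over all base assignments to the four copies
  # (1 = reference base), canonicalize by treating the two chromosomes --
  # each a (gene exon4, gene exon7, P1 exon4, P1 exon7) tuple -- as
  # unordered, and count distinct configurations.
  oracle_configs <- function(l4, l7) {
    seen <- character(0)
    for (bits4 in 0:15) for (bits7 in 0:15) {
      a4 <- as.integer(intToBits(bits4))[1:4]
      a7 <- as.integer(intToBits(bits7))[1:4]
      if (any(a7[3:4] == 1)) next  # pseudogene exon-7 slots fixed to T
      if (sum(a4) * 25 != l4 || sum(a7) * 25 != l7) next
      chrom <- vapply(1:2, function(i) {
        paste(a4[i], a7[i], a4[i + 2], a7[i + 2], sep = ",")
      }, character(1))
      seen <- c(seen, paste(sort(chrom), collapse = "|"))
    }
    unique(seen)
  }
  for (l4 in seq(0, 100, 25)) for (l7 in seq(0, 100, 25)) {
    oracle <- oracle_configs(l4, l7)
    if (length(oracle) == 0) {
      expect_error(enumerate_haplotypes(l4, l7),
                   class = "cd177conv_model_error")
    } else {
      cfgs <- enumerate_haplotypes(l4, l7)
      expect_equal(max(cfgs$config_id), length(oracle))
      # every returned configuration reproduces both levels
      for (cf in split(cfgs, cfgs$config_id)) {
        expect_equal(sum(c(cf$gene_exon4, cf$p1_exon4) == "C") * 25, l4)
        expect_equal(sum(c(cf$gene_exon7, cf$p1_exon7) == "A") * 25, l7)
      }
    }
  }
  # the 50/50 case: the all-reference arrangement (gene C/C + A/A,
  # pseudogene G/G + T/T) is among the consistent configurations; exon-4
  # heterozygosity on either locus accounts for the alternatives
  u <- enumerate_haplotypes(50, 50)
  expect_setequal(u$gene_exon7, "A")
  expect_setequal(u$p1_exon7, "T")
  allref <- split(u, u$config_id) |>
    purrr::keep(\(cf) all(cf$gene_exon4 == "C") && all(cf$p1_exon4 == "G"))
  expect_equal(length(allref), 1L)
  # exon-7 ref level 0: both gene slots carry the pseudogene base (null)
  v <- enumerate_haplotypes(50, 0)
  expect_setequal(v$gene_exon7, "T")
  # 75% ref at exon 4 with 50% at exon 7: some configuration carries the
  # gene base on a pseudogene exon-4 slot
  w <- enumerate_haplotypes(75, 50)
  expect_true(any(w$p1_exon4 == "C"))
})
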