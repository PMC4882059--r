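test_that("cohort genotype frequencies follow Hardy-Weinberg sampling", {
  # degenerate allele frequencies
  all_ref <- simulate_cohort(sim_config(n_samples = 50, q = 0, seed = 7))
  expect_true(all(all_ref$exon7_class == "ref_hom"))
  all_null <- simulate_cohort(sim_config(n_samples = 50, q = 1, seed = 7))
  expect_true(all(all_null$exon7_class == "null"))
  # q = 0.16: homozygous-converted fraction within 3 s.e. of q^2
  n <- 1e5
  truth <- simulate_cohort(sim_config(n_samples = n, q = 0.16, seed = 11))
  p_null <- mean(truth$exon7_class == "null")
  se <- sqrt(0.16^2 * (1 - 0.16^2) / n)
  expect_lt(abs(p_null - 0.0256), 3 * se)
})

test_that("simulated outputs are byte-identical under a fixed seed", {
  cfg <- sim_config(n_samples = 30, seed = 42)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  truth <- simulate_cohort(cfg)
  expect_identical(simulate_reads(truth, the_model, cfg),
                   simulate_reads(truth, the_model, cfg))
  expect_identical(simulate_mlpa(truth, mlpa_probe_panel(), cfg),
                   simulate_mlpa(truth, mlpa_probe_panel(), cfg))
  expect_identical(simulate_phenotype(truth, cfg),
                   simulate_phenotype(truth, cfg))
})

test_that("read dosage model yields the quarter-copy quanta at zero error", {
  cases <- list(list(gt = ref_hom_gt(), want = 0.50),
                list(gt = ectopic_het_gt(), want = 0.75),
                list(gt = null_gt(), want = 1.00))
  for (case in cases) {
    ev <- expected_vaf(case$gt, the_model, error_rate = 0)
    e7 <- dplyr::filter(ev, site_id %in% exon7_psv_ids)
    expect_equal(e7$true_vaf, rep(case$want, 5))
  }
  # conservation + quantization at every site and genotype
  gts <- dplyr::bind_rows(ref_hom_gt("a"), ectopic_het_gt("b"),
                          null_gt("c"), null_gt("d", "converted:5-7"))
  ev <- expected_vaf(gts, the_model, error_rate = 0)
  expect_true(all(ev$true_vaf %in% ((0:4) / 4)))
  # error rate shifts fractions symmetrically: f -> f(1-e) + (1-f)e
  e <- 0.005
  ev_e <- expected_vaf(gts, the_model, error_rate = e)
  expect_equal(ev_e$true_vaf, ev$true_vaf * (1 - e) + (1 - ev$true_vaf) * e)
})

test_that("tract extent controls which exons show pseudogene dosage", {
  ev <- expected_vaf(null_gt("x", "converted:5-7"), the_model, 0)
  by_site <- setNames(ev$true_vaf, ev$site_id)
  expect_equal(by_site[["g.1991"]], 0.50)   # exon 4 retained
  expect_equal(by_site[["g.2368"]], 1.00)   # exon 5 converted
  expect_equal(by_site[["g.7497"]], 1.00)   # exon 7 converted
  # SNP dosage rides on chromosomes, not on conversion state
  snp <- tibble::tibble(sample_id = "x", site_id = "g.6724", dosage = 1)
  ev2 <- expected_vaf(null_gt("x"), the_model, 0, snp_dosage = snp)
  expect_equal(ev2$true_vaf[ev2$site_id == "g.6724"], 0.5)
})

test_that("saliva profiles are drawn from the same germline genotype", {
  cfg <- sim_config(n_samples = 10, seed = 3)
  truth <- simulate_cohort(cfg)
  neut <- simulate_reads(truth, the_model, cfg, tissue = "neutrophil")
  sal <- simulate_reads(truth, the_model, cfg, tissue = "saliva")
  expect_equal(unique(neut$tissue), "neutrophil")
  expect_equal(unique(sal$tissue), "saliva")
  # same expected fractions: observed VAFs agree within binomial noise
  merged <- dplyr::inner_join(
    dplyr::select(neut, sample_id, site_id,
                  v_n = var_count, d = depth),
    dplyr::select(sal, sample_id, site_id, v_s = var_count),
    by = c("sample_id", "site_id"))
  expect_lt(max(abs(merged$v_n - merged$v_s) / merged$d), 0.05)
  # but they are independent draws, not copies
  expect_false(identical(merged$v_n, merged$v_s))
})

test_that("transcript simulation mirrors the subset-specific expression
           model", {
  hi <- simulate_transcripts("intact", "intact", "hi", the_model)
  expect_equal(nrow(hi), 1L)  # identical haplotypes collapse
  expect_equal(hi$bases[[1]][["g.7497"]], "A")
  expect_false(any(hi$chimeric))

  neg <- simulate_transcripts("intact", "converted:7-7", "neg", the_model)
  expect_equal(nrow(neg), 2L)
  chim <- dplyr::filter(neg, chimeric)
  expect_equal(nrow(chim), 1L)
  expect_true(chim$stop_containing)
  expect_equal(chim$bases[[1]][["g.7497"]], "T")
  expect_equal(chim$bases[[1]][["g.242"]],
               dplyr::filter(the_model$sites, site_id == "g.242")$ref_base)

  nullneg <- simulate_transcripts("converted:7-7", "converted:5-7", "neg",
                                  the_model)
  expect_true(all(nullneg$chimeric))
  expect_true(all(nullneg$stop_containing))
  expect_error(simulate_transcripts("converted:7-7", "converted:7-7", "hi",
                                    the_model),
               class = "cd177conv_subset_error")
})

test_that("phenotype model orders classes and fixes the null at 100% neg", {
  cfg <- sim_config(n_samples = 1, seed = 5)
  ph_null <- simulate_phenotype(null_gt(), cfg)
  expect_equal(ph_null$pct_hi, 0)
  expect_equal(ph_null$pct_int, 0)
  expect_equal(ph_null$pct_neg, 100)
  # zero dispersion reproduces the configured class means exactly
  cfg0 <- sim_config(n_samples = 1, pheno_sd = 0, int_sd = 0, mfi_cv = 0,
                     seed = 5)
  ph0 <- simulate_phenotype(ref_hom_gt(), cfg0)
  expect_equal(ph0$pct_hi, 85)
  expect_equal(ph0$pct_int, 3)
  expect_equal(ph0$mfi, 5000)
  # sampled ordering of class means
  cfg2 <- sim_config(n_samples = 200, seed = 6)
  ph_rh <- simulate_phenotype(
    simulate_cohort(sim_config(200, q = 0, seed = 6)), cfg2)
  ph_eh <- simulate_phenotype(
    tibble::tibble(sample_id = sprintf("E%d", 1:200), allele1 = "intact",
                   allele2 = "converted:7-7"), cfg2)
  expect_gt(mean(ph_rh$pct_hi), mean(ph_eh$pct_hi))
  # percentages partition the neutrophil pool
  expect_true(all(abs(ph_eh$pct_hi + ph_eh$pct_int + ph_eh$pct_neg - 100)
                  < 1e-9))
  expect_true(all(ph_eh$pct_neg >= 0 & ph_eh$pct_neg <= 100))
  # atypical mode pushes pct_int above the 20% rule
  cfg_a <- sim_config(n_samples = 100, atypical_rate = 1, seed = 8)
  ph_a <- simulate_phenotype(
    tibble::tibble(sample_id = sprintf("A%d", 1:100), allele1 = "intact",
                   allele2 = "intact"), cfg_a)
  expect_gt(mean(ph_a$pct_int > 20), 0.9)
})

test_that("pedigree simulation transmits one allele per parent", {
  cfg <- sim_config(seed = 9)
  # homozygous-intact parents: all offspring intact/intact
  ped1 <- simulate_pedigree(c("intact", "intact"), c("intact", "intact"),
                            5L, cfg, "P1")
  kids1 <- dplyr::filter(ped1, !is.na(father_id))
  expect_true(all(kids1$exon7_class == "ref_hom"))
  # converted x converted: all offspring null
  ped3 <- simulate_pedigree(rep("converted:7-7", 2), rep("converted:7-7", 2),
                            4L, cfg, "P3")
  expect_true(all(dplyr::filter(ped3, !is.na(father_id))$exon7_class ==
                    "null"))
  # het x ref: offspring ectopic_het with probability 1/2
  cfg_big <- sim_config(seed = 10)
  ped2 <- simulate_pedigree(c("intact", "converted:7-7"),
                            c("intact", "intact"), 400L, cfg_big, "P2")
  kids2 <- dplyr::filter(ped2, !is.na(father_id))
  frac_het <- mean(kids2$exon7_class == "ectopic_het")
  expect_lt(abs(frac_het - 0.5), 3 * sqrt(0.25 / 400))
  # no offspring allele absent from its parents (property over a mixed case)
  ped4 <- simulate_pedigree(c("converted:5-7", "intact"),
                            c("converted:7-7", "intact"), 50L, cfg, "P4")
  kids4 <- dplyr::filter(ped4, !is.na(father_id))
  expect_true(all(kids4$allele1 %in% c("converted:5-7", "intact")))
  expect_true(all(kids4$allele2 %in% c("converted:7-7", "intact")))
})
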