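#' Simulation configuration
#'
#' Bundles the study conditions the generators emulate: cohort size, the
#' population frequency of the converted CD177 allele, amplicon read depth,
#' per-base sequencing error, MLPA peak noise, and the phenotype model.
#' Defaults follow the study design: read depth 9,000x; conversion-allele
#' frequency 0.16 (a 2.6% CD177null prevalence is q^2 with q ~ 0.16);
#' symmetric base-flip error 0.005; phenotype class means ordered
#' ref_hom > ectopic_het with the null fixed at 100% CD177neg.
#'
#' @param n_samples Cohort size.
#' @param q Converted-allele frequency, in `[0, 1]`.
#' @param depth Read depth per site.
#' @param error_rate Symmetric per-base error; the expected variant fraction
#'   `f` becomes `f (1 - e) + (1 - f) e`.
#' @param mlpa_cv Coefficient of variation of the multiplicative log-normal
#'   MLPA peak noise.
#' @param pheno_mean_hi Mean `pct_hi` for ref_hom and ectopic_het classes.
#' @param pheno_sd Standard deviation of `pct_hi` (0 = deterministic means).
#' @param int_mean,int_sd Mean/SD of the small CD177int subset.
#' @param atypical_rate Probability, independent of genotype, of the atypical
#'   expression mode in which `pct_int` is drawn around `atypical_int_mean`
#'   (> 20%).
#' @param atypical_int_mean Mean `pct_int` in the atypical mode.
#' @param mfi_mean Named mean surface-expression MFI per genotype class.
#' @param mfi_cv MFI coefficient of variation.
#' @param p1_exon4_c_freq Population frequency of the pseudogene allele
#'   whose exon-4 slot carries the gene base (C at the exon-4 PSV). This
#'   pseudogene-locus polymorphism shifts the exon-4 variant level by
#'   quarter steps independently of conversion, producing the 25/50/75
#'   exon-4 levels seen alongside a flat 50 at exon 7.
#' @param seed Integer seed recorded in all outputs.
#' @return A list of class `cd177_sim_config`.
#' @export
sim_config <- function(n_samples = 500L, q = 0.16, depth = 9000L,
                       error_rate = 0.005, mlpa_cv = 0.04,
                       pheno_mean_hi = c(ref_hom = 85, ectopic_het = 45),
                       pheno_sd = 10, int_mean = 3, int_sd = 2,
                       atypical_rate = 0, atypical_int_mean = 30,
                       mfi_mean = c(ref_hom = 5000, ectopic_het = 2500,
                                    null = 30),
                       mfi_cv = 0.2, p1_exon4_c_freq = 0.2, seed = 1L) {
  stopifnot(q >= 0, q <= 1, depth > 0, error_rate >= 0, error_rate < 0.5,
            n_samples >= 1, mlpa_cv >= 0, pheno_sd >= 0,
            p1_exon4_c_freq >= 0, p1_exon4_c_freq <= 1,
            is.numeric(seed), length(seed) == 1)
  structure(list(n_samples = as.integer(n_samples), q = q,
                 depth = as.integer(depth), error_rate = error_rate,
                 mlpa_cv = mlpa_cv, pheno_mean_hi = pheno_mean_hi,
                 pheno_sd = pheno_sd, int_mean = int_mean, int_sd = int_sd,
                 atypical_rate = atypical_rate,
                 atypical_int_mean = atypical_int_mean,
                 mfi_mean = mfi_mean, mfi_cv = mfi_cv,
                 p1_exon4_c_freq = p1_exon4_c_freq,
                 seed = as.integer(seed)),
            class = "cd177_sim_config")
}

with_sim_seed <- function(cfg, offset, code) {
  withr::with_seed(cfg$seed + offset, code)
}

#' Simulate a cohort of conversion genotypes under Hardy-Weinberg
#'
#' Each gene-locus allele is converted with probability `q` independently
#' (random mating), so class frequencies converge to `(1-q)^2`, `2q(1-q)`,
#' `q^2`. Tracts: a single converted allele in a heterozygote carries the
#' exon-7-only tract; in a null genotype each allele independently draws its
#' left endpoint from {before exon 5, before exon 7}, the two breakpoint
#' classes seen in CD177null genomes.
#'
#' @param cfg A [sim_config()].
#' @return Truth tibble: `sample_id`, `allele1`, `allele2`, `exon7_class`,
#'   with the seed in `attr(, "seed")`.
#' @export
simulate_cohort <- function(cfg) {
  truth <- with_sim_seed(cfg, 101L, {
    n <- cfg$n_samples
    conv1 <- stats::runif(n) < cfg$q
    conv2 <- stats::runif(n) < cfg$q
    tract <- function(is_conv, both) {
      dplyr::case_when(
        !is_conv ~ "intact",
        both ~ sample(c("converted:5-7", "converted:7-7"), length(is_conv),
                      replace = TRUE),
        TRUE ~ "converted:7-7")
    }
    both <- conv1 & conv2
    tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      allele1 = tract(conv1, both),
      allele2 = tract(conv2, both),
      n_p1_c_exon4 = rbinom(n, 2L, cfg$p1_exon4_c_freq))
  })
  truth$exon7_class <- exon7_class(truth$allele1, truth$allele2)
  attr(truth, "seed") <- cfg$seed
  truth
}

#' Expected variant-allele fraction under the four-copy dosage model
#'
#' The core read-dosage model. At a PSV in exon `e`, reads pool the four
#' homologous copies (two gene-locus, two pseudogene-locus); the
#' pseudogene-divergent base is carried by `2 + n_conv(e)` of them, where
#' `n_conv(e)` is the number of gene alleles converted at `e`, giving
#' expected variant fractions 2/4, 3/4 or 4/4. At SNP sites the variant
#' fraction is `dosage / 2` for a dosage of 0-2 variant-carrying
#' chromosomes: in exons 1-3 only the two gene copies are read; in exons 4-9
#' each chromosome contributes its gene and pseudogene copy alike, so the
#' fraction is unchanged. Sequencing error moves `f` to `f(1-e) + (1-f)e`.
#'
#' @param genotypes Truth tibble (`sample_id`, `allele1`, `allele2`).
#' @param model A `cd177_locus`.
#' @param error_rate Symmetric base-flip error rate.
#' @param snp_dosage Optional tibble (`sample_id`, `site_id`, `dosage`)
#'   giving variant-chromosome counts at SNP sites; absent pairs are 0.
#'
#' If `genotypes` carries an `n_p1_c_exon4` column (pseudogene-locus copies
#' whose exon-4 slot holds the gene base), those copies are subtracted from
#' the pseudogene-derived count at exon-4 PSV sites, lowering the variant
#' level by 25 points each.
#' @return Tibble: one row per sample x catalogued site with `true_vaf`.
#' @examples
#' model <- load_builtin_cd177_model()
#' het <- tibble::tibble(sample_id = "A", allele1 = "intact",
#'                       allele2 = "converted:7-7")
#' ev <- expected_vaf(het, model, error_rate = 0)
#' ev$true_vaf[ev$site_id == "g.7497"]  # 0.75
#' @export
expected_vaf <- function(genotypes, model, error_rate = 0,
                         snp_dosage = NULL) {
  copies <- gene_copies_by_exon(
    dplyr::select(genotypes, "sample_id", "allele1", "allele2"))
  grid <- tidyr::crossing(
    dplyr::select(genotypes, "sample_id"),
    dplyr::select(model$sites, "site_id", "g_pos", "exon", "site_class")) |>
    dplyr::left_join(
      dplyr::select(copies, "sample_id", "exon", "pseudogene_copies"),
      by = c("sample_id", "exon"))
  if (is.null(snp_dosage)) {
    grid$dosage <- 0
  } else {
    grid <- dplyr::left_join(grid, snp_dosage,
                             by = c("sample_id", "site_id")) |>
      dplyr::mutate(dosage = dplyr::coalesce(.data$dosage, 0))
  }
  if ("n_p1_c_exon4" %in% names(genotypes)) {
    grid <- dplyr::left_join(
      grid, dplyr::select(genotypes, "sample_id", "n_p1_c_exon4"),
      by = "sample_id") |>
      dplyr::mutate(pseudogene_copies = dplyr::if_else(
        .data$site_class == "PSV" & .data$exon == 4L,
        .data$pseudogene_copies - dplyr::coalesce(.data$n_p1_c_exon4, 0L),
        .data$pseudogene_copies)) |>
      dplyr::select(-"n_p1_c_exon4")
  }
  grid |>
    dplyr::mutate(
      f = dplyr::if_else(.data$site_class == "PSV",
                         .data$pseudogene_copies / 4,
                         .data$dosage / 2),
      true_vaf = .data$f * (1 - error_rate) + (1 - .data$f) * error_rate) |>
    dplyr::select(-"f", -"pseudogene_copies", -"dosage")
}

#' Simulate per-site allele counts for a cohort
#'
#' Draws `var_count ~ Binomial(depth, f)` at every catalogued site with `f`
#' from [expected_vaf()]. Saliva and neutrophil profiles are drawn from the
#' same genotype (the germline model): the same call with
#' `tissue = "saliva"` yields an independent draw from identical expected
#' fractions.
#'
#' @inheritParams expected_vaf
#' @param cfg A [sim_config()] (depth, error rate, seed).
#' @param tissue `"neutrophil"` or `"saliva"`.
#' @return Tibble: `sample_id`, `tissue`, `site_id`, `g_pos`, `exon`,
#'   `site_class`, `ref_count`, `var_count`, `depth`.
#' @export
simulate_reads <- function(genotypes, model, cfg, tissue = "neutrophil",
                           snp_dosage = NULL) {
  tissue <- match.arg(tissue, c("neutrophil", "saliva"))
  ev <- expected_vaf(genotypes, model, cfg$error_rate, snp_dosage)
  offset <- if (tissue == "neutrophil") 211L else 223L
  ev$var_count <- with_sim_seed(cfg, offset,
                                rbinom(nrow(ev), cfg$depth, ev$true_vaf))
  ev |>
    dplyr::mutate(tissue = tissue, depth = cfg$depth,
                  ref_count = .data$depth - .data$var_count) |>
    dplyr::select("sample_id", "tissue", "site_id", "g_pos", "exon",
                  "site_class", "ref_count", "var_count", "depth")
}

#' Simulate MLPA peak heights
#'
#' Noiseless peak height is proportional to target copy number under the
#' genotype: gene-only probes see the two gene alleles (conversion tracts
#' never reach exon 2), shared probes see all four homologous copies
#' regardless of conversion, pseudogene-specific probes see the two
#' pseudogene-locus copies plus every converted gene allele whose tract
#' covers the probe's exon, and control probes see two autosomal copies.
#' Multiplicative log-normal noise at `cfg$mlpa_cv` (0 = noiseless).
#'
#' @inheritParams simulate_reads
#' @param panel A probe panel from [mlpa_probe_panel()].
#' @return Tibble: `sample_id`, `probe_id`, `role`, `target_exon`,
#'   `true_copies`, `height`.
#' @export
simulate_mlpa <- function(genotypes, panel, cfg) {
  copies <- gene_copies_by_exon(
    dplyr::select(genotypes, "sample_id", "allele1", "allele2"))
  grid <- tidyr::crossing(dplyr::select(genotypes, "sample_id"), panel) |>
    dplyr::left_join(
      dplyr::select(copies, "sample_id", "exon", "gene_copies",
                    "pseudogene_copies"),
      by = c("sample_id", target_exon = "exon")) |>
    dplyr::mutate(true_copies = dplyr::case_when(
      role == "control" ~ 2L,
      role == "gene_only" ~ 2L,
      role == "shared" ~ 4L,
      role == "p1_specific" ~ as.integer(.data$pseudogene_copies)))
  sdlog <- sqrt(log(1 + cfg$mlpa_cv^2))
  noise <- if (cfg$mlpa_cv > 0) {
    with_sim_seed(cfg, 307L, rlnorm(nrow(grid), -sdlog^2 / 2, sdlog))
  } else rep(1, nrow(grid))
  grid |>
    dplyr::mutate(height = 1000 * .data$true_copies * noise) |>
    dplyr::select("sample_id", "probe_id", "role", "target_exon",
                  "true_copies", "height")
}

#' Simulate CD177 transcripts from a sorted neutrophil subset
#'
#' CD177hi neutrophils transcribe only the intact gene allele; CD177neg
#' neutrophils of a conversion carrier transcribe both the intact allele and
#' the chimeric allele carrying pseudogene bases across its tract (including
#' the c.787T stop when the tract covers exon 7). Pseudogene-locus
#' transcripts are modelled as degraded (nonsense-mediated decay) and never
#' appear.
#'
#' @param allele1,allele2 Allele codes of one genotype.
#' @param subset `"hi"` or `"neg"`.
#' @param model A `cd177_locus`.
#' @return Tibble: one row per transcript haplotype with `source_allele`,
#'   `chimeric`, `stop_containing`, and a `bases` list-column of base calls
#'   named by catalogued coding site.
#' @export
simulate_transcripts <- function(allele1, allele2, subset,
                                 model = load_builtin_cd177_model()) {
  subset <- match.arg(subset, c("hi", "neg"))
  alleles <- c(allele1, allele2)
  converted7 <- allele_is_converted_at(alleles, 7L)
  if (subset == "hi" && all(converted7)) {
    abort("a null genotype has no CD177hi subset to transcribe",
          class = "cd177conv_subset_error")
  }
  keep <- if (subset == "hi") !converted7 else rep(TRUE, 2L)
  tracts <- allele_tract(alleles)
  rows <- lapply(which(keep), function(i) {
    tract <- tracts[[i]]
    bases <- ifelse(model$sites$site_class == "PSV" &
                      model$sites$exon %in% tract,
                    model$sites$var_base, model$sites$ref_base)
    names(bases) <- model$sites$site_id
    tibble::tibble(source_allele = alleles[i],
                   chimeric = length(tract) > 0,
                   stop_containing = 7L %in% tract,
                   bases = list(bases))
  })
  out <- dplyr::bind_rows(rows)
  # within-subset duplicates collapse to distinct haplotypes
  out <- dplyr::distinct(out, .data$source_allele, .keep_all = TRUE)
  dplyr::mutate(out, cell_subset = subset,
                transcript_id = paste0("tx", dplyr::row_number()),
                .before = 1)
}

#' Simulate neutrophil CD177 phenotypes from genotype
#'
#' `pct_hi` is a clipped normal around ordered class means (ref_hom >
#' ectopic_het); null genotypes are fixed at `pct_neg = 100`. The small
#' CD177int subset is drawn near `int_mean`, except in the atypical mode
#' (probability `atypical_rate`, independent of genotype) where it is drawn
#' around `atypical_int_mean` (> 20%). MFI is log-normal around class means.
#'
#' @inheritParams simulate_reads
#' @return The input tibble with `pct_hi`, `pct_int`, `pct_neg`, `mfi`,
#'   `atypical` appended.
#' @export
simulate_phenotype <- function(genotypes, cfg) {
  cls <- exon7_class(genotypes$allele1, genotypes$allele2)
  n <- nrow(genotypes)
  with_sim_seed(cfg, 401L, {
    hi_mean <- dplyr::case_when(
      cls == "ref_hom" ~ cfg$pheno_mean_hi[["ref_hom"]],
      cls == "ectopic_het" ~ cfg$pheno_mean_hi[["ectopic_het"]],
      TRUE ~ 0)
    atypical <- stats::runif(n) < cfg$atypical_rate
    int_mean <- ifelse(atypical, cfg$atypical_int_mean, cfg$int_mean)
    int_sd <- ifelse(atypical, cfg$int_sd * 2, cfg$int_sd)
    # the intermediate subset expands at the expense of the high subset
    pct_int <- pmin(pmax(rnorm(n, int_mean, int_sd), 0), 100)
    pct_hi <- pmin(pmax(rnorm(n, hi_mean, cfg$pheno_sd), 0), 100 - pct_int)
    is_null <- cls == "null"
    pct_hi[is_null] <- 0
    pct_int[is_null] <- 0
    atypical[is_null] <- FALSE
    mfi_mean <- unname(cfg$mfi_mean[cls])
    sdlog <- sqrt(log(1 + cfg$mfi_cv^2))
    mfi <- if (cfg$mfi_cv > 0) {
      mfi_mean * rlnorm(n, -sdlog^2 / 2, sdlog)
    } else mfi_mean
    dplyr::mutate(genotypes,
                  pct_hi = pct_hi, pct_int = pct_int,
                  pct_neg = 100 - pct_hi - pct_int,
                  mfi = mfi, atypical = atypical)
  })
}

#' Simulate a two-generation pedigree with Mendelian transmission
#'
#' Offspring receive one gene-locus allele drawn uniformly from each
#' founder's pair; phenotypes follow [simulate_phenotype()].
#'
#' @param father,mother Length-2 character vectors of allele codes.
#' @param n_offspring Number of offspring.
#' @param cfg A [sim_config()].
#' @param family_id Family label.
#' @return PED-like tibble: `family_id`, `id`, `father_id`, `mother_id`,
#'   `sex`, `allele1` (paternal), `allele2` (maternal), `exon7_class`, and
#'   phenotype columns.
#' @export
simulate_pedigree <- function(father, mother, n_offspring, cfg,
                              family_id = "F1") {
  stopifnot(length(father) == 2, length(mother) == 2)
  kids <- with_sim_seed(cfg, 503L, {
    tibble::tibble(
      id = sprintf("%s-C%d", family_id, seq_len(n_offspring)),
      father_id = paste0(family_id, "-P1"),
      mother_id = paste0(family_id, "-P2"),
      sex = sample(c("M", "F"), n_offspring, replace = TRUE),
      allele1 = sample(father, n_offspring, replace = TRUE),
      allele2 = sample(mother, n_offspring, replace = TRUE))
  })
  parents <- tibble::tibble(
    id = paste0(family_id, c("-P1", "-P2")),
    father_id = NA_character_, mother_id = NA_character_,
    sex = c("M", "F"),
    allele1 = c(father[1], mother[1]),
    allele2 = c(father[2], mother[2]))
  ped <- dplyr::bind_rows(parents, kids) |>
    dplyr::mutate(family_id = family_id, .before = 1) |>
    dplyr::mutate(exon7_class = exon7_class(.data$allele1, .data$allele2),
                  sample_id = .data$id)
  simulate_phenotype(ped, cfg) |> dplyr::select(-"sample_id")
}
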