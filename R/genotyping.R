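#' Quantize per-site variant-allele fractions to quarter-copy levels
#'
#' At a paralog-collapsed site the expected variant fraction is a multiple
#' of one quarter (0, 25, 50, 75, 100 percent of reads), shifted by the
#' sequencing error rate. `call_sites()` computes, per row, the VAF point
#' estimate, an exact (Clopper-Pearson) binomial confidence interval, and
#' assigns the level whose error-adjusted predicted fraction is the unique
#' one inside the interval; if several (or no) predicted fractions fall
#' inside, the site is `ambiguous` and `level` is `NA`.
#'
#' @param counts Tibble with `ref_count` and `var_count` columns (any other
#'   columns, e.g. `sample_id`/`site_id`, are carried through).
#' @param confidence Two-sided confidence for the exact interval.
#' @param error_rate Assumed upper bound on the symmetric base-flip error;
#'   level `k` predicts a fraction in the band between `k/4` and
#'   `k/4 (1-e) + (1 - k/4) e`, and a level is assigned when the confidence
#'   interval intersects exactly one band.
#' @return The input with `depth`, `vaf`, `ci_lo`, `ci_hi`, `level`
#'   (percent, one of 0/25/50/75/100 or `NA`) and `ambiguous` appended.
#' @examples
#' calls <- call_sites(tibble::tibble(ref_count = c(0, 4500, 2250),
#'                                    var_count = c(9000, 4500, 6750)))
#' calls$level  # 100, 50, 75
#' @export
call_sites <- function(counts, confidence = 0.99, error_rate = 0.005) {
  n <- counts$ref_count + counts$var_count
  if (any(n <= 0)) {
    abort("zero read depth: missing data at one or more sites",
          class = "cd177conv_depth_error")
  }
  x <- counts$var_count
  alpha <- 1 - confidence
  ci_lo <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
  ci_hi <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  bands <- quantum_bands(error_rate)
  inside <- outer(ci_lo, bands$hi, `<=`) & outer(ci_hi, bands$lo, `>=`)
  n_in <- rowSums(inside)
  level <- ifelse(n_in == 1, (max.col(inside, "first") - 1L) * 25L,
                  NA_integer_)
  dplyr::mutate(counts, depth = n, vaf = x / n,
                ci_lo = ci_lo, ci_hi = ci_hi,
                level = as.integer(level), ambiguous = n_in != 1L)
}

#' @rdname call_sites
#' @param ref_count,var_count Read counts at a single site.
#' @export
call_site <- function(ref_count, var_count, confidence = 0.99,
                      error_rate = 0.005) {
  call_sites(tibble::tibble(ref_count = ref_count, var_count = var_count),
             confidence, error_rate)
}

# Predicted-fraction band per level: the error rate is an upper bound, so
# level k/4 predicts fractions between the raw quantum and its fully
# error-shifted value f(1-e) + (1-f)e.
quantum_bands <- function(error_rate) {
  f <- (0:4) / 4
  adj <- f * (1 - error_rate) + (1 - f) * error_rate
  list(lo = pmin(f, adj), hi = pmax(f, adj))
}

#' Call conversion genotypes from read profiles
#'
#' Groups a cohort read table by sample, quantizes each site with
#' [call_sites()], and infers: the exon-7 class from the five exon-7 PSV
#' levels (50 -> `ref_hom`, 75 -> `ectopic_het`, 100 -> `null`), requiring
#' at least `min_agree` of them to resolve to the same level (a
#' supermajority tolerates one dropout; anything less, or conflicting
#' levels, yields `unresolved` with a concordance flag); and per-exon
#' gene-derived copy counts for the PSV-bearing exons 4, 5 and 7 (variant
#' level `v` implies `4 - v/25` gene copies when that is 0-2; a variant
#' level below 50, i.e. a pseudogene-locus copy carrying the gene base,
#' leaves the gene locus at 2 copies and is flagged).
#'
#' @param profile Read tibble as produced by [simulate_reads()] (columns
#'   `sample_id`, `site_id`, `ref_count`, `var_count`; `exon`/`site_class`
#'   are taken from the model catalog).
#' @param model A `cd177_locus`.
#' @inheritParams call_sites
#' @param min_agree Minimum number of agreeing exon-7 PSV levels.
#' @return Tibble, one row per sample: `exon7_class`, `gene_copies_exon4`,
#'   `gene_copies_exon5`, `gene_copies_exon7`, `n_exon7_sites`,
#'   `n_exon7_agree`, `exon7_concordant`, `qc_flags`.
#' @export
call_genotype <- function(profile, model, confidence = 0.99,
                          error_rate = 0.005, min_agree = 4L) {
  psv <- dplyr::filter(model$sites, .data$site_class == "PSV")
  exon7_ids <- psv$site_id[psv$exon == 7L]
  present <- unique(profile$site_id)
  if (!any(exon7_ids %in% present)) {
    abort("profile covers no exon-7 PSV sites: insufficient input",
          class = "cd177conv_input_error")
  }
  calls <- profile |>
    dplyr::select(-dplyr::any_of(c("exon", "site_class"))) |>
    dplyr::inner_join(
      dplyr::select(model$sites, "site_id", "exon", "site_class"),
      by = "site_id") |>
    dplyr::filter(.data$site_class == "PSV") |>
    call_sites(confidence, error_rate)

  exon_copies <- calls |>
    dplyr::group_by(.data$sample_id, .data$exon) |>
    dplyr::summarise(consensus = consensus_level(.data$level),
                     .groups = "drop") |>
    dplyr::mutate(
      gene_copies = dplyr::if_else(
        !is.na(.data$consensus) & .data$consensus >= 50L,
        4L - .data$consensus %/% 25L, NA_integer_),
      low_level = !is.na(.data$consensus) & .data$consensus < 50L)
  wide <- exon_copies |>
    dplyr::mutate(
      gene_copies = dplyr::if_else(.data$low_level, 2L, .data$gene_copies)) |>
    dplyr::select("sample_id", "exon", "gene_copies") |>
    tidyr::pivot_wider(names_from = "exon", values_from = "gene_copies",
                       names_prefix = "gene_copies_exon")

  exon7 <- calls |>
    dplyr::filter(.data$exon == 7L) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_exon7_sites = dplyr::n(),
      n_exon7_agree = max_level_agreement(.data$level),
      modal_level = modal_level(.data$level),
      .groups = "drop") |>
    dplyr::mutate(
      exon7_concordant = .data$n_exon7_agree == .data$n_exon7_sites,
      exon7_class = dplyr::case_when(
        n_exon7_agree < min_agree ~ "unresolved",
        modal_level == 50L ~ "ref_hom",
        modal_level == 75L ~ "ectopic_het",
        modal_level == 100L ~ "null",
        TRUE ~ "unresolved"))
  low_flag <- exon_copies |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(low = any(.data$low_level), .groups = "drop")
  exon7 |>
    dplyr::left_join(wide, by = "sample_id") |>
    dplyr::left_join(low_flag, by = "sample_id") |>
    dplyr::mutate(qc_flags = dplyr::case_when(
      !exon7_concordant & exon7_class == "unresolved" ~ "exon7_discordant",
      !exon7_concordant ~ "exon7_one_dropout",
      low ~ "pseudogene_locus_variation",
      TRUE ~ "")) |>
    dplyr::select("sample_id", "exon7_class",
                  dplyr::starts_with("gene_copies_exon"),
                  "n_exon7_sites", "n_exon7_agree", "exon7_concordant",
                  "qc_flags")
}

consensus_level <- function(level) {
  lv <- level[!is.na(level)]
  if (length(lv) == 0) return(NA_integer_)
  tab <- table(lv)
  top <- as.integer(names(tab)[which.max(tab)])
  if (max(tab) > length(lv) / 2 || length(tab) == 1L) top else NA_integer_
}

modal_level <- function(level) {
  lv <- level[!is.na(level)]
  if (length(lv) == 0) return(NA_integer_)
  tab <- table(lv)
  as.integer(names(tab)[which.max(tab)])
}

max_level_agreement <- function(level) {
  lv <- level[!is.na(level)]
  if (length(lv) == 0) return(0L)
  max(table(lv))
}

#' Classify a catalogued site as SNP or PSV
#'
#' A site in exons 1-3 has no pseudogene counterpart and is a SNP. For
#' exons 4-9: if the variant base appears in transcripts of intact alleles
#' (cDNA evidence), it segregates on the gene itself -> SNP; if the cohort's
#' quantized gDNA levels include 25 or 75 (quarter-copy dosage, impossible
#' for a two-allele gene locus alone) and the variant base is absent from
#' intact-allele cDNA -> PSV; otherwise unknown.
#'
#' @param site One-row tibble (or row) with `site_id`, `exon`, `var_base`.
#' @param cohort_levels Integer vector of quantized variant levels observed
#'   across a cohort at this site.
#' @param cdna_bases Character vector of bases observed at this site in
#'   intact-allele transcripts.
#' @return `"SNP"`, `"PSV"` or `"unknown"`.
#' @export
classify_site <- function(site, cohort_levels, cdna_bases) {
  if (site$exon <= 3L) return("SNP")
  in_cdna <- site$var_base %in% cdna_bases
  if (in_cdna) return("SNP")
  if (any(cohort_levels %in% c(25L, 75L), na.rm = TRUE)) return("PSV")
  "unknown"
}

#' Localize a conversion breakpoint from per-exon gene copy counts
#'
#' Scans ordered assayed exons for the transition from the expected
#' gene-derived copy count to a deficit; the crossover lies in the half-open
#' interval between the last retained exon and the first deficient one. A
#' deficit followed downstream by restoration is a complex event: every
#' deficit run is reported (entry interval, plus an exit interval when the
#' run ends before the last assayed exon) and flagged.
#'
#' @param gene_copies Named numeric vector of gene-derived copy counts, names
#'   are exon indices in increasing order (e.g. `c("4" = 2, "5" = 0,
#'   "7" = 0)`), or a tibble with `exon` and `gene_copies`.
#' @param expected Expected copy count in unconverted material (2 per sample,
#'   1 per allele).
#' @param scope `"sample"` or `"allele"` label carried into the result.
#' @return Tibble of breakpoint intervals: `left_exon` (last retained exon,
#'   `NA` when the deficit begins at the first assayed exon), `right_exon`,
#'   `boundary` (`"entry"`/`"exit"`), `scope`, `complex`. Zero rows when no
#'   deficit exists.
#' @examples
#' infer_breakpoint(c("4" = 2, "5" = 0, "7" = 0))   # interval (4, 5)
#' infer_breakpoint(c("4" = 2, "5" = 2, "7" = 0))   # interval (5, 7)
#' @export
infer_breakpoint <- function(gene_copies, expected = 2, scope = "sample") {
  if (is.data.frame(gene_copies)) {
    exons <- as.integer(gene_copies$exon)
    copies <- gene_copies$gene_copies
  } else {
    exons <- as.integer(names(gene_copies))
    copies <- unname(gene_copies)
  }
  if (length(exons) < 2L) {
    abort("need copy counts for at least two ordered exons",
          class = "cd177conv_input_error")
  }
  ord <- order(exons)
  exons <- exons[ord]; copies <- copies[ord]
  deficit <- copies < expected
  if (!any(deficit)) {
    return(tibble::tibble(left_exon = integer(0), right_exon = integer(0),
                          boundary = character(0), scope = character(0),
                          complex = logical(0)))
  }
  runs <- rle(deficit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in which(runs$values)) {
    s <- starts[k]; e <- ends[k]
    out[[length(out) + 1L]] <- tibble::tibble(
      left_exon = if (s == 1L) NA_integer_ else exons[s - 1L],
      right_exon = exons[s], boundary = "entry")
    if (e < length(exons)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        left_exon = exons[e], right_exon = exons[e + 1L],
        boundary = "exit")
    }
  }
  res <- dplyr::bind_rows(out)
  complex <- any(res$boundary == "exit") || sum(runs$values) > 1L
  dplyr::mutate(res, scope = scope, complex = complex)
}

#' Check germline concordance between two tissues
#'
#' Quantizes both profiles and compares levels site by site. The verdict is
#' `"germline"` iff every site resolvable in both tissues agrees; any
#' disagreement raises a somatic-difference flag.
#'
#' @param neutrophil,saliva Read tibbles for the same sample from the two
#'   tissues (must carry distinct `tissue` labels).
#' @inheritParams call_sites
#' @return List of class `cd177_concordance`: `per_site` tibble
#'   (`site_id`, levels in each tissue, `agree`), `n_compared`,
#'   `n_agree`, `verdict`, `somatic_flag`.
#' @export
germline_concordance <- function(neutrophil, saliva, confidence = 0.99,
                                 error_rate = 0.005) {
  if ("tissue" %in% names(neutrophil) && "tissue" %in% names(saliva) &&
      any(neutrophil$tissue %in% saliva$tissue)) {
    abort("both profiles carry the same tissue label: comparison is between "
          %+% "tissues of one sample", class = "cd177conv_input_error")
  }
  lv <- function(x, nm) {
    call_sites(x, confidence, error_rate) |>
      dplyr::select("site_id", !!nm := "level")
  }
  per_site <- dplyr::inner_join(lv(neutrophil, "level_neutrophil"),
                                lv(saliva, "level_saliva"),
                                by = "site_id") |>
    dplyr::mutate(agree = .data$level_neutrophil == .data$level_saliva)
  resolvable <- !is.na(per_site$agree)
  n_compared <- sum(resolvable)
  n_agree <- sum(per_site$agree[resolvable])
  structure(list(per_site = per_site, n_compared = n_compared,
                 n_agree = n_agree,
                 verdict = if (n_agree == n_compared) "germline"
                           else "somatic_difference",
                 somatic_flag = n_agree != n_compared),
            class = "cd177_concordance")
}

`%+%` <- function(a, b) paste0(a, b)

#' @export
print.cd177_concordance <- function(x, ...) {
  cat("<cd177_concordance>", x$n_agree, "/", x$n_compared,
      "resolvable sites agree ->", x$verdict, "\n")
  invisible(x)
}

#' Enumerate four-copy haplotype configurations for two PSV loci
#'
#' Given quantized reference-allele levels at one exon-4 PSV and one exon-7
#' PSV, enumerates every assignment of gene/pseudogene bases to the four
#' homologous copies (two chromosomes, each carrying a gene slot and a
#' pseudogene slot) whose predicted read fractions match both levels. The
#' pseudogene slots are constrained to the divergent base at exon 7
#' (the population is homozygous for pseudogene exon 7), while either base
#' may occupy any slot at exon 4. Configurations identical up to swapping
#' the two chromosomes are collapsed.
#'
#' @param exon4_ref_level,exon7_ref_level Reference-allele percent of reads
#'   (0, 25, 50, 75 or 100) at the two loci.
#' @param bases Named list giving the gene (`ref`) and pseudogene (`var`)
#'   base at each locus; defaults to g.1991 C/G and g.7497 A/T.
#' @return Tibble: one row per chromosome per configuration, with
#'   `config_id`, `chromosome`, `gene_exon4`, `p1_exon4`, `gene_exon7`,
#'   `p1_exon7`. Errors if no assignment is consistent.
#' @export
enumerate_haplotypes <- function(exon4_ref_level, exon7_ref_level,
                                 bases = list(
                                   exon4 = c(ref = "C", var = "G"),
                                   exon7 = c(ref = "A", var = "T"))) {
  stopifnot(exon4_ref_level %in% seq(0, 100, 25),
            exon7_ref_level %in% seq(0, 100, 25))
  # slots: gene1, gene2, p1_1, p1_2; TRUE = reference (gene) base
  slots <- expand.grid(g1_4 = c(TRUE, FALSE), g2_4 = c(TRUE, FALSE),
                       p1_4 = c(TRUE, FALSE), p2_4 = c(TRUE, FALSE),
                       g1_7 = c(TRUE, FALSE), g2_7 = c(TRUE, FALSE))
  slots$p1_7 <- FALSE
  slots$p2_7 <- FALSE
  ok4 <- with(slots, g1_4 + g2_4 + p1_4 + p2_4) * 25 == exon4_ref_level
  ok7 <- with(slots, g1_7 + g2_7 + p1_7 + p2_7) * 25 == exon7_ref_level
  hits <- slots[ok4 & ok7, , drop = FALSE]
  if (nrow(hits) == 0) {
    abort("no four-copy assignment matches both levels: model violation",
          class = "cd177conv_model_error")
  }
  b <- function(locus, is_ref) {
    ifelse(is_ref, bases[[locus]][["ref"]], bases[[locus]][["var"]])
  }
  configs <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    chrom <- tibble::tibble(
      chromosome = 1:2,
      gene_exon4 = b("exon4", c(h$g1_4, h$g2_4)),
      p1_exon4 = b("exon4", c(h$p1_4, h$p2_4)),
      gene_exon7 = b("exon7", c(h$g1_7, h$g2_7)),
      p1_exon7 = b("exon7", c(h$p1_7, h$p2_7)))
    # canonical order: chromosomes are unordered
    key <- do.call(paste, c(chrom[, -1], sep = "|"))
    chrom[order(key), ] |> dplyr::mutate(chromosome = 1:2)
  })
  keys <- vapply(configs, function(cf) {
    paste(do.call(paste, c(cf[, -1], sep = "|")), collapse = "||")
  }, character(1))
  configs <- configs[!duplicated(keys)]
  dplyr::bind_rows(configs, .id = "config_id") |>
    dplyr::mutate(config_id = as.integer(.data$config_id))
}
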