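#' Hardy-Weinberg test on conversion genotype counts
#'
#' Estimates the converted-allele frequency from the genotype counts and
#' tests the observed table against Hardy-Weinberg expectations with a
#' 1-df chi-square. Also reports the observed/expected heterozygosity ratio
#' `het_freq / (2 p (1-p))`. For a monomorphic table the chi-square is 0 and
#' the heterozygosity ratio undefined (flagged).
#'
#' @param n_ref_hom,n_ectopic_het,n_null Genotype counts, or pass a tibble
#'   with those columns (one row) as the first argument.
#' @return Object of class `cd177_hwe` with [tidy()] and [glance()] methods:
#'   allele frequency `q_hat`, `observed`, `expected`, `chisq`, `df`,
#'   `p.value`, `het_ratio`, `monomorphic`.
#' @examples
#' hwe_test(25, 50, 25)          # exact HWE: chi-square 0
#' glance(hwe_test(100, 0, 100)) # complete het deficit: chi-square = n
#' @export
hwe_test <- function(n_ref_hom, n_ectopic_het = NULL, n_null = NULL) {
  if (is.data.frame(n_ref_hom)) {
    counts <- n_ref_hom
    n_ref_hom <- counts$n_ref_hom
    n_ectopic_het <- counts$n_ectopic_het
    n_null <- counts$n_null
  }
  obs <- c(ref_hom = n_ref_hom, ectopic_het = n_ectopic_het, null = n_null)
  stopifnot(all(obs >= 0), sum(obs) > 0)
  n <- sum(obs)
  q_hat <- (2 * obs[["null"]] + obs[["ectopic_het"]]) / (2 * n)
  exp_counts <- n * c(ref_hom = (1 - q_hat)^2,
                      ectopic_het = 2 * q_hat * (1 - q_hat),
                      null = q_hat^2)
  monomorphic <- q_hat == 0 || q_hat == 1
  if (monomorphic) {
    chisq <- 0
    het_ratio <- NA_real_
  } else {
    chisq <- sum((obs - exp_counts)^2 / exp_counts)
    het_ratio <- (obs[["ectopic_het"]] / n) / (2 * q_hat * (1 - q_hat))
  }
  structure(list(q_hat = unname(q_hat), observed = obs,
                 expected = exp_counts, chisq = unname(chisq), df = 1L,
                 p.value = unname(pchisq(chisq, 1, lower.tail = FALSE)),
                 het_ratio = unname(het_ratio), n = n,
                 monomorphic = monomorphic),
            class = "cd177_hwe")
}

#' @export
print.cd177_hwe <- function(x, ...) {
  cat("<cd177_hwe> n =", x$n, " q_hat =", signif(x$q_hat, 4), "\n")
  cat("  chi-square(1) =", signif(x$chisq, 4), ", p =",
      signif(x$p.value, 4), "\n")
  cat("  obs/exp heterozygosity ratio =",
      if (x$monomorphic) "undefined (monomorphic)"
      else signif(x$het_ratio, 4), "\n")
  invisible(x)
}

#' Classify a neutrophil CD177 phenotype record
#'
#' Atypical expression (`atypical_int`) when the intermediate subset exceeds
#' `int_threshold` (the >20% rule); `null` when essentially no CD177 is
#' expressed (`pct_hi + pct_int` below `null_threshold`); otherwise `hi`
#' when the high subset dominates (`pct_hi >= hi_threshold`) and `hi_neg`
#' when high and negative subsets co-occur.
#'
#' @param phenotypes Tibble with `pct_hi`, `pct_int`, `pct_neg`.
#' @param int_threshold Percent of CD177int neutrophils above which the
#'   record is atypical (default 20).
#' @param null_threshold Upper bound on `pct_hi + pct_int` for the null
#'   class (default 1).
#' @param hi_threshold `pct_hi` at or above which the record is `hi`
#'   (default 65).
#' @return The input with a `phenotype_class` column appended.
#' @export
classify_phenotype <- function(phenotypes, int_threshold = 20,
                               null_threshold = 1, hi_threshold = 65) {
  stopifnot(all(phenotypes$pct_hi >= 0 & phenotypes$pct_hi <= 100),
            all(phenotypes$pct_int >= 0 & phenotypes$pct_int <= 100))
  dplyr::mutate(phenotypes, phenotype_class = dplyr::case_when(
    pct_int > int_threshold ~ "atypical_int",
    pct_hi + pct_int < null_threshold ~ "null",
    pct_hi >= hi_threshold ~ "hi",
    TRUE ~ "hi_neg"))
}

#' Genotype-phenotype association by rank statistics
#'
#' Correlates the reference-allele dosage (2 for ref_hom, 1 for ectopic_het,
#' 0 for null) with each phenotype measure by Spearman rank correlation, and
#' tests differences across genotype classes by Kruskal-Wallis. Expected
#' directions under the conversion model: positive for `pct_hi` and `mfi`,
#' negative for `pct_neg`.
#'
#' @param cohort Tibble with `exon7_class` and at least one of `pct_hi`,
#'   `pct_neg`, `pct_int`, `mfi`; rows with `unresolved` class are dropped.
#' @return Object of class `cd177_assoc` with [tidy()]/[glance()] methods:
#'   per-measure Spearman rho and p-value, Kruskal-Wallis per measure, and
#'   per-class summaries.
#' @export
associate <- function(cohort) {
  cohort <- dplyr::filter(cohort,
                          .data$exon7_class %in% c("ref_hom", "ectopic_het",
                                                   "null"))
  if (dplyr::n_distinct(cohort$exon7_class) < 2) {
    abort("association needs at least two genotype classes",
          class = "cd177conv_input_error")
  }
  dosage <- c(ref_hom = 2, ectopic_het = 1, null = 0)[cohort$exon7_class]
  measures <- intersect(c("pct_hi", "pct_neg", "pct_int", "mfi"),
                        names(cohort))
  per_measure <- purrr::map_dfr(measures, function(m) {
    y <- cohort[[m]]
    ct <- suppressWarnings(
      stats::cor.test(dosage, y, method = "spearman", exact = FALSE))
    kw <- stats::kruskal.test(y, factor(cohort$exon7_class))
    tibble::tibble(measure = m, rho = unname(ct$estimate),
                   rho_p = ct$p.value,
                   kruskal_stat = unname(kw$statistic),
                   kruskal_p = kw$p.value)
  })
  by_class <- cohort |>
    dplyr::group_by(.data$exon7_class) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(measures), mean,
                                   .names = "mean_{.col}"),
                     .groups = "drop")
  structure(list(per_measure = per_measure, by_class = by_class,
                 n = nrow(cohort), data = cohort),
            class = "cd177_assoc")
}

#' @export
print.cd177_assoc <- function(x, ...) {
  cat("<cd177_assoc> n =", x$n, "samples,",
      nrow(x$by_class), "genotype classes\n")
  print(x$per_measure)
  invisible(x)
}

#' Check Mendelian transmission of conversion alleles in a pedigree
#'
#' For every member with both parents in the pedigree, checks that the
#' member's gene-locus allele pair can be formed by taking one allele from
#' each parent (alleles compared by their full code, i.e. tract included).
#' Members with a missing parental genotype are skipped and flagged.
#'
#' @param pedigree Tibble with `id`, `father_id`, `mother_id`, `allele1`,
#'   `allele2` (e.g. from [simulate_pedigree()]).
#' @return Tibble of violations (zero rows = consistent): `id`, `alleles`,
#'   `father_alleles`, `mother_alleles`. Skipped members are listed in
#'   `attr(, "skipped")`.
#' @export
mendelian_check <- function(pedigree) {
  idx <- match(pedigree$father_id, pedigree$id)
  midx <- match(pedigree$mother_id, pedigree$id)
  offspring <- which(!is.na(pedigree$father_id) | !is.na(pedigree$mother_id))
  skipped <- character(0)
  rows <- list()
  for (i in offspring) {
    fi <- idx[i]; mi <- midx[i]
    if (is.na(fi) || is.na(mi) ||
        anyNA(c(pedigree$allele1[c(fi, mi)], pedigree$allele2[c(fi, mi)]))) {
      skipped <- c(skipped, pedigree$id[i])
      next
    }
    child <- c(pedigree$allele1[i], pedigree$allele2[i])
    pat <- c(pedigree$allele1[fi], pedigree$allele2[fi])
    mat <- c(pedigree$allele1[mi], pedigree$allele2[mi])
    ok <- any(vapply(pat, function(p) any(vapply(mat, function(m) {
      setequal_multiset(child, c(p, m))
    }, logical(1))), logical(1)))
    if (!ok) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = pedigree$id[i],
        alleles = paste(child, collapse = " / "),
        father_alleles = paste(pat, collapse = " / "),
        mother_alleles = paste(mat, collapse = " / "))
    }
  }
  if (length(skipped) > 0) {
    warn(paste("skipped members with missing parental genotypes:",
               paste(skipped, collapse = ", ")))
  }
  out <- if (length(rows) == 0) {
    tibble::tibble(id = character(0), alleles = character(0),
                   father_alleles = character(0),
                   mother_alleles = character(0))
  } else dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

setequal_multiset <- function(a, b) {
  identical(sort(a), sort(b))
}
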