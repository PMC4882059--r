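#' Tidy a Hardy-Weinberg test
#'
#' @param x A `cd177_hwe` object.
#' @param ... Unused.
#' @return One row per genotype class with observed and expected counts.
#' @export
tidy.cd177_hwe <- function(x, ...) {
  tibble::tibble(class = names(x$observed),
                 observed = unname(x$observed),
                 expected = unname(x$expected))
}

#' @rdname tidy.cd177_hwe
#' @export
glance.cd177_hwe <- function(x, ...) {
  tibble::tibble(n = x$n, q_hat = x$q_hat, chisq = x$chisq, df = x$df,
                 p.value = x$p.value, het_ratio = x$het_ratio,
                 monomorphic = x$monomorphic)
}

#' Tidy a genotype-phenotype association
#'
#' @param x A `cd177_assoc` object.
#' @param ... Unused.
#' @return `tidy()`: one row per phenotype measure with Spearman rho and
#'   Kruskal-Wallis statistics; `glance()`: one-row cohort summary.
#' @export
tidy.cd177_assoc <- function(x, ...) x$per_measure

#' @rdname tidy.cd177_assoc
#' @export
glance.cd177_assoc <- function(x, ...) {
  tibble::tibble(n = x$n,
                 n_classes = nrow(x$by_class),
                 min_rho_p = min(x$per_measure$rho_p))
}
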