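#' Plot quantized variant-allele fractions across the catalog
#'
#' Echoes the cohort read-frequency picture: one point per sample x site at
#' its VAF, dashed guides at the quarter-copy quanta. PSV sites cluster on
#' 0.25 multiples; SNP sites on 0/0.5/1.
#'
#' @param calls Output of [call_sites()] carrying `g_pos` and `vaf`.
#' @return A ggplot.
#' @export
plot_vaf_quanta <- function(calls) {
  ggplot2::ggplot(calls, ggplot2::aes(x = factor(.data$g_pos),
                                      y = .data$vaf)) +
    ggplot2::geom_hline(yintercept = (0:4) / 4, linetype = "dashed",
                        colour = "grey70") +
    ggplot2::geom_jitter(ggplot2::aes(colour = factor(.data$level)),
                         width = 0.15, height = 0, alpha = 0.6, size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "catalogued site (g. position)",
                  y = "variant-allele fraction",
                  colour = "quantized level (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn mlpa_normalize Autoplot method: per-probe normalized ratios
#'   with the deletion/duplication thresholds.
#' @param object A `cd177_mlpa` tibble.
#' @param ... Unused.
#' @export
autoplot.cd177_mlpa <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$probe_id, y = .data$ratio,
                                       colour = .data$state)) +
    ggplot2::geom_hline(yintercept = c(0.75, 1.25), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = NULL, y = "normalized peak ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn associate Autoplot method: phenotype by reference-allele
#'   dosage class.
#' @param object A `cd177_assoc` object.
#' @param measure Phenotype column to plot.
#' @param ... Unused.
#' @export
autoplot.cd177_assoc <- function(object, measure = "pct_hi", ...) {
  df <- dplyr::mutate(object$data, exon7_class = factor(
    .data$exon7_class, levels = c("null", "ectopic_het", "ref_hom")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$exon7_class,
                                   y = .data[[measure]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "exon-7 conversion class (ref-allele dosage 0/1/2)",
                  y = measure) +
    ggplot2::theme_minimal()
}

#' @describeIn hwe_test Autoplot method: observed vs expected genotype
#'   counts.
#' @param object A `cd177_hwe` object.
#' @param ... Unused.
#' @export
autoplot.cd177_hwe <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("observed", "expected"), names_to = "kind",
                        values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$count,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "genotypes",
                  subtitle = sprintf("chi-square(1) = %.3g, p = %.3g",
                                     object$chisq, object$p.value)) +
    ggplot2::theme_minimal()
}
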