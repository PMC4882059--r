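#' Conversion-genotype allele encoding
#'
#' A gene-locus allele is encoded as `"intact"` or `"converted:L-R"`, where
#' `L-R` is a contiguous run of exon indices within 4-9 replaced by the
#' pseudogene homolog (e.g. `"converted:7-7"` for an exon-7-only tract,
#' `"converted:5-7"` for a tract entering upstream of exon 5). The two
#' pseudogene-locus copies are always intact pseudogene, so a diploid carries
#' exactly four copies of every exon 4-9 homologous segment.
#'
#' @param allele Character vector of allele codes.
#' @return `allele_tract()` returns a list of integer exon vectors (empty for
#'   intact alleles); `allele_is_converted_at()` a logical vector.
#' @examples
#' allele_tract(c("intact", "converted:5-7"))
#' allele_is_converted_at("converted:7-7", 7)
#' @export
allele_tract <- function(allele) {
  lapply(allele, function(a) {
    if (a == "intact") return(integer(0))
    m <- regmatches(a, regexec("^converted:([4-9])-([4-9])$", a))[[1]]
    if (length(m) != 3) {
      abort(paste0("malformed allele code: ", a),
            class = "cd177conv_allele_error")
    }
    ex <- as.integer(m[2]):as.integer(m[3])
    if (any(diff(ex) != 1L)) {
      abort("converted tract must be an increasing exon run",
            class = "cd177conv_allele_error")
    }
    ex
  })
}

#' @rdname allele_tract
#' @param exon Single exon index.
#' @export
allele_is_converted_at <- function(allele, exon) {
  vapply(allele_tract(allele), function(t) exon %in% t, logical(1))
}

#' Gene-derived copy count per exon for conversion genotypes
#'
#' For each genotype (rows of a truth table with `allele1`, `allele2`) and
#' each exon, the number of gene-derived copies among the homologous copies:
#' 2 minus the number of gene alleles whose conversion tract covers the exon.
#'
#' @param genotypes Tibble with `allele1` and `allele2` columns.
#' @param exons Integer vector of exon indices (default 4-9).
#' @return Tibble: one row per genotype row x exon with `gene_copies` and
#'   `pseudogene_copies` (always `gene_copies + 2` within exons 4-9).
#' @export
gene_copies_by_exon <- function(genotypes, exons = 4:9) {
  tidyr::crossing(dplyr::mutate(genotypes, .row = dplyr::row_number()),
                  exon = as.integer(exons)) |>
    dplyr::mutate(
      n_conv = vapply(seq_len(dplyr::n()), function(i) {
        sum(allele_is_converted_at(
          c(.data$allele1[i], .data$allele2[i]), .data$exon[i]))
      }, numeric(1)),
      gene_copies = 2L - .data$n_conv,
      pseudogene_copies = 2L + .data$n_conv) |>
    dplyr::select(-"n_conv") |>
    dplyr::arrange(.data$.row, .data$exon) |>
    dplyr::select(-".row")
}

#' Exon-7 conversion class of a diploid genotype
#'
#' @param allele1,allele2 Character vectors of allele codes.
#' @return `"ref_hom"`, `"ectopic_het"` or `"null"` according to whether
#'   0, 1 or 2 gene alleles are converted at exon 7.
#' @export
exon7_class <- function(allele1, allele2) {
  n <- allele_is_converted_at(allele1, 7L) +
    allele_is_converted_at(allele2, 7L)
  c("ref_hom", "ectopic_het", "null")[n + 1L]
}
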