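#' Load the built-in CD177/CD177P1 locus model
#'
#' Reads the packaged synthetic locus: a 8,700 bp gene record covering the
#' nine CD177 exons, a pseudogene record homologous to exons 4-9 carrying the
#' divergent base at every PSV, the 17-variant coding catalog with paired
#' gene-relative (g.) and CDS (c.) coordinates, and the piecewise g.-to-c.
#' offset map. Coordinates are 1-based gene-relative positions; exon
#' intervals are half-open (`g_end` is one past the last exonic base).
#'
#' Bases not pinned by the catalog are synthetic filler fixed at build time,
#' so codon contexts around catalogued sites (e.g. the AAA lysine codon at
#' c.787-789) are stable.
#'
#' @return An object of class `cd177_locus`: a list with
#'   \describe{
#'     \item{exons}{tibble of exon index and half-open g. interval,}
#'     \item{segments}{tibble of CDS segments (`c_start`, `c_end`, `offset`)
#'       with `g = c + offset`; exon 7 maps as two segments separated by a
#'       one-base alignment gap, honoring the catalogued coordinate pairs,}
#'     \item{sites}{tibble of SiteRecords (site_id, g_pos, c_pos, exon,
#'       ref_base, var_base, site_class, aa_label, rsid, prevalence,
#'       hg38_pos alias, db_note),}
#'     \item{gene_seq, pseudogene_seq}{`Biostrings::DNAString` records,}
#'     \item{pseudogene_g_start}{g. position of the first pseudogene-homologous
#'       base (start of exon 4).}
#'   }
#' @examples
#' model <- load_builtin_cd177_model()
#' dplyr::filter(model$sites, site_id == "g.7497")
#' @export
load_builtin_cd177_model <- function() {
  ext <- function(f) system.file("extdata", f, package = "cd177conv",
                                 mustWork = TRUE)
  sites <- readr::read_tsv(ext("cd177_sites.tsv"), comment = "#",
                           show_col_types = FALSE,
                           col_types = readr::cols(
                             site_id = "c", rsid = "c", g_pos = "i",
                             c_pos = "i", exon = "i", ref_base = "c",
                             var_base = "c", site_class = "c", aa_label = "c",
                             prevalence = "c", hg38_pos = "d", db_note = "c"))
  segments <- readr::read_tsv(ext("cd177_segments.tsv"), comment = "#",
                              show_col_types = FALSE,
                              col_types = "iiii")
  exons <- segments |>
    dplyr::group_by(exon) |>
    dplyr::summarise(
      g_start = min(.data$c_start + .data$offset),
      g_end = max(.data$c_end + .data$offset) + 1L,
      c_start = min(.data$c_start), c_end = max(.data$c_end),
      .groups = "drop")
  seqs <- Biostrings::readDNAStringSet(ext("cd177_locus.fasta"))
  model <- structure(
    list(exons = exons, segments = segments, sites = sites,
         gene_seq = seqs[["CD177_synthetic"]],
         pseudogene_seq = seqs[["CD177P1_synthetic"]],
         pseudogene_g_start = exons$g_start[exons$exon == 4L],
         pseudogene_exons = 4:9),
    class = "cd177_locus")
  validate_locus_model(model)
  model
}

validate_locus_model <- function(model) {
  ex <- model$exons
  stopifnot(
    all(diff(ex$g_start) > 0),
    all(ex$g_end > ex$g_start),
    all(utils::head(ex$g_end, -1) <= utils::tail(ex$g_start, -1)),
    identical(model$pseudogene_exons, 4:9))
  s <- model$sites
  stopifnot(
    all(s$ref_base != s$var_base),
    all(s$g_pos >= ex$g_start[s$exon] & s$g_pos < ex$g_end[s$exon]),
    all(s$exon[s$site_class == "PSV"] %in% model$pseudogene_exons))
  invisible(model)
}

#' @export
print.cd177_locus <- function(x, ...) {
  cat("<cd177_locus> synthetic CD177/CD177P1 locus\n")
  cat("  gene:", length(x$gene_seq), "bp, 9 exons; pseudogene:",
      length(x$pseudogene_seq), "bp (homolog of exons 4-9)\n")
  cat("  catalog:", nrow(x$sites), "coding sites (",
      sum(x$sites$site_class == "PSV"), "PSV,",
      sum(x$sites$site_class == "SNP"), "SNP )\n")
  invisible(x)
}

#' Convert between gene-relative (g.) and CDS (c.) coordinates
#'
#' The map is piecewise-constant per CDS segment (`c = g - offset`), built
#' from the catalogued coordinate pairs. Positions outside coding segments
#' (intronic, UTR, or the one-base exon-7 alignment gap) are errors.
#'
#' @param model A `cd177_locus`.
#' @param g_pos,c_pos Integer vector of positions to convert.
#' @return Integer vector of converted positions.
#' @examples
#' model <- load_builtin_cd177_model()
#' g_to_c(model, 7497)  # 787
#' c_to_g(model, 787)   # 7497
#' @export
g_to_c <- function(model, g_pos) {
  seg <- model$segments
  out <- rep(NA_integer_, length(g_pos))
  for (i in seq_len(nrow(seg))) {
    hit <- g_pos >= seg$c_start[i] + seg$offset[i] &
      g_pos <= seg$c_end[i] + seg$offset[i]
    out[hit] <- g_pos[hit] - seg$offset[i]
  }
  if (anyNA(out)) {
    abort(paste0("non-coding g. position(s): ",
                 paste(g_pos[is.na(out)], collapse = ", ")),
          class = "cd177conv_coordinate_error")
  }
  out
}

#' @rdname g_to_c
#' @export
c_to_g <- function(model, c_pos) {
  seg <- model$segments
  out <- rep(NA_integer_, length(c_pos))
  for (i in seq_len(nrow(seg))) {
    hit <- c_pos >= seg$c_start[i] & c_pos <= seg$c_end[i]
    out[hit] <- c_pos[hit] + seg$offset[i]
  }
  if (anyNA(out)) {
    abort(paste0("out-of-range c. position(s): ",
                 paste(c_pos[is.na(out)], collapse = ", ")),
          class = "cd177conv_coordinate_error")
  }
  out
}

#' Annotate the coding consequence of catalogued substitutions
#'
#' Computes, from the packaged gene sequence, the codon containing each
#' site's CDS position (`codon_index = ceiling(c_pos / 3)`), the reference
#' and substituted codons, amino acids, and a stop-gain flag. The catalog's
#' printed `aa_label` is carried alongside; for a handful of sites the
#' printed label reflects a historical numbering and differs from the
#' computed consequence.
#'
#' @param model A `cd177_locus`.
#' @param sites Tibble with at least `c_pos`, `ref_base`, `var_base`
#'   (e.g. rows of `model$sites`). Rows without a `c_pos` are an error.
#' @return The input tibble with columns `codon_index`, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`, `is_stop_gain` appended.
#' @examples
#' model <- load_builtin_cd177_model()
#' annotate_consequence(model, dplyr::filter(model$sites, site_id == "g.7497"))
#' @export
annotate_consequence <- function(model, sites) {
  if (nrow(sites) == 0) return(sites)
  if (anyNA(sites$c_pos)) {
    abort("site(s) without a CDS position are non-coding",
          class = "cd177conv_noncoding_error")
  }
  cds <- extract_cds(model)
  codon_index <- ceiling(sites$c_pos / 3)
  pos_in_codon <- sites$c_pos - 3L * (codon_index - 1L)
  ref_codon <- substring(cds, 3L * (codon_index - 1L) + 1L, 3L * codon_index)
  stopifnot(substring(ref_codon, pos_in_codon, pos_in_codon) ==
              sites$ref_base)
  alt_codon <- ref_codon
  substring(alt_codon, pos_in_codon, pos_in_codon) <- sites$var_base
  code <- Biostrings::GENETIC_CODE
  dplyr::mutate(sites,
                codon_index = codon_index,
                ref_codon = ref_codon,
                alt_codon = alt_codon,
                ref_aa = unname(code[ref_codon]),
                alt_aa = unname(code[alt_codon]),
                is_stop_gain = .data$alt_aa == "*" & .data$ref_aa != "*")
}

# Spliced CDS as a character scalar, assembled from the segment map.
extract_cds <- function(model) {
  seg <- model$segments
  pieces <- vapply(seq_len(nrow(seg)), function(i) {
    as.character(Biostrings::subseq(model$gene_seq,
                                    seg$c_start[i] + seg$offset[i],
                                    seg$c_end[i] + seg$offset[i]))
  }, character(1))
  paste(pieces, collapse = "")
}
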