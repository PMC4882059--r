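#' Built-in MLPA probe panel for the CD177/CD177P1 locus
#'
#' Probe roles mirror the locus structure: the exon-2 probe reads out the
#' CD177 gene only (exon 2 has no pseudogene counterpart); probes for exons
#' 4, 5, 7 and 9 bind both paralogs; two probes are specific to the
#' pseudogene-derived sequence of exons 5 and 7; three autosomal control
#' probes anchor the normalization. `expected_copies` is the diploid copy
#' number in an unrearranged genome.
#'
#' @return Tibble: `probe_id`, `target_exon`, `role`, `expected_copies`.
#' @export
mlpa_probe_panel <- function() {
  tibble::tibble(
    probe_id = c("Exon2", "Exon4", "Exon5", "Exon5_P1", "Exon7", "Exon7_P1",
                 "Exon9", "C1_chr22", "C2_chr9", "C3_chr17"),
    target_exon = c(2L, 4L, 5L, 5L, 7L, 7L, 9L, NA, NA, NA),
    role = c("gene_only", "shared", "shared", "p1_specific", "shared",
             "p1_specific", "shared", "control", "control", "control"),
    expected_copies = c(2L, 4L, 4L, 2L, 4L, 2L, 4L, 2L, 2L, 2L))
}

#' Two-step MLPA peak-height normalization and copy-number calling
#'
#' Each probe's peak height is first divided by the mean height of the
#' control probes within the same sample, then by the mean of that
#' within-sample ratio across the declared control samples (samples known,
#' e.g. from PSV genotyping, to carry one copy of gene and pseudogene per
#' chromosome). Control samples therefore average ratio 1 at every probe.
#' The ratio is integerized to an estimated copy number
#' (`round(ratio * expected_copies)`) and categorized with
#' [call_copy_state()].
#'
#' @param runs Peak-height tibble from [simulate_mlpa()] or equivalent
#'   (`sample_id`, `probe_id`, `height`).
#' @param panel Probe panel tibble ([mlpa_probe_panel()]).
#' @param control_samples Character vector of unrearranged control sample
#'   ids present in `runs` (at least 3).
#' @param del_threshold,dup_threshold Copy-state thresholds on the ratio.
#' @return Tibble of class `cd177_mlpa`: one row per sample x probe with
#'   `ratio`, `copies_est`, `state`.
#' @export
mlpa_normalize <- function(runs, panel, control_samples,
                           del_threshold = 0.75, dup_threshold = 1.25) {
  stopifnot(length(control_samples) >= 3)
  if (!all(control_samples %in% runs$sample_id)) {
    abort("control samples missing from runs",
          class = "cd177conv_input_error")
  }
  ctrl_probes <- panel$probe_id[panel$role == "control"]
  runs <- dplyr::select(runs, "sample_id", "probe_id", "height") |>
    dplyr::left_join(dplyr::select(panel, "probe_id", "role",
                                   "target_exon", "expected_copies"),
                     by = "probe_id")
  step1 <- runs |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(ctrl_mean = mean(
      .data$height[.data$probe_id %in% ctrl_probes])) |>
    dplyr::ungroup()
  if (any(step1$ctrl_mean <= 0)) {
    abort("zero control-probe signal: failed run",
          class = "cd177conv_mlpa_error")
  }
  step1 <- dplyr::mutate(step1, r1 = .data$height / .data$ctrl_mean)
  ref <- step1 |>
    dplyr::filter(.data$sample_id %in% control_samples) |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(r1_ref = mean(.data$r1), .groups = "drop")
  out <- step1 |>
    dplyr::left_join(ref, by = "probe_id") |>
    dplyr::mutate(
      ratio = .data$r1 / .data$r1_ref,
      copies_est = as.integer(round(.data$ratio * .data$expected_copies)),
      state = call_copy_state(.data$ratio, del_threshold, dup_threshold)) |>
    dplyr::select("sample_id", "probe_id", "role", "target_exon",
                  "expected_copies", "ratio", "copies_est", "state")
  class(out) <- c("cd177_mlpa", class(out))
  out
}

#' Categorize a normalized MLPA ratio
#'
#' @param ratio Normalized probe ratio (positive).
#' @param del_threshold Ratios below this are deletions (default 0.75).
#' @param dup_threshold Ratios above this are duplications (default 1.25).
#' @return Character vector in `{"deleted", "normal", "duplicated"}`.
#' @export
call_copy_state <- function(ratio, del_threshold = 0.75,
                            dup_threshold = 1.25) {
  if (any(ratio <= 0)) {
    abort("non-positive ratio: invalid normalization",
          class = "cd177conv_mlpa_error")
  }
  dplyr::case_when(ratio < del_threshold ~ "deleted",
                   ratio > dup_threshold ~ "duplicated",
                   TRUE ~ "normal")
}

#' Cross-check PSV genotype calls against MLPA copy states
#'
#' A sample is consistent iff the pseudogene-specific exon-7 probe state
#' matches its converted-allele count (ref_hom -> normal; ectopic_het ->
#' duplicated; null -> duplicated with an integerized estimate of 4 copies)
#' and all shared probes are normal (conversion moves sequence between
#' paralogs without changing total copy number).
#'
#' @param genotype_calls Tibble from [call_genotype()] (`sample_id`,
#'   `exon7_class`).
#' @param mlpa_calls Normalized tibble from [mlpa_normalize()].
#' @return Tibble: one row per sample with `consistent` and a
#'   semicolon-separated `issues` string (empty when consistent).
#' @export
mlpa_integrate <- function(genotype_calls, mlpa_calls) {
  per_sample <- function(cls, mk) {
    issues <- character(0)
    p1e7 <- mk[mk$probe_id == "Exon7_P1", ]
    if (nrow(p1e7) != 1) {
      issues <- c(issues, "missing Exon7_P1 probe")
    } else {
      want <- switch(cls, ref_hom = "normal", ectopic_het = "duplicated",
                     null = "duplicated", NA_character_)
      if (is.na(want)) {
        issues <- c(issues, "genotype unresolved")
      } else if (p1e7$state != want) {
        issues <- c(issues, sprintf("Exon7_P1 %s, expected %s for %s",
                                    p1e7$state, want, cls))
      } else if (cls == "null" && p1e7$copies_est != 4L) {
        issues <- c(issues, sprintf(
          "Exon7_P1 estimate %d copies, expected 4 for null",
          p1e7$copies_est))
      }
    }
    shared_bad <- mk$probe_id[mk$role == "shared" & mk$state != "normal"]
    if (length(shared_bad) > 0) {
      issues <- c(issues,
                  paste0("shared probe not normal: ",
                         paste(shared_bad, collapse = ",")))
    }
    paste(issues, collapse = "; ")
  }
  dplyr::inner_join(
    dplyr::select(genotype_calls, "sample_id", "exon7_class"),
    tidyr::nest(tibble::as_tibble(mlpa_calls), mlpa = -"sample_id"),
    by = "sample_id") |>
    dplyr::mutate(
      issues = purrr::map2_chr(.data$exon7_class, .data$mlpa, per_sample),
      consistent = .data$issues == "") |>
    dplyr::select("sample_id", "exon7_class", "consistent", "issues")
}
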