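#' Versioned TSV readers and writers
#'
#' Every pipeline table is plain TSV with named headers preceded by a
#' schema comment line (`# cd177conv-schema: <name>/v1`). Reading a file
#' whose schema line does not match the expected name is an error, never a
#' silent coercion.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @param schema Schema name (e.g. `"counts"`).
#' @return `read_pipeline_tsv()` returns a tibble.
#' @keywords internal
#' @export
write_pipeline_tsv <- function(x, path, schema) {
  writeLines(paste0("# cd177conv-schema: ", schema, "/v1"), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_tsv
#' @export
read_pipeline_tsv <- function(path, schema) {
  first <- readLines(path, n = 1)
  want <- paste0("# cd177conv-schema: ", schema, "/v1")
  if (!identical(first, want)) {
    abort(sprintf("schema mismatch in %s: found %s, expected %s",
                  path, dQuote(first), dQuote(want)),
          class = "cd177conv_schema_error")
  }
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Simulate a full study and write its files
#'
#' Generates a cohort truth set, neutrophil read counts, MLPA peaks,
#' phenotypes and four demonstration pedigrees (the transmission
#' configurations: ref_hom x ref_hom, ref_hom x ectopic_het twice, and
#' ectopic_het x ectopic_het), and writes everything as versioned TSVs plus
#' a JSON metadata sidecar recording the seed and a config hash.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param model A `cd177_locus`.
#' @return Invisibly, a named list of the written paths.
#' @export
pipeline_simulate <- function(cfg, out_dir,
                              model = load_builtin_cd177_model()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_cohort(cfg)
  counts <- simulate_reads(truth, model, cfg)
  phen <- simulate_phenotype(truth, cfg)
  mlpa <- simulate_mlpa(truth, mlpa_probe_panel(), cfg)
  peds <- dplyr::bind_rows(
    simulate_pedigree(c("intact", "intact"), c("intact", "intact"),
                      1L, cfg, "F1"),
    simulate_pedigree(c("intact", "converted:7-7"), c("intact", "intact"),
                      1L, cfg, "F2"),
    simulate_pedigree(c("intact", "converted:7-7"), c("intact", "intact"),
                      2L, cfg, "F3"),
    simulate_pedigree(c("intact", "converted:7-7"),
                      c("intact", "converted:7-7"), 2L, cfg, "F4"))
  paths <- list(
    truth = file.path(out_dir, "truth.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    mlpa = file.path(out_dir, "mlpa.tsv"),
    pedigree = file.path(out_dir, "pedigree.tsv"),
    metadata = file.path(out_dir, "metadata.json"))
  write_pipeline_tsv(truth, paths$truth, "truth")
  write_pipeline_tsv(counts, paths$counts, "counts")
  write_pipeline_tsv(
    dplyr::select(phen, "sample_id", "exon7_class", "pct_hi", "pct_int",
                  "pct_neg", "mfi", "atypical"),
    paths$phenotypes, "phenotypes")
  write_pipeline_tsv(mlpa, paths$mlpa, "mlpa")
  write_pipeline_tsv(peds, paths$pedigree, "pedigree")
  meta <- list(seed = cfg$seed,
               config = unclass(cfg),
               config_hash = rlang::hash(unclass(cfg)),
               package = "cd177conv",
               version = as.character(utils::packageVersion("cd177conv")))
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Genotype a counts file
#'
#' Reads a versioned counts TSV, calls per-sample conversion genotypes, and
#' writes a calls TSV; optionally also a VCF of the catalogued sites with
#' per-sample allele-depth FORMAT fields (contig = the packaged synthetic
#' gene record, positions = g. coordinates).
#'
#' @param counts_path Path to a `counts` TSV.
#' @param out_path Path for the calls TSV.
#' @param vcf_path Optional path for a VCF export.
#' @param model A `cd177_locus`.
#' @inheritParams call_genotype
#' @return The calls tibble, invisibly.
#' @export
pipeline_genotype <- function(counts_path, out_path, vcf_path = NULL,
                              model = load_builtin_cd177_model(),
                              confidence = 0.99, error_rate = 0.005,
                              min_agree = 4L) {
  counts <- read_pipeline_tsv(counts_path, "counts")
  needed <- c("sample_id", "site_id", "ref_count", "var_count")
  missing <- setdiff(needed, names(counts))
  if (length(missing) > 0 || nrow(counts) == 0) {
    abort(paste0("counts file does not conform to schema: ",
                 if (nrow(counts) == 0) "no data rows"
                 else paste("missing columns", toString(missing))),
          class = "cd177conv_schema_error")
  }
  calls <- call_genotype(counts, model, confidence, error_rate, min_agree)
  write_pipeline_tsv(calls, out_path, "calls")
  if (!is.null(vcf_path)) write_counts_vcf(counts, model, vcf_path)
  invisible(calls)
}

# Minimal VCF 4.2 export: catalogued sites as rows, samples as columns,
# GT omitted in favour of allele depth / fraction FORMAT fields.
write_counts_vcf <- function(counts, model, path) {
  sites <- model$sites
  samples <- sort(unique(counts$sample_id))
  wide <- counts |>
    dplyr::mutate(fmt = sprintf("%d,%d:%d:%.4f", .data$ref_count,
                                .data$var_count,
                                .data$ref_count + .data$var_count,
                                .data$var_count /
                                  (.data$ref_count + .data$var_count))) |>
    dplyr::select("sample_id", "site_id", "fmt") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "fmt",
                       values_fill = ".")
  body <- dplyr::inner_join(sites, wide, by = "site_id")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=CD177_synthetic,length=%d>",
            length(model$gene_seq)),
    "##INFO=<ID=EXON,Number=1,Type=Integer,Description=\"Exon index\">",
    paste0("##INFO=<ID=CLASS,Number=1,Type=String,Description=",
           "\"Site class: SNP or PSV\">"),
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Read depth per allele\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=VF,Number=1,Type=Float,Description=",
           "\"Variant allele fraction\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_len(nrow(body)), function(i) {
    paste(c("CD177_synthetic", body$g_pos[i], body$site_id[i],
            body$ref_base[i], body$var_base[i], ".", "PASS",
            sprintf("EXON=%d;CLASS=%s", body$exon[i], body$site_class[i]),
            "AD:DP:VF",
            unlist(body[i, samples])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Summarize a genotyped cohort
#'
#' Builds the cohort report: genotype prevalence, the Hardy-Weinberg test,
#' genotype-phenotype association, MLPA consistency tally, and Mendelian
#' violations. Sections whose inputs are not supplied are marked absent.
#'
#' @param calls_path Path to a `calls` TSV (required).
#' @param mlpa_path,phenotypes_path,pedigree_path Optional paths to the
#'   corresponding TSVs.
#' @param out_json,out_text Optional output paths for the JSON and plain-text
#'   renderings of the report.
#' @param control_samples Control sample ids for MLPA normalization; default
#'   is every sample called `ref_hom`.
#' @return The report as a list (class `cd177_report`), invisibly when
#'   written.
#' @export
pipeline_report <- function(calls_path, mlpa_path = NULL,
                            phenotypes_path = NULL, pedigree_path = NULL,
                            out_json = NULL, out_text = NULL,
                            control_samples = NULL) {
  calls <- read_pipeline_tsv(calls_path, "calls")
  prev <- calls |>
    dplyr::count(.data$exon7_class, name = "n") |>
    dplyr::mutate(percent = round(100 * .data$n / sum(.data$n), 1))
  counts <- function(cls) sum(calls$exon7_class == cls)
  n_classes <- sum(c(counts("ref_hom"), counts("ectopic_het"),
                     counts("null")) > 0)
  hwe <- if (n_classes >= 2) {
    glance(hwe_test(counts("ref_hom"), counts("ectopic_het"),
                    counts("null")))
  } else "absent (fewer than two genotype classes)"

  assoc <- if (!is.null(phenotypes_path)) {
    phen <- read_pipeline_tsv(phenotypes_path, "phenotypes")
    merged <- dplyr::inner_join(
      dplyr::select(calls, "sample_id", "exon7_class"),
      dplyr::select(phen, -dplyr::any_of("exon7_class")),
      by = "sample_id")
    if (nrow(merged) < nrow(calls)) {
      warn(sprintf("%d calls had no matching phenotype record",
                   nrow(calls) - nrow(merged)))
    }
    tidy(associate(merged))
  } else "absent"

  mlpa <- if (!is.null(mlpa_path)) {
    runs <- read_pipeline_tsv(mlpa_path, "mlpa")
    ctrl <- control_samples %||%
      head(calls$sample_id[calls$exon7_class == "ref_hom"], 10L)
    norm <- mlpa_normalize(runs, mlpa_probe_panel(), ctrl)
    verdicts <- mlpa_integrate(calls, norm)
    list(n_samples = nrow(verdicts),
         n_consistent = sum(verdicts$consistent),
         inconsistent = verdicts$sample_id[!verdicts$consistent])
  } else "absent"

  mendel <- if (!is.null(pedigree_path)) {
    ped <- read_pipeline_tsv(pedigree_path, "pedigree")
    v <- mendelian_check(ped)
    list(n_members = nrow(ped), n_violations = nrow(v),
         violations = v$id)
  } else "absent"

  report <- structure(
    list(prevalence = prev, hwe = hwe, association = assoc, mlpa = mlpa,
         mendelian = mendel,
         n_samples = nrow(calls)),
    class = "cd177_report")
  if (!is.null(out_json)) {
    jsonlite::write_json(unclass(report), out_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  if (!is.null(out_text)) {
    writeLines(utils::capture.output(print(report)), out_text)
  }
  if (is.null(out_json) && is.null(out_text)) report else invisible(report)
}

#' @export
print.cd177_report <- function(x, ...) {
  cat("== cd177conv cohort report ==\n")
  cat("samples:", x$n_samples, "\n\ngenotype prevalence:\n")
  print(as.data.frame(x$prevalence), row.names = FALSE)
  cat("\nHardy-Weinberg:\n")
  if (is.character(x$hwe)) cat(" ", x$hwe, "\n")
  else print(as.data.frame(x$hwe), row.names = FALSE)
  cat("\nassociation:\n")
  if (is.character(x$association)) cat(" ", x$association, "\n")
  else print(as.data.frame(x$association), row.names = FALSE)
  cat("\nMLPA consistency:\n")
  if (is.character(x$mlpa)) cat(" ", x$mlpa, "\n")
  else cat(sprintf("  %d/%d samples consistent\n", x$mlpa$n_consistent,
                   x$mlpa$n_samples))
  cat("\nMendelian check:\n")
  if (is.character(x$mendelian)) cat(" ", x$mendelian, "\n")
  else cat(sprintf("  %d members, %d violations\n", x$mendelian$n_members,
                   x$mendelian$n_violations))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
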