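# Shared fixtures: the built-in locus is immutable, load it once.
the_model <- load_builtin_cd177_model()

# The printed coordinate catalog: (g., c.) pairs for all 17 coding variants.
table1_pairs <- tibble::tribble(
  ~site_id, ~g_pos, ~c_pos,
  "g.49", 49L, 9L,
  "g.220", 220L, 92L,
  "g.242", 242L, 114L,
  "g.1991", 1991L, 381L,
  "g.2368", 2368L, 551L,
  "g.2427", 2427L, 610L,
  "g.2431", 2431L, 614L,
  "g.6683", 6683L, 710L,
  "g.6724", 6724L, 751L,
  "g.7492", 7492L, 782L,
  "g.7496", 7496L, 786L,
  "g.7497", 7497L, 787L,
  "g.7500", 7500L, 790L,
  "g.7501", 7501L, 791L,
  "g.7509", 7509L, 798L,
  "g.7968", 7968L, 1022L,
  "g.8625", 8625L, 1281L)

exon7_psv_ids <- c("g.7492", "g.7496", "g.7497", "g.7500", "g.7509")

genotype_of <- function(allele1, allele2, id = "S1") {
  tibble::tibble(sample_id = id, allele1 = allele1, allele2 = allele2)
}

# The three canonical diploid conversion states.
ref_hom_gt <- function(id = "RH") genotype_of("intact", "intact", id)
ectopic_het_gt <- function(id = "EH") {
  genotype_of("intact", "converted:7-7", id)
}
null_gt <- function(id = "NU", tract = "converted:7-7") {
  genotype_of(tract, tract, id)
}

# Exact expected read counts (no sampling) for a genotype at zero error.
noiseless_profile <- function(genotypes, depth = 9000L) {
  expected_vaf(genotypes, the_model, error_rate = 0) |>
    dplyr::mutate(depth = depth,
                  var_count = as.integer(round(depth * true_vaf)),
                  ref_count = depth - var_count)
}
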