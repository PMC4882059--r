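# Builds the packaged synthetic CD177/CD177P1 locus (inst/extdata/).
#
# The 17-variant coding catalog pins (g., c.) coordinate pairs, ref/var bases
# and codon contexts; everything between catalogued sites is synthetic filler
# drawn once from a fixed seed so codon contexts are stable across builds.
# Exon 7 is mapped as two CDS segments (one-base alignment gap at g.7502):
# the catalogued pairs imply offset 6710 up to c.791 and 6711 from c.792 on.

suppressPackageStartupMessages(library(Biostrings))

set.seed(177)

# CDS segments: exon index, c-interval [c_start, c_end] (closed), g = c + offset.
segments <- data.frame(
  exon    = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 7L, 8L, 9L),
  c_start = c(1L, 61L, 141L, 301L, 461L, 651L, 771L, 792L, 940L, 1101L),
  c_end   = c(60L, 140L, 300L, 460L, 650L, 770L, 791L, 939L, 1100L, 1314L),
  offset  = c(40L, 128L, 800L, 1610L, 1817L, 5973L, 6710L, 6711L, 6946L, 7344L)
)
segments$g_start <- segments$c_start + segments$offset
segments$g_end_incl <- segments$c_end + segments$offset

# Exon table (half-open g intervals: g_end = one past the last exonic base).
exons <- do.call(rbind, lapply(split(segments, segments$exon), function(s) {
  data.frame(exon = s$exon[1], g_start = min(s$g_start),
             g_end = max(s$g_end_incl) + 1L,
             c_start = min(s$c_start), c_end = max(s$c_end))
}))

gene_len <- 8700L
cds_len <- max(segments$c_end)  # 1314 = 438 codons
stopifnot(cds_len %% 3 == 0)

# Variant catalog: printed coordinates, bases (gene-corrected orientation),
# printed amino-acid label, prevalence in the 39 sequenced subjects, hg38
# position alias, and the pre-correction database call where it differed.
catalog <- data.frame(
  site_id   = c("g.49", "g.220", "g.242", "g.1991", "g.2368", "g.2427",
                "g.2431", "g.6683", "g.6724", "g.7492", "g.7496", "g.7497",
                "g.7500", "g.7501", "g.7509", "g.7968", "g.8625"),
  rsid      = c("rs45441892", "rs45553433", "rs45571738", NA, "rs12981714",
                "rs12980412", "rs12981771", "rs57802244", "rs10425835",
                NA, NA, NA, "rs200145410", "rs200006364", "rs201266439",
                "rs17856829", "rs78718189"),
  g_pos     = c(49L, 220L, 242L, 1991L, 2368L, 2427L, 2431L, 6683L, 6724L,
                7492L, 7496L, 7497L, 7500L, 7501L, 7509L, 7968L, 8625L),
  c_pos     = c(9L, 92L, 114L, 381L, 551L, 610L, 614L, 710L, 751L,
                782L, 786L, 787L, 790L, 791L, 798L, 1022L, 1281L),
  exon      = c(1L, 2L, 2L, 4L, 5L, 5L, 5L, 6L, 6L, 7L, 7L, 7L, 7L, 7L, 7L,
                8L, 9L),
  ref_base  = c("G", "A", "G", "C", "T", "G", "T", "T", "C",
                "G", "A", "A", "G", "G", "A", "G", "G"),
  var_base  = c("C", "T", "A", "G", "G", "A", "G", "C", "A",
                "C", "C", "T", "A", "T", "G", "A", "A"),
  site_class = c("SNP", "SNP", "SNP", "PSV", "PSV", "PSV", "PSV", "SNP",
                 "SNP", "PSV", "PSV", "PSV", "PSV", "SNP", "PSV", "SNP",
                 "SNP"),
  aa_label  = c("A3P", "H31L", "L38L", "P128A", "V184G", "D204N", "M205R",
                "M237T", "L251I", "G261A", "T262T", "K263X", "G264S",
                "G264V", "T267A", "A348T", "G431R"),
  prevalence = c("23/39", "2/39", "7/39", "39/39", "38/39", "38/39", "38/39",
                 "1/39", "27/39", "39/39", "39/39", "39/39", "39/39",
                 "10/39", "39/39", "15/39", "4/39"),
  hg38_pos  = c(43353721, 43353892, 43353914, 43355663, 43356040, 43356099,
                43356103, 43360355, 43360396, 43361164, 43361168, 43361169,
                43361172, 43361173, 43361181, 43361540, 43362297),
  db_note   = c(NA, NA, NA, NA, "hg19 ref/var reversed (A->C V184G printed)",
                "hg19 reversed", "hg19 reversed", NA, NA,
                "hg19 C->G A261G (reversed)", "hg19 C->A (reversed)",
                "hg19 T->A X263K (reversed)", "hg19 A->G S264G (reversed)",
                "hg19 G->T S264I (reversed)", "hg19 G->A A267T (reversed)",
                NA, NA),
  stringsAsFactors = FALSE
)

# Random CDS with no internal stop codons, then pinned codon contexts.
codon_space <- names(GENETIC_CODE)[GENETIC_CODE != "*"]
cds <- unlist(strsplit(sample(codon_space, cds_len / 3, replace = TRUE), ""))
pin <- function(cds, codon, bases) {
  cds[(3 * (codon - 1) + 1):(3 * codon)] <- strsplit(bases, "")[[1]]
  cds
}
cds <- pin(cds, 1L, "ATG")
cds <- pin(cds, 438L, "TAA")
cds <- pin(cds, 3L,   "GCG")  # c.9  G (ref)
cds <- pin(cds, 31L,  "CAC")  # c.92 A  -> H31L on A>T
cds <- pin(cds, 38L,  "CTG")  # c.114 G -> L38L on G>A
cds <- pin(cds, 127L, "CCC")  # c.381 C
cds <- pin(cds, 184L, "GTC")  # c.551 T -> V184G on T>G
cds <- pin(cds, 204L, "GAC")  # c.610 G -> D204N on G>A
cds <- pin(cds, 205L, "ATG")  # c.614 T -> M205R on T>G
cds <- pin(cds, 237L, "ATG")  # c.710 T -> M237T on T>C
cds <- pin(cds, 251L, "CTC")  # c.751 C -> L251I on C>A
cds <- pin(cds, 261L, "GGC")  # c.782 G -> G261A on G>C
cds <- pin(cds, 262L, "ACA")  # c.786 A -> T262T on A>C
cds <- pin(cds, 263L, "AAA")  # c.787 A -> K263X on A>T
cds <- pin(cds, 264L, "GGC")  # c.790 G -> G264S; c.791 G -> G264V
cds <- pin(cds, 266L, "ACA")  # c.798 A
cds <- pin(cds, 341L, "GGC")  # c.1022 G
cds <- pin(cds, 427L, "GGG")  # c.1281 G

gene <- sample(c("A", "C", "G", "T"), gene_len, replace = TRUE)
for (i in seq_len(nrow(segments))) {
  s <- segments[i, ]
  gene[s$g_start:s$g_end_incl] <- cds[s$c_start:s$c_end]
}
stopifnot(identical(gene[catalog$g_pos], catalog$ref_base))

# Pseudogene: homolog of exons 4-9 carrying the divergent (var) base at PSVs.
p1_start <- exons$g_start[exons$exon == 4]
p1_end <- exons$g_end[exons$exon == 9] - 1L
p1 <- gene[p1_start:p1_end]
psv <- catalog[catalog$site_class == "PSV", ]
p1[psv$g_pos - p1_start + 1L] <- psv$var_base

out <- file.path("inst", "extdata")
seqs <- DNAStringSet(c(CD177_synthetic = paste(gene, collapse = ""),
                       CD177P1_synthetic = paste(p1, collapse = "")))
writeXStringSet(seqs, file.path(out, "cd177_locus.fasta"), width = 70)

hdr <- "# cd177conv-schema: sites/v1"
f <- file.path(out, "cd177_sites.tsv")
writeLines(hdr, f)
suppressWarnings(write.table(catalog, f, sep = "\t", quote = FALSE,
                             row.names = FALSE, append = TRUE))

seg_out <- segments[, c("exon", "c_start", "c_end", "offset")]
f <- file.path(out, "cd177_segments.tsv")
writeLines("# cd177conv-schema: segments/v1", f)
suppressWarnings(write.table(seg_out, f, sep = "\t", quote = FALSE,
                             row.names = FALSE, append = TRUE))
message("locus written: gene ", gene_len, " bp, pseudogene ", length(p1),
        " bp, ", nrow(catalog), " sites")
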