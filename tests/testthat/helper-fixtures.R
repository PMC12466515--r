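# Shared in-code fixtures: tiny genotype matrices, toy genomes and VCF text.

make_gm <- function(dosage, chrom = NULL, pos = NULL, samples = NULL) {
  dosage <- as.matrix(dosage)
  L <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("chr1", L)
  if (is.null(pos)) pos <- seq_len(L) * 100L
  loci <- locus_table(chrom, pos, rep("A", L), rep("G", L))
  if (is.null(samples)) {
    samples <- rownames(dosage)
    if (is.null(samples)) samples <- paste0("s", seq_len(nrow(dosage)))
  }
  genotype_matrix(dosage, loci, samples = samples)
}

write_vcf_text <- function(records, samples = c("a", "b", "c")) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

# toy genome: named character vector -> DNAStringSet on demand via
# extract_region's character support; kept as plain strings in tests
toy_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

# exhaustive max-min-gap oracle for uniform selection (n small)
best_min_gap <- function(pos, k) {
  best <- -Inf
  for (sel in utils::combn(length(pos), k, simplify = FALSE)) {
    g <- min(diff(sort(pos[sel])))
    if (g > best) best <- g
  }
  best
}
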