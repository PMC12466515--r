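#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (plain or gzipped) with `vcfR`, keeps only
#' biallelic SNP records, and decodes GT fields into ALT-allele dosages.
#' `0/0 -> 0`, `0/1`/`1/0 -> 1`, `1/1 -> 2`; phased separators (`|`) are
#' accepted; any call containing `.` (including half-calls such as `0/.`)
#' becomes `NA`. Multiallelic and indel records are dropped and the drop
#' count is reported via `attr(, "n_dropped")` and a message.
#'
#' @param path VCF file path.
#' @param region optional region filter, either `"chrom"` or a list
#'   `list(chrom=, start=, end=)` (1-based closed).
#' @return A [genotype_matrix()] with attribute `n_dropped` (records removed
#'   by the biallelic-SNP rule or the region filter keeps its own count out).
#' @export
read_vcf <- function(path, region = NULL) {
  header <- vcf_header_samples(path)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    empty <- locus_table(character(), integer(), character(), character())
    d <- matrix(integer(), nrow = length(header), ncol = 0,
                dimnames = list(header, NULL))
    gm <- genotype_matrix(d, empty, samples = header)
    attr(gm, "n_dropped") <- 0L
    return(gm)
  }
  fmt <- colnames(vcf@gt)[1]
  if (is.null(vcf@gt) || fmt != "FORMAT") stop("VCF has no FORMAT/genotype columns")
  has_gt <- vapply(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE),
                   function(f) "GT" %in% f, logical(1))
  if (!all(has_gt)) {
    bad <- which(!has_gt)[1]
    stop(sprintf("record %s:%s has no GT field", fix[bad, "CHROM"], fix[bad, "POS"]))
  }

  bases <- c("A", "C", "G", "T")
  keep <- fix[, "REF"] %in% bases & fix[, "ALT"] %in% bases
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " non-biallelic-SNP record(s) dropped")
  }
  if (!is.null(region)) {
    if (is.character(region)) region <- list(chrom = region)
    in_reg <- fix[, "CHROM"] == region$chrom
    if (!is.null(region$start)) {
      p <- as.integer(fix[, "POS"])
      in_reg <- in_reg & p >= region$start & p <= region$end
    }
    keep <- keep & in_reg
  }

  fix <- fix[keep, , drop = FALSE]
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  ids <- make.unique(ids)
  loci <- locus_table(fix[, "CHROM"], as.integer(fix[, "POS"]),
                      fix[, "REF"], fix[, "ALT"], id = ids)

  code <- gsub("|", "/", as.vector(gt), fixed = TRUE)
  dos <- rep(NA_integer_, length(code))
  dos[code %in% "0/0"] <- 0L
  dos[code %in% c("0/1", "1/0")] <- 1L
  dos[code %in% "1/1"] <- 2L
  d <- matrix(dos, nrow = nrow(gt), ncol = ncol(gt))
  gm <- genotype_matrix(t(d), loci, samples = colnames(gt))
  attr(gm, "n_dropped") <- n_dropped
  gm
}

# Sample names from the #CHROM header line (works for header-only files,
# which vcfR returns without genotype column names).
vcf_header_samples <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("malformed VCF: no #CHROM header line")
    if (startsWith(line, "#CHROM")) {
      cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(cols) < 9L) return(character())
      return(cols[-(1:9)])
    }
    if (!startsWith(line, "##")) stop("malformed VCF header")
  }
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF 4.2 file with GT-only genotype columns. Dosage 0, 1,
#' 2 map to `0/0`, `0/1`, `1/1`; `NA` maps to `./.`. Reading the file back
#' with [read_vcf()] reproduces dosages, sample order and locus order
#' exactly. Output is bgzip-agnostic plain text unless `path` ends in `.gz`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (`.vcf` or `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- gm$dosage
  body <- character(0)
  if (n_loci(gm) > 0) {
    gt_chr <- matrix(gt_code[as.character(t(d))], nrow = n_loci(gm))
    gt_chr[is.na(gt_chr)] <- "./."
    loci <- gm$loci
    rows <- cbind(loci$chrom, loci$pos, loci$id, loci$ref, loci$alt,
                  ".", "PASS", ".", "GT", gt_chr)
    body <- apply(rows, 1, paste, collapse = "\t")
  }
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", gm$samples), collapse = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  ok <- tryCatch({ writeLines(c(meta, body), con); TRUE },
                 error = function(e) { close(con); stop("cannot write VCF: ",
                                                        conditionMessage(e)) })
  close(con)
  invisible(path)
}
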