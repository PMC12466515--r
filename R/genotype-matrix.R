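#' Locus table constructor
#'
#' Builds and validates the per-locus record table used throughout the
#' package: one row per biallelic SNP with chromosome, 1-based position,
#' single-base REF/ALT alleles and a unique locus identifier.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-character alleles from `{A, C, G, T}`; `ref != alt`
#'   row-wise.
#' @param id locus identifiers; defaults to `"chrom:pos"`. Must be unique.
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, `id`.
#' @examples
#' locus_table("chr1", 100L, "A", "G")
#' @export
locus_table <- function(chrom, pos, ref, alt, id = NULL) {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (n > 0) {
    if (any(pos < 1L)) stop("locus positions must be >= 1")
    bases <- c("A", "C", "G", "T")
    if (!all(ref %in% bases) || !all(alt %in% bases)) {
      stop("ref and alt must be single bases from {A,C,G,T}")
    }
    if (any(ref == alt)) stop("ref and alt alleles must differ")
  }
  if (is.null(id)) {
    id <- if (n == 0) character() else paste0(chrom, ":", pos)
  }
  if (anyDuplicated(id)) stop("locus ids must be unique")
  data.frame(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
             id = as.character(id), stringsAsFactors = FALSE)
}

#' Genotype matrix container
#'
#' The central container of the package: an integer matrix of ALT-allele
#' dosages (0, 1, 2; `NA` for a missing call) with samples in rows and loci
#' in columns, plus the locus record table. All screening, validation and
#' population-structure functions consume this object.
#'
#' @param dosage integer matrix, samples x loci, entries in `{0, 1, 2, NA}`.
#' @param loci locus table as returned by [locus_table()]; one row per
#'   dosage column.
#' @param samples sample identifiers; defaults to `rownames(dosage)`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` (named integer matrix), `loci`, and `samples`.
#' @examples
#' gm <- genotype_matrix(rbind(s1 = c(0L, 1L), s2 = c(2L, NA)),
#'                       locus_table(c("chr1", "chr1"), c(10L, 20L),
#'                                   c("A", "C"), c("G", "T")))
#' n_loci(gm)
#' @export
genotype_matrix <- function(dosage, loci, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  stopifnot(length(samples) == nrow(dosage), nrow(loci) == ncol(dosage))
  bad <- !(dosage %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  rownames(dosage) <- as.character(samples)
  colnames(dosage) <- loci$id
  structure(list(dosage = dosage, loci = loci,
                 samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%.1f%% missing)\n",
              n_samples(x), n_loci(x),
              if (length(x$dosage)) 100 * mean(is.na(x$dosage)) else 0))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`.
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname genotype_matrix
#' @export
n_loci <- function(gm) nrow(gm$loci)

#' Subset a genotype matrix by sample and/or locus
#'
#' @param gm a `genotype_matrix`.
#' @param samples sample names or indices to keep (default all).
#' @param loci locus ids or column indices to keep (default all). Ids may be
#'   repeated (used by the locus bootstrap).
#' @return A `genotype_matrix` restricted (or re-indexed) accordingly.
#' @export
subset_genotypes <- function(gm, samples = NULL, loci = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(gm)) else {
    if (is.character(samples)) match(samples, gm$samples) else samples
  }
  li <- if (is.null(loci)) seq_len(n_loci(gm)) else {
    if (is.character(loci)) match(loci, gm$loci$id) else loci
  }
  if (anyNA(si)) stop("unknown sample in subset")
  if (anyNA(li)) stop("unknown locus in subset")
  loci_df <- gm$loci[li, , drop = FALSE]
  if (anyDuplicated(loci_df$id)) {
    loci_df$id <- make.unique(loci_df$id)  # bootstrap resampling duplicates
  }
  d <- gm$dosage[si, li, drop = FALSE]
  genotype_matrix(d, loci_df, samples = gm$samples[si])
}

#' Read a two-column sample-to-group map
#'
#' Reads a TSV with columns `sample` and `group` (header optional) mapping
#' each sample to a population label, e.g. the target breed versus all other
#' breeds for the delta-MAF screen.
#'
#' @param path TSV file path.
#' @return Named character vector: `names` are sample ids, values are group
#'   labels.
#' @export
read_sample_groups <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("^sample\t", first)
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE,
                          col.names = c("sample", "group"))
  stats::setNames(as.character(df$group), as.character(df$sample))
}

#' @rdname read_sample_groups
#' @param groups named character vector (sample -> group).
#' @param path output TSV path.
#' @export
write_sample_groups <- function(groups, path) {
  utils::write.table(data.frame(sample = names(groups), group = unname(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Checks a group map against a matrix: every mapped sample must exist and,
# for the two-group screens, exactly two labels must be present.
check_groups <- function(gm, groups, two_groups = TRUE) {
  missing_samples <- setdiff(names(groups), gm$samples)
  if (length(missing_samples)) {
    stop("group map contains samples absent from the genotype matrix: ",
         paste(utils::head(missing_samples, 5), collapse = ", "))
  }
  labs <- unique(unname(groups))
  if (two_groups && length(labs) != 2L) {
    stop("exactly two group labels are required, got ", length(labs))
  }
  invisible(labs)
}
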