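#' Per-locus summary statistics
#'
#' Computes, for every locus of a genotype matrix, the quantities the panel
#' screens operate on: missing rate ("deletion rate"), ALT allele frequency
#' among called alleles, minor allele frequency, heterozygote rate among
#' called genotypes and, when a two-group sample map is supplied, per-group
#' ALT frequencies and their absolute difference (delta-MAF).
#'
#' Frequencies use called alleles only; a locus with no called genotypes
#' gets `NA` frequencies (never 0) and `missing_rate = 1`. delta-MAF is the
#' absolute difference of the two groups' aligned ALT-allele frequencies,
#' which makes it invariant both to swapping the group labels and to
#' swapping REF/ALT orientation. It is `NA` when either group has no called
#' genotype at the locus.
#'
#' @param gm a [genotype_matrix()].
#' @param groups optional named vector (sample -> group label) with exactly
#'   two labels, e.g. from [read_sample_groups()].
#' @return A `data.frame`, one row per locus: `id`, `chrom`, `pos`,
#'   `missing_rate`, `alt_freq`, `maf`, `het_rate` and, with groups,
#'   `alt_freq_<group>` for each label plus `delta_maf`.
#' @examples
#' gm <- genotype_matrix(matrix(c(0L, 1L, 2L, 1L, NA), ncol = 1),
#'                       locus_table("chr1", 1L, "A", "G"))
#' summarize_loci(gm)  # missing 0.2, alt_freq 0.5, het 0.5
#' @export
summarize_loci <- function(gm, groups = NULL) {
  d <- gm$dosage
  n <- nrow(d)
  called <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  alt_freq <- ifelse(called > 0, alt / (2 * called), NA_real_)
  out <- data.frame(
    id = gm$loci$id, chrom = gm$loci$chrom, pos = gm$loci$pos,
    missing_rate = if (n > 0) colSums(is.na(d)) / n else rep(NA_real_, ncol(d)),
    alt_freq = alt_freq,
    maf = pmin(alt_freq, 1 - alt_freq),
    het_rate = ifelse(called > 0, colSums(d == 1L, na.rm = TRUE) / called, NA_real_),
    stringsAsFactors = FALSE
  )
  if (!is.null(groups)) {
    labs <- check_groups(gm, groups, two_groups = TRUE)
    gf <- sapply(labs, function(lab) {
      rows <- gm$samples %in% names(groups)[groups == lab]
      sub <- d[rows, , drop = FALSE]
      cg <- colSums(!is.na(sub))
      ifelse(cg > 0, colSums(sub, na.rm = TRUE) / (2 * cg), NA_real_)
    })
    gf <- matrix(gf, ncol = 2, dimnames = list(NULL, labs))
    out[[paste0("alt_freq_", labs[1])]] <- gf[, 1]
    out[[paste0("alt_freq_", labs[2])]] <- gf[, 2]
    out$delta_maf <- abs(gf[, 1] - gf[, 2])
  }
  rownames(out) <- NULL
  out
}

#' Background-locus screen
#'
#' Retains loci with missing rate strictly below 30% and minor allele
#' frequency strictly above 0.1 — well-genotyped, highly polymorphic sites
#' suitable for genome-wide background coverage. Thresholds are strict
#' inequalities: boundary values are excluded.
#'
#' @param summaries output of [summarize_loci()] over all samples pooled.
#' @param max_missing,min_maf screen thresholds (defaults 0.30 and 0.10).
#' @return Character vector of retained locus ids.
#' @export
screen_background <- function(summaries, max_missing = 0.30, min_maf = 0.10) {
  keep <- !is.na(summaries$maf) &
    summaries$missing_rate < max_missing &
    summaries$maf > min_maf
  summaries$id[keep]
}

#' Breed-specific locus screen
#'
#' Retains loci that pass a stricter QC (missing rate below 10%,
#' heterozygote rate below 50%) and show strong between-group allele
#' frequency differentiation (delta-MAF strictly above 0.2). Loci with an
#' undefined delta-MAF (a group with no called genotypes) are excluded; their
#' ids are returned in `attr(, "undefined")`.
#'
#' @param summaries output of [summarize_loci()] computed with a two-group
#'   map.
#' @param max_missing,max_het,min_delta screen thresholds (defaults 0.10,
#'   0.50, 0.20), all strict.
#' @return Character vector of retained locus ids, with attribute
#'   `undefined` listing loci skipped for lack of per-group frequencies.
#' @export
screen_specific <- function(summaries, max_missing = 0.10, max_het = 0.50,
                            min_delta = 0.20) {
  if (is.null(summaries$delta_maf)) {
    stop("summaries lack delta_maf; run summarize_loci() with a group map")
  }
  undef <- is.na(summaries$delta_maf)
  keep <- !undef &
    summaries$missing_rate < max_missing &
    summaries$het_rate < max_het &
    summaries$delta_maf > min_delta
  out <- summaries$id[keep]
  attr(out, "undefined") <- summaries$id[undef]
  out
}

#' Write a locus summary table as TSV
#'
#' @param summaries output of [summarize_loci()].
#' @param path output path.
#' @export
write_locus_summaries <- function(summaries, path) {
  utils::write.table(summaries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
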