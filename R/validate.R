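# Rates are reported half-up to 2 decimals, the convention of chip QC
# reports (base round() is banker's rounding).
round2 <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-sample SNP detection rate
#'
#' Percentage of panel loci with a genotype call in one sample,
#' `100 * called / panel_size`, reported to 2 decimals.
#'
#' @param sample_calls dosage vector for one sample (`NA` = no call).
#' @param panel_size number of panel loci (defaults to
#'   `length(sample_calls)`).
#' @return Percentage in `[0, 100]`.
#' @export
detection_rate <- function(sample_calls, panel_size = length(sample_calls)) {
  stopifnot(panel_size >= 1)
  round2(100 * sum(!is.na(sample_calls)) / panel_size)
}

#' Detection rates for every sample of a matrix
#'
#' @param gm a [genotype_matrix()].
#' @return Named numeric vector of per-sample detection rates (%).
#' @export
detection_rates <- function(gm) {
  stats::setNames(apply(gm$dosage, 1, detection_rate), gm$samples)
}

concordance_report <- function(ids, a, b) {
  both <- !is.na(a) & !is.na(b)
  n_comp <- sum(both)
  disc <- both & a != b
  n_disc <- sum(disc)
  structure(list(
    n_compared = n_comp,
    n_discordant = n_disc,
    concordance_rate = if (n_comp > 0) round2(100 * (1 - n_disc / n_comp)) else NA_real_,
    discordant_loci = data.frame(id = ids[disc], call_a = a[disc],
                                 call_b = b[disc], stringsAsFactors = FALSE)
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance: %d discordant of %d compared loci -> %.2f%%\n",
              x$n_discordant, x$n_compared, x$concordance_rate))
  invisible(x)
}

#' Genotype concordance between two replicate call sets
#'
#' Compares two call vectors over the same locus set; only loci called in
#' both replicates enter the denominator. Symmetric in its arguments.
#'
#' @param rep1,rep2 dosage vectors over an identical locus set; either
#'   named by locus id, or accompanied by `ids`.
#' @param ids locus ids (defaults to `names(rep1)` or an index).
#' @return A `concordance_report`: `n_compared`, `n_discordant`,
#'   `concordance_rate` (%, 2 decimals, `NA` when no locus is comparable),
#'   `discordant_loci` table.
#' @examples
#' a <- rep(0L, 5062); b <- a; b[1:5] <- 1L
#' duplicate_concordance(a, b)$concordance_rate  # 99.90
#' @export
duplicate_concordance <- function(rep1, rep2, ids = NULL) {
  stopifnot(length(rep1) == length(rep2))
  if (is.null(ids)) ids <- if (!is.null(names(rep1))) names(rep1) else as.character(seq_along(rep1))
  rep <- concordance_report(ids, rep1, rep2)
  if (rep$n_compared == 0) warning("no locus called in both replicates",
                                   call. = FALSE)
  rep
}

#' Genotype concordance of chip calls against a truth set
#'
#' Computed over the intersection of the two locus sets; loci missing a
#' call in either set are excluded from the denominator. A per-locus
#' discordance table is kept for audit.
#'
#' @param chip_calls,truth_calls named dosage vectors (names = locus ids).
#' @return A `concordance_report` (see [duplicate_concordance()]).
#' @export
truth_concordance <- function(chip_calls, truth_calls) {
  shared <- intersect(names(chip_calls), names(truth_calls))
  if (!length(shared)) stop("no shared loci between chip and truth call sets")
  concordance_report(shared, chip_calls[shared], truth_calls[shared])
}

#' Minor-allele-frequency spectrum
#'
#' Histograms MAFs into half-open bins `[k*w, (k+1)*w)` of width `w`
#' spanning `[0, 0.5]`, with the final bin closed at 0.5 so a MAF of
#' exactly 0.5 is counted. A separate count of near-monomorphic loci
#' (MAF < 0.01) is reported, since such loci carry little information.
#'
#' @param maf numeric vector of MAFs (NAs dropped) or a
#'   [summarize_loci()] table.
#' @param bin_width bin width (default 0.05).
#' @return data.frame `bin_lo`, `bin_hi`, `count`, with attributes
#'   `n_low_maf` (MAF < 0.01) and `n_defined`.
#' @export
maf_spectrum <- function(maf, bin_width = 0.05) {
  if (is.data.frame(maf)) maf <- maf$maf
  maf <- maf[!is.na(maf)]
  n_bins <- ceiling(0.5 / bin_width)
  idx <- pmin(floor(maf / bin_width), n_bins - 1L)  # closes the last bin
  counts <- tabulate(idx + 1L, nbins = n_bins)
  out <- data.frame(bin_lo = (seq_len(n_bins) - 1L) * bin_width,
                    bin_hi = seq_len(n_bins) * bin_width,
                    count = counts)
  attr(out, "n_low_maf") <- sum(maf < 0.01)
  attr(out, "n_defined") <- length(maf)
  out
}

#' Full panel validation report
#'
#' Bundles the chip-validation quantities for one genotyped cohort:
#' per-sample detection rates, per-locus missing rates, the MAF spectrum,
#' and summary means.
#'
#' @param gm chip-genotype [genotype_matrix()].
#' @param bin_width MAF spectrum bin width.
#' @return List of class `validation_report`.
#' @export
validation_report <- function(gm, bin_width = 0.05) {
  summ <- summarize_loci(gm)
  det <- detection_rates(gm)
  structure(list(
    detection = det,
    mean_detection = round2(mean(det)),
    locus_missing = stats::setNames(summ$missing_rate, summ$id),
    maf_spectrum = maf_spectrum(summ, bin_width = bin_width),
    mean_maf = mean(summ$maf, na.rm = TRUE)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: %d samples, mean detection %.2f%% (range %.2f-%.2f)\n",
              length(x$detection), x$mean_detection,
              min(x$detection), max(x$detection)))
  invisible(x)
}
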