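#' Proportional per-chromosome quotas by largest remainder
#'
#' Splits a total locus count across chromosomes in proportion to their
#' lengths, integerized by the largest-remainder (Hamilton) method so the
#' quotas always sum exactly to `n` and each deviates from exact
#' proportionality by at most 1. Remainder ties go to the lexicographically
#' first chromosome name.
#'
#' @param chrom_lengths named numeric vector, chromosome -> length in bp.
#' @param n total number of loci to allocate (`>= 0`).
#' @return Named integer vector of quotas summing to `n`.
#' @examples
#' allocate_quota(c(chr1 = 60e6, chr2 = 30e6, chr3 = 10e6), 10)
#' @export
allocate_quota <- function(chrom_lengths, n) {
  stopifnot(n >= 0)
  if (length(chrom_lengths) == 0) {
    if (n > 0) stop("cannot allocate loci over an empty chromosome map")
    return(stats::setNames(integer(), character()))
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  exact <- n * chrom_lengths / sum(chrom_lengths)
  base <- floor(exact)
  rem <- n - sum(base)
  quota <- base
  if (rem > 0) {
    frac <- exact - base
    ord <- order(-frac, names(chrom_lengths))
    quota[ord[seq_len(rem)]] <- quota[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(quota), names(chrom_lengths))
}

#' Uniformly spaced locus selection along one chromosome
#'
#' Operationalizes "evenly distributed" selection: the chromosome is cut
#' into `quota` equal-width bins; within each non-empty bin the candidate
#' with the highest MAF is picked (ties broken toward the smallest
#' position). Quota left over by empty bins is redistributed to the nearest
#' non-empty bins (by bin distance, then lower bin index) until the quota is
#' met or the candidates are exhausted, so clustered candidates are never
#' lost to empty bins. Deterministic for a given input order.
#'
#' @param candidates data.frame with at least `pos` and `maf` columns (and
#'   usually `id`), sorted or not; rows are one chromosome's candidates.
#' @param quota number of loci to select.
#' @param chrom_length chromosome length in bp used for the bin grid
#'   (defaults to `max(pos)`).
#' @return The selected rows of `candidates`, sorted by position;
#'   `min(quota, nrow(candidates))` of them.
#' @export
select_uniform <- function(candidates, quota, chrom_length = NULL) {
  if (quota <= 0 || nrow(candidates) == 0) return(candidates[0, , drop = FALSE])
  candidates <- candidates[order(candidates$pos), , drop = FALSE]
  if (quota >= nrow(candidates)) return(candidates)
  if (is.null(chrom_length)) chrom_length <- max(candidates$pos)
  bin <- pmin(pmax(ceiling(candidates$pos / chrom_length * quota), 1L), quota)

  # per-bin candidate ordering: best MAF first, then smallest position
  picked <- logical(nrow(candidates))
  take_best <- function(b) {
    idx <- which(bin == b & !picked)
    if (!length(idx)) return(NA_integer_)
    idx[order(-candidates$maf[idx], candidates$pos[idx])][1]
  }
  n_sel <- 0L
  for (b in seq_len(quota)) {
    i <- take_best(b)
    if (!is.na(i)) { picked[i] <- TRUE; n_sel <- n_sel + 1L }
  }
  # redistribute unmet quota to nearest bins that still hold candidates
  while (n_sel < quota && n_sel < nrow(candidates)) {
    open <- sort(unique(bin[!picked]))
    empty <- setdiff(seq_len(quota), unique(bin[picked]))
    # one unmet slot per loop pass: nearest open bin to the first empty bin
    target <- if (length(empty)) empty[1] else open[1]
    b <- open[order(abs(open - target), open)][1]
    i <- take_best(b)
    picked[i] <- TRUE
    n_sel <- n_sel + 1L
  }
  candidates[picked, , drop = FALSE]
}

#' Assemble the final panel from the three locus categories
#'
#' Combines forced-include functional loci, screened breed-specific loci and
#' screened background candidates into a single panel of at most
#' `target_size` loci. Category precedence is functional > specific >
#' background: a locus appearing in several inputs is counted once under its
#' highest-precedence label. Functional loci are always included (those
#' absent from the genotyped candidate set are reported as not genotypable,
#' never silently dropped); specific loci are included up to availability
#' and budget; the remaining budget is filled with background loci spread
#' proportionally over chromosomes ([allocate_quota()]) and uniformly within
#' each ([select_uniform()]).
#'
#' @param functional data.frame of forced loci (`chrom`, `pos`, `ref`,
#'   `alt`, optionally `id`, `trait`); may be `NULL` or empty.
#' @param specific character vector of specific locus ids (from
#'   [screen_specific()]).
#' @param background character vector of background candidate ids (from
#'   [screen_background()]).
#' @param summaries locus summary table ([summarize_loci()]) covering every
#'   id referenced; supplies coordinates and MAFs.
#' @param target_size maximum panel size.
#' @param chrom_lengths named vector of chromosome lengths for the
#'   background quotas.
#' @return An object of class `panel_design`: list with `panel` (data.frame
#'   `chrom`, `pos`, `id`, `category`, `maf`, `delta_maf` sorted by
#'   chromosome then position), `composition` (named counts), and
#'   `not_genotypable` (functional loci missing from `summaries`).
#' @export
assemble_panel <- function(functional, specific, background, summaries,
                           target_size, chrom_lengths) {
  if (is.null(functional)) functional <- data.frame(chrom = character(),
                                                    pos = integer())
  if (nrow(functional) > 0 && is.null(functional$id)) {
    functional$id <- paste0(functional$chrom, ":", functional$pos)
  }
  fun_ids <- unique(as.character(functional$id))
  not_geno <- setdiff(fun_ids, summaries$id)
  fun_in <- intersect(fun_ids, summaries$id)

  spec_ids <- setdiff(unique(as.character(specific)), fun_ids)
  spec_budget <- max(target_size - length(fun_in), 0L)
  if (length(spec_ids) > spec_budget) spec_ids <- spec_ids[seq_len(spec_budget)]

  bg_candidates <- setdiff(unique(as.character(background)),
                           c(fun_ids, spec_ids))
  bg_budget <- max(target_size - length(fun_in) - length(spec_ids), 0L)
  bg_ids <- character()
  if (bg_budget > 0 && length(bg_candidates) > 0) {
    cand <- summaries[summaries$id %in% bg_candidates, , drop = FALSE]
    quota <- allocate_quota(chrom_lengths[names(chrom_lengths) %in% cand$chrom],
                            min(bg_budget, nrow(cand)))
    sel <- lapply(names(quota), function(ch) {
      select_uniform(cand[cand$chrom == ch, , drop = FALSE], quota[[ch]],
                     chrom_length = chrom_lengths[[ch]])
    })
    bg_ids <- unlist(lapply(sel, `[[`, "id"), use.names = FALSE)
    # per-chromosome shortfall (fewer candidates than quota): top up from
    # the remaining pool, best-MAF first
    short <- bg_budget - length(bg_ids)
    if (short > 0) {
      pool <- cand[!cand$id %in% bg_ids, , drop = FALSE]
      pool <- pool[order(-pool$maf, pool$chrom, pool$pos), , drop = FALSE]
      bg_ids <- c(bg_ids, utils::head(pool$id, short))
    }
  }

  ids <- c(fun_in, spec_ids, bg_ids)
  cat_lab <- c(rep("functional", length(fun_in)),
               rep("specific", length(spec_ids)),
               rep("background", length(bg_ids)))
  rows <- summaries[match(ids, summaries$id), , drop = FALSE]
  panel <- data.frame(chrom = rows$chrom, pos = rows$pos, id = ids,
                      category = cat_lab, maf = rows$maf,
                      delta_maf = if (!is.null(rows$delta_maf)) rows$delta_maf else NA_real_,
                      stringsAsFactors = FALSE)
  panel <- panel[order(panel$chrom, panel$pos), , drop = FALSE]
  rownames(panel) <- NULL
  structure(list(panel = panel,
                 composition = c(functional = length(fun_in),
                                 specific = length(spec_ids),
                                 background = length(bg_ids)),
                 target_size = target_size,
                 not_genotypable = not_geno),
            class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf("panel_design: %d loci (target %d) = %d functional + %d specific + %d background\n",
              nrow(x$panel), x$target_size, x$composition[["functional"]],
              x$composition[["specific"]], x$composition[["background"]]))
  if (length(x$not_genotypable)) {
    cat("  not genotypable:", length(x$not_genotypable), "functional loci\n")
  }
  invisible(x)
}

#' Write a panel design table as TSV
#'
#' @param design a `panel_design` from [assemble_panel()].
#' @param path output path.
#' @export
write_panel <- function(design, path) {
  utils::write.table(design$panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
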