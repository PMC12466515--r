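#' GC fraction of a sequence
#'
#' `(#G + #C) / length`; ambiguous `N` bases count in the denominator only,
#' so an N-rich window is penalized, not ignored.
#'
#' @param sequence non-empty A/C/G/T/N string.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  s <- Biostrings::DNAString(toupper(sequence))
  sum(Biostrings::letterFrequency(s, c("G", "C"))) / length(s)
}

#' Capture-probe candidate windows for a SNP
#'
#' Generates `n_candidates` 110-bp windows that each fully cover the SNP.
#' The first candidate centers the SNP (probe offset 56 of 110, i.e. window
#' `[pos - 55, pos + 54]`); further candidates place the SNP at offsets
#' spread across the middle half of the probe so the candidates tile
#' different flanking sequence. Windows that would run past a chromosome
#' end are shifted inward, keeping length 110 and the SNP covered.
#'
#' @param locus one-row data.frame (or list) with `chrom`, `pos`, `id`.
#' @param genome genome as in [extract_region()].
#' @param n_candidates number of windows (default 2).
#' @param probe_length probe length in bp (default 110).
#' @return data.frame of probes: `locus_id`, `chrom`, `start`, `end`,
#'   `offset` (1-based SNP offset within the probe), `sequence`.
#' @export
candidate_probes <- function(locus, genome, n_candidates = 2,
                             probe_length = 110L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  chrom <- locus$chrom; pos <- as.integer(locus$pos)
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  len <- Biostrings::width(genome[chrom])
  if (len < probe_length) stop("chromosome ", chrom, " shorter than a probe")

  center <- floor(probe_length / 2) + 1L               # 56 for 110 bp
  offs <- center
  if (n_candidates > 1) {
    extra <- round(seq(0.25, 0.75, length.out = n_candidates - 1L) * probe_length)
    extra[extra == center] <- extra[extra == center] + 1L
    offs <- c(center, extra)
  }
  offs <- offs[seq_len(n_candidates)]

  rows <- lapply(offs, function(off) {
    start <- pos - off + 1L
    start <- min(max(start, 1L), len - probe_length + 1L)  # shift at ends
    end <- start + probe_length - 1L
    data.frame(locus_id = as.character(locus$id), chrom = chrom,
               start = start, end = end, offset = pos - start + 1L,
               sequence = extract_region(genome, chrom, start, end),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Genome-wide homology count of a probe by exact k-mer seeding
#'
#' Counts the distinct genomic loci that share at least one exact k-mer with
#' the probe, on either strand. All k-mers of the probe are matched against
#' every chromosome and its reverse complement; hits on the same chromosome
#' and strand whose starts lie within one probe length of each other are
#' merged into a single locus. A probe extracted from the genome always
#' scores at least 1 (its own source locus).
#'
#' @param probe_sequence probe string (length `>= k`).
#' @param genome genome as in [extract_region()].
#' @param k seed length (default 25).
#' @param merge_window hit-merging distance in bp (default the probe
#'   length).
#' @return Integer count of distinct homologous loci.
#' @export
homology_count <- function(probe_sequence, genome, k = 25L,
                           merge_window = nchar(probe_sequence)) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  L <- nchar(probe_sequence)
  if (k > L) stop("k exceeds probe length")
  probe <- Biostrings::DNAString(toupper(probe_sequence))
  starts <- seq_len(L - k + 1L)
  kmers <- Biostrings::DNAStringSet(probe, start = starts, width = k)
  kmers <- unique(kmers)
  # seeds with ambiguous bases cannot anchor an exact match
  kmers <- kmers[!grepl("[^ACGT]", as.character(kmers))]
  if (!length(kmers)) return(0L)
  pd <- Biostrings::PDict(kmers)

  n_hits <- 0L
  for (chrom in names(genome)) {
    seq_fwd <- genome[[chrom]]
    clen <- length(seq_fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq_fwd else Biostrings::reverseComplement(seq_fwd)
      m <- Biostrings::matchPDict(pd, s)
      hit_starts <- sort(unique(unlist(lapply(m, Biostrings::start))))
      if (strand == "-" && length(hit_starts)) {
        hit_starts <- sort(clen - (hit_starts + k - 1L) + 1L)
      }
      if (length(hit_starts)) {
        gaps <- diff(hit_starts)
        n_hits <- n_hits + 1L + sum(gaps > merge_window)
      }
    }
  }
  n_hits
}

#' Vet probe candidates against the capture-design rules
#'
#' A probe passes when its GC fraction lies in the closed band
#' `[gc_min, gc_max]`, its genome-wide homology count is strictly below
#' `max_homology`, and it contains no ambiguous base. Loci none of whose
#' candidates pass are flagged undesignable so the panel assembly can drop
#' them.
#'
#' @param candidates probe data.frame from [candidate_probes()] (any number
#'   of loci).
#' @param genome genome as in [extract_region()] (used for homology).
#' @param gc_min,gc_max inclusive GC band (defaults 0.30, 0.70).
#' @param max_homology probes with `homology_count >= max_homology` fail
#'   (default 5, i.e. "fewer than five" homologous loci).
#' @param k homology seed length (default 25).
#' @return `candidates` with added columns `gc`, `homology`, `pass`
#'   (logical) and `reasons` (semicolon-joined failure reasons among
#'   `gc`, `homology`, `ambiguous_base`), plus attribute `undesignable`:
#'   locus ids with zero passing candidates.
#' @export
vet_probes <- function(candidates, genome, gc_min = 0.30, gc_max = 0.70,
                       max_homology = 5L, k = 25L) {
  n <- nrow(candidates)
  gc <- vapply(candidates$sequence, gc_content, numeric(1), USE.NAMES = FALSE)
  hom <- vapply(candidates$sequence, homology_count, integer(1),
                genome = genome, k = k, USE.NAMES = FALSE)
  has_n <- grepl("N", candidates$sequence, fixed = TRUE)
  reasons <- character(n)
  for (i in seq_len(n)) {
    r <- character()
    if (gc[i] < gc_min || gc[i] > gc_max) r <- c(r, "gc")
    if (hom[i] >= max_homology) r <- c(r, "homology")
    if (has_n[i]) r <- c(r, "ambiguous_base")
    reasons[i] <- paste(r, collapse = ";")
  }
  out <- candidates
  out$gc <- gc
  out$homology <- hom
  out$pass <- reasons == ""
  out$reasons <- reasons
  ok_by_locus <- tapply(out$pass, out$locus_id, any)
  attr(out, "undesignable") <- names(ok_by_locus)[!ok_by_locus]
  out
}

#' Design and vet probes for every locus of a panel
#'
#' @param panel data.frame with `chrom`, `pos`, `id` (e.g.
#'   `panel_design$panel`).
#' @param genome genome as in [extract_region()].
#' @param n_candidates candidates per locus (default 2).
#' @param ... passed to [vet_probes()].
#' @return Vetted probe table (see [vet_probes()]).
#' @export
design_probes <- function(panel, genome, n_candidates = 2, ...) {
  cands <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    candidate_probes(panel[i, ], genome, n_candidates = n_candidates)
  }))
  vet_probes(cands, genome, ...)
}

#' Export passing probes as FASTA
#'
#' @param probes vetted probe table.
#' @param path FASTA output path.
#' @export
write_probe_fasta <- function(probes, path) {
  ok <- probes[probes$pass, , drop = FALSE]
  seqs <- Biostrings::DNAStringSet(ok$sequence)
  names(seqs) <- sprintf("%s|%s:%d-%d", ok$locus_id, ok$chrom, ok$start, ok$end)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
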