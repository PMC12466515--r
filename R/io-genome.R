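#' Load a reference genome FASTA
#'
#' @param path FASTA file path.
#' @return A `Biostrings::DNAStringSet`, names truncated at the first
#'   whitespace (the usual FASTA id convention).
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract a genomic interval as an uppercase sequence
#'
#' Coordinates are 1-based closed throughout the package. Out-of-bounds
#' requests are an error, never silently clipped.
#'
#' @param genome a `DNAStringSet` (see [read_genome()]) or a named character
#'   vector of sequences.
#' @param chrom chromosome name (exact match).
#' @param start,end 1-based inclusive interval bounds.
#' @return Character scalar of length `end - start + 1`.
#' @export
extract_region <- function(genome, chrom, start, end) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  len <- Biostrings::width(genome[chrom])
  if (start < 1 || end > len || start > end) {
    stop(sprintf("interval %s:%d-%d outside chromosome bounds [1,%d]",
                 chrom, start, end, len))
  }
  toupper(as.character(Biostrings::subseq(genome[[chrom]], start, end)))
}

#' Gene model constructor
#'
#' A gene model is the unit consumed by the annotation functions: a strand,
#' a set of sorted non-overlapping exons and the CDS intervals they contain,
#' all in 1-based closed coordinates.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end` columns (1-based closed).
#' @param cds data.frame with `start`, `end` columns; must fall inside exons.
#' @return An object of class `gene_model` (list). A `cds_warning` field is
#'   set when the total CDS length is not divisible by 3.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = exons) {
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("overlapping exons in gene ", gene_id)
  }
  cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
  in_exon <- vapply(seq_len(nrow(cds)), function(i) {
    any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
  }, logical(1))
  if (!all(in_exon)) stop("CDS interval outside exons in gene ", gene_id)
  cds_len <- sum(cds$end - cds$start + 1)
  m <- structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                      exons = exons, cds = cds, cds_length = cds_len,
                      cds_warning = NULL),
                 class = "gene_model")
  if (cds_len %% 3 != 0) {
    m$cds_warning <- sprintf("CDS length %d not divisible by 3", cds_len)
    warning("gene ", gene_id, ": ", m$cds_warning, call. = FALSE)
  }
  m
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s %s:%d-%d(%s), %d exon(s), CDS %d bp\n",
              x$gene_id, x$chrom, min(x$exons$start), max(x$exons$end),
              x$strand, nrow(x$exons), x$cds_length))
  invisible(x)
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 coordinates are used as-is (1-based closed); BED12 block starts are
#' 0-based half-open and converted at the boundary (start + 1). For GFF3,
#' `exon` and `CDS` features are grouped by their `Parent` transcript; for
#' BED12, blocks become exons and the thick interval intersected with the
#' blocks becomes the CDS.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED12 (`.bed`) file.
#' @return A named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    read_models_bed12(path)
  } else {
    read_models_gff3(path)
  }
}

read_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  tx <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  parts <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  parent_of <- function(p) vapply(p, function(x) as.character(x)[1], character(1))
  parts$parent <- parent_of(parts$Parent)
  models <- list()
  for (i in seq_len(nrow(tx))) {
    tid <- tx$ID[i]
    gid <- if (!is.null(tx$Parent) && length(tx$Parent[[i]])) {
      as.character(tx$Parent[[i]])[1]
    } else tid
    sub <- parts[parts$parent == tid, , drop = FALSE]
    ex <- sub[sub$type == "exon", c("start", "end"), drop = FALSE]
    cd <- sub[sub$type == "CDS", c("start", "end"), drop = FALSE]
    if (nrow(ex) == 0) ex <- cd
    models[[gid]] <- gene_model(gid, as.character(tx$seqnames[i]),
                                as.character(tx$strand[i]), ex,
                                if (nrow(cd)) cd else ex)
  }
  models
}

read_models_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  models <- list()
  for (i in seq_along(gr)) {
    rec <- gr[i]
    gid <- if (!is.null(rec$name) && !is.na(rec$name)) rec$name else paste0("bed_", i)
    strand <- as.character(GenomicRanges::strand(rec))
    if (strand == "*") strand <- "+"
    blocks <- if (!is.null(rec$blocks)) rec$blocks[[1]] else NULL
    if (is.null(blocks) || length(blocks) == 0) {
      ex <- data.frame(start = GenomicRanges::start(rec), end = GenomicRanges::end(rec))
    } else {
      # blocks from rtracklayer are relative to the record start
      ex <- data.frame(start = GenomicRanges::start(rec) + IRanges::start(blocks) - 1L,
                       end = GenomicRanges::start(rec) + IRanges::end(blocks) - 1L)
    }
    cd <- ex
    if (!is.null(rec$thick)) {
      th <- rec$thick
      cd <- data.frame(start = pmax(ex$start, IRanges::start(th)),
                       end = pmin(ex$end, IRanges::end(th)))
      cd <- cd[cd$start <= cd$end, , drop = FALSE]
      if (nrow(cd) == 0) cd <- ex
    }
    models[[gid]] <- gene_model(gid, as.character(GenomicRanges::seqnames(rec)),
                                strand, ex, cd)
  }
  models
}

#' Spliced CDS sequence of a gene model
#'
#' Concatenates the CDS intervals in genomic order and, for minus-strand
#' genes, reverse-complements the result so the returned string reads
#' 5' to 3' in the coding direction.
#'
#' @param model a [gene_model()].
#' @param genome genome as in [extract_region()].
#' @return Character scalar, the spliced CDS.
#' @export
spliced_cds <- function(model, genome) {
  pieces <- vapply(seq_len(nrow(model$cds)), function(i) {
    extract_region(genome, model$chrom, model$cds$start[i], model$cds$end[i])
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}
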