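#' Classify a SNP by genic context
#'
#' Assigns one of the standard region classes: `exonic` (inside any exon),
#' `intronic` (inside a gene body but not an exon), `upstream` /
#' `downstream` (within `flank` bp of a gene on the strand-appropriate
#' side), `upstream;downstream` (within flank of two different genes on
#' opposite sides), or `intergenic`. Precedence is
#' exonic > intronic > flanking > intergenic; a locus on a chromosome with
#' no gene model is intergenic (with a warning).
#'
#' @param locus one-row data.frame or list with `chrom`, `pos`.
#' @param gene_models list of [gene_model()] objects.
#' @param flank flanking distance in bp (default 2000).
#' @return Character scalar, the region class.
#' @export
classify_location <- function(locus, gene_models, flank = 2000L) {
  chrom <- locus$chrom; pos <- as.integer(locus$pos)
  models <- Filter(function(m) m$chrom == chrom, gene_models)
  if (!length(models)) {
    if (!chrom %in% vapply(gene_models, `[[`, character(1), "chrom")) {
      warning("no gene model on chromosome ", chrom, "; classified intergenic",
              call. = FALSE)
    }
    return("intergenic")
  }
  up <- down <- FALSE
  for (m in models) {
    g_start <- min(m$exons$start); g_end <- max(m$exons$end)
    if (pos >= g_start && pos <= g_end) {
      if (any(pos >= m$exons$start & pos <= m$exons$end)) return("exonic")
      return("intronic")
    }
    # strand-aware flanks: upstream is 5' of the gene, downstream 3'
    before <- pos < g_start && g_start - pos <= flank
    after <- pos > g_end && pos - g_end <= flank
    if (m$strand == "+") {
      up <- up || before; down <- down || after
    } else {
      up <- up || after; down <- down || before
    }
  }
  if (up && down) return("upstream;downstream")
  if (up) return("upstream")
  if (down) return("downstream")
  "intergenic"
}

#' Map a genomic position into spliced CDS coordinates
#'
#' Returns the 1-based position of a genomic coordinate within a gene
#' model's spliced CDS, reading in the coding direction (so on the minus
#' strand the last genomic CDS base is position 1). Alleles must be
#' complemented by the caller for minus-strand genes before consequence
#' calling; [annotate_panel()] does this.
#'
#' @param locus one-row data.frame or list with `chrom`, `pos`.
#' @param model a [gene_model()].
#' @return Integer CDS position.
#' @export
genomic_to_cds <- function(locus, model) {
  pos <- as.integer(locus$pos)
  cds <- model$cds
  hit <- which(pos >= cds$start & pos <= cds$end)
  if (!length(hit)) {
    stop("position ", pos, " not in the CDS of ", model$gene_id,
         "; use classify_location() for non-coding sites")
  }
  widths <- cds$end - cds$start + 1
  fwd <- sum(widths[seq_len(hit - 1)]) + (pos - cds$start[hit] + 1)
  if (model$strand == "+") as.integer(fwd) else as.integer(model$cds_length - fwd + 1)
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("cannot translate codon ", codon)
  aa
}

#' Codon-level consequence of a coding SNP
#'
#' Locates the codon containing a CDS position (`codon_index =
#' ceiling(cds_pos / 3)`), substitutes the alternate base at the within-codon
#' offset, translates both codons with the standard genetic code, and emits
#' HGVS-style coding (`c.<pos><ref>><alt>`) and protein
#' (`p.<codon><refAA>><altAA>`, one-letter amino acids) notations. A stop
#' codon is reported as `*`.
#'
#' @param cds_pos 1-based position within the spliced CDS.
#' @param ref_base,alt_base strand-adjusted alleles (single bases).
#' @param cds spliced CDS string, 5' to 3' in coding direction
#'   ([spliced_cds()]).
#' @return List of class `consequence`: `cds_pos`, `codon_index`,
#'   `codon_offset` (0/1/2), `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`
#'   (one-letter), `synonymous`, `c_notation`, `p_notation`.
#' @examples
#' cds <- paste(rep("GCC", 200), collapse = "")  # poly-Ala toy
#' cds_consequence(464, "C", "T", cds)$p_notation  # "p.155A>V"
#' @export
cds_consequence <- function(cds_pos, ref_base, alt_base, cds) {
  cds <- toupper(cds)
  L <- nchar(cds)
  if (cds_pos < 1 || cds_pos > L) stop("cds_pos outside CDS (length ", L, ")")
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  found <- substr(cds, cds_pos, cds_pos)
  if (found != ref_base) {
    stop(sprintf("reference mismatch at CDS position %d: CDS has %s, expected %s",
                 cds_pos, found, ref_base))
  }
  codon_index <- ceiling(cds_pos / 3)
  codon_offset <- (cds_pos - 1) %% 3
  c_start <- 3 * (codon_index - 1) + 1
  ref_codon <- substr(cds, c_start, min(c_start + 2, L))
  if (nchar(ref_codon) < 3) stop("incomplete terminal codon at index ", codon_index)
  alt_codon <- ref_codon
  substr(alt_codon, codon_offset + 1, codon_offset + 1) <- alt_base
  ref_aa <- translate_codon(ref_codon)  # GENETIC_CODE is one-letter, "*" = stop
  alt_aa <- translate_codon(alt_codon)
  structure(list(
    cds_pos = as.integer(cds_pos), codon_index = as.integer(codon_index),
    codon_offset = as.integer(codon_offset),
    ref_codon = ref_codon, alt_codon = alt_codon,
    ref_aa = ref_aa, alt_aa = alt_aa,
    synonymous = ref_aa == alt_aa,
    c_notation = sprintf("c.%d%s>%s", cds_pos, ref_base, alt_base),
    p_notation = sprintf("p.%d%s>%s", codon_index, ref_aa, alt_aa)
  ), class = "consequence")
}

#' @export
print.consequence <- function(x, ...) {
  cat(sprintf("%s %s (%s, codon %d %s>%s)\n", x$c_notation, x$p_notation,
              if (x$synonymous) "synonymous" else "non-synonymous",
              x$codon_index, x$ref_codon, x$alt_codon))
  invisible(x)
}

#' Annotate every locus of a panel
#'
#' Region-classifies each locus and, for loci inside a CDS, computes the
#' codon-level consequence (complementing alleles for minus-strand genes).
#'
#' @param panel data.frame with `chrom`, `pos`, `ref`, `alt`, `id`.
#' @param gene_models list of [gene_model()] objects.
#' @param genome genome as in [extract_region()] (needed for consequences).
#' @param flank flanking distance in bp (default 2000).
#' @return data.frame: `id`, `chrom`, `pos`, `region_class`, `gene`,
#'   `c_notation`, `p_notation`, `synonymous` (NA outside CDS).
#' @export
annotate_panel <- function(panel, gene_models, genome = NULL, flank = 2000L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cds_cache <- list()
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    loc <- panel[i, ]
    cls <- classify_location(loc, gene_models, flank = flank)
    gene <- NA_character_; cn <- pn <- NA_character_; syn <- NA
    if (cls == "exonic" && !is.null(genome)) {
      for (m in gene_models) {
        if (m$chrom != loc$chrom) next
        in_cds <- any(loc$pos >= m$cds$start & loc$pos <= m$cds$end)
        if (!in_cds) next
        gene <- m$gene_id
        if (is.null(cds_cache[[m$gene_id]])) {
          cds_cache[[m$gene_id]] <<- spliced_cds(m, genome)
        }
        ref <- loc$ref; alt <- loc$alt
        if (m$strand == "-") { ref <- comp[[ref]]; alt <- comp[[alt]] }
        cq <- cds_consequence(genomic_to_cds(loc, m), ref, alt,
                              cds_cache[[m$gene_id]])
        cn <- cq$c_notation; pn <- cq$p_notation; syn <- cq$synonymous
        break
      }
    }
    data.frame(id = loc$id, chrom = loc$chrom, pos = loc$pos,
               region_class = cls, gene = gene, c_notation = cn,
               p_notation = pn, synonymous = syn, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
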