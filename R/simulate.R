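#' Simulation configuration for a two-population cohort
#'
#' Bundles and validates the generator settings. Defaults mirror a
#' small-breed conservation scenario: a modest target population genotyped
#' alongside a large reference panel of other breeds (15 vs 128 samples),
#' moderate between-breed differentiation (FST 0.1, typical of livestock
#' breeds), and low assay noise.
#'
#' @param n_loci number of simulated loci.
#' @param n_per_pop integer vector of samples per population (length =
#'   number of populations; default `c(target = 15, other = 128)`).
#' @param maf_range ancestral MAF drawn uniformly from this interval
#'   (default `[0.05, 0.5]`).
#' @param fst Balding-Nichols differentiation parameter in (0, 1).
#' @param missing_rate i.i.d. genotype missingness probability.
#' @param error_rate probability a call is replaced by a different dosage.
#' @param n_chrom number of chromosomes positions are spread over.
#' @param seed integer seed (mandatory).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 1000L,
                       n_per_pop = c(target = 15L, other = 128L),
                       maf_range = c(0.05, 0.5), fst = 0.1,
                       missing_rate = 0.02, error_rate = 0.005,
                       n_chrom = 5L, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_loci >= 1, all(n_per_pop >= 1), length(n_per_pop) >= 1,
            fst > 0, fst < 1,
            missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  if (is.null(names(n_per_pop))) {
    names(n_per_pop) <- paste0("pop", seq_along(n_per_pop))
  }
  structure(list(n_loci = as.integer(n_loci), n_per_pop = n_per_pop,
                 maf_range = maf_range, fst = fst,
                 missing_rate = missing_rate, error_rate = error_rate,
                 n_chrom = as.integer(n_chrom), seed = as.integer(seed)),
            class = "sim_config")
}

#' Balding-Nichols population allele frequencies
#'
#' Draws each population's allele frequency from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, the Balding-Nichols model:
#' frequencies stay centered on the ancestral frequency `p` with variance
#' `F p (1 - p)`, the standard parameterization of drift by FST.
#'
#' @param p_ancestral vector of ancestral frequencies, each in (0, 1).
#' @param fst differentiation parameter in (0, 1).
#' @param n_pops number of populations.
#' @param seed optional seed (set it here only when calling standalone).
#' @return Matrix `length(p_ancestral)` x `n_pops` of population
#'   frequencies.
#' @export
balding_nichols_freqs <- function(p_ancestral, fst, n_pops, seed = NULL) {
  if (any(p_ancestral <= 0 | p_ancestral >= 1)) {
    stop("ancestral frequencies must lie strictly inside (0, 1)")
  }
  stopifnot(fst > 0, fst < 1)
  if (!is.null(seed)) set.seed(seed)
  scale <- (1 - fst) / fst
  n <- length(p_ancestral)
  freqs <- matrix(NA_real_, n, n_pops)
  for (k in seq_len(n_pops)) {
    freqs[, k] <- stats::rbeta(n, p_ancestral * scale, (1 - p_ancestral) * scale)
  }
  freqs
}

#' Simulate a multi-population genotyped cohort
#'
#' Draws ancestral frequencies, drifts them per population under the
#' Balding-Nichols model, samples Hardy-Weinberg genotypes per individual,
#' then applies genotyping error (a call replaced uniformly by one of the
#' two other dosages) and i.i.d. missingness. The error-free genotypes and
#' all true frequencies are returned as a truth table aligned one-to-one
#' with the emitted loci, enabling parameter-recovery tests.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, `cohort.vcf.gz`, `groups.tsv`
#'   and `truth.tsv` are written there.
#' @return List: `genotypes` (observed [genotype_matrix()]), `truth_genotypes`
#'   (pre-noise matrix), `groups` (named vector sample -> population),
#'   `truth` (data.frame: `id`, `p_ancestral`, per-population `freq_*`,
#'   `delta_p`), and `paths` when `dir` is given.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_loci
  pops <- names(config$n_per_pop)

  # loci spread over chromosomes at sorted random positions
  chrom <- sort(sample(paste0("chr", seq_len(config$n_chrom)), L, replace = TRUE))
  pos <- integer(L)
  for (ch in unique(chrom)) {
    k <- sum(chrom == ch)
    pos[chrom == ch] <- sort(sample.int(1e7, k))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
                USE.NAMES = FALSE)
  loci <- locus_table(chrom, pos, ref, alt)

  p_anc <- stats::runif(L, config$maf_range[1], config$maf_range[2])
  freqs <- balding_nichols_freqs(p_anc, config$fst, length(pops))
  colnames(freqs) <- pops

  samples <- unlist(lapply(pops, function(p) {
    paste0(p, "_", seq_len(config$n_per_pop[[p]]))
  }))
  groups <- stats::setNames(rep(pops, times = config$n_per_pop), samples)

  n_tot <- length(samples)
  truth_d <- matrix(NA_integer_, n_tot, L)
  row <- 1L
  for (k in seq_along(pops)) {
    for (s in seq_len(config$n_per_pop[[k]])) {
      truth_d[row, ] <- stats::rbinom(L, 2L, freqs[, k])
      row <- row + 1L
    }
  }
  truth_gm <- genotype_matrix(truth_d, loci, samples = samples)
  obs_gm <- apply_noise(truth_gm, config$missing_rate, config$error_rate)

  truth <- data.frame(id = loci$id, p_ancestral = p_anc,
                      stringsAsFactors = FALSE)
  for (p in pops) truth[[paste0("freq_", p)]] <- freqs[, p]
  if (length(pops) == 2) truth$delta_p <- abs(freqs[, 1] - freqs[, 2])

  out <- list(genotypes = obs_gm, truth_genotypes = truth_gm,
              groups = groups, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(vcf = file.path(dir, "cohort.vcf.gz"),
                  groups = file.path(dir, "groups.tsv"),
                  truth = file.path(dir, "truth.tsv"))
    write_vcf(obs_gm, paths$vcf)
    write_sample_groups(groups, paths$groups)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

# Applies uniform-substitution genotype error then i.i.d. missingness to a
# truth matrix (error first: a dropped call cannot also be miscalled).
apply_noise <- function(gm, missing_rate, error_rate) {
  d <- gm$dosage
  if (error_rate > 0) {
    flip <- which(!is.na(d) & stats::runif(length(d)) < error_rate)
    if (length(flip)) {
      d[flip] <- vapply(d[flip], function(g) sample(setdiff(0:2, g), 1),
                        integer(1))
    }
  }
  if (missing_rate > 0) {
    d[stats::runif(length(d)) < missing_rate] <- NA_integer_
  }
  genotype_matrix(d, gm$loci, samples = gm$samples)
}

#' Simulate a chip readout of known truth genotypes
#'
#' Two modes. Stochastic mode perturbs calls with the given error and
#' missingness rates (as in [simulate_cohort()]). Exact mode
#' (`exact_discordant = k`) flips exactly `k` randomly chosen called
#' genotypes to a different dosage and changes nothing else — the
#' deterministic construction used to verify replicate-concordance
#' arithmetic.
#'
#' @param truth a [genotype_matrix()].
#' @param missing_rate,error_rate stochastic perturbation rates.
#' @param seed integer seed (required).
#' @param exact_discordant optional integer `k`; overrides the stochastic
#'   mode.
#' @return A perturbed [genotype_matrix()].
#' @export
simulate_chip_readout <- function(truth, missing_rate = 0, error_rate = 0,
                                  seed, exact_discordant = NULL) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  if (!is.null(exact_discordant)) {
    k <- as.integer(exact_discordant)
    d <- truth$dosage
    callable <- which(!is.na(d))
    if (k > length(callable)) stop("exact_discordant exceeds callable genotypes")
    flip <- sample(callable, k)
    d[flip] <- vapply(d[flip], function(g) sample(setdiff(0:2, g), 1), integer(1))
    return(genotype_matrix(d, truth$loci, samples = truth$samples))
  }
  apply_noise(truth, missing_rate, error_rate)
}

#' Simulate a reference genome with planted duplications and toy genes
#'
#' Generates i.i.d. uniform-base chromosomes, copies a designated 110-bp
#' source window to `n_duplications` recorded positions (alternate copies
#' reverse-complemented) so probe-homology behavior is known by
#' construction, and plants small gene models with in-frame CDS (one
#' two-exon plus-strand gene and one single-exon minus-strand gene per
#' chromosome requested).
#'
#' @param chrom_lengths named vector of chromosome lengths (each >= 1000).
#' @param n_duplications copies of the source window to plant (may be 0).
#' @param seed integer seed (required).
#' @param dir optional directory; writes `genome.fa` and `genes.gff3`.
#' @param window_length length of the duplicated window (default 110).
#' @return List: `genome` (`DNAStringSet`), `gene_models` (list of
#'   [gene_model()]), `dup_source` (`chrom`, `start`, `end`), `dup_sites`
#'   (data.frame of planted copies with strand), and `paths` when `dir` is
#'   given.
#' @export
simulate_reference <- function(chrom_lengths, n_duplications = 0L, seed,
                               dir = NULL, window_length = 110L) {
  if (missing(seed)) stop("a seed is required")
  if (any(chrom_lengths < 1000)) stop("chromosomes must be >= 1000 bp")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- lapply(chrom_lengths, function(len) {
    paste(sample(bases, len, replace = TRUE), collapse = "")
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(chrom_lengths)

  ch1 <- names(chrom_lengths)[1]
  len1 <- chrom_lengths[[1]]
  src_start <- floor(len1 / 2)
  src_end <- src_start + window_length - 1L
  if (src_end > len1 - window_length) stop("chromosome too short for duplications")
  dup_sites <- data.frame(chrom = character(), start = integer(),
                          end = integer(), strand = character())
  if (n_duplications > 0) {
    src <- Biostrings::subseq(genome[[ch1]], src_start, src_end)
    # evenly spaced landing slots, skipping any that touch the source window
    slots <- round(seq(window_length + 1, len1 - 2 * window_length,
                       length.out = n_duplications + 3))
    slots <- slots[abs(slots - src_start) >= 2 * window_length]
    if (length(slots) < n_duplications) stop("chromosome too short for duplications")
    slots <- slots[seq_len(n_duplications)]
    for (i in seq_len(n_duplications)) {
      s <- slots[i]; e <- s + window_length - 1L
      piece <- if (i %% 2 == 0) Biostrings::reverseComplement(src) else src
      genome[[ch1]] <- Biostrings::replaceAt(genome[[ch1]],
                                             IRanges::IRanges(s, e),
                                             as.character(piece))
      dup_sites <- rbind(dup_sites, data.frame(
        chrom = ch1, start = s, end = e,
        strand = if (i %% 2 == 0) "-" else "+"))
    }
  }

  models <- plant_genes(genome)
  genome <- models$genome
  out <- list(genome = genome, gene_models = models$models,
              dup_source = list(chrom = ch1, start = src_start, end = src_end),
              dup_sites = dup_sites)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(dir, "genome.fa"),
                  gff = file.path(dir, "genes.gff3"))
    Biostrings::writeXStringSet(genome, paths$fasta)
    write_gene_models_gff3(models$models, paths$gff)
    out$paths <- paths
  }
  out
}

# Overwrites small windows of the first chromosome with in-frame coding
# sequence and returns matching gene models: a two-exon plus-strand gene
# and a single-exon minus-strand gene.
plant_genes <- function(genome) {
  ch <- names(genome)[1]
  atg <- "ATG"
  body <- function(n_codon) {
    paste(sample(c("GCC", "GTT", "TTT", "GGA", "AAA", "CCC", "GAT", "TCA"),
                 n_codon, replace = TRUE), collapse = "")
  }
  # plus-strand gene: exon1 CDS 30 bp at 101..130, exon2 CDS 30 bp at 201..230
  cds1 <- paste0(atg, body(9))
  cds2 <- paste0(body(9), "TAA")
  genome[[ch]] <- Biostrings::replaceAt(genome[[ch]],
                                        IRanges::IRanges(101, 130), cds1)
  genome[[ch]] <- Biostrings::replaceAt(genome[[ch]],
                                        IRanges::IRanges(201, 230), cds2)
  g_plus <- gene_model("toyA", ch, "+",
                       exons = data.frame(start = c(101, 201), end = c(130, 230)))
  # minus-strand gene: single 60-bp CDS at 501..560 (reverse-complemented)
  cds_m <- paste0(atg, body(17), "TGA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_m)))
  genome[[ch]] <- Biostrings::replaceAt(genome[[ch]],
                                        IRanges::IRanges(501, 560), rc)
  g_minus <- gene_model("toyB", ch, "-",
                        exons = data.frame(start = 501, end = 560))
  list(genome = genome, models = list(toyA = g_plus, toyB = g_minus))
}

#' Write gene models as GFF3
#'
#' @param models list of [gene_model()] objects.
#' @param path output GFF3 path.
#' @export
write_gene_models_gff3 <- function(models, path) {
  grs <- lapply(models, function(m) {
    n_ex <- nrow(m$exons); n_cds <- nrow(m$cds)
    gr <- GenomicRanges::GRanges(
      seqnames = m$chrom,
      ranges = IRanges::IRanges(
        start = c(min(m$exons$start), m$exons$start, m$cds$start),
        end = c(max(m$exons$end), m$exons$end, m$cds$end)),
      strand = m$strand)
    gr$type <- c("mRNA", rep("exon", n_ex), rep("CDS", n_cds))
    gr$ID <- c(m$gene_id, paste0(m$gene_id, ".exon", seq_len(n_ex)),
               paste0(m$gene_id, ".cds", seq_len(n_cds)))
    # CDS phase in transcription order
    widths <- m$cds$end - m$cds$start + 1
    ord <- if (m$strand == "+") seq_len(n_cds) else rev(seq_len(n_cds))
    phase <- integer(n_cds)
    phase[ord] <- (3 - cumsum(c(0, widths[ord][-n_cds])) %% 3) %% 3
    gr$phase <- c(NA_integer_, rep(NA_integer_, n_ex), phase)
    gr$Parent <- IRanges::CharacterList(
      c(list(character()), rep(list(m$gene_id), n_ex + n_cds)))
    gr
  })
  all <- do.call(c, unname(grs))
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}
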