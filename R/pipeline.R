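#' Pipeline configuration with the standard panel-design thresholds
#'
#' Collects every tunable of the design workflow with its default: the
#' background screen (missing rate < 0.30, MAF > 0.10), the specific-locus
#' screen (missing rate < 0.10, heterozygote rate < 0.50, delta-MAF >
#' 0.20), the probe rules (length 110 bp, GC in [0.30, 0.70], fewer than 5
#' homologous loci, k-mer seed 25) and the annotation flank (2000 bp).
#' Every threshold is overridable; the full configuration is echoed into
#' the run manifest.
#'
#' @param vcf,genome,gff,groups,functional input file paths (any may be
#'   `NULL` when the corresponding stage is skipped).
#' @param target_size panel size budget (default 5000).
#' @param bg_max_missing,bg_min_maf background screen thresholds.
#' @param sp_max_missing,sp_max_het,sp_min_delta specific screen thresholds.
#' @param probe_length,gc_min,gc_max,max_homology,homology_k probe rules.
#' @param flank annotation flank (bp).
#' @param seed integer seed driving every stochastic step.
#' @return List of class `panel_config`.
#' @export
panel_config <- function(vcf = NULL, genome = NULL, gff = NULL,
                         groups = NULL, functional = NULL,
                         target_size = 5000L,
                         bg_max_missing = 0.30, bg_min_maf = 0.10,
                         sp_max_missing = 0.10, sp_max_het = 0.50,
                         sp_min_delta = 0.20,
                         probe_length = 110L, gc_min = 0.30, gc_max = 0.70,
                         max_homology = 5L, homology_k = 25L,
                         flank = 2000L, seed = 1L) {
  structure(list(vcf = vcf, genome = genome, gff = gff, groups = groups,
                 functional = functional, target_size = as.integer(target_size),
                 bg_max_missing = bg_max_missing, bg_min_maf = bg_min_maf,
                 sp_max_missing = sp_max_missing, sp_max_het = sp_max_het,
                 sp_min_delta = sp_min_delta,
                 probe_length = as.integer(probe_length),
                 gc_min = gc_min, gc_max = gc_max,
                 max_homology = as.integer(max_homology),
                 homology_k = as.integer(homology_k),
                 flank = as.integer(flank), seed = as.integer(seed)),
            class = "panel_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [panel_config()] arguments.
#' @return A `panel_config`.
#' @export
read_panel_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(panel_config, vals)
}

#' Run the full panel-design pipeline
#'
#' Wires the stages end to end: read the cohort VCF and group map, compute
#' locus summaries, run the background and specific screens, assemble the
#' panel with forced functional loci, design and vet capture probes (when a
#' genome is supplied), drop undesignable loci, annotate (when gene models
#' are supplied), and write every stage output plus a JSON manifest with
#' the echoed configuration and the filter-count ledger.
#'
#' @param config a [panel_config()] with at least `vcf` and `groups` set.
#' @param out_dir run directory (created).
#' @return List: `panel` (final panel data.frame), `counts` (named filter
#'   ledger), `probes`, `annotation`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "panel_config"))
  for (f in c("vcf", "groups")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      stop("required input missing: ", f)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  gm <- read_vcf(config$vcf)
  groups <- read_sample_groups(config$groups)
  counts <- c(input_loci = n_loci(gm),
              dropped_records = attr(gm, "n_dropped") %||% 0L)
  say("input: %d samples x %d loci (%d record(s) dropped)",
      n_samples(gm), n_loci(gm), counts[["dropped_records"]])

  summaries <- summarize_loci(gm, groups = groups)
  write_locus_summaries(summaries, file.path(out_dir, "locus_summaries.tsv"))
  bg <- screen_background(summaries, config$bg_max_missing, config$bg_min_maf)
  sp <- screen_specific(summaries, config$sp_max_missing, config$sp_max_het,
                        config$sp_min_delta)
  counts["background_candidates"] <- length(bg)
  counts["specific_candidates"] <- length(sp)
  say("screens: %d background, %d specific candidates", length(bg), length(sp))

  fun <- NULL
  if (!is.null(config$functional) && file.exists(config$functional)) {
    fun <- utils::read.table(config$functional, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  }
  chrom_lengths <- if (!is.null(config$genome)) {
    g <- read_genome(config$genome)
    stats::setNames(Biostrings::width(g), names(g))
  } else {
    # fall back to the observed locus span per chromosome
    tapply(gm$loci$pos, gm$loci$chrom, max)
  }
  design <- assemble_panel(fun, sp, bg, summaries, config$target_size,
                           chrom_lengths)
  counts["designed_loci"] <- nrow(design$panel)
  say("panel: %d loci (%s)", nrow(design$panel),
      paste(names(design$composition), design$composition,
            sep = "=", collapse = ", "))

  probes <- NULL
  if (!is.null(config$genome)) {
    genome <- read_genome(config$genome)
    probes <- design_probes(design$panel, genome,
                            gc_min = config$gc_min, gc_max = config$gc_max,
                            max_homology = config$max_homology,
                            k = config$homology_k)
    undesignable <- attr(probes, "undesignable")
    design$panel <- design$panel[!design$panel$id %in% undesignable, ,
                                 drop = FALSE]
    counts["undesignable_loci"] <- length(undesignable)
    counts["retained_loci"] <- nrow(design$panel)
    say("probes: %d candidates, %d loci undesignable, %d loci retained",
        nrow(probes), length(undesignable), nrow(design$panel))
    utils::write.table(probes, file.path(out_dir, "probes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_probe_fasta(probes, file.path(out_dir, "probes.fa"))
  }
  write_panel(design, file.path(out_dir, "panel.tsv"))

  annotation <- NULL
  if (!is.null(config$gff) && file.exists(config$gff)) {
    models <- read_gene_models(config$gff)
    genome <- if (!is.null(config$genome)) read_genome(config$genome) else NULL
    ann_panel <- merge(design$panel, gm$loci[, c("id", "ref", "alt")], by = "id")
    annotation <- annotate_panel(ann_panel, models, genome,
                                 flank = config$flank)
    utils::write.table(annotation, file.path(out_dir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(config = unclass(config), counts = as.list(counts),
                   n_samples = n_samples(gm),
                   not_genotypable = design$not_genotypable)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  list(panel = design$panel, counts = counts, probes = probes,
       annotation = annotation, out_dir = out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
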