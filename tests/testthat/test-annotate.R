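# two well-separated genes on one 30-kb chromosome:
# geneP (+): exons [10001,10100] and [10301,10400], all CDS
# geneQ (-): exon [20001,20600], all CDS
toy_models <- function() {
  list(
    geneP = gene_model("geneP", "chr1", "+",
                       exons = data.frame(start = c(10001, 10301),
                                          end = c(10100, 10400)),
                       cds = data.frame(start = c(10001, 10301),
                                        end = c(10099, 10399))),
    geneQ = gene_model("geneQ", "chr1", "-",
                       exons = data.frame(start = 20001, end = 20600))
  )
}

test_that("region classes follow containment, strand-aware flanks and precedence", {
  m <- toy_models()
  cl <- function(pos) classify_location(list(chrom = "chr1", pos = pos), m)
  expect_equal(cl(10050), "exonic")
  expect_equal(cl(10200), "intronic")
  expect_equal(cl(8501), "upstream")      # 1500 bp 5' of geneP (+)
  expect_equal(cl(10900), "downstream")   # 500 bp 3' of geneP
  expect_equal(cl(21500), "upstream")     # 900 bp 5' of geneQ (-)
  expect_equal(cl(19500), "downstream")   # 501 bp 3' of geneQ (-)
  expect_equal(cl(5000), "intergenic")    # > 2 kb from every gene
  expect_equal(cl(25000), "intergenic")
  expect_warning(
    out <- classify_location(list(chrom = "chrX", pos = 5), m),
    "no gene model")
  expect_equal(out, "intergenic")
})

test_that("a SNP between two genes on the right sides is upstream;downstream", {
  m <- list(
    gA = gene_model("gA", "chr1", "+",
                    exons = data.frame(start = 1000, end = 1299)),
    gB = gene_model("gB", "chr1", "+",
                    exons = data.frame(start = 2601, end = 2900)))
  # 500 bp downstream of gA and 800 bp upstream of gB
  expect_equal(classify_location(list(chrom = "chr1", pos = 1799), m),
               "upstream;downstream")
})

test_that("genomic positions map to spliced CDS coordinates", {
  m <- toy_models()
  # plus strand: CDS starts at 10001 -> genomic 10004 is cds 4
  expect_equal(genomic_to_cds(list(pos = 10004), m$geneP), 4L)
  # exon1 CDS is 99 bp: first base of exon2 CDS -> cds 100
  expect_equal(genomic_to_cds(list(pos = 10301), m$geneP), 100L)
  # minus strand: last genomic CDS base is cds position 1
  expect_equal(genomic_to_cds(list(pos = 20600), m$geneQ), 1L)
  expect_equal(genomic_to_cds(list(pos = 20001), m$geneQ), 600L)
  expect_error(genomic_to_cds(list(pos = 10200), m$geneP), "classify_location")
})

test_that("codon arithmetic reproduces the validated non-synonymous calls", {
  # codon 155 GCC: c.464 C>T -> GTC, Ala -> Val
  cds155 <- paste(c(rep("AAA", 154), rep("GCC", 50)), collapse = "")
  cq <- cds_consequence(464, "C", "T", cds155)
  expect_equal(cq$codon_index, 155L)
  expect_equal(cq$codon_offset, 1L)
  expect_equal(cq$ref_codon, "GCC")
  expect_equal(cq$alt_codon, "GTC")
  expect_equal(cq$ref_aa, "A")
  expect_equal(cq$alt_aa, "V")
  expect_false(cq$synonymous)
  expect_equal(cq$c_notation, "c.464C>T")
  expect_equal(cq$p_notation, "p.155A>V")

  # codon 141 TTT: c.421 T>G -> GTT, Phe -> Val
  cds141 <- paste(c(rep("AAA", 140), rep("TTT", 10)), collapse = "")
  cq2 <- cds_consequence(421, "T", "G", cds141)
  expect_equal(cq2$codon_index, 141L)
  expect_equal(cq2$codon_offset, 0L)
  expect_equal(cq2$p_notation, "p.141F>V")
  expect_false(cq2$synonymous)

  # wobble position: GGA -> GGG stays Gly
  cq3 <- cds_consequence(3, "A", "G", "GGATTT")
  expect_true(cq3$synonymous)
  expect_equal(cq3$p_notation, "p.1G>G")

  expect_error(cds_consequence(2, "T", "G", "GGATTT"), "mismatch")
})

test_that("codon bookkeeping identity holds and stops are starred", {
  for (p in 1:12) {
    cq <- cds_consequence(p, substr(strrep("GATCTGGCAAAA", 2), p, p), "C",
                          strrep("GATCTGGCAAAA", 2))
    expect_equal(3 * (cq$codon_index - 1) + cq$codon_offset + 1, cq$cds_pos)
  }
  # TCA -> TAA: stop gain reported as *
  cq <- cds_consequence(2, "C", "A", "TCAGGG")
  expect_equal(cq$alt_aa, "*")
  expect_equal(cq$p_notation, "p.1S>*")
})

test_that("consequence calls agree with brute-force whole-CDS translation", {
  translate_str <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       no.init.codon = TRUE))
  }
  set.seed(8)
  for (rep in 1:10) {
    n_codon <- sample(4:20, 1)
    cds <- paste(sample(c("A", "C", "G", "T"), 3 * n_codon, replace = TRUE),
                 collapse = "")
    p <- sample(3 * n_codon, 1)
    ref <- substr(cds, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    cq <- cds_consequence(p, ref, alt, cds)
    mutant <- cds
    substr(mutant, p, p) <- alt
    expect_equal(cq$synonymous, translate_str(cds) == translate_str(mutant))
    aa_ref <- translate_str(cds)
    aa_alt <- translate_str(mutant)
    expect_equal(cq$ref_aa, substr(aa_ref, cq$codon_index, cq$codon_index))
    expect_equal(cq$alt_aa, substr(aa_alt, cq$codon_index, cq$codon_index))
  }
})

test_that("annotate_panel ties everything together, complementing minus-strand alleles", {
  ref <- simulate_reference(c(chr1 = 20000), seed = 12)
  models <- ref$gene_models
  genome <- ref$genome
  # toyB is minus strand over [501, 560]; pick its CDS position 1 (genomic 560)
  base560 <- extract_region(genome, "chr1", 560, 560)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  alt_g <- setdiff(c("A", "C", "G", "T"), base560)[1]
  panel <- data.frame(chrom = "chr1", pos = c(105L, 560L, 15000L),
                      ref = c(extract_region(genome, "chr1", 105, 105),
                              base560, "A"),
                      alt = c(setdiff(c("A", "C", "G", "T"),
                                      extract_region(genome, "chr1", 105, 105))[1],
                              alt_g, "G"),
                      id = c("p1", "p2", "p3"))
  ann <- annotate_panel(panel, models, genome)
  expect_equal(ann$region_class, c("exonic", "exonic", "intergenic"))
  expect_equal(ann$gene[1:2], c("toyA", "toyB"))
  # minus-strand c. notation uses complemented alleles at CDS position 1
  expect_equal(ann$c_notation[2],
               sprintf("c.1%s>%s", comp[[base560]], comp[[alt_g]]))
  expect_true(is.na(ann$c_notation[3]))
})
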