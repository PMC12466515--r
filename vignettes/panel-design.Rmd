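---
title: "Designing and validating low-density targeted SNP panels with snpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating low-density targeted SNP panels with snpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpanel)
```

## The problem

Low-density targeted genotyping panels ("liquid-phase chips", genotyping by
target sequencing) are the workhorse of affordable breed management for
local livestock populations: a few thousand SNPs, captured by
hybridization probes and read by sequencing, are enough for breed
identification, kinship estimation and marker-assisted selection at a
fraction of the cost of whole-genome resequencing. snpanel implements the
full design-and-validation loop for such a panel from a multi-sample VCF:
locus screening, uniform genomic placement, capture-probe vetting,
functional annotation, and post-genotyping QC, together with a cohort
simulator so every step can be exercised and tested without external data.

## The screening model

Every statistic is computed from an ALT-dosage matrix (samples x loci,
entries 0/1/2 or missing). For each locus we compute:

* **missing rate** ("deletion rate"): fraction of samples with no call;
* **ALT frequency** $p$: ALT alleles over called alleles;
* **MAF**: $\min(p, 1-p)$;
* **heterozygote rate**: heterozygotes over called genotypes;
* **delta-MAF**: with samples partitioned into a target group and a
  reference group, $|p_{\mathrm{target}} - p_{\mathrm{other}}|$ on aligned
  ALT frequencies.

Two screens define the panel's candidate pools:

* **Background loci** — well-genotyped, informative genome-wide markers:
  missing rate $< 0.30$ and MAF $> 0.10$.
* **Breed-specific loci** — markers differentiating the target population:
  missing rate $< 0.10$, heterozygote rate $< 0.50$, and delta-MAF
  $> 0.20$.

All five thresholds are strict inequalities (boundary values are
excluded), are the package defaults in `panel_config()`, and every one is
overridable. delta-MAF is deliberately defined on aligned ALT frequencies
rather than on independently-minored MAFs: the absolute difference of a
frequency and its complement is unchanged when REF/ALT orientation flips,
so the statistic cannot be inflated by allele-coding inconsistencies
between groups. Pooled-sample frequencies are used for the background MAF
and the heterozygosity filter; frequencies are always computed over called
alleles only, and a locus with no called genotypes propagates as undefined
rather than as frequency zero.

## Panel assembly

`assemble_panel()` combines three inputs with precedence
functional > specific > background. Curated functional (trait-associated)
loci are forced in — any that are absent from the genotyped candidate set
are reported as "not genotypable" rather than silently dropped. Specific
loci follow up to the budget; the remaining budget is filled with
background loci placed as uniformly as practical:

* `allocate_quota()` splits the background budget across chromosomes in
  proportion to chromosome length, integerized by largest remainder
  (Hamilton), so quotas sum exactly and each deviates from exact
  proportionality by less than 1; remainder ties go to the
  lexicographically first chromosome name, which keeps the procedure
  deterministic.
* `select_uniform()` cuts each chromosome into quota-many equal-width bins
  and picks the highest-MAF candidate in each (position breaks ties);
  quota stranded in empty bins is pushed to the nearest occupied bins. We
  chose this binning heuristic over exhaustive max–min-gap optimization
  because it is deterministic, linear-time and auditable at genome scale;
  on small configurations where the bin grid aligns with candidate
  clusters it provably attains the exhaustive optimum, which the test
  suite checks against a brute-force oracle.

## Probe feasibility

Each panel SNP gets `n_candidates` (default 2) 110-bp probe windows that
fully cover the SNP; the first candidate centers it (offset 56 of 110),
further candidates spread the SNP across the middle half of the probe so
they tile different flanking sequence, and windows are shifted inward at
chromosome ends. A candidate passes when:

* GC fraction lies in the closed band [0.30, 0.70] (N bases count in the
  denominator only);
* its genome-wide homology count is below 5; and
* it contains no ambiguous base.

Homology is operationalized as exact k-mer seeding (default k = 25): the
number of distinct genomic loci — both strands, hits within one probe
length merged — sharing at least one exact 25-mer with the probe. The
probe's own source locus always counts, so 1 is the floor. This is a
deliberately conservative, index-friendly stand-in for alignment-based
similarity search: any high-identity 110-bp repeat almost surely shares an
exact 25-mer, while random 1-Mb sequence essentially never does
($\approx 10^6 \times 86 \times 4^{-25}$ expected collisions). Loci with
no passing candidate are flagged undesignable and dropped from the panel,
the in-silico analog of probe-synthesis attrition.

## Annotation

`classify_location()` assigns exonic / intronic / upstream / downstream /
"upstream;downstream" / intergenic with precedence
exonic > intronic > flanking > intergenic and a strand-aware flank of
2000 bp (configurable). A SNP within the flank of two different genes on
the appropriate sides gets the combined "upstream;downstream" label. For
CDS SNPs, `genomic_to_cds()` maps the genomic coordinate into the spliced
CDS (complementing alleles on minus-strand genes) and `cds_consequence()`
does the codon arithmetic: codon index $\lceil \mathrm{pos}/3 \rceil$,
substitution at offset $(\mathrm{pos}-1) \bmod 3$, translation under the
standard genetic code only (no organellar loci are in scope), and
HGVS-style `c.`/`p.` notations with one-letter amino acids and `*` for
stops. The test suite checks the per-codon calls against brute-force
translation of the entire mutant CDS.

## Validation metrics

* **Detection rate**: percentage of panel loci called in a sample.
* **Replicate concordance**: over loci called in both replicates,
  $100 \times (1 - \mathrm{discordant}/\mathrm{compared})$. With a fully
  called 5062-locus pair, 5, 3 and 2 flips give 99.90%, 99.94% and 99.96%.
* **Truth concordance**: the same statistic against a resequencing truth
  set, computed over the called intersection, with a per-locus discordance
  table for audit. Using the both-called denominator is standard QC
  practice; at call rates near 99.8% the alternative (all shared loci)
  changes rates by less than the reporting precision.
* **MAF spectrum**: half-open bins of width 0.05 over [0, 0.5], last bin
  closed, plus a separate count of near-monomorphic loci (MAF < 0.01),
  which carry little information for downstream analyses.

Rates are reported half-up to two decimals, matching how chip QC reports
are printed.

## Population structure

* **IBS distance**: one minus the allele-sharing fraction over pairwise
  complete loci.
* **PCA**: per-locus mean imputation, column centering, then the exact
  eigendecomposition via SVD (`prcomp`); explained variance percentages
  are eigenvalue shares and sum to 100.
* **Neighbor joining** is implemented in-package with explicit numerical
  policy: Q-matrix ties break toward the smallest row-major index pair,
  and a negative branch length is clamped to zero with the deficit moved
  to its sibling so the joined pair's path length is preserved. NJ is
  exact on additive matrices; the tests verify recovery of generating
  topologies and branch lengths for 4–6 taxa and agreement with an
  exhaustive least-squares topology search. We use distance-based NJ with
  locus bootstrap (resampling loci with replacement, supports =
  percentage of replicates containing each original bipartition) rather
  than maximum likelihood: for genotype dosage data at panel scale it is
  fast, deterministic under a fixed seed, and sufficient to demonstrate
  population grouping.
* **Kinship**: VanRaden's centered cross-product
  $K = ZZ^\top / (2\sum_l p_l(1-p_l))$ with $Z$ the dosage matrix centered
  at $2p_l$; missing dosages contribute zero after centering. Note that
  with in-sample allele frequencies each row of $K$ sums to zero, so the
  off-diagonal mean is $-\overline{\mathrm{diag}}/(n-1)$, slightly
  negative — the tests assert this identity rather than a naive zero.

## The simulator and what it does (not) emulate

`simulate_cohort()` draws ancestral frequencies uniformly on [0.05, 0.5],
drifts them per population under the Balding–Nichols model
(Beta$(p(1-F)/F,\,(1-p)(1-F)/F)$, so population frequencies have mean $p$
and variance $Fp(1-p)$), samples Hardy–Weinberg genotypes, and applies
uniform-substitution genotyping error followed by i.i.d. missingness.
Defaults mirror a small-breed conservation scenario: 15 target samples
against 128 reference samples across other breeds, FST 0.1 (a typical
between-breed value for livestock), 2% missingness and 0.5% genotyping
error for resequencing-grade input; chip-grade readouts in the validation
examples use 0.18% missingness, the call-rate class this assay type
achieves. `simulate_reference()` adds a uniform-base genome with planted
110-bp duplications (alternate copies reverse-complemented) and two toy
gene models with in-frame CDS, so probe homology and consequence calling
have ground truth by construction.

The simulator intentionally omits linkage disequilibrium, mutation-model
sequence context, batch effects and locus-specific (non-i.i.d.) dropout.
Passing tests therefore demonstrate correctness of the statistics and the
recovery of planted parameters under the stated model — not that a panel
designed from any particular real cohort will hit specific field
performance numbers, which depend on the cohort itself.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale, chosen to
keep binomial noise well inside the asserted tolerances: screening
recovery uses 50 samples per population with 200 strongly differentiated
(true $|\Delta p| \ge 0.4$) and 800 near-null loci; probe tests use a 1-Mb
reference with 4 planted duplications; tree and PCA checks use cohorts of
40–100 samples and up to 1000 loci; concordance arithmetic uses fully
called 5062-locus replicate pairs. Every stochastic step takes an explicit
seed and is bit-reproducible; all thresholds and generator settings were
fixed as the study conditions described above.

## Known limitations

* Multiallelic records are dropped, not split; half-calls are treated as
  missing. Both are conservative choices for frequency estimation.
* The k-mer homology count is a proxy, not an aligner: a repeat diverged
  enough to share no exact 25-mer is invisible to it.
* UTR subclasses are folded into exonic/intronic; splice-site annotation
  is not attempted.
* Chromosome names must match exactly across VCF/FASTA/GFF inputs.
* NJ with IBS distances is a grouping tool, not a substitute for model-
  based phylogenetics.
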