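---
title: "Methods: gene-centric analysis of natural variation at a single locus"
author: "locusvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-centric analysis of natural variation at a single locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locusvar)
```

# What the package computes

`locusvar` analyses natural single-nucleotide variation at one gene locus
the way population-scale gene portraits are usually assembled: partition the
locus into region classes and compute SNP densities, split variants into
rare and common frequency classes, annotate coding variants as synonymous
or non-synonymous, normalise coding counts by fractional mutational-site
totals to obtain pN/pS per domain, test regional non-synonymous enrichment
against a placement null, trace SNP density along the gene and along the
protein with sliding windows, compare intron positions and phases across
orthologs, profile per-column conservation of an ortholog alignment, and
rank the amino-acid-changing variants by functional evidence. A seeded
synthetic-data generator produces complete, ground-truth-labelled test
datasets with the geometry of a real 1000 Genomes single-gene extract.

The motivating system is the human co-chaperone gene *BAG1* (a nucleotide
exchange factor for Hsp70 with an N-terminal ubiquitin-like domain and a
C-terminal three-helix BAG domain), and the package defaults encode that
locus's published geometry; every operation is generic over any
single-transcript gene model.

# The gene model and coordinate conventions

A `gene_model` holds ordered exons, one CDS span (stop codon included) and
two regulatory flanks. All coordinates, external and internal, are 1-based
inclusive — the native convention of GFF3, VCF and the Bioconductor ranges
stack. We deliberately do not introduce a second internal convention; the
absence of any conversion layer is itself the defence against off-by-one
errors, and every boundary rule is pinned by tests (the first base of the
start codon and the last base of the stop codon are `coding`).

The five region labels — regulatory, intronic, 5'UTR, 3'UTR, coding —
partition the locus exactly:

```{r}
loc <- generate_locus(synthetic_config(seed = 1))
region_lengths(loc$model)
```

Minus-strand genes are fully supported: transcript-space quantities (UTR
sides, CDS offsets, intron phases, codon substitution) are computed after
orientation normalisation, and the suite checks that reflecting a locus
through its midpoint (with allele complementation) leaves every
classification unchanged.

The published locus reports a single 10,000 bp regulatory total without an
upstream/downstream split; the generator defaults to 5,000 + 5,000, which
is a package choice, not a literature fact, and is configurable.

Intron phase follows the GFF convention: the number of coding nucleotides
preceding the junction, modulo 3. Introns lying in the UTRs carry a
`coding_interrupting = FALSE` flag and are excluded from phase-conservation
comparisons. Two introns from different genes count as conserved when
their junctions map to the same alignment column (the codon containing the
junction; for phase-0 introns the codon immediately after it) *and* their
phases agree — position without phase, or phase without position, is not
homology evidence.

# Variant annotation

Coding SNPs are annotated by substituting the alternative allele
(complemented for minus-strand genes) into its codon and translating with
the standard genetic code (translation table 1). A variant whose reference
allele disagrees with the CDS fails loudly rather than being skipped:
silent skips would corrupt every density downstream. Variants in the stop
codon are coding; a change that abolishes the stop is non-synonymous.
Multi-allelic VCF records are decomposed into one variant per alternative
allele and each is counted once.

"Rare" means a global minor allele frequency strictly below 1%; a MAF of
exactly 0.01 is common. SNP density is `1000 * n / length` with lengths in
bp for genomic regions and in fractional sites for the synonymous and
non-synonymous rows.

# Site counting and pN/pS

Fractional site totals follow the Nei–Gojobori convention: at each codon
position, each of the three alternative bases that preserves the amino
acid contributes 1/3 of a synonymous site; the remainder of the 3 sites
per codon is non-synonymous. Mutations creating a stop count as
non-synonymous, and the terminal stop codon is excluded from totals (a
1,038 bp CDS contributes 1,035 counted bases). The implementation is a
64-codon lookup table built once by enumeration; the test suite verifies
it against an independent exhaustive 9-mutant enumeration that uses a
different translation source.

pN/pS is `(nsSNPs / non-synonymous sites) / (sSNPs / synonymous sites)`.
With zero synonymous SNPs the ratio is reported as undefined and flagged,
never as a number. The literature sometimes writes dN/dS for this
within-species quantity; the package standardises on pN/pS since no
divergence correction (Jukes–Cantor, maximum-likelihood codon models) is
applied — those are deliberately out of scope.

# The Monte-Carlo enrichment test

The source analyses report that a domain's non-synonymous enrichment is
"significant" without naming a test. The package implements and documents
one interpretation: a position-uniform placement null. The observed total
number of coding SNPs is dropped uniformly at random over the coding
positions (terminal stop excluded), each with a uniformly random
alternative base; per replicate the region's pN/pS is recomputed; the
p-value is `(1 + #{replicate >= observed}) / (1 + n_replicates)`.
Replicate positions are drawn with replacement — at ~37 SNPs over ~1,000
positions the collision probability is negligible and the draw stays
vectorised. The replicate count (default 100,000) and seed are always
exposed and logged.

Two numerical choices deserve a note:

* **Degenerate replicates.** A replicate with zero synonymous SNPs in the
  region has an infinite ratio. Ranking all such replicates above every
  finite ratio would give the test a p-value floor of roughly the null
  probability of that tier (~10% at study-like counts), making small
  p-values unreachable. The ordering statistic therefore refines the
  degenerate tier lexicographically: zero-sSNP outcomes rank above all
  finite ratios *and are ordered by pN among themselves*. This is a pure
  refinement of the ordering — validity is unchanged.
* **Ties and calibration.** The reported p-value counts ties against the
  observation (conservative). Because the statistic is discrete, raw
  p-values under the null are lumpy and stochastically larger than
  uniform; the calibration test in the suite therefore applies the
  standard randomized tie-breaking construction, which is exactly uniform
  under the null, and additionally checks that the conservative p-value
  never exceeds its nominal level. Under this null, the study-like BAG
  observation (6 nsSNPs, 1 sSNP of 37 coding SNPs) is *not* significant
  at 0.001 — the published claim evidently rests on a different, unstated
  test; we report what this null supports and leave the choice visible to
  the user.

# Sliding windows

Windows are left-aligned at the span start, advance by the step, and count
by half-open membership. Only fully contained windows are emitted, so a
200 kb span with a 10 kb window and 1 kb step yields exactly
`floor((200000-10000)/1000)+1 = 191` windows; an `include_partial` switch
adds a final truncated window for users who prefer full coverage. The
reported coordinate is the window start. Defaults follow the study:
10,000/1,000 bp on the genomic axis and 100/10 aa on the protein axis,
where a coding SNP sits at the amino-acid position of its codon.

# Conservation profiling

Reference positions map to alignment columns through the reference's gap
structure. Conservation of a column is the percentage of non-gap residues
(reference included) matching the reference residue; gaps are excluded
from numerator and denominator, a convention the source tables do not
state and which is therefore documented here rather than assumed silently.

A kingdom-specific conserved difference is a column where every group's
modal residue reaches the consensus threshold within its group (inclusive,
default 0.9, over non-gap residues) and the modal residues are not all
identical. Logo-style rendering is limited to emitting per-column
frequency tables; graphics are left to dedicated tools.

# Prioritization of non-synonymous variants

Four computable criteria are applied lexicographically — no weighted score
is invented:

1. **Functional-site overlap.** Exact position match against a user table
   of known functional residues. The table may carry an evidence tier
   (`priority`, 1 = strongest): residues whose mutation is known to
   abolish the protein's core interaction (for BAG-1, Hsp70 binding) rank
   above weaker structural annotations such as packing contacts, and both
   rank above unannotated positions. A flat table (no `priority` column)
   treats all annotated sites equally.
2. **Conservation**, descending.
3. **Radicalness**: different physicochemical class *and* substitution
   score ≤ 0 in both BLOSUM62 and BLOSUM80 (the matrices ship with
   Biostrings; the six-class partition AVLIM/FWY/STNQ/KRH/DE/GCP is a
   declared configuration, and a stop counts as its own class so nonsense
   changes are always radical). The literature's reference to a
   "BLOSUM 65" is read as BLOSUM62 — no standard BLOSUM65 exists.
4. **Population frequency**, lower MAF first.

Ties break by protein position; variants lacking conservation data are
flagged and ranked last, never dropped. Structural modelling (the fifth
criterion used in the source study) is out of scope; records carry an
optional free-text field for externally supplied assessments.

```{r}
tab5 <- read.table(system.file("extdata", "table5_variants.tsv",
                               package = "locusvar"),
                   header = TRUE, sep = "\t")
sites <- read_functional_sites(system.file("extdata",
                                           "functional_sites.tsv",
                                           package = "locusvar"))
prioritize_variants(tab5[, c("snp_id", "ref_aa", "alt_aa",
                             "protein_position", "maf",
                             "conservation_pct")],
                    functional_sites = sites)[
  , c("rank", "snp_id", "functional_annotation", "conservation_pct",
      "maf", "radical")]
```

# The synthetic-data generator

The generator is first-class, tested code, not a fixture. Its defaults
*are* the study conditions: a 22,283 bp locus (10,000 regulatory + 8,418
intronic + 87 + 2,740 UTR + 1,038 coding), six introns, per-region SNP
densities of 22.70/26.02/22.99/27.74/35.65 per 1000 bp, and a rare
fraction of 0.886.

Modelling choices, chosen once:

* **Placement** is a per-region homogeneous Poisson process (the study
  reports only densities; homogeneity is the minimal assumption), with
  distinct positions sampled without replacement within each region — a
  configuration whose expected count exceeds the region size raises a
  generation error rather than looping.
* **MAF spectrum.** The study gives only the rare/common split, not a
  spectrum. Rare MAFs are drawn as `0.01 * Beta(0.5, 3)` — a heavy mass
  near zero, qualitatively matching the site-frequency spectra of large
  human cohorts — and common MAFs uniformly on [0.01, 0.5].
* **CDS generation** draws sense codons uniformly between a fixed ATG and
  a uniformly chosen stop, so ORFs are always valid and internal stops
  impossible by construction.
* **Alignments** are gap-free by default with an independent per-column
  per-sequence reference-match probability; a gap-injection option
  exercises the gap-handling rules. Engineered kingdom-difference columns
  give each group its own fully conserved residue (the first group keeps
  the reference residue).

What the generator does **not** emulate — and hence what green tests do
not certify about real data: linkage disequilibrium, coalescent-realistic
frequency spectra, mutation-rate heterogeneity (CpG effects), indels and
structural variants, phylogenetically correlated substitutions in the
alignment, and alignment error. The round-trip guarantees are about the
pipeline's bookkeeping (classification, counting, normalisation), not
about evolutionary realism.

# Problem sizes used by the checks

The suite validates region labelling and intron phases against brute-force
oracles on hundreds of randomized models, site counting against exhaustive
enumeration on all 64 codons and 100 random CDSs of up to 500 codons,
truth recovery on 50 seeded loci with density calibration over 100 seeds,
and Monte-Carlo calibration on 500 null datasets of 2,000 replicates each.
These sizes give stable verdicts at interactive runtimes; all of them
scale up by changing one constant.

# Known limitations

* One transcript per run: isoform resolution (e.g. BAG-1's L/M/S forms
  from alternative starts) is out of scope; a position-offset
  configuration maps between isoform numbering frames.
* pN/pS on a handful of SNPs is noisy; the Monte-Carlo test quantifies
  exactly one null (uniform placement) and cannot rescue the ratio's
  small-sample instability.
* Conservation percentages depend on the ortholog set supplied; the
  package profiles whatever alignment it is given and does not curate
  orthology.
* No deleteriousness prediction is computed; SIFT/PolyPhen-style columns
  are accepted as optional input annotations only.
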