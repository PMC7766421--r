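#!/usr/bin/env Rscript

# Stage 6: prioritization of non-synonymous variants.
#
# Two runs: (a) the five published BAG-1 variants with their printed
# function, conservation and MAF annotations, ranked by the lexicographic
# criteria (functional-site tier, conservation, radicalness, MAF); (b) the
# simulated locus's nsSNPs, with conservation drawn from the ortholog
# alignment profile.

suppressPackageStartupMessages(library(locusvar))

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

# (a) published variants
tab5 <- read.table(system.file("extdata", "table5_variants.tsv",
                               package = "locusvar"),
                   header = TRUE, sep = "\t")
sites <- read_functional_sites(system.file("extdata",
                                           "functional_sites.tsv",
                                           package = "locusvar"))
pub <- prioritize_variants(
  tab5[, c("snp_id", "ref_aa", "alt_aa", "protein_position", "maf",
           "conservation_pct")],
  functional_sites = sites)
locusvar:::write_report_tsv(pub, "results/tables/priority_published.tsv")
cat("published variants, ranked:\n")
print(pub[, c("rank", "snp_id", "ref_aa", "alt_aa", "protein_position",
              "functional_annotation", "conservation_pct", "maf",
              "radical")], row.names = FALSE)

# (b) simulated locus
model <- read_gene_model("results/data/gene.gff3", 5000, 5000)
cds <- read_cds("results/data/cds.fa")
snps <- read_snps("results/data/snps.vcf")
aln <- read_protein_alignment("results/data/orthologs.fa")
profile <- column_conservation(aln, "ref")
cls <- classify_snps(snps, model, cds)
ns <- cls[!is.na(cls$effect) & cls$effect == "non_synonymous",
          c("snp_id", "ref_aa", "alt_aa", "protein_position", "maf")]
sim <- prioritize_variants(ns, conservation = profile)
locusvar:::write_report_tsv(sim, "results/tables/priority_simulated.tsv",
                            round_cols = "conservation_pct")
cat(sprintf("\nsimulated locus: %d nsSNPs ranked; %d radical; top position aa %d (%.1f%% conserved)\n",
            nrow(sim), sum(sim$radical), sim$protein_position[1],
            sim$conservation_pct[1]))
cat("written: results/tables/priority_{published,simulated}.tsv\n")
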