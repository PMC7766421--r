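#!/usr/bin/env Rscript

# Stage 5: intron architecture and ortholog conservation.
#
# Reports the simulated gene's intron positions/phases, demonstrates
# cross-species intron conservation on an animal-like (6 introns) vs
# plant-like (3 introns) pair sharing exactly one intron, and profiles the
# ortholog alignment: per-column conservation relative to the reference and
# kingdom-specific conserved differences at the 0.9 consensus threshold.

suppressPackageStartupMessages(library(locusvar))

model <- read_gene_model("results/data/gene.gff3", 5000, 5000)
introns <- intron_map(model)
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
locusvar:::write_report_tsv(introns, "results/tables/introns.tsv")
cat("intron map of the simulated gene:\n")
print(introns, row.names = FALSE)

# constructed two-kingdom fixture: one junction (after 30 coding nt,
# phase 0) coincides in aligned position and phase
cds30 <- paste(rep(c("ATG", "GCT", "AAA"), 10), collapse = "")
junc <- function(id, cuts) {
  seg <- diff(c(0, cuts, nchar(cds30)))
  starts <- 501 + cumsum(c(0, head(seg, -1) + 100))
  gene_model(id, "chrT", "+",
             data.frame(start = starts, end = starts + seg - 1),
             cds_start = starts[1], cds_end = starts[length(seg)] + seg[length(seg)] - 1,
             flank_up_bp = 50, flank_down_bp = 50)
}
animal <- junc("animal", c(9, 21, 30, 48, 60, 75))
plant <- junc("plant", c(12, 30, 57))
prot30 <- paste(locusvar:::translate_codons(locusvar:::cds_codons(cds30)),
                collapse = "")
shared <- conserved_introns(list(animal = intron_map(animal),
                                 plant = intron_map(plant)),
                            c(animal = prot30, plant = prot30))
cat(sprintf("\nanimal-like gene: %d introns; plant-like gene: %d introns; shared: %d\n",
            nrow(intron_map(animal)), nrow(intron_map(plant)),
            nrow(shared$shared)))
print(shared$shared, row.names = FALSE)
locusvar:::write_report_tsv(shared$introns,
                            "results/tables/intron_conservation.tsv")

# alignment conservation
aln <- read_protein_alignment("results/data/orthologs.fa")
gdf <- read.table("results/data/groups.tsv", header = TRUE, sep = "\t")
groups <- setNames(gdf$group, gdf$name)
profile <- column_conservation(aln, "ref")
kd <- kingdom_specific_positions(aln, groups, consensus_threshold = 0.9)
locusvar:::write_report_tsv(profile, "results/tables/conservation.tsv",
                            round_cols = "conservation_pct")
locusvar:::write_report_tsv(kd, "results/tables/kingdom_differences.tsv")
cat(sprintf("\nmean column conservation: %.1f%% (configured 90%%)\n",
            mean(profile$conservation_pct)))
cat("kingdom-specific conserved differences at columns:",
    paste(which(kd$flagged), collapse = ", "), "\n")
cat("written: results/tables/{introns,intron_conservation,conservation,kingdom_differences}.tsv\n")
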