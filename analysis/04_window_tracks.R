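#!/usr/bin/env Rscript

# Stage 4: sliding-window SNP tracks.
#
# Produces the genomic track (all SNPs over the locus, 10,000 bp window,
# 1,000 bp step) and the protein-space track (coding SNPs by amino-acid
# position, split synonymous/non-synonymous, 100 aa window, 10 aa step).
# Tables are plotting-tool agnostic; PNG figures are rendered when ggplot2
# is available.

suppressPackageStartupMessages(library(locusvar))

model <- read_gene_model("results/data/gene.gff3", 5000, 5000)
cds <- read_cds("results/data/cds.fa")
snps <- read_snps("results/data/snps.vcf")
cls <- classify_snps(snps, model, cds)
coding <- cls[!is.na(cls$effect), ]

genomic <- window_counts(snps$pos, model$locus_start, model$locus_end + 1L,
                         window_size = 10000, step_size = 1000)
n_aa <- nchar(cds) %/% 3L
protein <- window_counts(coding$protein_position, 1L, n_aa + 1L,
                         window_size = 100, step_size = 10,
                         categories = coding$effect)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
locusvar:::write_report_tsv(genomic, "results/tables/windows_genomic.tsv")
locusvar:::write_report_tsv(protein, "results/tables/windows_protein.tsv")

cat(sprintf("genomic track: %d windows, counts %d-%d\n",
            nrow(genomic), min(genomic$count), max(genomic$count)))
cat(sprintf("protein track: %d windows; nsSNP peak window starts at aa %d\n",
            nrow(protein),
            protein$window_start[which.max(protein$count_non_synonymous)]))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
  ggsave("results/figures/windows_genomic.png",
         ggplot(genomic, aes(window_start, count)) +
           geom_line() +
           labs(x = "window start (bp)", y = "SNPs per 10 kb window",
                title = "SNP density across the locus"),
         width = 7, height = 3, dpi = 150)
  long <- rbind(
    data.frame(window_start = protein$window_start,
               count = protein$count_synonymous, type = "synonymous"),
    data.frame(window_start = protein$window_start,
               count = protein$count_non_synonymous,
               type = "non-synonymous"))
  ggsave("results/figures/windows_protein.png",
         ggplot(long, aes(window_start, count, colour = type)) +
           geom_line() +
           labs(x = "window start (aa)", y = "SNPs per 100 aa window",
                title = "Coding SNP distribution along the protein"),
         width = 7, height = 3, dpi = 150)
  cat("figures: results/figures/windows_{genomic,protein}.png\n")
}
cat("written: results/tables/windows_{genomic,protein}.tsv\n")
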