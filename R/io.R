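#' Read SNPs from VCF or 6-column TSV
#'
#' VCF v4.x records are decomposed into one SNP per alternate allele; the
#' minor allele frequency is parsed from the configured INFO key (per-allele
#' when comma-separated). Records lacking the MAF key are collected and
#' reported together with their record numbers. Alleles that are not single
#' A/C/G/T bases (indels, MNPs) are dropped with a warning — they are out of
#' scope, not errors.
#'
#' The TSV alternative has columns `snp_id`, `chrom`, `pos`, `ref`, `alt`,
#' `maf` (header required).
#'
#' @param path input file.
#' @param maf_key INFO key holding the minor allele frequency (default
#'   `"MAF"`; e.g. `"AF"` for raw 1000 Genomes exports).
#' @param format `"auto"` (sniff the `##fileformat` header), `"vcf"` or
#'   `"tsv"`.
#' @return validated SNP `data.frame` (see [snp_table()]).
#' @export
read_snps <- function(path, maf_key = "MAF",
                      format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "##fileformat=VCF")) "vcf" else "tsv"
  }
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    return(snp_table(df$snp_id, df$chrom, df$pos, df$ref, df$alt, df$maf,
                     if (!is.null(df$population)) df$population else NA))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)        # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  maf_raw <- vcfR::extract.info(vcf, element = maf_key)
  missing <- which(is.na(maf_raw) | maf_raw == "")
  if (length(missing))
    stop("missing INFO key '", maf_key, "' in VCF record(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  mafs <- strsplit(maf_raw, ",", fixed = TRUE)
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    a <- alts[[i]]
    m <- mafs[[i]]
    if (length(m) == 1L && length(a) > 1L) m <- rep(m, length(a))
    if (length(m) != length(a))
      stop("MAF/ALT arity mismatch in VCF record ", i, call. = FALSE)
    data.frame(snp_id = if (is.na(fix$ID[i]) || fix$ID[i] == ".")
                 sprintf("%s:%s", fix$CHROM[i], fix$POS[i]) else fix$ID[i],
               chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
               ref = fix$REF[i], alt = a, maf = as.numeric(m))
  })
  df <- do.call(rbind, rows)
  snp <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    df$ref %in% BASES & df$alt %in% BASES
  if (any(!snp))
    warning(sum(!snp), " non-SNP allele(s) dropped")
  df <- df[snp, , drop = FALSE]
  df$population <- NA_character_
  validate_snp_table(df)
}

#' Write SNPs as a minimal VCF
#'
#' One biallelic record per SNP row, MAF carried in the INFO field.
#' `read_snps(write_snps(x))` is the identity on the core columns.
#'
#' @param snps SNP `data.frame`.
#' @param path output file.
#' @param maf_key INFO key to write (default `"MAF"`).
#' @return `path`, invisibly.
#' @export
write_snps <- function(snps, path, maf_key = "MAF") {
  snps <- validate_snp_table(snps)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"Global minor allele frequency\">",
                   maf_key),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s=%s",
                  snps$chrom, snps$pos, snps$snp_id, snps$ref, snps$alt,
                  maf_key, format(snps$maf, scientific = FALSE, trim = TRUE,
                                  digits = 10))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a gene model from GFF3 or BED12
#'
#' GFF3 input must contain `exon` and `CDS` features for one transcript;
#' BED12 input uses the block structure for exons and the thick range for
#' the CDS. Regulatory flank lengths come from the caller (they are not
#' encoded in either format).
#'
#' @param path annotation file.
#' @param flank_up_bp,flank_down_bp regulatory flank lengths (bp).
#' @param gene_id identifier for the model; default: basename of `path`.
#' @return a [gene_model()].
#' @export
read_gene_model <- function(path, flank_up_bp, flank_down_bp,
                            gene_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "bed") {
    stopifnot(length(gr) == 1L)
    blocks <- rtracklayer::blocks(gr)[[1]]
    exons <- data.frame(start = BiocGenerics::start(blocks),
                        end = BiocGenerics::end(blocks))
    cds_start <- gr$thick@start
    cds_end <- cds_start + gr$thick@width - 1L
    strand <- as.character(BiocGenerics::strand(gr))
    chrom <- as.character(GenomicRanges::seqnames(gr))
    if (is.null(gene_id)) gene_id <- if (!is.null(gr$name)) gr$name else
      basename(path)
  } else {
    type <- as.character(gr$type)
    ex <- gr[type == "exon"]
    cds <- gr[type == "CDS"]
    if (!length(ex) || !length(cds))
      stop("GFF3 must contain exon and CDS features", call. = FALSE)
    exons <- data.frame(start = BiocGenerics::start(ex),
                        end = BiocGenerics::end(ex))
    cds_start <- min(BiocGenerics::start(cds))
    cds_end <- max(BiocGenerics::end(cds))
    strand <- as.character(BiocGenerics::strand(ex))[1]
    chrom <- as.character(GenomicRanges::seqnames(ex))[1]
    if (is.null(gene_id)) {
      gene <- gr[type == "gene"]
      gene_id <- if (length(gene) && !is.null(gene$ID)) gene$ID[1] else
        basename(path)
    }
  }
  gene_model(gene_id, chrom, strand, exons, cds_start, cds_end,
             flank_up_bp, flank_down_bp)
}

#' Write a gene model as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (the CDS split by exon).
#'
#' @param model a [gene_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path) {
  ex <- model$exons
  cds <- data.frame(start = pmax(ex$start, model$cds_start),
                    end = pmin(ex$end, model$cds_end))
  cds <- cds[cds$start <= cds$end, , drop = FALSE]
  # GFF phase of each CDS chunk, in transcript order
  w <- cds$end - cds$start + 1L
  ord <- if (model$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
  cum_before <- c(0L, cumsum(w[ord]))[seq_len(nrow(cds))]
  phase <- integer(nrow(cds))
  phase[ord] <- (3L - cum_before %% 3L) %% 3L
  mk <- function(start, end, type, id, parent = NA, ph = NA_integer_) {
    GenomicRanges::GRanges(model$chrom,
                           IRanges::IRanges(start, end),
                           strand = model$strand, type = type,
                           ID = id, Parent = parent, phase = ph)
  }
  gr <- c(mk(model$genic_start, model$genic_end, "gene", model$gene_id),
          mk(model$genic_start, model$genic_end, "mRNA",
             paste0(model$gene_id, ".t1"), model$gene_id),
          mk(ex$start, ex$end, "exon",
             sprintf("%s.exon%d", model$gene_id, seq_len(nrow(ex))),
             paste0(model$gene_id, ".t1")),
          mk(cds$start, cds$end, "CDS",
             sprintf("%s.cds%d", model$gene_id, seq_len(nrow(cds))),
             paste0(model$gene_id, ".t1"), phase))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a coding sequence from FASTA
#' @param path FASTA file; the first record is used.
#' @return character CDS string.
#' @export
read_cds <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  as.character(x[[1]])
}

#' Read a protein multiple alignment from FASTA
#' @param path FASTA file of equal-length gapped sequences.
#' @return named character vector.
#' @export
read_protein_alignment <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read domain definitions (TSV: name, start_codon, end_codon)
#' @param path TSV file.
#' @return named list of codon ranges `c(first, last)`.
#' @export
read_domains <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(lapply(seq_len(nrow(df)), function(i)
    c(df$start_codon[i], df$end_codon[i])), df$name)
}

#' Read functional sites (TSV: protein_position, annotation)
#' @param path TSV file.
#' @return `data.frame` with `protein_position`, `annotation`.
#' @export
read_functional_sites <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

# TSV writer used for all report tables: densities/ratios rounded to 2
# decimals, full precision retained in memory
write_report_tsv <- function(df, path, round_cols = NULL) {
  for (cl in intersect(round_cols, names(df)))
    df[[cl]] <- round(df[[cl]], 2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to the standard formats
#'
#' Emits everything the pipeline reads: VCF (SNPs), GFF3 (gene model), FASTA
#' (CDS and, when given, the ortholog alignment), a groups TSV, a
#' truth-label TSV and a YAML echo of the configuration.
#'
#' @param locus a [generate_locus()] result.
#' @param dir output directory (created if needed).
#' @param alignment optional [generate_alignment()] result.
#' @return named character vector of file paths, invisibly.
#' @export
write_synthetic_dataset <- function(locus, dir, alignment = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(vcf = file.path(dir, "snps.vcf"),
         gff3 = file.path(dir, "gene.gff3"),
         cds = file.path(dir, "cds.fa"),
         truth = file.path(dir, "truth.tsv"),
         config = file.path(dir, "config.yaml"))
  write_snps(locus$snps, p[["vcf"]])
  write_gene_model(locus$model, p[["gff3"]])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(locus$cds, locus$model$gene_id)),
    p[["cds"]])
  utils::write.table(
    locus$snps[, c("snp_id", "pos", "truth_region", "truth_effect",
                   "truth_class")],
    p[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- locus$config
  cfg$domains <- lapply(cfg$domains, as.integer)
  yaml::write_yaml(unclass(cfg), p[["config"]])
  if (!is.null(alignment)) {
    p[["alignment"]] <- file.path(dir, "orthologs.fa")
    p[["groups"]] <- file.path(dir, "groups.tsv")
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(alignment$alignment), p[["alignment"]])
    utils::write.table(
      data.frame(name = names(alignment$groups),
                 group = unname(alignment$groups)),
      p[["groups"]], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(p)
}
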