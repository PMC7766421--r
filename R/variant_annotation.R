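#' Construct and validate a SNP table
#'
#' A SNP set is a plain `data.frame` with one biallelic substitution per row:
#' columns `snp_id`, `chrom`, `pos` (1-based genomic), `ref`, `alt` (single
#' bases), `maf` (global minor allele frequency in \[0, 0.5\]) and an optional
#' `population` tag. Multi-allelic records must already be decomposed into
#' one row per alternate allele (see [read_snps()]).
#'
#' @param snp_id,chrom,pos,ref,alt,maf,population vectors of equal length.
#' @return validated `data.frame`.
#' @export
snp_table <- function(snp_id, chrom, pos, ref, alt, maf, population = NA) {
  df <- data.frame(snp_id = as.character(snp_id), chrom = as.character(chrom),
                   pos = as.integer(pos), ref = toupper(ref),
                   alt = toupper(alt), maf = as.numeric(maf),
                   population = population)
  validate_snp_table(df)
}

validate_snp_table <- function(df) {
  need <- c("snp_id", "chrom", "pos", "ref", "alt", "maf")
  if (!all(need %in% names(df)))
    stop("SNP table missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (!all(df$ref %in% BASES) || !all(df$alt %in% BASES))
    stop("SNP alleles must be single A/C/G/T bases", call. = FALSE)
  if (any(df$ref == df$alt))
    stop("ref and alt alleles must differ", call. = FALSE)
  if (any(is.na(df$maf) | df$maf < 0 | df$maf > 0.5))
    stop("MAF must lie in [0, 0.5]", call. = FALSE)
  df
}

#' Rare/common frequency class
#'
#' Rare means a global minor allele frequency below 1%; a MAF of exactly
#' 0.01 is common.
#'
#' @param maf numeric vector of minor allele frequencies in \[0, 0.5\].
#' @return character vector, `"rare"` or `"common"`.
#' @examples
#' frequency_class(c(0.0004, 0.0124, 0.01))
#' @export
frequency_class <- function(maf) {
  if (any(is.na(maf) | maf < 0 | maf > 0.5))
    stop("MAF must lie in [0, 0.5]", call. = FALSE)
  ifelse(maf < 0.01, "rare", "common")
}

#' Classify SNPs by region and coding effect
#'
#' Assigns each SNP its region label (via [region_of()]) and, for coding
#' SNPs, the codon-level consequence: the alternative allele (complemented
#' for minus-strand genes) is substituted into the codon and translated with
#' the standard genetic code. A SNP whose reference allele disagrees with
#' the CDS base at its position fails loudly — silent skips would corrupt
#' densities.
#'
#' @param snps SNP `data.frame` (see [snp_table()]).
#' @param model a [gene_model()].
#' @param cds spliced coding sequence in transcript orientation, stop codon
#'   included (character or `DNAString`).
#' @return the SNP table with added columns `region`, `frequency_class`, and
#'   for coding SNPs `cds_pos`, `codon_index`, `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa`, `effect` (`synonymous`/`non_synonymous`),
#'   `protein_position`.
#' @export
classify_snps <- function(snps, model, cds) {
  snps <- validate_snp_table(snps)
  cod <- cds_codons(cds)
  if (3L * length(cod) != model$cds_len)
    stop("CDS length does not match the gene model", call. = FALSE)
  out <- snps
  out$region <- region_of(model, snps$pos)
  out$frequency_class <- frequency_class(snps$maf)
  n <- nrow(out)
  out$cds_pos <- rep(NA_integer_, n); out$codon_index <- rep(NA_integer_, n)
  out$ref_codon <- rep(NA_character_, n); out$alt_codon <- rep(NA_character_, n)
  out$ref_aa <- rep(NA_character_, n); out$alt_aa <- rep(NA_character_, n)
  out$effect <- rep(NA_character_, n)
  out$protein_position <- rep(NA_integer_, n)

  idx <- which(out$region == "coding")
  if (!length(idx)) return(out)
  t <- tx_position(model, snps$pos[idx])
  cds_pos <- t - model$cds_tx_start + 1L
  ref_tx <- snps$ref[idx]; alt_tx <- snps$alt[idx]
  if (model$strand == "-") {
    ref_tx <- unname(COMPLEMENT[ref_tx])
    alt_tx <- unname(COMPLEMENT[alt_tx])
  }
  codon_index <- (cds_pos - 1L) %/% 3L + 1L
  within <- (cds_pos - 1L) %% 3L + 1L
  ref_codon <- cod[codon_index]
  seq_base <- substr(ref_codon, within, within)
  bad <- seq_base != ref_tx
  if (any(bad))
    stop("ref allele mismatch vs CDS at genomic position(s): ",
         paste(snps$pos[idx][bad], collapse = ", "), call. = FALSE)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_tx
  ref_aa <- translate_codons(ref_codon)
  alt_aa <- translate_codons(alt_codon)
  out$cds_pos[idx] <- cds_pos
  out$codon_index[idx] <- codon_index
  out$ref_codon[idx] <- ref_codon
  out$alt_codon[idx] <- alt_codon
  out$ref_aa[idx] <- ref_aa
  out$alt_aa[idx] <- alt_aa
  out$effect[idx] <- ifelse(ref_aa == alt_aa, "synonymous", "non_synonymous")
  out$protein_position[idx] <- codon_index
  out
}

#' Region-partitioned SNP summary
#'
#' One row per region class plus total/genic rollups and synonymous /
#' non-synonymous coding rows, each with SNP count, length (fractional site
#' totals for the syn/non-syn rows, terminal stop codon excluded), density
#' per 1000 bp and the rare/common split. The count hierarchy is checked on
#' every call: total = regulatory + genic; genic = intronic + 5'UTR + 3'UTR
#' + coding; coding = synonymous + non-synonymous.
#'
#' @param snps SNP `data.frame`.
#' @param model a [gene_model()].
#' @param cds spliced coding sequence (stop codon included).
#' @return `data.frame` with columns `region`, `length_bp`, `n_snps`,
#'   `density`, `n_rare`, `n_common`. Attribute `"classified"` carries the
#'   per-SNP classification.
#' @export
summarize_regions <- function(snps, model, cds) {
  cls <- classify_snps(snps, model, cds)
  rl <- region_lengths(model)
  sites <- count_sites(cds, region_name = "full_cds")

  tally <- function(sel) {
    c(n = sum(sel), rare = sum(cls$frequency_class[sel] == "rare"),
      common = sum(cls$frequency_class[sel] == "common"))
  }
  rows <- list(
    total        = list(len = rl[["locus"]], sel = rep(TRUE, nrow(cls))),
    regulatory   = list(len = rl[["regulatory"]], sel = cls$region == "regulatory"),
    genic        = list(len = rl[["genic"]], sel = cls$region != "regulatory"),
    intronic     = list(len = rl[["intronic"]], sel = cls$region == "intronic"),
    five_prime_UTR  = list(len = rl[["five_prime_UTR"]], sel = cls$region == "five_prime_UTR"),
    three_prime_UTR = list(len = rl[["three_prime_UTR"]], sel = cls$region == "three_prime_UTR"),
    coding       = list(len = rl[["coding"]], sel = cls$region == "coding"),
    synonymous   = list(len = sites$syn_sites,
                        sel = !is.na(cls$effect) & cls$effect == "synonymous"),
    non_synonymous = list(len = sites$nonsyn_sites,
                          sel = !is.na(cls$effect) & cls$effect == "non_synonymous"))
  out <- do.call(rbind, lapply(names(rows), function(r) {
    t <- tally(rows[[r]]$sel)
    len <- unname(rows[[r]]$len)
    data.frame(region = r, length_bp = len, n_snps = unname(t["n"]),
               density = if (len > 0) snp_density(t[["n"]], len) else 0,
               n_rare = unname(t["rare"]), n_common = unname(t["common"]))
  }))
  # count-conservation invariants across the region hierarchy
  g <- function(r, col = "n_snps") out[out$region == r, col]
  stopifnot(g("total") == g("regulatory") + g("genic"),
            g("genic") == g("intronic") + g("five_prime_UTR") +
              g("three_prime_UTR") + g("coding"),
            g("coding") == g("synonymous") + g("non_synonymous"),
            all(out$n_rare + out$n_common == out$n_snps))
  attr(out, "classified") <- cls
  out
}
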