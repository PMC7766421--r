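#' Configuration for the synthetic locus generator
#'
#' Defaults emulate the study locus: a 22,283 bp span made of 10,000 bp of
#' regulatory flank (split 5,000 + 5,000; the split is a package choice),
#' a genic region of 12,283 bp with six introns totalling 8,418 bp, an
#' 87 bp 5'UTR, a 2,740 bp 3'UTR, and a 1,038 bp CDS (346 codons including
#' the stop). Default per-region SNP densities and the 0.886 rare fraction
#' match the observed 1000 Genomes extract; the minor-allele-frequency
#' spectrum is a mixture of a Beta-shaped low-frequency component below 0.01
#' and a uniform common component on \[0.01, 0.5\].
#'
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @param gene_id,chrom,strand identity of the synthetic locus.
#' @param flank_up_bp,flank_down_bp regulatory flank lengths (bp).
#' @param utr5_len,utr3_len untranslated region lengths (bp).
#' @param n_codons CDS length in codons, stop codon included.
#' @param intron_lengths numeric vector of intron lengths; its length sets
#'   the intron count.
#' @param densities named per-region SNP densities (SNPs per 1000 bp) for
#'   `regulatory`, `intronic`, `five_prime_UTR`, `three_prime_UTR`,
#'   `coding`.
#' @param rare_fraction target fraction of SNPs with MAF < 0.01.
#' @param domains named list of codon ranges `c(first, last)` embedded as
#'   "domains" (defaults shaped like a 77-codon N-terminal and an 81-codon
#'   C-terminal domain).
#' @param alignment list: `groups` (named sizes), `conservation` (per-column
#'   reference-match probability), `engineered_positions` (columns given
#'   group-specific conserved residues), `gap_rate`.
#' @param locus_start genomic coordinate of the first locus base.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             gene_id = "synthGene", chrom = "chrS",
                             strand = "+",
                             flank_up_bp = 5000, flank_down_bp = 5000,
                             utr5_len = 87, utr3_len = 2740,
                             n_codons = 346,
                             intron_lengths = c(1903, 1627, 1409, 1217, 1153, 1109),
                             densities = c(regulatory = 22.70,
                                           intronic = 26.02,
                                           five_prime_UTR = 22.99,
                                           three_prime_UTR = 27.74,
                                           coding = 35.65),
                             rare_fraction = 0.886,
                             domains = list(UBQ_like = c(10, 86),
                                            BAG = c(220, 300)),
                             alignment = list(groups = c(animal = 129,
                                                         plant = 32,
                                                         fungi = 5),
                                              conservation = 0.9,
                                              engineered_positions = integer(0),
                                              gap_rate = 0),
                             locus_start = 1000001) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (any(c(flank_up_bp, flank_down_bp) < 0) ||
      any(c(utr5_len, utr3_len) < 0) || n_codons < 2 ||
      (length(intron_lengths) && any(intron_lengths < 1)))
    stop("invalid synthetic config: lengths must be positive", call. = FALSE)
  if (any(densities < 0)) stop("densities must be >= 0", call. = FALSE)
  if (rare_fraction < 0 || rare_fraction > 1)
    stop("rare_fraction must lie in [0, 1]", call. = FALSE)
  if (!is.null(alignment$conservation) &&
      (alignment$conservation < 0 || alignment$conservation > 1))
    stop("conservation level must lie in [0, 1]", call. = FALSE)
  structure(as.list(environment()), class = "synthetic_config")
}

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                    c("A","C","G","T")), 1, paste0, collapse = ""),
  c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

# transcript position -> genomic coordinate for an exon table in genomic
# ascending order
t2g <- function(exons, strand, t) {
  widths <- exons$end - exons$start + 1L
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  cum_end <- cumsum(widths[ord])
  k <- findInterval(t - 1L, cum_end) + 1L
  off <- t - c(0L, cum_end)[k]
  if (strand == "+") exons$start[ord[k]] + off - 1L
  else exons$end[ord[k]] - off + 1L
}

#' Generate a seeded synthetic locus with recorded ground truth
#'
#' Builds a valid gene model and CDS (ATG start, no internal stops, terminal
#' stop), then places SNPs per region by a Poisson draw at the configured
#' density with uniform distinct positions and uniform alternative alleles,
#' and draws MAFs from the configured rare/common mixture. Every SNP carries
#' ground-truth labels (`truth_region`, `truth_effect`, `truth_class`)
#' recorded at generation time, so pipeline classifications can be checked
#' against them exactly. Byte-identical output for identical configurations.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_locus`: `model`, `cds`, `snps`,
#'   `config`.
#' @export
generate_locus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    n_cod <- config$n_codons
    cds_len <- 3L * n_cod
    codons <- c("ATG",
                sample(SENSE_CODONS, n_cod - 2L, replace = TRUE),
                sample(STOP_CODONS, 1L))
    cds <- paste0(codons, collapse = "")

    utr5 <- config$utr5_len; utr3 <- config$utr3_len
    tx_len <- utr5 + cds_len + utr3
    n_int <- length(config$intron_lengths)
    if (n_int > 0) {
      junctions <- sort(sample(seq(utr5 + 1L, utr5 + cds_len - 1L), n_int))
    } else junctions <- integer(0)
    seg_w <- diff(c(0L, junctions, tx_len))

    genic_len <- tx_len + sum(config$intron_lengths)
    if (config$strand == "+") {
      genic_start <- config$locus_start + config$flank_up_bp
      starts <- integer(n_int + 1L); ends <- integer(n_int + 1L)
      cursor <- genic_start
      for (i in seq_along(seg_w)) {
        starts[i] <- cursor; ends[i] <- cursor + seg_w[i] - 1L
        cursor <- ends[i] + 1L +
          if (i <= n_int) config$intron_lengths[i] else 0L
      }
      exons <- data.frame(start = starts, end = ends)
    } else {
      genic_end <- config$locus_start + config$flank_down_bp + genic_len - 1L
      starts <- integer(n_int + 1L); ends <- integer(n_int + 1L)
      cursor <- genic_end
      for (i in seq_along(seg_w)) {
        ends[i] <- cursor; starts[i] <- cursor - seg_w[i] + 1L
        cursor <- starts[i] - 1L -
          if (i <= n_int) config$intron_lengths[i] else 0L
      }
      exons <- data.frame(start = rev(starts), end = rev(ends))
    }
    cds_g <- range(t2g(exons, config$strand, c(utr5 + 1L, utr5 + cds_len)))
    model <- gene_model(config$gene_id, config$chrom, config$strand, exons,
                        cds_start = cds_g[1], cds_end = cds_g[2],
                        flank_up_bp = config$flank_up_bp,
                        flank_down_bp = config$flank_down_bp)
    rl <- region_lengths(model)
    stopifnot(rl[["intronic"]] == sum(config$intron_lengths),
              rl[["five_prime_UTR"]] == utr5,
              rl[["three_prime_UTR"]] == utr3,
              rl[["coding"]] == cds_len)

    # region position pools
    all_pos <- seq(model$locus_start, model$locus_end)
    labels <- region_of(model, all_pos)
    snp_rows <- list()
    for (r in names(config$densities)) {
      pool <- all_pos[labels == r]
      if (!length(pool)) next
      n <- stats::rpois(1, config$densities[[r]] * length(pool) / 1000)
      if (n > length(pool))
        stop("infeasible config: density too high for region ", r,
             call. = FALSE)
      if (n == 0) next
      pos <- sort(sample(pool, n))
      snp_rows[[r]] <- data.frame(pos = pos, truth_region = r)
    }
    snps <- do.call(rbind, snp_rows)
    snps <- snps[order(snps$pos), , drop = FALSE]

    # reference alleles: coding positions from the CDS (genome strand),
    # non-coding positions uniform
    ref <- character(nrow(snps))
    coding <- snps$truth_region == "coding"
    if (any(coding)) {
      t <- tx_position(model, snps$pos[coding])
      cds_pos <- t - model$cds_tx_start + 1L
      base_tx <- substring(cds, cds_pos, cds_pos)
      ref[coding] <- if (config$strand == "-") unname(COMPLEMENT[base_tx])
                     else base_tx
    }
    ref[!coding] <- sample(BASES, sum(!coding), replace = TRUE)
    alt_choice <- sample.int(3L, nrow(snps), replace = TRUE)
    alt <- vapply(seq_len(nrow(snps)),
                  function(i) setdiff(BASES, ref[i])[alt_choice[i]],
                  character(1))

    # truth coding effect by direct codon substitution
    truth_effect <- rep(NA_character_, nrow(snps))
    if (any(coding)) {
      t <- tx_position(model, snps$pos[coding])
      cds_pos <- t - model$cds_tx_start + 1L
      ci <- (cds_pos - 1L) %/% 3L + 1L
      wi <- (cds_pos - 1L) %% 3L + 1L
      ref_cod <- codons[ci]
      alt_tx <- alt[coding]
      if (config$strand == "-") alt_tx <- unname(COMPLEMENT[alt_tx])
      alt_cod <- ref_cod
      substr(alt_cod, wi, wi) <- alt_tx
      truth_effect[coding] <-
        ifelse(translate_codons(ref_cod) == translate_codons(alt_cod),
               "synonymous", "non_synonymous")
    }

    rare <- stats::rbinom(nrow(snps), 1L, config$rare_fraction) == 1L
    maf <- numeric(nrow(snps))
    maf[rare] <- 0.01 * stats::rbeta(sum(rare), 0.5, 3)
    maf[!rare] <- stats::runif(sum(!rare), 0.01, 0.5)
    maf <- pmin(pmax(maf, 1e-6), 0.5)
    maf[rare] <- pmin(maf[rare], 0.0099999)

    snps <- data.frame(
      snp_id = sprintf("ss%05d", seq_len(nrow(snps))),
      chrom = config$chrom, pos = snps$pos, ref = ref, alt = alt, maf = maf,
      population = NA_character_,
      truth_region = snps$truth_region,
      truth_effect = truth_effect,
      truth_class = ifelse(rare, "rare", "common"))
    rownames(snps) <- NULL
    structure(list(model = model, cds = cds, snps = snps, config = config),
              class = "synthetic_locus")
  })
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat(sprintf("<synthetic_locus> %s: %d SNPs over %d bp (seed %s)\n",
              x$model$gene_id, nrow(x$snps),
              x$model$locus_end - x$model$locus_start + 1L,
              format(x$config$seed)))
  invisible(x)
}

#' Generate a grouped ortholog protein alignment with known truth
#'
#' Produces a gap-free (by default) protein multiple alignment around a
#' reference sequence. Each non-reference residue matches the reference with
#' the configured per-column conservation probability, otherwise it is
#' uniform over the other 19 residues. At engineered difference columns
#' every group is given its own fully conserved residue (the first group
#' keeps the reference residue), so those columns — and only those, at
#' conservation level 1 — are kingdom-specific conserved differences.
#' Optional uniform gap injection (never in the reference row or engineered
#' columns) exercises the gap-handling rules.
#'
#' @param config a [synthetic_config()] (fields `alignment` and `seed` are
#'   used).
#' @param reference reference protein sequence (character); default: the
#'   translation of the configured CDS, regenerated from the same seed.
#' @return list of class `synthetic_alignment`: `alignment` (named
#'   character), `groups` (named vector sequence -> group), `reference_id`,
#'   `engineered_positions`.
#' @export
generate_alignment <- function(config, reference = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  spec <- config$alignment
  if (length(spec$groups) < 1L || any(spec$groups < 2L))
    stop("need >= 1 group with >= 2 sequences each", call. = FALSE)
  if (is.null(reference)) {
    locus <- generate_locus(config)
    prot <- translate_codons(cds_codons(locus$cds))
    reference <- paste0(prot[prot != "*"], collapse = "")
  }
  ref_chars <- strsplit(toupper(reference), "")[[1]]
  L <- length(ref_chars)
  eng <- spec$engineered_positions
  if (any(eng < 1L | eng > L))
    stop("engineered positions outside reference length", call. = FALSE)
  residues <- rownames(get_blosum("BLOSUM62"))[1:20]

  withr::with_seed(config$seed + 1L, {
    # one conserved residue per group per engineered column, all distinct
    group_names <- names(spec$groups)
    eng_res <- matrix(NA_character_, nrow = length(eng),
                      ncol = length(group_names),
                      dimnames = list(NULL, group_names))
    for (j in seq_along(eng)) {
      eng_res[j, 1] <- ref_chars[eng[j]]
      others <- sample(setdiff(residues, ref_chars[eng[j]]),
                       length(group_names) - 1L)
      if (length(group_names) > 1L) eng_res[j, -1] <- others
    }
    seqs <- list(); groups <- character(0)
    for (g in group_names) {
      for (i in seq_len(spec$groups[[g]])) {
        id <- if (g == group_names[1] && i == 1L) "ref"
              else sprintf("%s_%03d", g, i)
        if (id == "ref") {
          chars <- ref_chars
        } else {
          keep <- stats::runif(L) < spec$conservation
          chars <- ref_chars
          nsub <- sum(!keep)
          if (nsub) chars[!keep] <- vapply(which(!keep), function(p)
            sample(setdiff(residues, ref_chars[p]), 1L), character(1))
          if (!is.null(spec$gap_rate) && spec$gap_rate > 0) {
            gap <- stats::runif(L) < spec$gap_rate
            gap[eng] <- FALSE
            chars[gap] <- "-"
          }
        }
        chars[eng] <- eng_res[, g]
        seqs[[id]] <- paste0(chars, collapse = "")
        groups[id] <- g
      }
    }
    structure(list(alignment = unlist(seqs), groups = groups,
                   reference_id = "ref", engineered_positions = eng),
              class = "synthetic_alignment")
  })
}
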