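#' Build a validated single-locus gene model
#'
#' Represents one gene locus: ordered exons, a single CDS span (stop codon
#' included), and upstream/downstream regulatory flanks. All coordinates are
#' genomic, 1-based and inclusive (GFF3/VCF convention). Minus-strand genes
#' are fully supported; transcript-space quantities (UTR assignment, CDS
#' offsets, intron phases) are computed in transcript orientation.
#'
#' The locus is partitioned into five region classes (regulatory, intronic,
#' 5'UTR, 3'UTR, coding) whose lengths satisfy
#' `genic = intronic + utr5 + utr3 + coding` and
#' `locus = regulatory + genic` exactly.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome/contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column `data.frame` (or matrix) of exon `start`, `end`
#'   genomic coordinates, 1-based inclusive.
#' @param cds_start,cds_end genomic coordinates of the translated span
#'   (lowest and highest coordinate; the stop codon is included).
#' @param flank_up_bp,flank_down_bp lengths (bp) of the upstream and
#'   downstream regulatory flanks, relative to transcription direction.
#' @return an object of class `gene_model`.
#' @examples
#' gm <- gene_model("g1", "chr9", "+",
#'                  exons = data.frame(start = c(101, 401), end = c(200, 700)),
#'                  cds_start = 151, cds_end = 550,
#'                  flank_up_bp = 50, flank_down_bp = 50)
#' region_lengths(gm)
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds_start, cds_end,
                       flank_up_bp, flank_down_bp) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'", call. = FALSE)
  exons <- as.data.frame(exons)
  if (!all(c("start", "end") %in% names(exons)))
    names(exons)[1:2] <- c("start", "end")
  exons <- exons[order(exons$start), c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  rownames(exons) <- NULL
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (any(exons$end < exons$start))
    stop("invalid gene model: exon end precedes start", call. = FALSE)
  n <- nrow(exons)
  if (n > 1L && any(exons$start[-1] <= exons$end[-n]))
    stop("invalid gene model: exons overlap or touch", call. = FALSE)
  if (flank_up_bp < 0 || flank_down_bp < 0)
    stop("invalid gene model: negative regulatory flank", call. = FALSE)

  genic_start <- exons$start[1]
  genic_end   <- exons$end[n]
  if (strand == "+") {
    locus_start <- as.integer(genic_start - flank_up_bp)
    locus_end   <- as.integer(genic_end + flank_down_bp)
  } else {
    locus_start <- as.integer(genic_start - flank_down_bp)
    locus_end   <- as.integer(genic_end + flank_up_bp)
  }

  model <- structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons, cds_start = cds_start, cds_end = cds_end,
         flank_up_bp = flank_up_bp, flank_down_bp = flank_down_bp,
         locus_start = locus_start, locus_end = locus_end,
         genic_start = genic_start, genic_end = genic_end),
    class = "gene_model")

  # transcript-space geometry
  widths <- exons$end - exons$start + 1L
  ord <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  cum_end <- cumsum(widths[ord])                  # transcript end of each exon
  model$tx_exon_order <- ord
  model$tx_cum_end <- cum_end
  model$tx_len <- sum(widths)

  t_cds <- tx_position(model, c(cds_start, cds_end))
  if (anyNA(t_cds))
    stop("invalid gene model: CDS boundary outside exons", call. = FALSE)
  model$cds_tx_start <- min(t_cds)
  model$cds_tx_end   <- max(t_cds)
  model$cds_len <- model$cds_tx_end - model$cds_tx_start + 1L

  # the CDS must be fully exonic: every genomic base of every exon overlapping
  # [cds_start, cds_end] maps inside [cds_tx_start, cds_tx_end], so the exonic
  # base count between the boundaries must equal the transcript span
  exonic_cds <- sum(pmax(0L, pmin(exons$end, cds_end) -
                           pmax(exons$start, cds_start) + 1L))
  if (exonic_cds != model$cds_len)
    stop("invalid gene model: CDS not fully contained in exons", call. = FALSE)
  if (model$cds_len %% 3L != 0L)
    stop("invalid gene model: spliced CDS length not divisible by 3",
         call. = FALSE)
  model
}

#' @export
print.gene_model <- function(x, ...) {
  rl <- region_lengths(x)
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)\n", x$gene_id, x$chrom,
              x$locus_start, x$locus_end, x$strand))
  cat(sprintf("  exons: %d   spliced CDS: %d bp (%d codons)\n",
              nrow(x$exons), x$cds_len, x$cds_len %/% 3L))
  cat(sprintf("  lengths: locus %d = regulatory %d + genic %d (intronic %d, 5'UTR %d, 3'UTR %d, coding %d)\n",
              rl[["locus"]], rl[["regulatory"]], rl[["genic"]],
              rl[["intronic"]], rl[["five_prime_UTR"]], rl[["three_prime_UTR"]],
              rl[["coding"]]))
  invisible(x)
}

#' Map genomic positions to transcript coordinates
#'
#' @param model a [gene_model()].
#' @param pos vector of genomic positions.
#' @return integer vector of 1-based transcript positions (5' end of the
#'   mature transcript = 1); `NA` for non-exonic positions.
#' @export
tx_position <- function(model, pos) {
  exons <- model$exons
  idx <- findInterval(pos, exons$start)
  ok <- idx >= 1L & pos <= exons$end[pmax(idx, 1L)]
  out <- rep(NA_integer_, length(pos))
  if (!any(ok)) return(out)
  i <- idx[ok]
  # transcript start offset of each genomic exon
  tx_start_of <- integer(nrow(exons))
  tx_start_of[model$tx_exon_order] <- c(0L, model$tx_cum_end[-nrow(exons)])
  if (nrow(exons) == 1L) tx_start_of <- 0L
  if (model$strand == "+") {
    out[ok] <- tx_start_of[i] + (pos[ok] - exons$start[i]) + 1L
  } else {
    out[ok] <- tx_start_of[i] + (exons$end[i] - pos[ok]) + 1L
  }
  out
}

#' Region lengths of a gene model
#'
#' @param model a [gene_model()].
#' @return named numeric vector with elements `locus`, `regulatory`, `genic`,
#'   `intronic`, `five_prime_UTR`, `three_prime_UTR`, `coding`.
#' @export
region_lengths <- function(model) {
  locus <- model$locus_end - model$locus_start + 1L
  genic <- model$genic_end - model$genic_start + 1L
  coding <- model$cds_len
  utr5 <- model$cds_tx_start - 1L
  utr3 <- model$tx_len - model$cds_tx_end
  intronic <- genic - model$tx_len
  c(locus = locus, regulatory = locus - genic, genic = genic,
    intronic = intronic, five_prime_UTR = utr5, three_prime_UTR = utr3,
    coding = coding)
}

#' Classify genomic positions into region labels
#'
#' Every position in the locus gets exactly one of `regulatory`, `intronic`,
#' `five_prime_UTR`, `three_prime_UTR`, `coding`. The first base of the start
#' codon and the last base of the stop codon are `coding`.
#'
#' @param model a [gene_model()].
#' @param pos vector of genomic positions (must lie within the locus span).
#' @return character vector of region labels.
#' @export
region_of <- function(model, pos) {
  if (any(pos < model$locus_start | pos > model$locus_end))
    stop("position outside locus span", call. = FALSE)
  out <- rep("regulatory", length(pos))
  genic <- pos >= model$genic_start & pos <= model$genic_end
  t <- tx_position(model, pos[genic])
  lab <- ifelse(is.na(t), "intronic",
         ifelse(t < model$cds_tx_start, "five_prime_UTR",
         ifelse(t > model$cds_tx_end, "three_prime_UTR", "coding")))
  out[genic] <- lab
  out
}

#' Intron positions and phases
#'
#' One record per inter-exon gap, in transcript order. `cds_offset` is the
#' number of coding nucleotides preceding the intron junction; `phase` is
#' `cds_offset mod 3` (GFF convention: 0 = between codons). Introns lying in
#' the UTRs have `cds_offset` 0 or the full CDS length and are flagged
#' `coding_interrupting = FALSE`; they are excluded from phase-conservation
#' comparisons.
#'
#' @param model a [gene_model()].
#' @return `data.frame` with columns `gene_id`, `index`, `cds_offset`,
#'   `phase`, `genomic_start`, `genomic_end`, `coding_interrupting`.
#' @export
intron_map <- function(model) {
  n <- nrow(model$exons)
  if (n == 1L)
    return(data.frame(gene_id = character(), index = integer(),
                      cds_offset = integer(), phase = integer(),
                      genomic_start = integer(), genomic_end = integer(),
                      coding_interrupting = logical()))
  ord <- model$tx_exon_order
  ce <- model$tx_cum_end
  k <- seq_len(n - 1L)
  cds_offset <- pmin(pmax(ce[k] - (model$cds_tx_start - 1L), 0L),
                     model$cds_len)
  a <- pmin(ord[k], ord[k + 1L])
  b <- pmax(ord[k], ord[k + 1L])
  data.frame(
    gene_id = model$gene_id,
    index = k,
    cds_offset = as.integer(cds_offset),
    phase = as.integer(cds_offset %% 3L),
    genomic_start = model$exons$end[a] + 1L,
    genomic_end = model$exons$start[b] - 1L,
    coding_interrupting = cds_offset > 0L & cds_offset < model$cds_len)
}

#' Detect introns conserved in position and phase across orthologs
#'
#' Two introns from different genes are reported as shared when their
#' insertion points fall in the same column of the ortholog protein alignment
#' (the codon containing the intron junction; for phase-0 introns the codon
#' immediately following the junction) and their phases are equal. UTR
#' introns are excluded.
#'
#' @param intron_maps named list of [intron_map()] tables, one per ortholog;
#'   names must match alignment sequence names.
#' @param alignment protein multiple alignment: named character vector or
#'   `Biostrings::AAStringSet` of equal-length gapped sequences.
#' @return list with `introns` (per-intron table with the mapped protein
#'   position and alignment column) and `shared` (one row per group of >= 2
#'   introns agreeing in column and phase, with member genes).
#' @export
conserved_introns <- function(intron_maps, alignment) {
  aln <- as_alignment_matrix(alignment)
  missing <- setdiff(names(intron_maps), rownames(aln))
  if (length(missing))
    stop("ortholog(s) missing from alignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  recs <- lapply(names(intron_maps), function(id) {
    im <- intron_maps[[id]]
    im <- im[im$coding_interrupting, , drop = FALSE]
    if (!nrow(im)) return(NULL)
    codon <- im$cds_offset %/% 3L + 1L
    data.frame(gene_id = id, intron_index = im$index,
               cds_offset = im$cds_offset, phase = im$phase,
               protein_position = codon,
               column = alignment_column(aln[id, ], codon))
  })
  introns <- do.call(rbind, recs)
  if (is.null(introns))
    return(list(introns = data.frame(), shared = data.frame()))
  key <- paste(introns$column, introns$phase, sep = "/")
  groups <- split(introns, key)
  shared <- do.call(rbind, lapply(groups, function(g) {
    if (nrow(g) < 2L) return(NULL)
    data.frame(column = g$column[1], phase = g$phase[1],
               n_members = nrow(g),
               members = paste(g$gene_id, collapse = ","),
               intron_indices = paste(g$intron_index, collapse = ","))
  }))
  if (is.null(shared))
    shared <- data.frame(column = integer(), phase = integer(),
                         n_members = integer(), members = character(),
                         intron_indices = character())
  rownames(shared) <- NULL
  list(introns = introns, shared = shared)
}
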