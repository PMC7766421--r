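#' @importFrom Biostrings AAStringSet
NULL

# coerce a named character vector / AAStringSet alignment into a character
# matrix (rows = sequences, cols = alignment columns)
as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  seqs <- stats::setNames(as.character(alignment), names(alignment))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("alignment sequences must have unique names", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment sequences must have equal length", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

# map 1-based ungapped positions of one aligned sequence to alignment columns
alignment_column <- function(aligned_chars, positions) {
  if (is.character(aligned_chars) && length(aligned_chars) == 1L)
    aligned_chars <- strsplit(aligned_chars, "")[[1]]
  nongap <- aligned_chars != "-"
  cols <- which(nongap)
  if (any(positions < 1L | positions > length(cols)))
    stop("position outside ungapped sequence length", call. = FALSE)
  cols[positions]
}

#' Per-column conservation relative to a reference sequence
#'
#' Maps reference positions to alignment columns through the reference's gap
#' structure and reports, per column, the percentage of non-gap residues
#' (reference included) matching the reference residue. Gaps are excluded
#' from both numerator and denominator.
#'
#' @param alignment named character vector or `Biostrings::AAStringSet` of
#'   equal-length gapped sequences.
#' @param reference_id name of the reference sequence in the alignment.
#' @param positions 1-based positions in the ungapped reference; default all.
#' @param groups optional named character vector (sequence name -> group
#'   label); when given, per-group consensus residue and frequency columns
#'   are added.
#' @return `data.frame` with columns `ref_position`, `column`, `ref_residue`,
#'   `n_nongap`, `n_match`, `conservation_pct` (plus per-group consensus
#'   columns when `groups` is supplied).
#' @export
column_conservation <- function(alignment, reference_id, positions = NULL,
                                groups = NULL) {
  aln <- as_alignment_matrix(alignment)
  if (!reference_id %in% rownames(aln))
    stop("reference '", reference_id, "' absent from alignment", call. = FALSE)
  ref <- aln[reference_id, ]
  ref_len <- sum(ref != "-")
  if (is.null(positions)) positions <- seq_len(ref_len)
  cols <- alignment_column(ref, positions)
  res <- aln[, cols, drop = FALSE]
  ref_res <- ref[cols]
  nongap <- res != "-"
  n_nongap <- colSums(nongap)
  n_match <- colSums(nongap & sweep(res, 2, ref_res, "=="))
  out <- data.frame(ref_position = positions, column = cols,
                    ref_residue = ref_res,
                    n_nongap = as.integer(n_nongap),
                    n_match = as.integer(n_match),
                    conservation_pct = 100 * n_match / n_nongap)
  if (!is.null(groups)) {
    cons <- group_consensus(aln, groups, cols)
    for (g in names(cons)) {
      out[[paste0("consensus_", g)]] <- cons[[g]]$residue
      out[[paste0("consensus_freq_", g)]] <- cons[[g]]$freq
    }
  }
  rownames(out) <- NULL
  out
}

# per-group modal residue and its within-group (non-gap) frequency for the
# given alignment columns
group_consensus <- function(aln, groups, cols) {
  groups <- groups[rownames(aln)]
  if (anyNA(groups))
    stop("every aligned sequence needs a group label", call. = FALSE)
  out <- list()
  for (g in unique(groups)) {
    sub <- aln[groups == g, cols, drop = FALSE]
    residue <- character(length(cols))
    freq <- numeric(length(cols))
    for (j in seq_along(cols)) {
      col <- sub[, j]
      col <- col[col != "-"]
      if (!length(col)) { residue[j] <- NA_character_; freq[j] <- 0; next }
      tab <- sort(table(col), decreasing = TRUE)
      residue[j] <- names(tab)[1]
      freq[j] <- tab[[1]] / length(col)
    }
    out[[g]] <- list(residue = residue, freq = freq)
  }
  out
}

#' Detect kingdom-specific conserved differences
#'
#' Flags alignment columns where every group's modal residue reaches the
#' consensus threshold within its group (inclusive `>=`, over non-gap
#' residues) and the modal residues are not all identical — the signature of
#' a conserved between-kingdom difference.
#'
#' @param alignment named character vector or `Biostrings::AAStringSet`.
#' @param groups named character vector: sequence name -> group label;
#'   every group must contain at least one sequence, and at least two groups
#'   are required.
#' @param consensus_threshold minimum within-group modal-residue frequency,
#'   default 0.9.
#' @return `data.frame` with one row per alignment column: `column`,
#'   per-group `consensus_*` and `consensus_freq_*` columns, and `flagged`.
#' @export
kingdom_specific_positions <- function(alignment, groups,
                                       consensus_threshold = 0.9) {
  aln <- as_alignment_matrix(alignment)
  groups <- groups[rownames(aln)]
  if (anyNA(groups))
    stop("every aligned sequence needs a group label", call. = FALSE)
  if (length(unique(groups)) < 2L)
    stop("at least two groups are required", call. = FALSE)
  if (any(table(groups) < 1L))
    stop("each group needs at least one sequence", call. = FALSE)
  cols <- seq_len(ncol(aln))
  cons <- group_consensus(aln, groups, cols)
  out <- data.frame(column = cols)
  freq_mat <- sapply(cons, function(x) x$freq)
  res_mat <- sapply(cons, function(x) x$residue)
  if (length(cols) == 1L) {
    freq_mat <- matrix(freq_mat, nrow = 1)
    res_mat <- matrix(res_mat, nrow = 1)
  }
  for (g in names(cons)) {
    out[[paste0("consensus_", g)]] <- cons[[g]]$residue
    out[[paste0("consensus_freq_", g)]] <- cons[[g]]$freq
  }
  all_conserved <- apply(freq_mat >= consensus_threshold, 1, all)
  differs <- apply(res_mat, 1, function(r) length(unique(r[!is.na(r)])) > 1L)
  out$flagged <- all_conserved & differs & !apply(is.na(res_mat), 1, any)
  out
}
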