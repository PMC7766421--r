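#' Amino-acid class partition used for radicalness calls
#'
#' Six physicochemical classes: aliphatic/hydrophobic (AVLIM), aromatic
#' (FWY), polar uncharged (STNQ), positively charged (KRH), negatively
#' charged (DE), special (GCP). Every standard residue belongs to exactly
#' one class.
#'
#' @return named character vector: residue -> class.
#' @export
aa_classes <- function() {
  classes <- list(aliphatic_hydrophobic = c("A", "V", "L", "I", "M"),
                  aromatic = c("F", "W", "Y"),
                  polar_uncharged = c("S", "T", "N", "Q"),
                  positive = c("K", "R", "H"),
                  negative = c("D", "E"),
                  special = c("G", "C", "P"))
  out <- unlist(lapply(names(classes), function(cl)
    stats::setNames(rep(cl, length(classes[[cl]])), classes[[cl]])))
  out
}

# standard NCBI substitution matrices shipped with Biostrings
get_blosum <- local({
  cache <- list()
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    cache[[name]] <<- e[[name]]
    cache[[name]]
  }
})

#' Radicalness of an amino-acid substitution
#'
#' A substitution is radical when the two residues belong to different
#' physicochemical classes AND its score is <= 0 in both BLOSUM62 and
#' BLOSUM80. Symmetric in its arguments. A stop (`"*"`, from stop-gain or
#' stop-loss variants) is treated as its own class and scored with the
#' matrices' `*` row, so nonsense changes always come out radical.
#'
#' @param ref_aa,alt_aa standard one-letter amino-acid codes (vectorized).
#' @return `data.frame` with `ref_aa`, `alt_aa`, `class_change`,
#'   `blosum62_score`, `blosum80_score`, `radical`.
#' @examples
#' radicalness("K", "E")  # class change but BLOSUM62 = +1: not radical
#' radicalness("D", "W")  # class change, both scores negative: radical
#' @export
radicalness <- function(ref_aa, alt_aa) {
  cls <- c(aa_classes(), "*" = "stop")
  if (!all(ref_aa %in% names(cls)) || !all(alt_aa %in% names(cls)))
    stop("non-standard amino acid", call. = FALSE)
  b62 <- get_blosum("BLOSUM62")[cbind(ref_aa, alt_aa)]
  b80 <- get_blosum("BLOSUM80")[cbind(ref_aa, alt_aa)]
  class_change <- cls[ref_aa] != cls[alt_aa]
  data.frame(ref_aa = ref_aa, alt_aa = alt_aa,
             class_change = unname(class_change),
             blosum62_score = as.integer(b62),
             blosum80_score = as.integer(b80),
             radical = unname(class_change & b62 <= 0 & b80 <= 0))
}

#' Annotate variants with known functional-site overlap
#'
#' Exact protein-position match against a functional-site table; no fuzzy
#' matching. Unmatched positions are annotated `"unknown"`.
#'
#' @param protein_positions 1-based protein positions of the variants.
#' @param functional_sites `data.frame` with columns `protein_position`,
#'   `annotation` (may be empty).
#' @return character vector of annotations.
#' @export
annotate_functional_overlap <- function(protein_positions, functional_sites) {
  if (is.null(functional_sites) || !nrow(functional_sites))
    return(rep("unknown", length(protein_positions)))
  i <- match(protein_positions, functional_sites$protein_position)
  ifelse(is.na(i), "unknown", functional_sites$annotation[i])
}

#' Prioritize non-synonymous variants
#'
#' Ranks amino-acid-changing variants lexicographically by the four
#' computable criteria: (1) overlap with a known functional site — site
#' tables may carry an evidence tier in an optional `priority` column
#' (1 = strongest, e.g. residues whose mutation abolishes Hsp70 binding;
#' higher numbers = weaker evidence such as packing contacts; unannotated
#' positions rank after all tiers), (2) positional conservation
#' (descending), (3) radicalness (radical first), (4) population frequency
#' (lower MAF first); ties broken by protein position ascending. Variants
#' lacking conservation data are flagged and ranked last, never dropped.
#' No weighted score is invented; the order is purely lexicographic.
#'
#' @param variants `data.frame` with columns `snp_id`, `ref_aa`, `alt_aa`,
#'   `protein_position`, `maf`, and optionally `conservation_pct`.
#' @param functional_sites optional `data.frame(protein_position,
#'   annotation)`.
#' @param conservation optional [column_conservation()] table used to fill
#'   `conservation_pct` by `ref_position` when the column is absent.
#' @return the input with added `functional_annotation`, `class_change`,
#'   `blosum62_score`, `blosum80_score`, `radical`,
#'   `missing_conservation`, and `rank` (1 = highest priority), sorted by
#'   rank.
#' @export
prioritize_variants <- function(variants, functional_sites = NULL,
                                conservation = NULL) {
  v <- as.data.frame(variants)
  need <- c("snp_id", "ref_aa", "alt_aa", "protein_position", "maf")
  if (!all(need %in% names(v)))
    stop("variants missing column(s): ",
         paste(setdiff(need, names(v)), collapse = ", "), call. = FALSE)
  if (is.null(v$conservation_pct)) {
    if (!is.null(conservation)) {
      v$conservation_pct <-
        conservation$conservation_pct[match(v$protein_position,
                                            conservation$ref_position)]
    } else v$conservation_pct <- NA_real_
  }
  v$functional_annotation <-
    annotate_functional_overlap(v$protein_position, functional_sites)
  rad <- radicalness(v$ref_aa, v$alt_aa)
  v$class_change <- rad$class_change
  v$blosum62_score <- rad$blosum62_score
  v$blosum80_score <- rad$blosum80_score
  v$radical <- rad$radical
  v$missing_conservation <- is.na(v$conservation_pct)
  tier <- rep(Inf, nrow(v))
  if (!is.null(functional_sites) && nrow(functional_sites)) {
    i <- match(v$protein_position, functional_sites$protein_position)
    pri <- if (!is.null(functional_sites$priority))
      functional_sites$priority else rep(1, nrow(functional_sites))
    tier[!is.na(i)] <- pri[i[!is.na(i)]]
  }
  v$site_tier <- tier
  cons_key <- ifelse(v$missing_conservation, -Inf, v$conservation_pct)
  ord <- order(v$missing_conservation,            # flagged records last
               tier,
               -cons_key,
               -as.integer(v$radical),
               v$maf,
               v$protein_position)
  v <- v[ord, , drop = FALSE]
  v$rank <- seq_len(nrow(v))
  rownames(v) <- NULL
  v
}
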