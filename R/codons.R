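# codon-level utilities shared by the annotation and site-counting modules

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# translate codon strings with the standard genetic code (table 1); "*" = stop
translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa))
    stop("non-ACGT base in codon(s): ",
         paste(unique(codons[is.na(aa)]), collapse = ", "), call. = FALSE)
  unname(aa)
}

# split a CDS string into its codon vector, validating length and alphabet
cds_codons <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length not divisible by 3", call. = FALSE)
  chars <- strsplit(cds, "")[[1]]
  if (!all(chars %in% BASES))
    stop("CDS contains non-ACGT characters", call. = FALSE)
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

# per-codon fractional synonymous site count: at each of the 3 positions,
# (number of the 3 alternative bases giving a synonymous codon) / 3, summed
codon_syn_sites <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste0, collapse = "")
    syn <- vapply(codons, function(cod) {
      aa <- translate_codons(cod)
      s <- 0
      for (p in 1:3) for (b in setdiff(BASES, substr(cod, p, p))) {
        mut <- cod
        substr(mut, p, p) <- b
        if (translate_codons(mut) == aa) s <- s + 1 / 3
      }
      s
    }, numeric(1))
    cache <<- syn
    syn
  }
})

# L x 3 logical matrix: for each coding position (rows, over the given codon
# index set) and each of the 3 alternative bases (columns, in BASES order
# minus the reference base), is the substitution synonymous?
syn_flags_matrix <- function(codons) {
  n <- length(codons)
  flags <- matrix(NA, nrow = 3L * n, ncol = 3L)
  ref_aa <- translate_codons(codons)
  for (k in seq_len(n)) {
    cod <- codons[k]
    for (p in 1:3) {
      alts <- setdiff(BASES, substr(cod, p, p))
      for (a in 1:3) {
        mut <- cod
        substr(mut, p, p) <- alts[a]
        flags[3L * (k - 1L) + p, a] <- translate_codons(mut) == ref_aa[k]
      }
    }
  }
  flags
}
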