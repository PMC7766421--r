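# independent brute-force oracles and fixture builders used across the suite

ORACLE_BASES <- c("A", "C", "G", "T")

# translation via seqinr, independent of the package's codon table
oracle_translate <- function(codon) {
  toupper(seqinr::translate(strsplit(codon, "")[[1]]))
}

# fractional site counts by exhaustive 9-mutant enumeration per codon;
# terminal stop codon excluded
oracle_site_counts <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  if (oracle_translate(codons[length(codons)]) == "*")
    codons <- codons[-length(codons)]
  syn <- 0
  for (cod in codons) {
    aa <- oracle_translate(cod)
    for (p in 1:3) for (b in setdiff(ORACLE_BASES, substr(cod, p, p))) {
      mut <- cod
      substr(mut, p, p) <- b
      if (oracle_translate(mut) == aa) syn <- syn + 1 / 3
    }
  }
  list(syn = syn, nonsyn = 3 * length(codons) - syn)
}

# genomic positions of the mature transcript, in transcript order
oracle_tx_positions <- function(model) {
  ex <- model$exons
  tx <- unlist(lapply(seq_len(nrow(ex)), function(i) ex$start[i]:ex$end[i]))
  if (model$strand == "-") rev(tx) else tx
}

# per-base region labels over the whole locus by explicit transcript
# reconstruction (interval walking, no arithmetic shared with region_of)
oracle_region_labels <- function(model) {
  labels <- rep("regulatory", model$locus_end - model$locus_start + 1)
  at <- function(pos) pos - model$locus_start + 1
  labels[at(seq(model$genic_start, model$genic_end))] <- "intronic"
  tx <- oracle_tx_positions(model)
  cds_span <- range(which(tx == model$cds_start | tx == model$cds_end))
  t <- seq_along(tx)
  labels[at(tx[t < cds_span[1]])] <- "five_prime_UTR"
  labels[at(tx[t > cds_span[2]])] <- "three_prime_UTR"
  labels[at(tx[t >= cds_span[1] & t <= cds_span[2]])] <- "coding"
  labels
}

# intron cds_offsets and phases by counting coding transcript bases before
# each junction, base by base
oracle_intron_offsets <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n == 1L) return(data.frame(cds_offset = integer(), phase = integer()))
  tx <- oracle_tx_positions(model)
  cds_span <- range(which(tx == model$cds_start | tx == model$cds_end))
  coding <- seq_along(tx) >= cds_span[1] & seq_along(tx) <= cds_span[2]
  widths <- ex$end - ex$start + 1
  ord <- if (model$strand == "+") seq_len(n) else rev(seq_len(n))
  ce <- cumsum(widths[ord])
  off <- vapply(ce[-n], function(j) sum(coding[1:j]), numeric(1))
  data.frame(cds_offset = off, phase = off %% 3)
}

# O(n*w) per-window membership count
oracle_window_counts <- function(positions, starts, window_size) {
  vapply(starts, function(s) {
    n <- 0
    for (p in positions) if (p >= s && p < s + window_size) n <- n + 1
    n
  }, numeric(1))
}

# small random-but-valid gene model (mixed strands, 1-6 exons)
random_model <- function(seed) {
  set.seed(seed)
  n_ex <- sample(1:6, 1)
  widths <- sample(30:200, n_ex, replace = TRUE)
  gaps <- if (n_ex > 1) sample(20:300, n_ex - 1, replace = TRUE) else integer(0)
  starts <- 1000 + cumsum(c(0, if (n_ex > 1) widths[-n_ex] + gaps))
  ends <- starts + widths - 1
  strand <- sample(c("+", "-"), 1)
  tx <- unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))
  if (strand == "-") tx <- rev(tx)
  tx_len <- length(tx)
  cds_len <- 3 * sample(2:(tx_len %/% 3), 1)
  utr5 <- sample(0:(tx_len - cds_len), 1)
  cds_g <- range(tx[c(utr5 + 1, utr5 + cds_len)])
  gene_model(paste0("rnd", seed), "chrT", strand,
             data.frame(start = starts, end = ends), cds_g[1], cds_g[2],
             flank_up_bp = sample(0:500, 1), flank_down_bp = sample(0:500, 1))
}

# single-exon model wrapping a CDS string, for effect-annotation fixtures
single_exon_model <- function(cds, flank = 100) {
  n <- nchar(cds)
  gene_model("mini", "chrT", "+",
             data.frame(start = 1001, end = 1000 + n),
             cds_start = 1001, cds_end = 1000 + n,
             flank_up_bp = flank, flank_down_bp = flank)
}

# build a plus-strand gene model whose CDS is interrupted by introns exactly
# after the given numbers of coding nucleotides (no UTRs)
model_from_junctions <- function(gene_id, cds, junction_offsets,
                                 intron_len = 100) {
  n <- nchar(cds)
  stopifnot(all(junction_offsets > 0 & junction_offsets < n))
  seg_w <- diff(c(0, sort(junction_offsets), n))
  starts <- integer(length(seg_w)); ends <- integer(length(seg_w))
  cursor <- 501
  for (i in seq_along(seg_w)) {
    starts[i] <- cursor
    ends[i] <- cursor + seg_w[i] - 1
    cursor <- ends[i] + 1 + intron_len
  }
  gene_model(gene_id, "chrT", "+", data.frame(start = starts, end = ends),
             cds_start = starts[1], cds_end = ends[length(ends)],
             flank_up_bp = 50, flank_down_bp = 50)
}

# reflect a synthetic locus through its midpoint: coordinates mirrored,
# strand flipped, alleles complemented; classification must be unchanged
mirror_locus <- function(loc) {
  m <- loc$model
  C <- m$locus_start + m$locus_end
  ex <- data.frame(start = C - m$exons$end, end = C - m$exons$start)
  m2 <- gene_model(m$gene_id, m$chrom, if (m$strand == "+") "-" else "+",
                   ex, C - m$cds_end, C - m$cds_start,
                   m$flank_up_bp, m$flank_down_bp)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s <- loc$snps
  s$pos <- C - s$pos
  s$ref <- unname(comp[s$ref])
  s$alt <- unname(comp[s$alt])
  s <- s[order(s$pos), ]
  rownames(s) <- NULL
  list(model = m2, snps = s)
}
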