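test_that("codon-level effects match known substitutions", {
  # M K L * ; SNPs hit codon 1 (ATG), codon 2 (AAG), codon 3 (CTT)
  cds <- "ATGAAGCTTTAA"
  m <- single_exon_model(cds)
  snps <- snp_table(c("s1", "s2", "s3"), "chrT",
                    pos = c(1001, 1004, 1009),
                    ref = c("A", "A", "T"), alt = c("G", "G", "C"),
                    maf = c(0.0004, 0.0124, 0.2))
  cls <- classify_snps(snps, m, cds)
  expect_equal(cls$effect, c("non_synonymous", "non_synonymous", "synonymous"))
  expect_equal(cls$ref_aa, c("M", "K", "L"))
  expect_equal(cls$alt_aa, c("V", "E", "L"))   # M/V and K/E changes
  expect_equal(cls$protein_position, c(1, 2, 3))
  expect_equal(cls$frequency_class, c("rare", "common", "common"))
})

test_that("all 576 single-base codon mutants agree with the translation oracle", {
  codons <- apply(expand.grid(ORACLE_BASES, ORACLE_BASES, ORACLE_BASES),
                  1, paste0, collapse = "")
  cds <- paste(codons, collapse = "")           # 192 nt, 64 codons
  m <- single_exon_model(cds)
  chars <- strsplit(cds, "")[[1]]
  pos <- rep(seq_along(chars), each = 3)
  alt <- unlist(lapply(chars, function(b) setdiff(ORACLE_BASES, b)))
  snps <- snp_table(sprintf("m%03d", seq_along(pos)), "chrT",
                    pos = 1000 + pos, ref = chars[pos], alt = alt,
                    maf = rep(0.001, length(pos)))
  cls <- classify_snps(snps, m, cds)
  expect_equal(nrow(cls), 576)
  codon_i <- (pos - 1) %/% 3 + 1
  within <- (pos - 1) %% 3 + 1
  expected <- vapply(seq_along(pos), function(i) {
    cod <- codons[codon_i[i]]
    mut <- cod
    substr(mut, within[i], within[i]) <- alt[i]
    if (oracle_translate(cod) == oracle_translate(mut))
      "synonymous" else "non_synonymous"
  }, character(1))
  expect_identical(cls$effect, expected)
})

test_that("rare/common classification uses a strict 1% cutoff", {
  expect_equal(frequency_class(c(0.0004, 0.0124, 0.01, 0.0099)),
               c("rare", "common", "common", "rare"))
  expect_error(frequency_class(0.7), "0.5")
  expect_error(frequency_class(-0.1), "0.5")
})

test_that("reference-allele mismatches fail loudly", {
  cds <- "ATGAAGCTTTAA"
  m <- single_exon_model(cds)
  snps <- snp_table("bad", "chrT", 1001, ref = "C", alt = "G", maf = 0.1)
  expect_error(classify_snps(snps, m, cds), "mismatch.*1001")
})

test_that("empty SNP set yields an all-zero summary", {
  loc <- generate_locus(synthetic_config(seed = 2))
  empty <- loc$snps[0, ]
  s <- summarize_regions(empty, loc$model, loc$cds)
  expect_true(all(s$n_snps == 0))
  expect_true(all(s$density == 0))
  expect_true(all(s$n_rare == 0 & s$n_common == 0))
})

test_that("summary counts equal generator ground truth and partition", {
  for (seed in c(3, 4)) {
    loc <- generate_locus(synthetic_config(seed = seed))
    s <- summarize_regions(loc$snps, loc$model, loc$cds)
    truth_n <- table(factor(loc$snps$truth_region,
                            levels = c("regulatory", "intronic",
                                       "five_prime_UTR", "three_prime_UTR",
                                       "coding")))
    for (r in names(truth_n))
      expect_equal(s$n_snps[s$region == r], unname(truth_n[[r]]),
                   label = paste(seed, r))
    expect_equal(s$n_snps[s$region == "synonymous"],
                 sum(loc$snps$truth_effect == "synonymous", na.rm = TRUE))
    expect_equal(s$n_snps[s$region == "non_synonymous"],
                 sum(loc$snps$truth_effect == "non_synonymous", na.rm = TRUE))
    # hierarchy conservation
    g <- function(r) s$n_snps[s$region == r]
    expect_equal(g("total"), g("regulatory") + g("genic"))
    expect_equal(g("genic"), g("intronic") + g("five_prime_UTR") +
                   g("three_prime_UTR") + g("coding"))
    expect_equal(g("coding"), g("synonymous") + g("non_synonymous"))
    expect_equal(s$n_rare + s$n_common, s$n_snps)
    # density definition on the headline rows
    expect_equal(s$density[s$region == "total"],
                 1000 * g("total") / 22283)
  }
})

test_that("annotation is invariant under strand mirroring", {
  loc <- generate_locus(synthetic_config(seed = 5))
  mir <- mirror_locus(loc)
  a <- classify_snps(loc$snps, loc$model, loc$cds)
  b <- classify_snps(mir$snps, mir$model, loc$cds)
  a <- a[order(a$snp_id), ]; b <- b[order(b$snp_id), ]
  expect_identical(a$region, b$region)
  expect_identical(a$effect, b$effect)
  expect_identical(a$protein_position, b$protein_position)
  expect_identical(a$ref_aa, b$ref_aa)
  expect_identical(a$alt_aa, b$alt_aa)
})
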