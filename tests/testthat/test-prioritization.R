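test_that("radicalness combines class change with both BLOSUM scores", {
  ke <- radicalness("K", "E")
  expect_true(ke$class_change)            # positive vs negative charge
  expect_equal(ke$blosum62_score, 1L)     # favourable substitution
  expect_false(ke$radical)

  mv <- radicalness("M", "V")             # same aliphatic class
  expect_false(mv$class_change)
  expect_false(mv$radical)

  dw <- radicalness("D", "W")
  expect_true(dw$class_change)
  expect_lt(dw$blosum62_score, 0)
  expect_lt(dw$blosum80_score, 0)
  expect_true(dw$radical)

  expect_error(radicalness("K", "U"), "non-standard")
})

test_that("radicalness is symmetric and every residue has one class", {
  cls <- aa_classes()
  expect_length(cls, 20)
  expect_false(anyNA(cls))
  set.seed(5)
  res <- names(cls)
  for (i in 1:30) {
    ab <- sample(res, 2)
    f <- radicalness(ab[1], ab[2])
    r <- radicalness(ab[2], ab[1])
    expect_equal(f$radical, r$radical)
    expect_equal(f$blosum62_score, r$blosum62_score)
    expect_equal(f$blosum80_score, r$blosum80_score)
  }
})

test_that("functional-site overlap is exact-match only", {
  sites <- data.frame(protein_position = 216, annotation = "Hsp70 interaction")
  expect_equal(annotate_functional_overlap(216, sites), "Hsp70 interaction")
  expect_equal(annotate_functional_overlap(217, sites), "unknown")  # off by one
  expect_equal(annotate_functional_overlap(c(216, 5), NULL),
               c("unknown", "unknown"))
})

test_that("printed study variants rank functional sites above the rest", {
  path <- system.file("extdata", "table5_variants.tsv", package = "locusvar")
  tab5 <- read.table(path, header = TRUE, sep = "\t")
  sites <- read_functional_sites(
    system.file("extdata", "functional_sites.tsv", package = "locusvar"))
  # use only the printed annotations: function comes from the site table
  v <- tab5[, c("snp_id", "ref_aa", "alt_aa", "protein_position", "maf",
                "conservation_pct")]
  ranked <- prioritize_variants(v, functional_sites = sites)
  hsp70 <- ranked$rank[ranked$functional_annotation == "Hsp70 interaction"]
  other <- ranked$rank[ranked$functional_annotation != "Hsp70 interaction"]
  packing <- ranked$rank[ranked$functional_annotation == "Packing interaction"]
  unknown <- ranked$rank[ranked$functional_annotation == "unknown"]
  expect_length(hsp70, 3)
  # the three Hsp70-interaction variants (K216E, E219K, N229I) outrank the
  # packing-site (M215V) and unknown (S233G) variants
  expect_lt(max(hsp70), min(packing, unknown))
  expect_true(all(sort(ranked$rank) == 1:5))
})

test_that("ranking is deterministic and permutation invariant", {
  path <- system.file("extdata", "table5_variants.tsv", package = "locusvar")
  tab5 <- read.table(path, header = TRUE, sep = "\t")
  sites <- read_functional_sites(
    system.file("extdata", "functional_sites.tsv", package = "locusvar"))
  v <- tab5[, c("snp_id", "ref_aa", "alt_aa", "protein_position", "maf",
                "conservation_pct")]
  r1 <- prioritize_variants(v, sites)
  set.seed(6)
  r2 <- prioritize_variants(v[sample(nrow(v)), ], sites)
  expect_identical(r1$snp_id, r2$snp_id)
  expect_identical(r1$rank, r2$rank)
})

test_that("ordering rules apply lexicographically", {
  base <- data.frame(snp_id = c("at_site", "not_at_site"),
                     ref_aa = "K", alt_aa = "E",
                     protein_position = c(216, 50),
                     maf = 0.001, conservation_pct = 90)
  sites <- data.frame(protein_position = 216, annotation = "Hsp70 interaction")
  r <- prioritize_variants(base, sites)
  expect_equal(r$snp_id[1], "at_site")   # site overlap dominates

  # conservation breaks ties within the same functional status
  v2 <- data.frame(snp_id = c("lo", "hi"), ref_aa = "K", alt_aa = "E",
                   protein_position = c(10, 20), maf = 0.001,
                   conservation_pct = c(80, 95))
  expect_equal(prioritize_variants(v2)$snp_id[1], "hi")

  # radicalness before MAF
  v3 <- data.frame(snp_id = c("mild_rare", "radical_common"),
                   ref_aa = c("K", "D"), alt_aa = c("E", "W"),
                   protein_position = c(10, 20), maf = c(0.0001, 0.01),
                   conservation_pct = 90)
  expect_equal(prioritize_variants(v3)$snp_id[1], "radical_common")

  # missing conservation is flagged and ranked last, not dropped
  v4 <- data.frame(snp_id = c("known", "nocons"), ref_aa = "K", alt_aa = "E",
                   protein_position = c(10, 20), maf = 0.001,
                   conservation_pct = c(50, NA))
  r4 <- prioritize_variants(v4)
  expect_equal(nrow(r4), 2)
  expect_true(r4$missing_conservation[r4$snp_id == "nocons"])
  expect_equal(r4$rank[r4$snp_id == "nocons"], 2)
})
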