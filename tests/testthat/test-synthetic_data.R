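test_that("generation is deterministic under seed and varies across seeds", {
  a <- generate_locus(synthetic_config(seed = 21))
  b <- generate_locus(synthetic_config(seed = 21))
  expect_identical(a$cds, b$cds)
  expect_identical(a$snps, b$snps)
  expect_identical(a$model$exons, b$model$exons)
  c <- generate_locus(synthetic_config(seed = 22))
  expect_false(identical(a$snps, c$snps))
})

test_that("generated CDS is a valid open reading frame", {
  loc <- generate_locus(synthetic_config(seed = 23))
  cod <- locusvar:::cds_codons(loc$cds)
  aa <- locusvar:::translate_codons(cod)
  expect_equal(aa[1], "M")
  expect_equal(aa[length(aa)], "*")
  expect_false(any(aa[-length(aa)] == "*"))  # no internal stops
})

test_that("default configuration reproduces the study locus geometry", {
  loc <- generate_locus(synthetic_config(seed = 24))
  rl <- region_lengths(loc$model)
  expect_equal(unname(rl[["locus"]]), 22283)
  expect_equal(unname(rl[["genic"]]), 12283)
  expect_equal(unname(rl[["regulatory"]]), 10000)
  expect_equal(nrow(loc$model$exons), 7)   # six introns
})

test_that("pipeline classification recovers generator truth labels", {
  for (seed in 31:36) {
    loc <- generate_locus(synthetic_config(
      seed = seed, strand = if (seed %% 2) "+" else "-"))
    cls <- classify_snps(loc$snps, loc$model, loc$cds)
    expect_identical(cls$region, loc$snps$truth_region,
                     label = paste("seed", seed))
    expect_identical(cls$effect, loc$snps$truth_effect)
    expect_identical(cls$frequency_class, loc$snps$truth_class)
  }
})

test_that("rare fraction recovers the configured target", {
  n_rare <- 0; n_tot <- 0
  for (seed in 41:55) {
    loc <- generate_locus(synthetic_config(seed = seed))
    n_rare <- n_rare + sum(loc$snps$truth_class == "rare")
    n_tot <- n_tot + nrow(loc$snps)
  }
  ci <- stats::binom.test(n_rare, n_tot, 0.886)
  expect_gt(ci$p.value, 0.001)
})

test_that("infeasible densities raise a generation error", {
  cfg <- synthetic_config(seed = 1, densities = c(regulatory = 2e6,
                                                  intronic = 0,
                                                  five_prime_UTR = 0,
                                                  three_prime_UTR = 0,
                                                  coding = 0))
  expect_error(generate_locus(cfg), "infeasible")
})

test_that("alignment generator honours conservation and engineered truth", {
  # full conservation: every column 100% identical to the reference
  cfg1 <- synthetic_config(seed = 61, alignment = list(
    groups = c(animal = 8, plant = 5, fungi = 3), conservation = 1,
    engineered_positions = integer(0), gap_rate = 0))
  a1 <- generate_alignment(cfg1)
  p1 <- column_conservation(a1$alignment, "ref")
  expect_true(all(p1$conservation_pct == 100))
  expect_false(any(kingdom_specific_positions(a1$alignment, a1$groups,
                                              0.9)$flagged))

  # engineered kingdom differences are exactly the flagged columns
  cfg2 <- synthetic_config(seed = 62, alignment = list(
    groups = c(animal = 10, plant = 6, fungi = 4), conservation = 1,
    engineered_positions = c(12L, 80L, 200L), gap_rate = 0))
  a2 <- generate_alignment(cfg2)
  ks <- kingdom_specific_positions(a2$alignment, a2$groups, 0.9)
  expect_equal(which(ks$flagged), c(12L, 80L, 200L))

  # same seed -> identical alignment (determinism)
  a3 <- generate_alignment(cfg2)
  expect_identical(a2$alignment, a3$alignment)

  # mean conservation near the configured level (binomial sampling error)
  cfg3 <- synthetic_config(seed = 63, alignment = list(
    groups = c(animal = 30, plant = 20), conservation = 0.9,
    engineered_positions = integer(0), gap_rate = 0))
  a4 <- generate_alignment(cfg3)
  p4 <- column_conservation(a4$alignment, "ref")
  # non-reference residue matches are Bernoulli(0.9)
  n_seq <- length(a4$alignment) - 1
  match_rate <- (sum(p4$n_match) - nrow(p4)) / (n_seq * nrow(p4))
  ci <- stats::binom.test(sum(p4$n_match) - nrow(p4), n_seq * nrow(p4), 0.9)
  expect_gt(ci$p.value, 0.001)

  # invalid conservation level rejected
  expect_error(synthetic_config(seed = 1, alignment = list(
    groups = c(a = 3, b = 3), conservation = 1.2,
    engineered_positions = integer(0), gap_rate = 0)), "conservation")
})

test_that("gap injection leaves gap-exclusion conservation consistent", {
  cfg <- synthetic_config(seed = 64, alignment = list(
    groups = c(animal = 10, plant = 6), conservation = 1,
    engineered_positions = integer(0), gap_rate = 0.2))
  a <- generate_alignment(cfg)
  p <- column_conservation(a$alignment, "ref")
  # with full conservation, non-gap residues always match the reference
  expect_true(all(p$conservation_pct == 100))
  expect_true(any(p$n_nongap < length(a$alignment)))  # gaps were injected
})
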