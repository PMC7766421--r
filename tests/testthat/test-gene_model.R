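test_that("degenerate single-exon gene has no introns and no UTRs", {
  gm <- gene_model("g1", "chr9", "+",
                   exons = data.frame(start = 101, end = 1135),
                   cds_start = 101, cds_end = 1135,
                   flank_up_bp = 500, flank_down_bp = 500)
  rl <- region_lengths(gm)
  expect_equal(unname(rl[["genic"]]), 1035)
  expect_equal(unname(rl[["intronic"]]), 0)
  expect_equal(unname(rl[["five_prime_UTR"]]), 0)
  expect_equal(unname(rl[["three_prime_UTR"]]), 0)
  expect_equal(nrow(intron_map(gm)), 0)
})

test_that("study-shaped locus partitions into the expected region lengths", {
  loc <- generate_locus(synthetic_config(seed = 1))
  rl <- region_lengths(loc$model)
  expect_equal(unname(rl[["intronic"]]), 8418)
  expect_equal(unname(rl[["five_prime_UTR"]]), 87)
  expect_equal(unname(rl[["three_prime_UTR"]]), 2740)
  expect_equal(unname(rl[["coding"]]), 1038)
  expect_equal(unname(rl[["genic"]]), 12283)
  expect_equal(unname(rl[["locus"]]), 22283)
})

test_that("model construction rejects invalid structures by name", {
  ex <- data.frame(start = c(100, 150), end = c(200, 300))
  expect_error(gene_model("g", "c", "+", ex, 100, 300, 0, 0), "overlap")
  expect_error(gene_model("g", "c", "+", data.frame(start = 100, end = 199),
                          50, 199, 0, 0), "outside exons")
  expect_error(gene_model("g", "c", "+", data.frame(start = 100, end = 199),
                          100, 199, 0, 0), "divisible by 3")
  expect_error(gene_model("g", "c", "+", data.frame(start = 100, end = 199),
                          100, 198, -1, 0), "flank")
})

test_that("region boundaries follow the coding-inclusive convention", {
  gm <- gene_model("g", "chrT", "+",
                   exons = data.frame(start = c(1001, 1201), end = c(1100, 1400)),
                   cds_start = 1051, cds_end = 1282,   # 50 + 82 = 132 nt spliced
                   flank_up_bp = 200, flank_down_bp = 100)
  expect_equal(region_of(gm, 900), "regulatory")
  expect_equal(region_of(gm, 1051), "coding")     # first base of start codon
  expect_equal(region_of(gm, 1282), "coding")     # last base of stop codon
  expect_equal(region_of(gm, 1050), "five_prime_UTR")
  expect_equal(region_of(gm, 1283), "three_prime_UTR")
  expect_equal(region_of(gm, 1150), "intronic")
  expect_error(region_of(gm, 100), "outside locus")
})

test_that("per-base labels agree with the brute-force interval walker", {
  for (seed in 1:60) {
    m <- random_model(seed)
    pos <- seq(m$locus_start, m$locus_end)
    got <- region_of(m, pos)
    expect_identical(got, oracle_region_labels(m), label = paste("seed", seed))
    # partition: every position exactly one label; counts match lengths
    rl <- region_lengths(m)
    cnt <- table(factor(got, levels = c("regulatory", "intronic",
                                        "five_prime_UTR", "three_prime_UTR",
                                        "coding")))
    expect_equal(unname(cnt[["regulatory"]]), unname(rl[["regulatory"]]))
    expect_equal(unname(cnt[["intronic"]]), unname(rl[["intronic"]]))
    expect_equal(unname(cnt[["coding"]]), unname(rl[["coding"]]))
    expect_equal(sum(cnt), unname(rl[["locus"]]))
  }
})

test_that("intron phase equals coding offset mod 3", {
  cds <- paste(rep("ATG", 20), collapse = "")   # 60 nt
  m0 <- model_from_junctions("p0", cds, 30)
  expect_equal(intron_map(m0)$cds_offset, 30)
  expect_equal(intron_map(m0)$phase, 0)
  m1 <- model_from_junctions("p1", cds, 31)
  expect_equal(intron_map(m1)$phase, 1)
  m2 <- model_from_junctions("p2", cds, 32)
  expect_equal(intron_map(m2)$phase, 2)
})

test_that("intron offsets and phases agree with the base-walking oracle", {
  for (seed in 61:120) {
    m <- random_model(seed)
    im <- intron_map(m)
    oc <- oracle_intron_offsets(m)
    expect_equal(im$cds_offset, oc$cds_offset, label = paste("seed", seed))
    expect_equal(im$phase, oc$phase, label = paste("seed", seed))
    if (nrow(im)) {
      expect_true(all(diff(im$cds_offset) >= 0))
      expect_identical(im$coding_interrupting,
                       im$cds_offset > 0 & im$cds_offset < m$cds_len)
    }
  }
})

test_that("mirroring a locus leaves region lengths and phases unchanged", {
  loc <- generate_locus(synthetic_config(seed = 17))
  mir <- mirror_locus(loc)
  expect_equal(region_lengths(mir$model), region_lengths(loc$model))
  expect_equal(intron_map(mir$model)$phase, intron_map(loc$model)$phase)
  expect_equal(intron_map(mir$model)$cds_offset,
               intron_map(loc$model)$cds_offset)
})

test_that("shared introns are detected by aligned position and phase", {
  # 30-codon CDS shared by an animal-like (6 introns) and plant-like
  # (3 introns) gene; only the junction after 30 coding nt coincides
  cds <- paste(rep(c("ATG", "GCT", "AAA"), 10), collapse = "")
  animal <- model_from_junctions("animal", cds, c(9, 21, 30, 48, 60, 75))
  plant <- model_from_junctions("plant", cds, c(12, 30, 57))
  prot <- paste(locusvar:::translate_codons(locusvar:::cds_codons(cds)),
                collapse = "")
  aln <- c(animal = prot, plant = prot)
  res <- conserved_introns(list(animal = intron_map(animal),
                                plant = intron_map(plant)), aln)
  shared <- res$shared
  expect_equal(nrow(shared), 1)
  expect_equal(shared$phase, 0)
  expect_equal(shared$n_members, 2)
  expect_match(shared$members, "animal")
  expect_match(shared$members, "plant")
  # the shared pair is animal intron 3 and plant intron 2
  expect_setequal(strsplit(shared$intron_indices, ",")[[1]], c("3", "2"))

  # identical models share every intron
  res2 <- conserved_introns(list(a = intron_map(animal),
                                 b = intron_map(animal)),
                            c(a = prot, b = prot))
  expect_equal(nrow(res2$shared), 6)

  # shifting the shared junction by one codon or changing its phase
  # removes it from the shared set
  plant_shift <- model_from_junctions("plant", cds, c(12, 33, 57))
  res3 <- conserved_introns(list(animal = intron_map(animal),
                                 plant = intron_map(plant_shift)), aln)
  expect_equal(nrow(res3$shared), 0)
  plant_phase <- model_from_junctions("plant", cds, c(12, 31, 57))
  res4 <- conserved_introns(list(animal = intron_map(animal),
                                 plant = intron_map(plant_phase)), aln)
  expect_equal(nrow(res4$shared), 0)

  expect_error(conserved_introns(list(x = intron_map(animal)), aln),
               "missing from alignment")
})
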