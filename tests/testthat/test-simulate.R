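test_that("ancestral-genome generation is deterministic under a seed", {
  g1 <- simulate_ancestral_genome(n_chrom = 3, seed = 91)
  g2 <- simulate_ancestral_genome(n_chrom = 3, seed = 91)
  expect_identical(g1$markers, g2$markers)
  expect_identical(as.character(genome_sequences(g1)),
                   as.character(genome_sequences(g2)))
  g3 <- simulate_ancestral_genome(n_chrom = 3, seed = 92)
  expect_false(identical(g1$markers$fwd, g3$markers$fwd))
})

test_that("marker counts and primer uniqueness hold", {
  g <- simulate_ancestral_genome(
    n_chrom = 12,
    chrom_lengths_cM = setNames(rep(100, 12),
                                as.character(utils::as.roman(1:12))),
    markers_per_chrom = setNames(rep(20L, 12),
                                 as.character(utils::as.roman(1:12))),
    seed = 93)
  expect_equal(nrow(g$markers), 240)
  expect_equal(anyDuplicated(c(g$markers$fwd, g$markers$rev)), 0)
  expect_equal(anyDuplicated(g$markers$marker_id), 0)
})

test_that("marker positions are uniform along the chromosome", {
  g <- simulate_ancestral_genome(
    n_chrom = 1, chrom_lengths_cM = c(I = 100),
    markers_per_chrom = c(I = 1000L), seed = 94)
  ks <- suppressWarnings(ks.test(g$markers$cM / 100, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("an empty scenario leaves the chromosome set unchanged", {
  g <- simulate_ancestral_genome(n_chrom = 4, seed = 95)
  der <- apply_rearrangements(g, rearrangement_scenario(list()))
  expect_setequal(unique(der$markers$chrom), unique(g$markers$chrom))
  expect_equal(nrow(der$markers), nrow(g$markers))
  # source positions carried through unchanged
  expect_equal(der$markers$source_cM[order(der$markers$marker_id)],
               g$markers$cM[order(g$markers$marker_id)])
})

test_that("a single side-by-side fusion reduces the chromosome count and
           records the planted segments", {
  g <- simulate_ancestral_genome(n_chrom = 4, seed = 96)
  sc <- rearrangement_scenario(list(
    list(type = "fusion", style = "side_by_side", name = "F1",
         sources = list(seg("I"), seg("III")))))
  der <- apply_rearrangements(g, sc)
  expect_equal(length(unique(der$markers$chrom)), 3)
  segs <- der$segments[der$segments$chrom == "F1", ]
  expect_equal(segs$source_chrom, c("I", "III"))
  expect_error(apply_rearrangements(g, rearrangement_scenario(list(
    sc$events[[1]], sc$events[[1]]))), "consumed")
})

test_that("the default scenario plants the 12-to-7 correspondence", {
  g <- simulate_ancestral_genome(seed = 97)
  der <- apply_rearrangements(g, default_scenario())
  expect_equal(length(unique(der$markers$chrom)), 7)
  pc <- planted_correspondence(der)
  want_target <- c("1" = "II, XII", "2" = "III, V, XI", "3" = "IV, VI",
                   "4" = "VII, VIII", "5" = "IX, X",
                   "6" = "III, VIII, XI", "7" = "I")
  tgt <- pc[pc$view == "target", ]
  expect_equal(setNames(tgt$partners_label, tgt$chromosome), want_target)
  src <- pc[pc$view == "source", ]
  expect_equal(src$partners_label[src$chromosome == "I"], "7")
  expect_equal(src$partners_label[src$chromosome == "VIII"], "4, 6")
  # the planted inversion flips marker orientation inside chromosome 7
  inv <- der$markers[der$markers$chrom == "7", ]
  expect_true(any(inv$orientation == -1))
  expect_true(any(inv$orientation == 1))
})

test_that("virtual PCR recovers every uncorrupted planted marker uniquely", {
  g <- simulate_ancestral_genome(
    n_chrom = 3,
    chrom_lengths_cM = setNames(rep(60, 3), c("I", "II", "III")),
    markers_per_chrom = setNames(rep(8L, 3), c("I", "II", "III")),
    seed = 98)
  der <- apply_rearrangements(g, rearrangement_scenario(list(
    list(type = "fusion", style = "alternating", name = "1",
         sources = list(seg("I"), seg("II"))))))
  hits <- virtual_pcr(g$markers[, c("marker_id", "fwd", "rev")],
                      der$scaffolds)
  cls <- classify_hits(hits, g$markers$marker_id)
  expect_true(all(cls$class == "unique"))
  # hits land on the scaffold the truth says the marker lives on
  joined <- dplyr::inner_join(hits, der$marker_scaffold,
                              by = "marker_id",
                              suffix = c("", "_truth"))
  expect_true(all(joined$scaffold == joined$scaffold_truth))
})

test_that("corruption plants no-hit, multi-copy and mis-anchored markers
           at the requested rates", {
  g <- simulate_ancestral_genome(
    n_chrom = 3,
    chrom_lengths_cM = setNames(rep(80, 3), c("I", "II", "III")),
    markers_per_chrom = setNames(rep(25L, 3), c("I", "II", "III")),
    seed = 99)
  der <- apply_rearrangements(g, rearrangement_scenario(list()))
  same <- corrupt(der, c(no_hit = 0, multi_copy = 0, mis_anchor = 0))
  expect_identical(same$markers, der$markers)

  bad <- corrupt(der, c(no_hit = 0.2, multi_copy = 0.1, mis_anchor = 0),
                 seed = 100)
  hits <- virtual_pcr(g$markers[, c("marker_id", "fwd", "rev")],
                      bad$scaffolds)
  cls <- classify_hits(hits, g$markers$marker_id)
  tab <- table(factor(cls$class, c("no_hit", "unique", "multi_copy")))
  # binomial 3 SE around 75 * rate
  expect_gte(tab[["no_hit"]], 4)
  expect_lte(tab[["no_hit"]], 26)
  expect_gte(tab[["multi_copy"]], 1)
  expect_true(all(bad$markers$corruption[match(
    cls$marker_id[cls$class == "no_hit"], bad$markers$marker_id)]
    == "no_hit"))
})

test_that("meiosis simulation honours the map: zero distance never
           recombines and rf converges to the Haldane inverse", {
  map0 <- tibble::tibble(marker_id = c("a", "b"), chrom = "c",
                         cM = c(10, 10))
  g0 <- simulate_population(map0, "f2", 300, seed = 101,
                            missing_rate = 0)
  expect_true(all(g0$a == g0$b))

  geno <- sim_pair_geno(5000, r = 0.2, seed = 102)
  est <- estimate_rf_f2(geno$ma, geno$mb)
  expect_gte(est$r_hat, 0.183)                     # ~3 SE at n = 5000
  expect_lte(est$r_hat, 0.217)
})

test_that("simulated studies are reproducible and carry consistent truth", {
  s1 <- simulate_study(seed = 103, n_f2 = 20, n_ril = 20, n_chrom = 12,
                       chrom_lengths_cM = setNames(
                         rep(50, 12), as.character(utils::as.roman(1:12))),
                       markers_per_chrom = setNames(
                         rep(6L, 12), as.character(utils::as.roman(1:12))))
  s2 <- simulate_study(seed = 103, n_f2 = 20, n_ril = 20, n_chrom = 12,
                       chrom_lengths_cM = setNames(
                         rep(50, 12), as.character(utils::as.roman(1:12))),
                       markers_per_chrom = setNames(
                         rep(6L, 12), as.character(utils::as.roman(1:12))))
  expect_identical(s1$geno_f2, s2$geno_f2)
  expect_identical(as.character(s1$derived$scaffolds),
                   as.character(s2$derived$scaffolds))
  expect_identical(s1$truth$correspondence, s2$truth$correspondence)
  # every reference-map scaffold exists in the assembly
  expect_true(all(s1$reference_map$scaffold %in%
                    names(s1$derived$scaffolds)))
})
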