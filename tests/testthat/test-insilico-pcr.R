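rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

test_that("a planted primer pair is found with exact coordinates", {
  set.seed(71)
  fwd <- rnd_dna(20); rev <- rnd_dna(22); insert <- rnd_dna(200)
  amp <- paste0(fwd, insert, rc(rev))
  scaf <- paste0(rnd_dna(1000), amp, rnd_dna(800))
  asm <- load_assembly(c(s1 = scaf), name = "toy")
  hits <- virtual_pcr(tibble::tibble(marker_id = "mk", fwd = fwd,
                                     rev = rev), asm)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 1001)
  expect_equal(hits$end, 1000 + nchar(amp))
  expect_equal(hits$product_size, 200 + nchar(fwd) + nchar(rev))
  expect_equal(hits$strand, "+")
  expect_equal(hits$product_seq, amp)

  # absent primers yield an empty hit table
  none <- virtual_pcr(tibble::tibble(marker_id = "mk", fwd = rnd_dna(20),
                                     rev = rnd_dna(20)), asm)
  expect_equal(nrow(none), 0)
})

test_that("two planted loci give two hits; reverse-complementing the
           assembly mirrors coordinates and flips strand", {
  set.seed(72)
  fwd <- rnd_dna(21); rev <- rnd_dna(21)
  amp <- paste0(fwd, rnd_dna(150), rc(rev))
  s1 <- paste0(rnd_dna(500), amp, rnd_dna(300))
  s2 <- paste0(rnd_dna(200), amp, rnd_dna(400))
  asm <- load_assembly(c(s1 = s1, s2 = s2), name = "toy")
  hits <- virtual_pcr(tibble::tibble(marker_id = "mk", fwd = fwd,
                                     rev = rev), asm)
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$scaffold, c("s1", "s2"))

  asm_rc <- load_assembly(c(s1 = rc(s1), s2 = rc(s2)), name = "toy_rc")
  hits_rc <- virtual_pcr(tibble::tibble(marker_id = "mk", fwd = fwd,
                                        rev = rev), asm_rc)
  expect_equal(nrow(hits_rc), 2)
  expect_setequal(hits_rc$strand, "-")
  n <- setNames(nchar(c(s1, s2)), c("s1", "s2"))
  hr <- hits_rc[order(hits_rc$scaffold), ]
  h <- hits[order(hits$scaffold), ]
  expect_equal(unname(n[hr$scaffold] - hr$end + 1), h$start)
  expect_equal(unname(n[hr$scaffold] - hr$start + 1), h$end)
  expect_equal(hr$product_seq, h$product_seq)
})

test_that("two amplifiable loci within the product window on one scaffold
           also yield the bridging product", {
  set.seed(78)
  fwd <- rnd_dna(21); rev <- rnd_dna(21)
  amp <- paste0(fwd, rnd_dna(150), rc(rev))
  scaf <- paste0(rnd_dna(500), amp, rnd_dna(700), amp, rnd_dna(300))
  asm <- load_assembly(c(s1 = scaf), name = "toy")
  hits <- virtual_pcr(tibble::tibble(marker_id = "mk", fwd = fwd,
                                     rev = rev), asm)
  # two short products plus the long fwd(1)...rev(2) pairing
  expect_equal(nrow(hits), 3)
  expect_equal(sort(hits$product_size)[1:2], rep(nchar(amp), 2))
})

test_that("virtual PCR equals the brute-force scan on random scaffolds", {
  set.seed(73)
  for (i in 1:8) {
    scaf <- rnd_dna(20000)
    fwd <- rnd_dna(20); rev <- rnd_dna(20)
    if (i %% 2 == 0) {
      amp <- paste0(fwd, rnd_dna(sample(60:300, 1)), rc(rev))
      pos <- sample(15000, 1)
      substr(scaf, pos, pos + nchar(amp) - 1) <- amp
    }
    if (i %% 4 == 0) {  # second, mutated copy exercises the mismatch path
      amp2 <- paste0(fwd, rnd_dna(100), rc(rev))
      substr(amp2, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                    substr(amp2, 5, 5))[1]
      pos2 <- sample(2000, 1)
      substr(scaf, pos2, pos2 + nchar(amp2) - 1) <- amp2
    }
    asm <- load_assembly(c(s1 = scaf), name = "rand")
    got <- virtual_pcr(tibble::tibble(marker_id = "m", fwd = fwd,
                                      rev = rev), asm)
    ora <- oracle_vpcr(scaf, fwd, rev)
    expect_equal(nrow(got), nrow(ora))
    if (nrow(got) > 0) {
      g <- got[order(got$start, got$end, got$strand), ]
      o <- ora[order(ora$start, ora$end, ora$strand), ]
      expect_equal(g$start, o$start)
      expect_equal(g$end, o$end)
      expect_equal(g$strand, o$strand)
    }
  }
})

test_that("hits at zero mismatches are a subset of hits at one", {
  set.seed(74)
  fwd <- rnd_dna(20); rev <- rnd_dna(20)
  amp_exact <- paste0(fwd, rnd_dna(120), rc(rev))
  fwd_mut <- fwd
  substr(fwd_mut, 8, 8) <- setdiff(c("A", "C", "G", "T"),
                                   substr(fwd, 8, 8))[1]
  amp_mut <- paste0(fwd_mut, rnd_dna(120), rc(rev))
  asm <- load_assembly(c(s1 = paste0(rnd_dna(400), amp_exact,
                                     rnd_dna(200)),
                         s2 = paste0(rnd_dna(300), amp_mut,
                                     rnd_dna(200))), name = "toy")
  p <- tibble::tibble(marker_id = "m", fwd = fwd, rev = rev)
  h0 <- virtual_pcr(p, asm, max_mismatch = 0)
  h1 <- virtual_pcr(p, asm, max_mismatch = 1)
  expect_equal(nrow(h0), 1)
  expect_equal(nrow(h1), 2)
  expect_true(all(paste(h0$start, h0$end) %in% paste(h1$start, h1$end)))
})

test_that("primer validation and product-size window are enforced", {
  asm <- load_assembly(c(s1 = rnd_dna(500)), name = "toy")
  expect_error(virtual_pcr(tibble::tibble(marker_id = "m", fwd = "ACGT",
                                          rev = rnd_dna(20)), asm),
               "at least 15")
  expect_error(
    synmapr:::iupac_mismatches("ACGTX", "ACGTA"), "non-IUPAC")
  # product larger than max_size is rejected
  set.seed(75)
  fwd <- rnd_dna(20); rev <- rnd_dna(20)
  scaf <- paste0(fwd, rnd_dna(1000), rc(rev))
  asm2 <- load_assembly(c(s1 = scaf), name = "toy2")
  p <- tibble::tibble(marker_id = "m", fwd = fwd, rev = rev)
  expect_equal(nrow(virtual_pcr(p, asm2, max_size = 500)), 0)
  expect_equal(nrow(virtual_pcr(p, asm2, max_size = 2000)), 1)
})

test_that("assemblies with non-ACGTN letters or duplicate ids load-fail", {
  expect_error(load_assembly(c(s1 = "ACGTRYACGT")), "ACGTN")
  expect_error(load_assembly(setNames(c("ACGT", "ACGT"), c("s", "s"))),
               "unique")
})

test_that("hit classification separates no-hit, unique, multi-copy and
           repeat-region markers", {
  hits <- tibble::tibble(
    marker_id = c("u", "m", "m", "r"),
    assembly = "a", scaffold = c("s1", "s1", "s2", "s3"),
    start = c(100L, 10L, 20L, 1000L), end = c(300L, 200L, 210L, 1200L),
    strand = "+", product_size = c(201L, 191L, 191L, 201L),
    product_seq = NA_character_)
  cls <- classify_hits(hits, c("u", "m", "r", "n"),
                       repeats = tibble::tibble(scaffold = "s3",
                                                start = 900, end = 1500))
  got <- setNames(cls$class, cls$marker_id)
  expect_equal(got[["u"]], "unique")
  expect_equal(got[["m"]], "multi_copy")
  expect_equal(got[["r"]], "repeat_region")
  expect_equal(got[["n"]], "no_hit")
})

test_that("seed-and-extend anchors a sequence on itself and tolerates
           substitutions", {
  set.seed(76)
  scaf <- rnd_dna(5000)
  asm <- load_assembly(c(s1 = scaf), name = "toy")
  q <- substr(scaf, 1000, 1499)
  hit <- anchor_by_sequence(q, asm)
  expect_equal(hit$class, "unique")
  expect_equal(hit$start, 1000)
  expect_equal(hit$end, 1499)
  expect_equal(hit$identity, 1)

  # 5% substitutions: same location, identity >= 0.95 by construction
  qm <- strsplit(q, "")[[1]]
  mut <- sample(500, 25)
  qm[mut] <- vapply(qm[mut],
                    function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  hm <- anchor_by_sequence(paste(qm, collapse = ""), asm)
  expect_equal(hm$class, "unique")
  expect_equal(hm$start, 1000)
  expect_gte(hm$identity, 0.95)

  # a random query shares no 31-mer with the scaffold
  expect_equal(anchor_by_sequence(rnd_dna(500), asm)$class, "no_hit")
  expect_error(anchor_by_sequence(rnd_dna(20), asm), "shorter than seed")
  expect_error(anchor_by_sequence(rnd_dna(60), asm), ">= 100")
})

test_that("reverse-complement queries anchor on the minus strand", {
  set.seed(77)
  scaf <- rnd_dna(3000)
  asm <- load_assembly(c(s1 = scaf), name = "toy")
  hit <- anchor_by_sequence(rc(substr(scaf, 500, 899)), asm)
  expect_equal(hit$class, "unique")
  expect_equal(hit$strand, "-")
  expect_equal(hit$start, 500)
  expect_equal(hit$end, 899)
})

test_that("BED intervals convert to 1-based inclusive coordinates", {
  tmp <- tempfile(fileext = ".bed")
  writeLines("s1\t99\t200\trep1", tmp)
  bed <- read_bed(tmp)
  expect_equal(bed$start, 100L)
  expect_equal(bed$end, 200L)
})
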