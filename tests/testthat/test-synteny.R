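ref_map <- tibble::tibble(
  marker_id = c("cs1", "cs2", "cs3", "amb1", "amb2"),
  chromosome = c("5", "5", "5", "2", "6"),
  position_cM = c(30, 31, 40, 10, 50),
  scaffold = c("scfA", "scfA", "scfA", "scfB", "scfB"))

test_that("markers on the reference map are assigned directly", {
  src <- tibble::tibble(marker_id = "cs1", chromosome = "I",
                        position_cM = 31.2)
  hits <- tibble::tibble(marker_id = character(0), scaffold = character(0))
  cls <- tibble::tibble(marker_id = "cs1", class = "unique")
  a <- anchor_markers(src, hits, cls, ref_map)
  expect_equal(a$evidence, "direct_map")
  expect_equal(a$target_chrom, "5")
  expect_equal(a$target_cM, 30)      # the reference position of cs1
  expect_equal(a$status, "assigned")
})

test_that("scaffold-transitive assignment uses the majority chromosome at
           the median reference position", {
  src <- tibble::tibble(marker_id = "q1", chromosome = "I",
                        position_cM = 5)
  hits <- tibble::tibble(marker_id = "q1", scaffold = "scfA")
  cls <- tibble::tibble(marker_id = "q1", class = "unique")
  a <- anchor_markers(src, hits, cls, ref_map)
  expect_equal(a$evidence, "scaffold_transitive")
  expect_equal(a$target_chrom, "5")
  expect_equal(a$target_cM, 31)      # median of 30, 31, 40
})

test_that("a 1:1 split scaffold is ambiguous; no-hit and multi-copy
           markers stay unanchored with a reason", {
  src <- tibble::tibble(marker_id = c("q2", "q3", "q4"),
                        chromosome = "I", position_cM = c(1, 2, 3))
  hits <- tibble::tibble(marker_id = "q2", scaffold = "scfB")
  cls <- tibble::tibble(marker_id = c("q2", "q3", "q4"),
                        class = c("unique", "no_hit", "multi_copy"))
  a <- anchor_markers(src, hits, cls, ref_map)
  expect_equal(a$status, c("ambiguous", "unanchored", "unanchored"))
  expect_equal(a$reason[2:3], c("no_hit", "multi_copy"))
})

test_that("scaffolds with no mapped reference marker leave the marker
           unanchored", {
  src <- tibble::tibble(marker_id = "q5", chromosome = "I",
                        position_cM = 9)
  hits <- tibble::tibble(marker_id = "q5", scaffold = "scfZ")
  cls <- tibble::tibble(marker_id = "q5", class = "unique")
  a <- anchor_markers(src, hits, cls, ref_map)
  expect_equal(a$status, "unanchored")
  expect_match(a$reason, "no mapped reference")
})

anch <- function(targets, chrom = "I") {
  n <- length(targets)
  tibble::tibble(marker_id = sprintf("m%02d", 1:n), source_chrom = chrom,
                 source_cM = seq_len(n) * 2, target_chrom = targets,
                 target_cM = seq_len(n), evidence = "direct_map",
                 status = "assigned", reason = NA_character_)
}

test_that("block detection reproduces the worked segmentation examples", {
  b1 <- detect_blocks(anch(rep("5", 4)))
  expect_equal(nrow(b1), 1)
  expect_equal(b1$target_chrom, "5")
  expect_equal(b1$n_markers, 4L)
  expect_equal(b1$type, "block")

  b2 <- detect_blocks(anch(c("2", "2", "2", "6", "6", "2", "2")),
                      max_gap_markers = 0)
  expect_equal(b2$target_chrom, c("2", "6", "2"))
  expect_equal(b2$n_markers, c(3L, 2L, 2L))

  b3 <- detect_blocks(anch(c("2", "2", "6", "2", "2")),
                      max_gap_markers = 1)
  expect_equal(nrow(b3), 1)
  expect_equal(b3$target_chrom, "2")
  expect_equal(b3$n_markers, 4L)
  expect_equal(b3$n_discordant, 1L)
})

test_that("greedy segmentation equals the interval-enumeration oracle on
           short target strings", {
  alphabet <- c("a", "b")
  for (n in 1:6) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), n), stringsAsFactors = FALSE))
    for (i in seq_len(nrow(grid))) {
      s <- as.character(unlist(grid[i, ]))
      for (budget in 0:2) {
        got <- synmapr:::segment_targets(s, budget)
        ora <- oracle_segment(s, budget)
        expect_identical(lapply(got, `[[`, "members"),
                         lapply(ora, `[[`, "members"))
        expect_identical(vapply(got, `[[`, integer(1), "n_discordant"),
                         vapply(ora, `[[`, integer(1), "n_discordant"))
      }
    }
  }
})

test_that("every block member carries the block target and discordants
           stay within budget (random property)", {
  set.seed(81)
  for (rep in 1:30) {
    targets <- sample(c("1", "2", "3"), sample(4:14, 1), replace = TRUE)
    budget <- sample(0:2, 1)
    blocks <- detect_blocks(anch(targets), max_gap_markers = budget)
    a <- anch(targets)
    for (i in seq_len(nrow(blocks))) {
      mt <- a$target_chrom[match(blocks$members[[i]], a$marker_id)]
      expect_true(all(mt == blocks$target_chrom[i]))
      expect_lte(blocks$n_discordant[i], budget)
    }
    # every assigned locus is a member of exactly one run or absorbed as
    # a discordant; nothing is counted twice
    members <- unlist(blocks$members)
    expect_equal(anyDuplicated(members), 0)
    expect_equal(length(members) + sum(blocks$n_discordant),
                 length(targets))
  }
})

test_that("colinearity classifies monotone, inverted and shuffled blocks", {
  up <- colinearity(1:6, c(10, 20, 30, 40, 50, 60))
  expect_equal(up$tau, 1)
  expect_equal(up$colinearity, "colinear")
  dn <- colinearity(1:6, c(60, 50, 40, 30, 20, 10))
  expect_equal(dn$tau, -1)
  expect_equal(dn$colinearity, "inverted")
  expect_equal(colinearity(1:2, 1:2)$colinearity, "undetermined")

  set.seed(82)
  for (rep in 1:10) {
    x <- runif(6); y <- sample(runif(6))
    expect_equal(colinearity(x, y)$tau, oracle_tau(x, y),
                 tolerance = 1e-12)
  }
})

test_that("correspondence tables are symmetric between the two views", {
  targets_I <- c("7", "7", "7", "7")
  targets_III <- c("2", "2", "6", "6", "6")
  blocks <- dplyr::bind_rows(detect_blocks(anch(targets_I, "I")),
                             detect_blocks(anch(targets_III, "III")))
  corr <- correspondence_table(blocks)
  src <- corr[corr$view == "source", ]
  tgt <- corr[corr$view == "target", ]
  expect_equal(src$partners_label[src$chromosome == "I"], "7")
  expect_equal(src$partners_label[src$chromosome == "III"], "2, 6")
  expect_equal(tgt$partners_label[tgt$chromosome == "7"], "I")
  # symmetry: X in partners(Y) <=> Y in partners(X)
  for (i in seq_len(nrow(src))) {
    for (p in src$partners[[i]]) {
      expect_true(src$chromosome[i] %in%
                    tgt$partners[[which(tgt$chromosome == p)]])
    }
  }
  expect_equal(nrow(correspondence_table(blocks[0, ])), 0)
})

test_that("singleton runs do not enter the correspondence table", {
  blocks <- detect_blocks(anch(c("2", "2", "2", "9")),
                          max_gap_markers = 0)
  corr <- correspondence_table(blocks)
  expect_equal(corr$partners_label[corr$view == "source"], "2")
})

test_that("a nested fusion shows the A-B-A segment pattern in the
           target-direction view", {
  # target chromosome 4 carries VII, then nested VIII, then VII again
  a <- tibble::tibble(
    marker_id = sprintf("m%02d", 1:12),
    source_chrom = c(rep("VII", 4), rep("VIII", 4), rep("VII", 4)),
    source_cM = c(1:4, 1:4, 5:8),
    target_chrom = "4",
    target_cM = 1:12,
    evidence = "direct_map", status = "assigned", reason = NA_character_)
  tb <- detect_blocks(a, direction = "target")
  views <- block_views(detect_blocks(a), tb)
  v4 <- views[views$view == "target" & views$chromosome == "4", ]
  expect_equal(v4$partner, c("VII", "VIII", "VII"))

  # alternating fusion: >= 3 alternating segments of two colours
  b <- tibble::tibble(
    marker_id = sprintf("n%02d", 1:12),
    source_chrom = rep(c("II", "XII"), each = 6),
    source_cM = c(c(1:3, 7:9), c(4:6, 10:12)),
    target_chrom = "1",
    target_cM = c(c(1:3, 7:9), c(4:6, 10:12)),
    evidence = "direct_map", status = "assigned", reason = NA_character_)
  vb <- block_views(detect_blocks(b),
                    detect_blocks(b, direction = "target"))
  v1 <- vb[vb$view == "target" & vb$chromosome == "1", ]
  expect_equal(v1$partner, c("II", "XII", "II", "XII"))
})
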