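mk_map <- function(group, ids, pos) {
  new_genetic_map(tibble::tibble(group = group, marker_id = ids,
                                 position_cM = pos))
}

test_that("identical evidence in both populations gives G = 0, retained", {
  cnt <- matrix(c(20, 4, 0, 5, 40, 4, 1, 5, 21), 3, 3)
  ht <- heterogeneity_test(cnt, cnt, "f2", "f2")
  expect_equal(ht$G, 0, tolerance = 1e-6)
  expect_equal(ht$p_value, 1, tolerance = 1e-6)
  expect_false(ht$excluded)
})

test_that("heterogeneous recombination fractions are detected and match a
           numeric pooled-likelihood oracle", {
  ht <- heterogeneity_test(c(0, 100), c(40, 100), "ril", "ril")
  # oracle: maximise the pooled log-likelihood on a fine meiotic-r grid
  ll <- function(r, k, n) {
    R <- pmin(pmax(2 * r / (1 + 2 * r), 1e-12), 1 - 1e-12)
    k * log(R) + (n - k) * log(1 - R)
  }
  rs <- seq(1e-6, 0.5, by = 1e-6)
  pooled <- max(ll(rs, 0, 100) + ll(rs, 40, 100))
  r1 <- 0; r2 <- (40 / 100) / (2 - 2 * 40 / 100)
  g_oracle <- 2 * (ll(r1, 0, 100) + ll(r2, 40, 100) - pooled)
  expect_equal(ht$G, g_oracle, tolerance = 1e-6)
  expect_true(ht$excluded)
})

test_that("degenerate all-or-none evidence takes the G = 0 path", {
  ht <- heterogeneity_test(c(0, 50), c(0, 60), "ril", "ril")
  expect_equal(ht$G, 0, tolerance = 1e-9)
  expect_false(ht$excluded)
})

test_that("merging a map with itself is the identity", {
  map <- mk_map("1", c("a", "b", "c"), c(0, 4, 10))
  cons <- merge_maps(map, map)
  expect_equal(cons$marker_id, c("a", "b", "c"))
  expect_equal(cons$position_cM, c(0, 4, 10))
  expect_setequal(cons$provenance, "shared")
})

test_that("second-map-only loci interpolate into the reference frame", {
  ref <- mk_map("1", c("a1", "a2"), c(0, 10))
  sec <- mk_map("1", c("a1", "x", "a2"), c(0, 4, 10))
  cons <- merge_maps(ref, sec)
  expect_equal(cons$position_cM[cons$marker_id == "x"], 4)

  # anchors at 0/20 (reference) vs 0/10 (second): 4 cM rescales to 8
  ref2 <- mk_map("1", c("a1", "a2"), c(0, 20))
  cons2 <- merge_maps(ref2, sec)
  expect_equal(cons2$position_cM[cons2$marker_id == "x"], 8)
  expect_equal(cons2$provenance[cons2$marker_id == "x"], "ril_only")
})

test_that("extrapolation beyond terminal anchors uses the terminal scale", {
  ref <- mk_map("1", c("a1", "a2"), c(0, 20))
  sec <- mk_map("1", c("y", "a1", "a2", "z"), c(0, 2, 12, 15))
  cons <- merge_maps(ref, sec)
  # group re-zeroed: y sits 2 second-cM before a1, scale 2x -> 4 ref-cM
  pos <- setNames(cons$position_cM, cons$marker_id)
  expect_equal(pos[["a1"]] - pos[["y"]], 4)
  expect_equal(pos[["z"]] - pos[["a2"]], 6)
})

test_that("shared-locus order equals reference order on random merges", {
  set.seed(61)
  for (rep in 1:15) {
    n <- sample(8:16, 1)
    ref_ids <- sprintf("r%02d", 1:n)
    ref_pos <- sort(runif(n, 0, 80))
    ref <- mk_map("1", ref_ids, ref_pos - ref_pos[1])
    shared <- sort(sample(n, 5))
    extra <- sprintf("s%02d", 1:4)
    sec_ids <- c(ref_ids[shared], extra)
    sec_pos <- c(sort(runif(5, 0, 50)), runif(4, 0, 50))
    o <- order(sec_pos)
    sec <- mk_map("1", sec_ids[o], sort(sec_pos) - min(sec_pos))
    cons <- merge_maps(ref, sec)
    # Kendall tau = 1 between reference and consensus on shared loci
    both <- intersect(cons$marker_id, ref$marker_id)
    tau <- cor(match(both, ref$marker_id),
               match(both, cons$marker_id), method = "kendall")
    expect_equal(tau, 1)
    # deterministic and row-order independent
    cons2 <- merge_maps(ref, sec[sample(nrow(sec)), ])
    expect_equal(dplyr::arrange(tibble::as_tibble(cons), marker_id),
                 dplyr::arrange(tibble::as_tibble(cons2), marker_id))
  }
})

test_that("conflicting anchors are demoted, not silently reordered", {
  ref <- mk_map("1", c("a", "b", "c", "d"), c(0, 5, 10, 15))
  sec <- mk_map("1", c("b", "a", "c", "d"), c(0, 1, 6, 9))  # a/b swapped
  cons <- merge_maps(ref, sec)
  log <- attr(cons, "merge_log")
  expect_true(any(log$reason == "anchor order conflict"))
  both <- intersect(cons$marker_id, ref$marker_id)
  expect_equal(cor(match(both, ref$marker_id),
                   match(both, cons$marker_id), method = "kendall"), 1)
})

test_that("groups with fewer than two anchors leave second loci unplaced", {
  ref <- mk_map("1", c("a", "b"), c(0, 10))
  sec <- mk_map("1", c("a", "x"), c(0, 5))
  cons <- merge_maps(ref, sec)
  expect_false("x" %in% cons$marker_id)
  expect_true("x" %in% attr(cons, "merge_log")$marker_id)
})

test_that("map summaries reproduce length-over-loci arithmetic", {
  map <- mk_map(rep("1", 38), sprintf("m%02d", 1:38),
                seq(0, 107.3, length.out = 38))
  s <- map_summary(map)
  expect_equal(s$mean_interval_cM[s$group == "1"], 2.8)
  one <- mk_map("2", "solo", 0)
  s1 <- map_summary(one)
  expect_equal(s1$length_cM[s1$group == "2"], 0)
  expect_equal(s1$mean_interval_cM[s1$group == "2"], 0)
})
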