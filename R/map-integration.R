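#' @noRd
#' Log-likelihood of meiotic recombination fraction r for one population's
#' evidence.  F2 evidence is a 3x3 joint genotype-class table; RIL
#' evidence is c(n_rec, n_informative) on the observed (line) scale, where
#' the expected observed fraction for selfing RILs is R(r) = 2r/(1+2r).
pair_loglik <- function(r, counts, population) {
  if (population == "f2") {
    vapply(r, f2_loglik, numeric(1), counts = counts)
  } else {
    k <- counts[1]; n <- counts[2]
    big_r <- pmin(pmax(2 * r / (1 + 2 * r), 1e-12), 1 - 1e-12)
    k * log(big_r) + (n - k) * log(1 - big_r)
  }
}

#' @noRd
pair_mle <- function(counts, population) {
  if (population == "f2") {
    rf_em_f2_counts(counts)$r_hat
  } else {
    big_r <- min(counts[1] / counts[2], 0.5)
    big_r / (2 - 2 * big_r)
  }
}

#' Heterogeneity test for a shared marker pair
#'
#' Likelihood-ratio test of whether two mapping populations share the same
#' meiotic recombination fraction for a common marker pair:
#' `G = 2 [lnL1(r1) + lnL2(r2) - lnL1(rp) - lnL2(rp)]` with `rp` the
#' pooled maximum-likelihood estimate, compared to chi-square with 1 df.
#' Pairs with `p < alpha` are flagged for exclusion from consensus-map
#' anchoring.  RIL evidence is placed on the meiotic scale inside the
#' likelihood (expected observed fraction `2r/(1+2r)` under selfing), so
#' F2 and RIL populations pool coherently.
#'
#' @param counts1,counts2 Evidence per population: a 3x3 joint
#'   genotype-class matrix for an F2, or `c(n_rec, n_informative)` for a
#'   RIL.
#' @param population1,population2 `"f2"` or `"ril"`.
#' @param alpha Exclusion level (default 0.05).
#' @return One-row tibble: `r1`, `r2`, `r_pooled`, `G`, `p_value`,
#'   `excluded`.
#' @examples
#' f2 <- matrix(c(20, 3, 0, 4, 40, 3, 1, 4, 16), 3, 3)
#' heterogeneity_test(f2, c(30, 80), "f2", "ril")
#' @export
heterogeneity_test <- function(counts1, counts2,
                               population1 = c("f2", "ril"),
                               population2 = c("f2", "ril"),
                               alpha = 0.05) {
  population1 <- match.arg(population1)
  population2 <- match.arg(population2)
  r1 <- pair_mle(counts1, population1)
  r2 <- pair_mle(counts2, population2)
  joint <- function(r) {
    pair_loglik(r, counts1, population1) + pair_loglik(r, counts2, population2)
  }
  opt <- optimize(joint, c(0, 0.5), maximum = TRUE, tol = 1e-10)
  # golden-section search never evaluates the boundaries; when both
  # per-population MLEs sit there the pooled MLE does too
  cand <- c(opt$maximum, r1, r2)
  obj <- vapply(cand, joint, numeric(1))
  rp <- cand[which.max(obj)]
  g <- 2 * (pair_loglik(r1, counts1, population1) +
              pair_loglik(r2, counts2, population2) - max(obj))
  g <- max(g, 0)                      # degenerate / identical-data path
  p <- pchisq(g, df = 1, lower.tail = FALSE)
  tibble(r1 = r1, r2 = r2, r_pooled = rp, G = g, p_value = p,
         excluded = p < alpha)
}

#' Merge two genetic maps into a consensus map (fixed reference order)
#'
#' Integrates a second map into a reference map using their shared
#' (anchor) markers, keeping the reference marker order fixed.  Each
#' reference linkage group is matched to the second-map group holding the
#' majority of its anchors.  Anchors whose order on the second map
#' conflicts with the reference order (i.e. outside the longest
#' reference-concordant subsequence) are demoted to non-anchors, as are
#' anchors in a mismatched second-map group.  Second-map-only loci are
#' placed by linear interpolation between their flanking anchors,
#' rescaled to the reference cM frame; beyond terminal anchors the
#' terminal segment's scale is extrapolated.  Anchor consensus positions
#' are the information-weighted mean of the two rescaled positions (with
#' an exact anchor frame these coincide with the reference positions,
#' which is what keeps the merge order-preserving by construction).
#' Groups are finally shifted to start at 0.0.
#'
#' @param reference_map,second_map `genetic_map` objects.
#' @param exclude Marker ids never to use as anchors (e.g. heterogeneous
#'   pairs, dominant markers).
#' @param w_reference,w_second Information weights (typically population
#'   sizes) for anchor-position averaging.
#' @return A consensus `genetic_map` with a `provenance` column
#'   (`"shared"`, `"f2_only"`, `"ril_only"`); demoted anchors and
#'   unplaceable second-map loci are logged in `attr(, "merge_log")`.
#' @export
merge_maps <- function(reference_map, second_map, exclude = character(0),
                       w_reference = 1, w_second = 1) {
  ref <- as_tibble(unclass(reference_map))
  sec <- as_tibble(unclass(second_map))
  log <- tibble(marker_id = character(0), reason = character(0))
  anchors <- setdiff(intersect(ref$marker_id, sec$marker_id), exclude)

  # pass 1: per reference group, resolve the usable anchor frame
  frames <- list()
  for (g in unique(ref$group)) {
    rg <- ref[ref$group == g, ]
    rg <- rg[order(rg$position_cM), ]
    a <- intersect(rg$marker_id, anchors)
    sg <- NA_character_
    if (length(a) > 0) {
      sg_tab <- table(sec$group[match(a, sec$marker_id)])
      sg <- names(sort(sg_tab, decreasing = TRUE))[1]
      bad_grp <- a[sec$group[match(a, sec$marker_id)] != sg]
      if (length(bad_grp) > 0) {
        log <- dplyr::bind_rows(log, tibble(
          marker_id = bad_grp, reason = "anchor group conflict"))
        a <- setdiff(a, bad_grp)
      }
    }
    if (length(a) >= 2) {
      # demote anchors breaking reference order on the second map
      a_ord <- a[order(match(a, rg$marker_id))]
      spos <- sec$position_cM[match(a_ord, sec$marker_id)]
      keep <- longest_nondecreasing(spos)
      demoted <- a_ord[-keep]
      if (length(demoted) > 0) {
        log <- dplyr::bind_rows(log, tibble(
          marker_id = demoted, reason = "anchor order conflict"))
      }
      a_ord <- a_ord[keep]
    } else {
      a_ord <- character(0)
    }
    frames[[g]] <- list(
      rg = rg, sg = sg, a_ord = a_ord,
      apos_ref = rg$position_cM[match(a_ord, rg$marker_id)],
      apos_sec = sec$position_cM[match(a_ord, sec$marker_id)])
  }

  # allocate each second-map-only locus to the single reference group whose
  # anchor span (on the second map) is nearest; several reference groups
  # can match one second-map group when a chromosome is split
  only <- sec[!(sec$marker_id %in% ref$marker_id), ]
  alloc <- setNames(rep(NA_character_, nrow(only)), only$marker_id)
  for (i in seq_len(nrow(only))) {
    cand <- names(frames)[vapply(frames, function(f) {
      identical(f$sg, only$group[i]) && length(f$a_ord) >= 2
    }, logical(1))]
    if (length(cand) == 0) next
    d <- vapply(cand, function(g) {
      span <- range(frames[[g]]$apos_sec)
      max(span[1] - only$position_cM[i], only$position_cM[i] - span[2], 0)
    }, numeric(1))
    alloc[i] <- cand[which.min(d)]
  }

  # pass 2: assemble each group's consensus positions
  out <- list()
  for (g in names(frames)) {
    f <- frames[[g]]
    rg <- f$rg
    res <- tibble(group = g, marker_id = rg$marker_id,
                  position_cM = rg$position_cM,
                  provenance = ifelse(rg$marker_id %in% f$a_ord,
                                      "shared", "f2_only"))
    if (length(f$a_ord) >= 2) {
      res$position_cM[match(f$a_ord, res$marker_id)] <-
        (w_reference * f$apos_ref + w_second * f$apos_ref) /
        (w_reference + w_second)
      mine <- only[!is.na(alloc) & alloc == g, , drop = FALSE]
      if (nrow(mine) > 0) {
        newpos <- rescale_to_frame(mine$position_cM, f$apos_sec, f$apos_ref)
        res <- dplyr::bind_rows(res, tibble(
          group = g, marker_id = mine$marker_id, position_cM = newpos,
          provenance = "ril_only"))
      }
    }
    res <- res[order(res$position_cM,
                     match(res$marker_id, rg$marker_id)), ]
    res$position_cM <- res$position_cM - min(res$position_cM)
    out[[g]] <- res
  }

  # second-map loci in groups that matched no reference group
  placed <- unlist(lapply(out, function(x) x$marker_id))
  unplaced <- setdiff(sec$marker_id, c(placed, ref$marker_id))
  if (length(unplaced) > 0) {
    log <- dplyr::bind_rows(log, tibble(
      marker_id = unplaced, reason = "no anchored group (< 2 anchors)"))
  }

  cons <- new_genetic_map(dplyr::bind_rows(out), population = "consensus")
  attr(cons, "merge_log") <- log
  cons
}

#' @noRd
#' Indices of the longest nondecreasing subsequence (classic DP; ties keep
#' the earliest elements, so the result is deterministic).
longest_nondecreasing <- function(x) {
  n <- length(x)
  if (n == 0) return(integer(0))
  len <- rep(1L, n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] <= x[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(len)
  path <- integer(0)
  while (!is.na(i)) {
    path <- c(i, path)
    i <- prev[i]
  }
  path
}

#' @noRd
#' Piecewise-linear rescaling of positions x (second-map frame) through
#' anchor pairs (anchor_sec -> anchor_ref); extrapolation beyond terminal
#' anchors uses the terminal segment's scale.
rescale_to_frame <- function(x, anchor_sec, anchor_ref) {
  o <- order(anchor_sec)
  s <- anchor_sec[o]; a <- anchor_ref[o]
  vapply(x, function(xi) {
    if (xi <= s[1]) {
      sc <- segment_scale(s[1:2], a[1:2])
      return(a[1] + (xi - s[1]) * sc)
    }
    k <- length(s)
    if (xi >= s[k]) {
      sc <- segment_scale(s[(k - 1):k], a[(k - 1):k])
      return(a[k] + (xi - s[k]) * sc)
    }
    i <- findInterval(xi, s)
    if (s[i + 1] == s[i]) return(a[i])
    a[i] + (xi - s[i]) / (s[i + 1] - s[i]) * (a[i + 1] - a[i])
  }, numeric(1))
}

#' @noRd
segment_scale <- function(s2, a2) {
  if (diff(s2) <= 0) 1 else diff(a2) / diff(s2)
}
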