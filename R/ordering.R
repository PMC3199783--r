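#' Order markers within a linkage group
#'
#' Finds a locus order minimising the sum of adjacent recombination
#' fractions (SARF) by greedy insertion followed by repeated window-2/3
#' reversal (two-opt) passes.  Orientation is normalised so that the
#' lexicographically smaller terminal marker comes first.  A missing
#' pairwise estimate inside the group is filled by the shortest-path
#' additive distance through the available pairs (Kosambi scale), with a
#' message.
#'
#' @param markers Character vector: the group's marker ids.
#' @param estimates Pair table from [estimate_rf()].
#' @return Character vector of marker ids in map order.
#' @export
order_markers <- function(markers, estimates) {
  k <- length(markers)
  if (k < 2) return(markers)
  rmat <- rf_matrix(markers, estimates)
  if (k == 2) return(normalize_orientation(markers))

  placed <- as.integer(arrayInd(which.min(rmat + diag(Inf, k)), dim(rmat)))
  left <- setdiff(seq_len(k), placed)
  while (length(left) > 0) {
    # Prim-style: next marker is the unplaced one closest to the path
    dmin <- vapply(left, function(i) min(rmat[i, placed]), numeric(1))
    nxt <- left[which.min(dmin)]
    best <- Inf; best_pos <- 1L
    for (pos in 0:length(placed)) {
      cand <- append(placed, nxt, after = pos)
      s <- sarf(cand, rmat)
      if (s < best) { best <- s; best_pos <- pos }
    }
    placed <- append(placed, nxt, after = best_pos)
    left <- setdiff(left, nxt)
  }

  # window-2/3 reversal passes until no improvement
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (w in 2:3) {
      if (w > k) next
      for (s in 1:(k - w + 1)) {
        cand <- placed
        cand[s:(s + w - 1)] <- rev(cand[s:(s + w - 1)])
        if (sarf(cand, rmat) < sarf(placed, rmat) - 1e-12) {
          placed <- cand
          improved <- TRUE
        }
      }
    }
  }
  normalize_orientation(markers[placed])
}

#' @noRd
sarf <- function(ord, rmat) {
  sum(rmat[cbind(ord[-length(ord)], ord[-1])])
}

#' @noRd
normalize_orientation <- function(ids) {
  if (ids[length(ids)] < ids[1]) rev(ids) else ids
}

#' @noRd
#' Symmetric rf matrix for a marker set; missing entries filled by
#' shortest-path additive Kosambi distance over known pairs.
rf_matrix <- function(markers, estimates) {
  k <- length(markers)
  rmat <- matrix(NA_real_, k, k, dimnames = list(markers, markers))
  sel <- estimates$marker_a %in% markers & estimates$marker_b %in% markers
  ea <- estimates$marker_a[sel]; eb <- estimates$marker_b[sel]
  rmat[cbind(ea, eb)] <- estimates$r_hat[sel]
  rmat[cbind(eb, ea)] <- estimates$r_hat[sel]
  diag(rmat) <- 0
  if (anyNA(rmat)) {
    message("filling ", sum(is.na(rmat)) / 2,
            " missing pairwise estimate(s) by shortest-path distance")
    d <- matrix(Inf, k, k, dimnames = dimnames(rmat))
    known <- !is.na(rmat)
    d[known] <- kosambi_distance(pmin(rmat[known], 0.4999))
    for (via in seq_len(k)) {            # Floyd-Warshall, groups are small
      d <- pmin(d, outer(d[, via], d[via, ], `+`))
    }
    d[is.infinite(d)] <- kosambi_distance(0.4999)
    filled <- kosambi_inverse(d)
    rmat[is.na(rmat)] <- filled[is.na(rmat)]
  }
  rmat
}

#' Cumulative Kosambi map positions for an ordered group
#'
#' Converts adjacent-pair recombination fractions of an ordered locus list
#' into cumulative Kosambi cM positions, first locus at 0.0.  Adjacent
#' estimates at or above `r_cap` are capped there (a weakly joined
#' adjacency is kept on the map rather than aborting the group).
#'
#' @param ordered_markers Marker ids in map order.
#' @param estimates Pair table from [estimate_rf()].
#' @param r_cap Cap applied to adjacent recombination fractions.
#' @return Tibble with `marker_id`, `position_cM`.
#' @export
map_positions <- function(ordered_markers, estimates, r_cap = 0.49) {
  if (length(ordered_markers) == 1) {
    return(tibble(marker_id = ordered_markers, position_cM = 0))
  }
  rmat <- rf_matrix(ordered_markers, estimates)
  adj <- rmat[cbind(ordered_markers[-length(ordered_markers)],
                    ordered_markers[-1])]
  d <- kosambi_distance(pmin(adj, r_cap))
  tibble(marker_id = ordered_markers, position_cM = c(0, cumsum(d)))
}
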