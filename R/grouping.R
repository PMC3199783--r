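#' Partition markers into linkage groups
#'
#' Builds the linkage graph with an edge between two markers whenever their
#' two-point LOD is at least `lod_threshold` and the estimated
#' recombination fraction is below 0.5, then takes single-linkage connected
#' components.  Groups are numbered deterministically by descending size,
#' ties broken by the lexicographically smallest member id.  Markers whose
#' every pairwise estimate is unreliable (too few informative individuals)
#' are excluded from grouping and reported with status `"excluded"`;
#' markers with no qualifying edge become singleton groups (status
#' `"singleton"`).
#'
#' @param estimates Pair table from [estimate_rf()] (columns `marker_a`,
#'   `marker_b`, `r_hat`, `lod`, `reliable`).
#' @param lod_threshold Minimum LOD for a linkage edge (default 4.0).
#' @param markers Optional character vector fixing the marker universe;
#'   defaults to all markers present in `estimates`.
#' @return A tibble with columns `marker_id`, `group` (integer; `NA` for
#'   excluded markers), `group_size`, `status` in
#'   `{"grouped","singleton","excluded"}`.
#' @export
group_markers <- function(estimates, lod_threshold = 4.0, markers = NULL) {
  if (is.null(markers)) {
    markers <- unique(c(estimates$marker_a, estimates$marker_b))
  }
  reliable <- if ("reliable" %in% names(estimates)) estimates$reliable else TRUE
  excluded <- setdiff(markers,
                      unique(c(estimates$marker_a[reliable],
                               estimates$marker_b[reliable])))
  usable <- setdiff(markers, excluded)

  edge <- reliable & estimates$lod >= lod_threshold & estimates$r_hat < 0.5 &
    estimates$marker_a %in% usable & estimates$marker_b %in% usable
  comp <- connected_components(usable,
                               estimates$marker_a[edge],
                               estimates$marker_b[edge])

  sizes <- table(comp)
  first_member <- vapply(split(names(comp), comp),
                         function(ms) min(ms), character(1))
  ord <- order(-as.integer(sizes), first_member[names(sizes)])
  renum <- setNames(seq_along(ord), names(sizes)[ord])

  out <- tibble(
    marker_id = usable,
    group = as.integer(renum[as.character(comp[usable])]),
    group_size = as.integer(sizes[as.character(comp[usable])])
  )
  out$status <- ifelse(out$group_size == 1, "singleton", "grouped")
  if (length(excluded) > 0) {
    out <- dplyr::bind_rows(out, tibble(
      marker_id = excluded, group = NA_integer_,
      group_size = 0L, status = "excluded"
    ))
  }
  arrange(out, .data$group, .data$marker_id)
}

#' @noRd
#' Union-find connected components over a node/edge list; returns a named
#' integer vector of component labels.
connected_components <- function(nodes, from, to) {
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    ri <- find(match(from[k], nodes))
    rj <- find(match(to[k], nodes))
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_along(nodes), find, numeric(1))
  setNames(as.integer(roots), nodes)
}
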