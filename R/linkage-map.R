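#' Genetic map objects
#'
#' A `genetic_map` is a tibble with one row per mapped locus and columns
#' `group` (linkage-group label, character), `marker_id` and `position_cM`
#' (cumulative Kosambi position, first locus of each group at 0.0), plus
#' optional `provenance` (`"f2_only"`, `"ril_only"`, `"shared"`) on
#' consensus maps.  Positions are nondecreasing within a group and every
#' marker belongs to at most one group.
#'
#' @param x A data frame with at least `group`, `marker_id`,
#'   `position_cM`.
#' @param population Optional population tag kept as an attribute.
#' @return A `genetic_map` tibble.
#' @export
new_genetic_map <- function(x, population = NULL) {
  if (nrow(x) == 0) {
    x <- tibble(group = character(0), marker_id = character(0),
                position_cM = numeric(0))
  }
  stopifnot(all(c("group", "marker_id", "position_cM") %in% names(x)))
  x <- as_tibble(x)
  x$group <- as.character(x$group)
  if (anyDuplicated(x$marker_id) > 0) stop("marker mapped in > 1 group")
  bad <- x %>% group_by(.data$group) %>%
    summarise(ok = !is.unsorted(.data$position_cM) &&
                abs(.data$position_cM[1]) < 1e-9) %>%
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("positions must be nondecreasing from 0.0 in group(s): ",
         paste(bad$group, collapse = ", "))
  }
  structure(x, class = c("genetic_map", class(x)),
            population = population)
}

#' Build a linkage map from a genotype table
#'
#' Runs the full single-population mapping chain: segregation screening
#' (markers distorted at P < `distortion_alpha` are dropped), all-pairs
#' two-point estimation, LOD-threshold grouping, optional pruning of
#' spurious single-edge joins between well-populated subgroups, SARF
#' ordering within each group, and cumulative Kosambi positions.
#'
#' Grouping by single linkage can chain two true chromosomes through one
#' spurious high-LOD edge (with hundreds of markers a handful of null
#' pairs clears any fixed LOD cutoff).  When `split_bridges = TRUE`, an
#' edge is removed if it is the *only* connection (a graph bridge)
#' between two parts of a group that each hold at least
#' `bridge_min_side` markers and its estimated recombination fraction is
#' at least `bridge_min_r`: genuine neighbours inside a dense group are
#' supported by many parallel edges, a spurious join by exactly one.
#' The defaults are deliberately aggressive (sides of 2, r of 0.10):
#' cutting a genuine group in two only fragments a chromosome into
#' co-labelled pieces, while a false join corrupts the map.
#'
#' A second safeguard acts after ordering: a linkage group is cut wherever
#' two adjacent ordered loci show an estimated recombination fraction of at
#' least `split_gap_r` (default 0.30, about 35 cM Kosambi) -- an adjacency
#' that dense maps never produce genuinely but that spurious attachments
#' always do.  Fragments are renumbered as groups in their own right.
#'
#' @param geno Genotype table (first column id, marker columns A/H/B).
#' @param population `"f2"` or `"ril"`.
#' @param lod_threshold Grouping LOD threshold (default 4.0).
#' @param min_informative Minimum informative individuals per pair.
#' @param distortion_alpha Segregation-distortion exclusion level.
#' @param split_bridges,bridge_min_side,bridge_min_r Spurious-join pruning
#'   (see Details).
#' @param split_gap_r Adjacent recombination fraction at which an ordered
#'   group is cut into fragments.
#' @return A `genetic_map`; excluded / unplaced markers are recorded in
#'   `attr(map, "exclusions")` (tibble `marker_id`, `reason`), singleton
#'   groups in `attr(map, "singletons")`.
#' @export
make_linkage_map <- function(geno, population = c("f2", "ril"),
                             lod_threshold = 4.0, min_informative = 10,
                             distortion_alpha = 0.01,
                             split_bridges = TRUE, bridge_min_side = 2,
                             bridge_min_r = 0.10, split_gap_r = 0.30) {
  population <- match.arg(population)
  counts <- count_genotypes(geno)
  seg <- suppressWarnings(test_segregation(counts, population,
                                           alpha = distortion_alpha))
  excl <- tibble(marker_id = character(0), reason = character(0))
  if (any(seg$distorted)) {
    excl <- dplyr::bind_rows(excl, tibble(
      marker_id = seg$marker_id[seg$distorted],
      reason = sprintf("segregation distortion (P < %g)", distortion_alpha)
    ))
    geno <- geno[, c(names(geno)[1],
                     setdiff(names(geno)[-1], seg$marker_id[seg$distorted]))]
  }

  est <- estimate_rf(geno, population, min_informative = min_informative)
  grp <- group_markers(est, lod_threshold = lod_threshold)
  if (split_bridges) {
    grp <- split_bridge_joins(grp, est, lod_threshold,
                              min_side = bridge_min_side,
                              min_r = bridge_min_r)
  }
  if (any(grp$status == "excluded")) {
    excl <- dplyr::bind_rows(excl, tibble(
      marker_id = grp$marker_id[grp$status == "excluded"],
      reason = "too few informative pairs"
    ))
  }
  singletons <- grp$marker_id[grp$status == "singleton"]

  placed <- grp %>% filter(.data$status == "grouped")
  fragments <- list()
  for (ms in split(placed$marker_id, placed$group)) {
    ord <- order_markers(ms, est)
    if (length(ord) >= 2) {
      rmat <- suppressMessages(rf_matrix(ord, est))
      adj <- rmat[cbind(ord[-length(ord)], ord[-1])]
      cuts <- which(adj >= split_gap_r)
      starts <- c(1, cuts + 1)
      ends <- c(cuts, length(ord))
    } else {
      starts <- 1; ends <- length(ord)
    }
    for (k in seq_along(starts)) {
      fragments[[length(fragments) + 1]] <- ord[starts[k]:ends[k]]
    }
  }
  # fragments of one marker join the singletons; the rest are renumbered
  # deterministically (descending size, ties by smallest member id)
  singletons <- c(singletons,
                  unlist(fragments[lengths(fragments) == 1]))
  fragments <- fragments[lengths(fragments) > 1]
  if (length(fragments) > 0) {
    ord_frag <- order(-lengths(fragments),
                      vapply(fragments, min, character(1)))
    fragments <- fragments[ord_frag]
  }
  pieces <- lapply(fragments, function(ord) map_positions(ord, est))
  names(pieces) <- as.character(seq_along(pieces))
  out <- dplyr::bind_rows(pieces, .id = "group")
  map <- new_genetic_map(out, population = population)
  attr(map, "exclusions") <- excl
  attr(map, "singletons") <- singletons
  attr(map, "estimates") <- est
  map
}

#' @noRd
#' Remove single-edge joins between well-populated subgroups, then
#' recompute components and renumber.  See make_linkage_map().
split_bridge_joins <- function(groups, estimates, lod_threshold,
                               min_side = 2, min_r = 0.10) {
  placed <- groups$marker_id[groups$status %in% c("grouped", "singleton")]
  reliable <- if ("reliable" %in% names(estimates)) estimates$reliable else TRUE
  edge_ok <- reliable & estimates$lod >= lod_threshold &
    estimates$r_hat < 0.5 &
    estimates$marker_a %in% placed & estimates$marker_b %in% placed
  ed <- estimates[edge_ok, c("marker_a", "marker_b", "r_hat")]

  if (nrow(ed) > 0) {
    repeat {
      g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                         vertices = placed)
      br <- igraph::bridges(g)
      if (length(br) == 0) break
      ends <- igraph::ends(g, br)
      key <- function(a, b) paste(pmin(a, b), pmax(a, b))
      r_br <- ed$r_hat[match(key(ends[, 1], ends[, 2]),
                             key(ed$marker_a, ed$marker_b))]
      removed <- FALSE
      for (k in order(-r_br)) {          # weakest linkage first
        if (r_br[k] < min_r) break
        comp2 <- igraph::components(
          igraph::delete_edges(g, br[k]))$membership
        sides <- table(comp2)[as.character(comp2[ends[k, ]])]
        if (all(sides >= min_side)) {
          ed <- ed[key(ed$marker_a, ed$marker_b) !=
                     key(ends[k, 1], ends[k, 2]), ]
          removed <- TRUE
          break
        }
      }
      if (!removed) break
    }
  }

  comp <- connected_components(placed, ed$marker_a, ed$marker_b)
  sizes <- table(comp)
  first_member <- vapply(split(names(comp), comp), min, character(1))
  ord <- order(-as.integer(sizes), first_member[names(sizes)])
  renum <- setNames(seq_along(ord), names(sizes)[ord])
  out <- tibble(
    marker_id = placed,
    group = as.integer(renum[as.character(comp[placed])]),
    group_size = as.integer(sizes[as.character(comp[placed])])
  )
  out$status <- ifelse(out$group_size == 1, "singleton", "grouped")
  dplyr::bind_rows(out, groups[groups$status == "excluded", ]) %>%
    arrange(.data$group, .data$marker_id)
}

#' Label linkage groups with chromosome names
#'
#' Assigns each linkage group the chromosome label carried by the majority
#' of its markers found in a reference label table (the role played by
#' previously published maps of the species).  Groups without any labelled
#' marker keep their numeric group id.  If two groups receive the same
#' chromosome label they are suffixed `"a"`, `"b"`, ... in descending
#' group size (the conventional notation for a split linkage group).
#'
#' @param map A `genetic_map`.
#' @param labels Data frame `marker_id`, `chromosome`.
#' @return The map with a `chromosome` column.
#' @export
assign_lg_labels <- function(map, labels) {
  stopifnot(all(c("marker_id", "chromosome") %in% names(labels)))
  lab <- setNames(as.character(labels$chromosome), labels$marker_id)
  per_group <- vapply(split(map$marker_id, map$group), function(ms) {
    hits <- lab[intersect(ms, names(lab))]
    if (length(hits) == 0) return(NA_character_)
    names(sort(table(hits), decreasing = TRUE))[1]
  }, character(1))
  sizes <- table(map$group)
  chrom <- per_group
  chrom[is.na(chrom)] <- names(per_group)[is.na(chrom)]
  for (dup in unique(chrom[duplicated(chrom)])) {
    idx <- which(chrom == dup)
    idx <- idx[order(-as.integer(sizes[names(per_group)[idx]]))]
    chrom[idx] <- paste0(dup, letters[seq_along(idx)])
  }
  out <- map
  out$chromosome <- unname(chrom[as.character(out$group)])
  out
}

#' @noRd
round1 <- function(x) floor(x * 10 + 0.5 + 1e-9) / 10

#' Per-group and total map statistics
#'
#' Summarises a genetic map the way linkage-mapping studies tabulate them:
#' loci per group, group length in cM, and mean marker interval computed
#' as length / loci to one decimal.  A `total` row aggregates all groups
#' (total length / total loci).  If the map carries a `provenance` column
#' (consensus maps), per-source locus counts are included.
#'
#' @param map A `genetic_map` (or data frame with `group`, `marker_id`,
#'   `position_cM`).
#' @return Tibble with `group`, `n_loci`, `length_cM`,
#'   `mean_interval_cM`, plus provenance counts when available; final row
#'   `group == "total"`.
#' @export
map_summary <- function(map) {
  per <- map %>% group_by(.data$group) %>%
    summarise(n_loci = dplyr::n(),
              length_cM = max(.data$position_cM)) %>%
    ungroup()
  per$mean_interval_cM <- round1(per$length_cM / per$n_loci)
  tot <- tibble(group = "total",
                n_loci = sum(per$n_loci),
                length_cM = sum(per$length_cM),
                mean_interval_cM = round1(sum(per$length_cM) /
                                            sum(per$n_loci)))
  if ("provenance" %in% names(map)) {
    prov <- map %>% group_by(.data$group) %>%
      summarise(n_shared = sum(.data$provenance == "shared"),
                n_second_only = sum(.data$provenance == "ril_only"))
    per <- dplyr::left_join(per, prov, by = "group")
    tot$n_shared <- sum(prov$n_shared)
    tot$n_second_only <- sum(prov$n_second_only)
  }
  dplyr::bind_rows(per, tot)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @rdname new_genetic_map
#' @param ... Unused.
#' @export
tidy.genetic_map <- function(x, ...) {
  as_tibble(unclass(x)[setdiff(names(x), character(0))])
}

#' @rdname new_genetic_map
#' @export
glance.genetic_map <- function(x, ...) {
  s <- map_summary(x)
  tot <- s[s$group == "total", ]
  tibble(n_groups = nrow(s) - 1L, n_loci = tot$n_loci,
         total_cM = tot$length_cM,
         mean_interval_cM = tot$mean_interval_cM)
}

#' Plot a genetic map
#'
#' Draws each linkage group as a vertical bar with one tick per locus.
#'
#' @param object A `genetic_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genetic_map <- function(object, ...) {
  grp_col <- if ("chromosome" %in% names(object)) "chromosome" else "group"
  df <- as_tibble(unclass(object))
  df$grp <- df[[grp_col]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grp, y = .data$position_cM)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$grp), linewidth = 2,
                       colour = "grey80") +
    ggplot2::geom_point(shape = 95, size = 4) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "linkage group", y = "position (cM)") +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
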