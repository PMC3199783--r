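#' Assign source-map markers to target chromosomes
#'
#' Joins each locus of a source genetic map to a target-genome chromosome:
#' directly when the marker itself is present on the target reference map
#' (`evidence = "direct_map"`), else transitively through the scaffold
#' carrying its unique virtual-PCR hit (`evidence = "scaffold_transitive"`):
#' the chromosome carried by at least a `majority` fraction of the
#' reference markers on that scaffold, at their median cM.  Scaffolds whose
#' reference markers disagree without a qualifying majority yield status
#' `"ambiguous"`; scaffolds with no reference marker, multi-copy and
#' no-hit markers yield `"unanchored"` (with the reason).
#'
#' @param source_map Data frame of source-map loci: `marker_id`,
#'   `chromosome`, `position_cM` (a `genetic_map` with `chromosome` column
#'   works as-is).
#' @param hits Virtual-PCR hit table ([virtual_pcr()]).
#' @param classification Per-marker classification ([classify_hits()]).
#' @param reference_map Target reference map: `marker_id`, `chromosome`,
#'   `position_cM`, `scaffold`.
#' @param majority Fraction of a scaffold's reference markers that must
#'   agree on one chromosome (default 2/3).
#' @return Tibble of anchored markers: `marker_id`, `source_chrom`,
#'   `source_cM`, `target_chrom`, `target_cM`, `evidence`, `status`,
#'   `reason`.
#' @export
anchor_markers <- function(source_map, hits, classification, reference_map,
                           majority = 2 / 3) {
  stopifnot(all(c("marker_id", "chromosome", "position_cM", "scaffold")
                %in% names(reference_map)))
  src <- as_tibble(unclass(source_map))
  chrom_col <- if ("chromosome" %in% names(src)) "chromosome" else "group"
  uniq_scaffold <- hits$scaffold[match(src$marker_id, hits$marker_id)]
  cls <- classification$class[match(src$marker_id,
                                    classification$marker_id)]

  per_marker <- function(i) {
    id <- src$marker_id[i]
    base <- tibble(marker_id = id,
                   source_chrom = as.character(src[[chrom_col]][i]),
                   source_cM = src$position_cM[i],
                   target_chrom = NA_character_, target_cM = NA_real_,
                   evidence = NA_character_, status = "unanchored",
                   reason = NA_character_)
    j <- match(id, reference_map$marker_id)
    if (!is.na(j)) {
      base$target_chrom <- as.character(reference_map$chromosome[j])
      base$target_cM <- reference_map$position_cM[j]
      base$evidence <- "direct_map"
      base$status <- "assigned"
      return(base)
    }
    if (is.na(cls[i]) || cls[i] %in% c("no_hit", "multi_copy",
                                       "repeat_region")) {
      base$reason <- if (is.na(cls[i])) "not screened" else cls[i]
      return(base)
    }
    sc <- uniq_scaffold[i]
    refs <- reference_map[reference_map$scaffold %in% sc, , drop = FALSE]
    if (nrow(refs) == 0) {
      base$reason <- "scaffold has no mapped reference marker"
      return(base)
    }
    tab <- sort(table(as.character(refs$chromosome)), decreasing = TRUE)
    if (tab[1] / nrow(refs) >= majority) {
      chr <- names(tab)[1]
      base$target_chrom <- chr
      base$target_cM <- median(refs$position_cM[refs$chromosome == chr])
      base$evidence <- "scaffold_transitive"
      base$status <- "assigned"
    } else {
      base$status <- "ambiguous"
      base$reason <- paste0("scaffold maps to chromosomes ",
                            paste(names(tab), collapse = "/"))
    }
    base
  }
  if (nrow(src) == 0) {
    return(tibble(marker_id = character(0), source_chrom = character(0),
                  source_cM = numeric(0), target_chrom = character(0),
                  target_cM = numeric(0), evidence = character(0),
                  status = character(0), reason = character(0)))
  }
  dplyr::bind_rows(lapply(seq_len(nrow(src)), per_marker))
}

#' Detect syntenic blocks along one or all source chromosomes
#'
#' Walks the anchored loci of each source chromosome in map order and
#' reports maximal runs of consecutive assigned loci sharing one target
#' chromosome.  Up to `max_gap_markers` interleaved loci with a different
#' target may be absorbed per block (they are counted as discordant, not
#' as members); unanchored or ambiguous loci are transparent.  Runs with
#' fewer than `min_block_markers` members are reported with
#' `type = "singleton"` rather than `"block"`.  Block intervals span the
#' first to last member locus on both genomes.
#'
#' @param anchored Anchored-marker table from [anchor_markers()].
#' @param min_block_markers Minimum members for a run to count as a block.
#' @param max_gap_markers Discordant loci absorbable per block.
#' @param direction `"source"` walks each source chromosome (the default);
#'   `"target"` walks each target chromosome and segments by source
#'   chromosome (the view needed to see, e.g., a nested fusion as
#'   A-B-A along the fused chromosome).
#' @return Tibble: `source_chrom`, `block_id`, `target_chrom`, `start_cM`,
#'   `end_cM`, `target_start_cM`, `target_end_cM`, `n_markers`,
#'   `n_discordant`, `type`, and a `members` list-column of marker ids.
#' @export
detect_blocks <- function(anchored, min_block_markers = 2,
                          max_gap_markers = 1,
                          direction = c("source", "target")) {
  direction <- match.arg(direction)
  if (direction == "target") {
    anchored <- swap_anchored(anchored)
  }
  res <- list()
  for (chr in unique(anchored$source_chrom)) {
    loc <- anchored %>%
      filter(.data$source_chrom == chr, .data$status == "assigned") %>%
      arrange(.data$source_cM, .data$marker_id)
    if (nrow(loc) == 0) next
    runs <- segment_targets(loc$target_chrom, max_gap_markers)
    for (b in seq_along(runs)) {
      members <- loc[runs[[b]]$members, , drop = FALSE]
      res[[length(res) + 1]] <- tibble(
        source_chrom = chr,
        block_id = paste0(chr, ".", b),
        target_chrom = runs[[b]]$target,
        start_cM = members$source_cM[1],
        end_cM = members$source_cM[nrow(members)],
        target_start_cM = min(members$target_cM),
        target_end_cM = max(members$target_cM),
        n_markers = nrow(members),
        n_discordant = runs[[b]]$n_discordant,
        type = if (nrow(members) >= min_block_markers) "block"
               else "singleton",
        members = list(members$marker_id)
      )
    }
  }
  if (length(res) == 0) {
    return(tibble(source_chrom = character(0), block_id = character(0),
                  target_chrom = character(0), start_cM = numeric(0),
                  end_cM = numeric(0), target_start_cM = numeric(0),
                  target_end_cM = numeric(0), n_markers = integer(0),
                  n_discordant = integer(0), type = character(0),
                  members = list()))
  }
  dplyr::bind_rows(res)
}

#' @noRd
#' Greedy left-to-right segmentation of a target-chromosome string: each
#' block starts at the next unconsumed locus, extends through loci with
#' the same target, and may absorb runs of differing targets as long as
#' the block's total absorbed count stays within `budget` and the block's
#' target resumes immediately after the run.  Returns a list of
#' list(target, members = indices, n_discordant).
segment_targets <- function(targets, budget) {
  n <- length(targets)
  out <- list()
  i <- 1L
  while (i <= n) {
    t <- targets[i]
    members <- i
    used <- 0L
    j <- i + 1L
    while (j <= n) {
      if (targets[j] == t) {
        members <- c(members, j)
        j <- j + 1L
      } else {
        d <- 0L
        while (j + d <= n && targets[j + d] != t) d <- d + 1L
        if (j + d <= n && used + d <= budget) {
          used <- used + d
          members <- c(members, j + d)
          j <- j + d + 1L
        } else break
      }
    }
    out[[length(out) + 1]] <- list(target = t, members = members,
                                   n_discordant = used)
    i <- j
  }
  out
}

#' @noRd
#' Exchange the source and target roles of an anchored-marker table
#' (assigned loci only; the others have no target position to walk).
swap_anchored <- function(anchored) {
  a <- anchored %>% filter(.data$status == "assigned")
  tibble(marker_id = a$marker_id,
         source_chrom = a$target_chrom, source_cM = a$target_cM,
         target_chrom = a$source_chrom, target_cM = a$source_cM,
         evidence = a$evidence, status = a$status, reason = a$reason)
}

#' Colinearity statistic for a syntenic block
#'
#' Kendall's tau between the source and target cM positions of a block's
#' members, classified `colinear` (tau >= 0.8), `inverted`
#' (tau <= -0.8) or `rearranged` otherwise; blocks with fewer than three
#' positioned members are `undetermined`.
#'
#' @param source_cM,target_cM Member positions.
#' @return One-row tibble `tau`, `colinearity`.
#' @export
colinearity <- function(source_cM, target_cM) {
  ok <- !is.na(source_cM) & !is.na(target_cM)
  if (sum(ok) < 3) {
    return(tibble(tau = NA_real_, colinearity = "undetermined"))
  }
  tau <- suppressWarnings(stats::cor(source_cM[ok], target_cM[ok],
                                     method = "kendall"))
  cls <- if (is.na(tau)) "undetermined"
         else if (tau >= 0.8) "colinear"
         else if (tau <= -0.8) "inverted"
         else "rearranged"
  tibble(tau = tau, colinearity = cls)
}

#' Annotate blocks with colinearity
#'
#' @param blocks Block table from [detect_blocks()].
#' @param anchored The anchored-marker table the blocks came from.
#' @return `blocks` with `tau` and `colinearity` columns.
#' @export
add_colinearity <- function(blocks, anchored) {
  ann <- lapply(seq_len(nrow(blocks)), function(i) {
    m <- anchored[match(blocks$members[[i]], anchored$marker_id), ]
    colinearity(m$source_cM, m$target_cM)
  })
  dplyr::bind_cols(blocks, dplyr::bind_rows(ann))
}

#' @noRd
#' Sort chromosome labels naturally: Roman numerals by value, Arabic by
#' number, anything else lexicographically after those.
chrom_sort <- function(x) {
  rom <- suppressWarnings(as.integer(utils::as.roman(x)))
  num <- suppressWarnings(as.numeric(x))
  key <- ifelse(!is.na(num), num, ifelse(!is.na(rom), rom, Inf))
  x[order(key, x)]
}

#' Chromosome correspondence table
#'
#' Summarises genome-wide syntenic blocks into, for each chromosome of
#' either genome, the ordered set of partner chromosomes supported by at
#' least one block (singleton runs do not count).  Both directions are
#' emitted from the same block list, so the partner relation is
#' symmetric.
#'
#' @param blocks Block table from [detect_blocks()].
#' @return Tibble: `view` (`"source"` or `"target"`), `chromosome`,
#'   `partners` (list-column), `partners_label` (comma-separated, in
#'   natural chromosome order), `n_markers` supporting.
#' @export
correspondence_table <- function(blocks) {
  b <- blocks %>% filter(.data$type == "block")
  if (nrow(b) == 0) {
    return(tibble(view = character(0), chromosome = character(0),
                  partners = list(), partners_label = character(0),
                  n_markers = integer(0)))
  }
  one_view <- function(chrom_col, partner_col, view) {
    b %>% group_by(chromosome = .data[[chrom_col]]) %>%
      summarise(partners = list(chrom_sort(unique(.data[[partner_col]]))),
                n_markers = sum(.data$n_markers)) %>%
      mutate(view = view,
             partners_label = vapply(.data$partners, paste,
                                     character(1), collapse = ", ")) %>%
      select("view", "chromosome", "partners", "partners_label",
             "n_markers")
  }
  dplyr::bind_rows(one_view("source_chrom", "target_chrom", "source"),
                   one_view("target_chrom", "source_chrom", "target")) %>%
    group_by(.data$view) %>%
    dplyr::arrange(match(.data$chromosome,
                         chrom_sort(unique(.data$chromosome))),
                   .by_group = TRUE) %>%
    ungroup()
}

#' Stacked-segment views of syntenic blocks
#'
#' Serialises the block list into ordered per-chromosome segment records
#' for both genomes, ready for plotting or export: each chromosome is a
#' stack of segments, one per block, in map order, labelled with the
#' partner chromosome; segment lengths are proportional to marker counts.
#'
#' @param blocks Block table from [detect_blocks()] (source direction).
#' @param target_blocks Optional block table from
#'   `detect_blocks(anchored, direction = "target")`; when given, the
#'   target view is segmented along the target chromosomes themselves
#'   (required to see nested or alternating fusion patterns); otherwise
#'   the target view is the projection of the source-direction blocks.
#' @return Tibble of class `synteny_views`: `view`, `chromosome`,
#'   `segment`, `partner`, `n_markers`, `span_cM`.
#' @export
block_views <- function(blocks, target_blocks = NULL) {
  one_view <- function(b, view) {
    b %>% filter(.data$type == "block") %>%
      arrange(.data$source_chrom, .data$start_cM) %>%
      group_by(.data$source_chrom) %>%
      mutate(segment = dplyr::row_number()) %>% ungroup() %>%
      dplyr::transmute(view = view, chromosome = .data$source_chrom,
                       segment = .data$segment,
                       partner = .data$target_chrom,
                       n_markers = .data$n_markers,
                       span_cM = .data$end_cM - .data$start_cM)
  }
  src <- one_view(blocks, "source")
  tgt <- if (!is.null(target_blocks)) {
    one_view(target_blocks, "target")
  } else {
    blocks %>% filter(.data$type == "block") %>%
      arrange(.data$target_chrom, .data$target_start_cM) %>%
      group_by(.data$target_chrom) %>%
      mutate(segment = dplyr::row_number()) %>% ungroup() %>%
      dplyr::transmute(view = "target", chromosome = .data$target_chrom,
                       segment = .data$segment,
                       partner = .data$source_chrom,
                       n_markers = .data$n_markers,
                       span_cM = .data$target_end_cM - .data$target_start_cM)
  }
  out <- dplyr::bind_rows(src, tgt)
  class(out) <- c("synteny_views", class(out))
  out
}

#' Plot syntenic block views
#'
#' Stacked bar per chromosome, one segment per syntenic block, coloured
#' by partner chromosome, heights proportional to marker counts.
#'
#' @param object A `synteny_views` table from [block_views()].
#' @param view `"source"` (12-chromosome genome) or `"target"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synteny_views <- function(object, view = "source", ...) {
  df <- as_tibble(unclass(object)) %>% filter(.data$view == !!view)
  df$chromosome <- factor(df$chromosome,
                          levels = chrom_sort(unique(df$chromosome)))
  ggplot2::ggplot(df,
                  ggplot2::aes(x = .data$chromosome, y = .data$n_markers,
                               fill = .data$partner)) +
    ggplot2::geom_col(position = ggplot2::position_stack(reverse = TRUE),
                      colour = "grey30", linewidth = 0.2) +
    ggplot2::labs(x = "chromosome", y = "marker loci",
                  fill = "partner") +
    ggplot2::theme_minimal()
}
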