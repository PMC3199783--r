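#' Pipeline parameters
#'
#' All tunable stage parameters of [run_pipeline()], with their defaults:
#' grouping LOD threshold 4.0, segregation-distortion cutoff P < 0.01,
#' heterogeneity exclusion P < 0.05, virtual-PCR mismatch/clamp/product
#' window (1 mismatch, 3-base 3' clamp, 40-5,000 bp), scaffold-majority
#' fraction 2/3, and block parameters (minimum 2 members, 1 absorbable
#' discordant).
#'
#' @param ... Overrides of the defaults.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(lod_threshold = 4.0, min_informative = 10,
            distortion_alpha = 0.01, het_alpha = 0.05,
            max_mismatch = 1, clamp3 = 3, min_size = 40, max_size = 5000,
            majority = 2 / 3, min_block_markers = 2, max_gap_markers = 1)
  over <- list(...)
  stopifnot(all(names(over) %in% names(p)))
  p[names(over)] <- over
  p
}

#' @noRd
#' RIL recombinant / informative counts for one marker pair.
ril_pair_counts <- function(calls_a, calls_b) {
  a <- ifelse(calls_a %in% c("A", "B"), calls_a, NA)
  b <- ifelse(calls_b %in% c("A", "B"), calls_b, NA)
  ok <- !is.na(a) & !is.na(b)
  c(sum(a[ok] != b[ok]), sum(ok))
}

#' Heterogeneity screening of shared anchor markers
#'
#' Runs the two-population heterogeneity test over every adjacent pair of
#' shared markers (adjacency taken along the reference map's order) and
#' returns the test table plus the markers to exclude from anchoring
#' (members of any pair heterogeneous at `alpha`).
#'
#' @param map_ref Reference (F2) `genetic_map`.
#' @param geno_f2,geno_ril Genotype tables of the two populations.
#' @param shared Shared marker ids (default: intersection of the genotype
#'   tables).
#' @param alpha Exclusion level.
#' @return List: `tests` tibble (pair, G, p_value, excluded),
#'   `excluded_markers`.
#' @export
screen_anchors <- function(map_ref, geno_f2, geno_ril, shared = NULL,
                           alpha = 0.05) {
  if (is.null(shared)) {
    shared <- intersect(names(geno_f2)[-1], names(geno_ril)[-1])
  }
  ref <- as_tibble(unclass(map_ref)) %>%
    filter(.data$marker_id %in% shared) %>%
    arrange(.data$group, .data$position_cM)
  tests <- list()
  for (g in unique(ref$group)) {
    ids <- ref$marker_id[ref$group == g]
    if (length(ids) < 2) next
    for (k in seq_len(length(ids) - 1)) {
      a <- ids[k]; b <- ids[k + 1]
      ht <- heterogeneity_test(
        joint_counts_f2(geno_f2[[a]], geno_f2[[b]]),
        ril_pair_counts(geno_ril[[a]], geno_ril[[b]]),
        "f2", "ril", alpha = alpha)
      tests[[length(tests) + 1]] <-
        dplyr::bind_cols(tibble(marker_a = a, marker_b = b, group = g), ht)
    }
  }
  tests <- dplyr::bind_rows(tests)
  excluded <- if (nrow(tests) > 0) {
    unique(c(tests$marker_a[tests$excluded], tests$marker_b[tests$excluded]))
  } else character(0)
  list(tests = tests, excluded_markers = excluded)
}

#' Run the full comparative-mapping pipeline
#'
#' Orchestrates every stage end-to-end: per-population linkage maps
#' (segregation screening, two-point EM, LOD grouping, ordering, Kosambi
#' positions), linkage-group labelling, heterogeneity screening of shared
#' anchors, fixed-order consensus merging, virtual PCR of the consensus
#' markers against the target assembly, hit classification, transitive
#' chromosome assignment, syntenic-block detection with colinearity, and
#' the chromosome-correspondence table.
#'
#' @param study A `synmap_study` from [simulate_study()], or `NULL` if
#'   the individual inputs are given.
#' @param geno_f2,geno_ril Genotype tables.
#' @param primers Primer table (`marker_id`, `fwd`, `rev`).
#' @param assembly Target assembly (`DNAStringSet` or FASTA path).
#' @param reference_map Target reference map (`marker_id`, `chromosome`,
#'   `position_cM`, `scaffold`).
#' @param lg_labels Source-map label anchors (`marker_id`, `chromosome`).
#' @param repeats Optional repeat intervals (`scaffold`, `start`, `end`).
#' @param params Parameter list from [pipeline_params()].
#' @return A `synmap_run` list with components `map_f2`, `map_ril`,
#'   `heterogeneity`, `consensus`, `hits`, `classification`, `anchored`,
#'   `blocks`, `correspondence`, `views`, `log`.
#' @export
run_pipeline <- function(study = NULL, geno_f2 = NULL, geno_ril = NULL,
                         primers = NULL, assembly = NULL,
                         reference_map = NULL, lg_labels = NULL,
                         repeats = NULL, params = pipeline_params()) {
  if (!is.null(study)) {
    stopifnot(inherits(study, "synmap_study"))
    geno_f2 <- study$geno_f2; geno_ril <- study$geno_ril
    primers <- study$panel; assembly <- study$derived$scaffolds
    reference_map <- study$reference_map; lg_labels <- study$lg_labels
  }
  for (nm in c("geno_f2", "geno_ril", "primers", "assembly",
               "reference_map", "lg_labels")) {
    if (is.null(get(nm))) stop("missing input: ", nm)
  }
  if (is.character(assembly)) assembly <- load_assembly(assembly)

  map_f2 <- make_linkage_map(geno_f2, "f2",
                             lod_threshold = params$lod_threshold,
                             min_informative = params$min_informative,
                             distortion_alpha = params$distortion_alpha)
  map_ril <- make_linkage_map(geno_ril, "ril",
                              lod_threshold = params$lod_threshold,
                              min_informative = params$min_informative,
                              distortion_alpha = params$distortion_alpha)
  map_f2 <- assign_lg_labels(map_f2, lg_labels)
  map_ril <- assign_lg_labels(map_ril, lg_labels)

  shared <- intersect(map_f2$marker_id, map_ril$marker_id)
  het <- screen_anchors(map_f2, geno_f2, geno_ril, shared,
                        alpha = params$het_alpha)
  consensus <- merge_maps(map_f2, map_ril,
                          exclude = het$excluded_markers,
                          w_reference = nrow(geno_f2),
                          w_second = nrow(geno_ril))
  consensus <- assign_lg_labels(consensus, lg_labels)

  # only linkage groups assignable to a chromosome (via the label anchors)
  # enter synteny inference; unassigned fragments are logged
  base_label <- sub("(?<=[A-ZIVX0-9])[a-z]+$", "", consensus$chromosome,
                    perl = TRUE)
  labelled <- base_label %in% unique(as.character(lg_labels$chromosome))
  unassigned_loci <- consensus$marker_id[!labelled]
  synteny_input <- consensus[labelled, ]

  cons_primers <- primers[primers$marker_id %in% synteny_input$marker_id, ]
  hits <- virtual_pcr(cons_primers, assembly,
                      max_mismatch = params$max_mismatch,
                      clamp3 = params$clamp3, min_size = params$min_size,
                      max_size = params$max_size, with_sequence = FALSE)
  classification <- classify_hits(hits, cons_primers$marker_id, repeats)

  anchored <- anchor_markers(synteny_input, hits, classification,
                             reference_map, majority = params$majority)
  blocks <- detect_blocks(anchored,
                          min_block_markers = params$min_block_markers,
                          max_gap_markers = params$max_gap_markers)
  blocks <- add_colinearity(blocks, anchored)
  # split linkage groups ("IVa"/"IVb") are analysed per group, then
  # reported under the base chromosome label
  blocks$source_chrom <- sub("(?<=[A-ZIVX0-9])[a-z]+$", "",
                             blocks$source_chrom, perl = TRUE)
  corr <- correspondence_table(blocks)
  target_blocks <- detect_blocks(anchored,
                                 min_block_markers = params$min_block_markers,
                                 max_gap_markers = params$max_gap_markers,
                                 direction = "target")
  target_blocks$target_chrom <- sub("(?<=[A-ZIVX0-9])[a-z]+$", "",
                                    target_blocks$target_chrom, perl = TRUE)
  views <- block_views(blocks, target_blocks)

  log <- tibble(
    stage = c("f2_map", "ril_map", "shared_anchors",
              "anchors_excluded_heterogeneous", "consensus_loci",
              "loci_in_unassigned_groups",
              "no_hit", "multi_copy", "assigned", "ambiguous",
              "blocks"),
    n = c(nrow(map_f2), nrow(map_ril), length(shared),
          length(het$excluded_markers), nrow(consensus),
          length(unassigned_loci),
          sum(classification$class == "no_hit"),
          sum(classification$class == "multi_copy"),
          sum(anchored$status == "assigned"),
          sum(anchored$status == "ambiguous"),
          sum(blocks$type == "block")))

  structure(list(map_f2 = map_f2, map_ril = map_ril,
                 heterogeneity = het$tests, consensus = consensus,
                 hits = hits, classification = classification,
                 anchored = anchored, blocks = blocks,
                 target_blocks = target_blocks,
                 correspondence = corr, views = views,
                 params = params, log = log),
            class = "synmap_run")
}

#' @rdname run_pipeline
#' @param x A `synmap_run`.
#' @param ... Unused.
#' @export
tidy.synmap_run <- function(x, ...) x$correspondence

#' @rdname run_pipeline
#' @export
glance.synmap_run <- function(x, ...) {
  s <- setNames(as.list(x$log$n), x$log$stage)
  as_tibble(s)
}

#' @export
print.synmap_run <- function(x, ...) {
  cat("<synmap_run>\n")
  print(x$log)
  invisible(x)
}

#' Marker-transferability report
#'
#' Cross-species screening arithmetic: per marker source, the number of
#' markers tested, the number amplifying in the other species, and the
#' number polymorphic, with percentages to one decimal (round half up):
#' amplified/tested, polymorphic/amplified and the overall
#' transferability polymorphic/tested.  An `overall` row sums the
#' sources.  Percentages recomputed from the report's own counts always
#' reproduce its printed percentages.
#'
#' @param screen Tibble: `source`, `n_tested`, `n_amplified`,
#'   `n_polymorphic`.
#' @return The report tibble with percentage columns `pct_amplified`,
#'   `pct_polymorphic`, `pct_transfer`.
#' @export
transferability_report <- function(screen) {
  stopifnot(all(c("source", "n_tested", "n_amplified", "n_polymorphic")
                %in% names(screen)),
            all(screen$n_amplified <= screen$n_tested),
            all(screen$n_polymorphic <= screen$n_amplified))
  tot <- tibble(source = "overall",
                n_tested = sum(screen$n_tested),
                n_amplified = sum(screen$n_amplified),
                n_polymorphic = sum(screen$n_polymorphic))
  out <- dplyr::bind_rows(as_tibble(screen), tot)
  pct <- function(num, den) ifelse(den > 0, round1(100 * num / den), 0)
  out$pct_amplified <- pct(out$n_amplified, out$n_tested)
  out$pct_polymorphic <- pct(out$n_polymorphic, out$n_amplified)
  out$pct_transfer <- pct(out$n_polymorphic, out$n_tested)
  out
}

#' Anchoring bookkeeping
#'
#' Tallies a per-marker hit classification into the counts reported when
#' anchoring a consensus map on a draft genome: total markers, no-hit
#' markers, markers lost to repeat regions, and the assignable remainder
#' (total minus no-hit minus repeat-region; multi-copy markers still have
#' scaffold locations and count as assignable).
#'
#' @param classification Tibble with `marker_id` and `class` in
#'   `{no_hit, unique, multi_copy, repeat_region}`.
#' @return One-row tibble: `n_total`, `n_no_hit`, `n_multi_copy`,
#'   `n_repeat_region`, `n_assignable`.
#' @export
marker_bookkeeping <- function(classification) {
  cl <- classification$class
  tibble(n_total = length(cl),
         n_no_hit = sum(cl == "no_hit"),
         n_multi_copy = sum(cl == "multi_copy"),
         n_repeat_region = sum(cl == "repeat_region"),
         n_assignable = length(cl) - sum(cl == "no_hit") -
           sum(cl == "repeat_region"))
}

#' Shared-anchor tally
#'
#' Counts shared (anchor) markers by their source genome, with a total.
#'
#' @param anchors Tibble with `marker_id` and `source`.
#' @return Tibble of per-source counts plus a `total` row.
#' @export
anchor_tally <- function(anchors) {
  per <- anchors %>% group_by(.data$source) %>%
    summarise(n = dplyr::n()) %>% ungroup()
  dplyr::bind_rows(per, tibble(source = "total", n = nrow(anchors)))
}
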