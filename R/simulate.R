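#' @noRd
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @noRd
#' Consensus-map preset used as the default simulated study scale:
#' 12 chromosomes, per-chromosome cM lengths and locus counts of a
#' saturated melon consensus map (~401 loci, ~1,029 cM).
default_chrom_lengths <- function() {
  setNames(c(107.3, 105.7, 81.8, 116.9, 58.2, 64.4,
             108.0, 87.2, 71.9, 62.5, 87.4, 77.6),
           as.character(utils::as.roman(1:12)))
}

#' @noRd
default_markers_per_chrom <- function() {
  setNames(c(38L, 33L, 24L, 50L, 28L, 25L, 41L, 39L, 27L, 30L, 43L, 23L),
           as.character(utils::as.roman(1:12)))
}

#' Simulate an ancestral 12-chromosome genome and marker panel
#'
#' Generates the source genome of the comparative-mapping simulation: a
#' set of chromosomes with uniformly placed codominant marker loci, each
#' locus carrying a unique random primer pair flanking a planted amplicon
#' insert.  The physical sequence of each chromosome is a concatenation
#' of per-marker blocks (random spacer + forward primer + insert +
#' reverse-complemented reverse primer), so every marker is a planted
#' virtual-PCR ground truth.  Defaults reproduce the scale of a saturated
#' melon consensus map: 12 chromosomes, 401 loci, ~1,029 cM.
#'
#' @param n_chrom Number of chromosomes (named by Roman numerals).
#' @param chrom_lengths_cM Named numeric vector of map lengths; default
#'   the 12-chromosome preset.
#' @param markers_per_chrom Named integer vector of locus counts per
#'   chromosome; default the preset locus counts.
#' @param seed RNG seed (determinism contract: same seed, same genome).
#' @param primer_len Range of primer lengths (nt).
#' @param insert_len Amplicon insert length (bp).
#' @param spacer_len Inter-marker spacer length (bp).
#' @return An `ancestral_genome` list: `markers` tibble (`marker_id`,
#'   `chrom`, `cM`, `fwd`, `rev`, `block_seq`), `chrom_lengths`,
#'   `terminal_spacer`, `seed`.
#' @export
simulate_ancestral_genome <- function(n_chrom = 12,
                                      chrom_lengths_cM = NULL,
                                      markers_per_chrom = NULL,
                                      seed = 1,
                                      primer_len = c(20, 24),
                                      insert_len = 160,
                                      spacer_len = 300) {
  if (is.null(chrom_lengths_cM)) {
    chrom_lengths_cM <- if (n_chrom == 12) default_chrom_lengths() else
      setNames(rep(100, n_chrom),
               as.character(utils::as.roman(seq_len(n_chrom))))
  }
  if (is.null(markers_per_chrom)) {
    markers_per_chrom <- if (n_chrom == 12) default_markers_per_chrom() else
      setNames(rep(20L, n_chrom), names(chrom_lengths_cM))
  }
  stopifnot(length(chrom_lengths_cM) == n_chrom,
            length(markers_per_chrom) == n_chrom,
            all(chrom_lengths_cM > 0), all(markers_per_chrom >= 2))
  set.seed(seed)

  total <- sum(markers_per_chrom)
  seen <- character(0)
  make_primer <- function() {
    repeat {
      p <- rand_dna(sample(primer_len[1]:primer_len[2], 1))
      if (!(p %in% seen)) {
        seen <<- c(seen, p)
        return(p)
      }
      message("duplicate primer collision; regenerating")
    }
  }

  rows <- list()
  idx <- 0L
  for (ch in names(chrom_lengths_cM)) {
    m <- markers_per_chrom[[ch]]
    pos <- sort(runif(m, 0, chrom_lengths_cM[[ch]]))
    for (k in seq_len(m)) {
      idx <- idx + 1L
      fwd <- make_primer(); rev <- make_primer()
      block <- paste0(rand_dna(spacer_len), fwd, rand_dna(insert_len),
                      revcomp(rev))
      rows[[idx]] <- tibble(
        marker_id = sprintf("SM%04d", idx), chrom = ch, cM = pos[k],
        fwd = fwd, rev = rev, block_seq = block)
    }
  }
  structure(list(markers = dplyr::bind_rows(rows),
                 chrom_lengths = chrom_lengths_cM,
                 terminal_spacer = rand_dna(spacer_len),
                 seed = seed),
            class = "ancestral_genome")
}

#' Chromosome sequences of a simulated genome
#'
#' @param genome An `ancestral_genome` or `derived_genome`.
#' @return A `DNAStringSet`, one sequence per chromosome.
#' @export
genome_sequences <- function(genome) {
  mk <- genome$markers
  ord_col <- if ("order" %in% names(mk)) "order" else "cM"
  seqs <- vapply(split(mk, mk$chrom), function(d) {
    d <- d[order(d[[ord_col]]), ]
    paste0(paste(d$block_seq, collapse = ""), genome$terminal_spacer)
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs[chrom_sort(unique(mk$chrom))])
  attr(out, "name") <- "simulated"
  out
}

#' Rearrangement scenarios
#'
#' A scenario is an ordered list of events turning the ancestral
#' chromosome set into a derived genome: `fusion` events (styles
#' `side_by_side`, `alternating`, `nested`, `three_way`) combine source
#' chromosomes or chromosome segments into one derived chromosome;
#' `intact` carries a chromosome over unchanged; `inversion` reverses a
#' fractional interval of a derived chromosome.  Segment sources are
#' written with [seg()].  `default_scenario()` is the 12-to-7 fusion
#' pattern used throughout the package: C1 = II+XII alternating,
#' C2 = V + first halves of XI and III, C3 = IV+VI side-by-side,
#' C4 = VII with the first half of VIII nested inside, C5 = IX+X
#' alternating, C6 = second halves of III, XI and VIII, C7 = I intact
#' with one internal inversion.
#'
#' @param events List of event lists (see Details).
#' @return A `rearrangement_scenario`.
#' @export
rearrangement_scenario <- function(events) {
  structure(list(events = events), class = "rearrangement_scenario")
}

#' @rdname rearrangement_scenario
#' @param chrom Source chromosome name.
#' @param from,to Fractional cM interval of the source chromosome.
#' @export
seg <- function(chrom, from = 0, to = 1) {
  stopifnot(from >= 0, to <= 1, from < to)
  list(chrom = chrom, from = from, to = to)
}

#' @rdname rearrangement_scenario
#' @export
default_scenario <- function() {
  rearrangement_scenario(list(
    list(type = "fusion", style = "alternating", name = "1",
         sources = list(seg("II"), seg("XII"))),
    list(type = "fusion", style = "three_way", name = "2",
         sources = list(seg("V"), seg("XI", 0, 0.5), seg("III", 0, 0.5))),
    list(type = "fusion", style = "side_by_side", name = "3",
         sources = list(seg("IV"), seg("VI"))),
    list(type = "fusion", style = "nested", name = "4",
         sources = list(seg("VII"), seg("VIII", 0, 0.5))),
    list(type = "fusion", style = "alternating", name = "5",
         sources = list(seg("IX"), seg("X"))),
    list(type = "fusion", style = "three_way", name = "6",
         sources = list(seg("III", 0.5, 1), seg("XI", 0.5, 1),
                        seg("VIII", 0.5, 1))),
    list(type = "intact", name = "7", sources = list(seg("I"))),
    list(type = "inversion", chromosome = "7", from = 0.3, to = 0.7)
  ))
}

#' Apply a rearrangement scenario to an ancestral genome
#'
#' Builds the derived genome: marker order and cM positions on the
#' derived chromosomes (intra-segment spacing preserved, a small fixed
#' junction gap between segments), the physical sequence plan, and the
#' planted truth (segment list per derived chromosome, the 12-to-7
#' correspondence, inversions).  Source chromosomes not consumed by any
#' event are carried over intact under their own names.  The derived
#' sequence is fragmented into scaffolds with [assemble_scaffolds()]
#' (log-normal target sizes, cuts at marker-block boundaries).
#'
#' @param ancestral An `ancestral_genome`.
#' @param scenario A `rearrangement_scenario`.
#' @param junction_gap_cM Map gap inserted at segment junctions.
#' @param scaffold_meanlog,scaffold_sdlog Log-normal scaffold-size target
#'   (bp).
#' @return A `derived_genome` list: `markers` (with `chrom`, `order`,
#'   `cM`, `source_chrom`, `source_cM`, `orientation`, `corruption`),
#'   `segments`, `inversions`, `scaffolds` (`DNAStringSet`),
#'   `scaffold_truth`, `marker_scaffold`, `terminal_spacer`.
#' @export
apply_rearrangements <- function(ancestral, scenario = default_scenario(),
                                 junction_gap_cM = 2,
                                 scaffold_meanlog = log(1500),
                                 scaffold_sdlog = 0.35) {
  mk <- ancestral$markers
  lens <- ancestral$chrom_lengths
  consumed <- lapply(lens, function(...) cbind(from = numeric(0),
                                               to = numeric(0)))

  take <- function(s) {
    if (!s$chrom %in% names(lens)) {
      stop("event references unknown chromosome ", s$chrom)
    }
    prev <- consumed[[s$chrom]]
    if (nrow(prev) > 0 &&
        any(s$from < prev[, "to"] & prev[, "from"] < s$to)) {
      stop("event references a consumed chromosome interval: ", s$chrom)
    }
    consumed[[s$chrom]] <<- rbind(prev, cbind(from = s$from, to = s$to))
    L <- lens[[s$chrom]]
    sel <- mk$chrom == s$chrom & mk$cM >= s$from * L &
      (mk$cM < s$to * L | (s$to == 1 & mk$cM <= L))
    d <- mk[sel, ]
    d[order(d$cM), ]
  }

  halves <- function(d) {
    mid <- (min(d$cM) + max(d$cM)) / 2
    list(d[d$cM <= mid, ], d[d$cM > mid, ])
  }

  derived <- list()   # chrom name -> list of segment tibbles
  orient <- list()    # chrom name -> per-segment orientation
  inversions <- list()
  for (ev in scenario$events) {
    if (ev$type %in% c("fusion", "intact")) {
      segs <- lapply(ev$sources, take)
      style <- if (ev$type == "intact") "side_by_side" else ev$style
      pieces <- switch(style,
        side_by_side = , three_way = segs,
        alternating = {
          stopifnot(length(segs) == 2)
          h1 <- halves(segs[[1]]); h2 <- halves(segs[[2]])
          list(h1[[1]], h2[[1]], h1[[2]], h2[[2]])
        },
        nested = {
          stopifnot(length(segs) == 2)
          h <- halves(segs[[1]])
          list(h[[1]], segs[[2]], h[[2]])
        },
        stop("unknown fusion style: ", style))
      pieces <- pieces[vapply(pieces, nrow, integer(1)) > 0]
      derived[[ev$name]] <- pieces
      orient[[ev$name]] <- rep(1L, length(pieces))
    } else if (ev$type == "inversion") {
      inversions[[length(inversions) + 1]] <- ev
    } else if (ev$type == "translocation") {
      d <- take(ev$source)
      derived[[ev$dest]] <- c(derived[[ev$dest]], list(d))
      orient[[ev$dest]] <- c(orient[[ev$dest]], 1L)
    } else {
      stop("unknown event type: ", ev$type)
    }
  }
  # untouched chromosomes pass through intact
  for (ch in names(lens)) {
    if (nrow(consumed[[ch]]) == 0) {
      derived[[ch]] <- list(take(seg(ch)))
      orient[[ch]] <- 1L
    }
  }

  out_rows <- list()
  seg_rows <- list()
  for (ch in names(derived)) {
    pos0 <- 0
    parts <- list()
    for (si in seq_along(derived[[ch]])) {
      d <- derived[[ch]][[si]]
      rel <- d$cM - min(d$cM)
      parts[[si]] <- tibble(
        marker_id = d$marker_id, chrom = ch, segment = si,
        cM = pos0 + rel, source_chrom = d$chrom, source_cM = d$cM,
        orientation = 1L, fwd = d$fwd, rev = d$rev,
        block_seq = d$block_seq)
      seg_rows[[length(seg_rows) + 1]] <- tibble(
        chrom = ch, segment = si, source_chrom = d$chrom[1],
        n_markers = nrow(d), start_cM = pos0,
        end_cM = pos0 + max(rel))
      pos0 <- pos0 + max(rel) + junction_gap_cM
    }
    out_rows[[ch]] <- dplyr::bind_rows(parts)
  }
  markers <- dplyr::bind_rows(out_rows) %>%
    arrange(match(.data$chrom, names(derived)), .data$cM) %>%
    group_by(.data$chrom) %>%
    mutate(order = dplyr::row_number()) %>% ungroup()

  for (ev in inversions) {
    d <- markers$chrom == ev$chromosome
    L <- max(markers$cM[d])
    i1 <- ev$from * L; i2 <- ev$to * L
    inside <- d & markers$cM >= i1 & markers$cM <= i2
    markers$cM[inside] <- i1 + i2 - markers$cM[inside]
    markers$orientation[inside] <- -markers$orientation[inside]
  }
  markers <- markers %>%
    arrange(match(.data$chrom, names(derived)), .data$cM) %>%
    group_by(.data$chrom) %>%
    mutate(order = dplyr::row_number()) %>% ungroup()
  markers$corruption <- "none"

  der <- structure(list(
    markers = markers,
    segments = dplyr::bind_rows(seg_rows),
    inversions = inversions,
    terminal_spacer = ancestral$terminal_spacer,
    scaffold_meanlog = scaffold_meanlog,
    scaffold_sdlog = scaffold_sdlog
  ), class = "derived_genome")
  assemble_scaffolds(der)
}

#' Fragment a derived genome into scaffolds
#'
#' Cuts each derived chromosome's block sequence into scaffolds whose
#' sizes follow the genome's log-normal target, with cuts only at
#' marker-block boundaries (clean substrings; assembly gaps are not
#' simulated).  Records the scaffold-to-chromosome and
#' marker-to-scaffold truth.
#'
#' @param derived A `derived_genome`.
#' @return The genome with `scaffolds`, `scaffold_truth` and
#'   `marker_scaffold` filled in.
#' @export
assemble_scaffolds <- function(derived) {
  mk <- derived$markers %>% arrange(match(.data$chrom, unique(.data$chrom)),
                                    .data$order)
  scf_seq <- character(0)
  scf_truth <- list()
  marker_rows <- list()
  scf_i <- 0L
  for (ch in unique(mk$chrom)) {
    d <- mk[mk$chrom == ch, ]
    blocks <- ifelse(d$orientation < 0,
                     vapply(d$block_seq, revcomp, character(1)),
                     d$block_seq)
    extra <- attr(derived, "extra_blocks")
    i <- 1L
    while (i <= nrow(d)) {
      scf_i <- scf_i + 1L
      id <- sprintf("scf%04d", scf_i)
      target <- stats::rlnorm(1, derived$scaffold_meanlog,
                              derived$scaffold_sdlog)
      bp <- 0
      seq_parts <- character(0)
      first <- i
      while (i <= nrow(d) && (bp < target || i == first)) {
        marker_rows[[length(marker_rows) + 1]] <- tibble(
          marker_id = d$marker_id[i], scaffold = id, block_start_bp = bp + 1)
        seq_parts <- c(seq_parts, blocks[i])
        bp <- bp + nchar(blocks[i])
        i <- i + 1L
      }
      if (i > nrow(d)) seq_parts <- c(seq_parts, derived$terminal_spacer)
      scf_seq[id] <- paste(seq_parts, collapse = "")
      scf_truth[[length(scf_truth) + 1]] <- tibble(
        chrom = ch, scaffold = id,
        n_blocks = i - first, length_bp = nchar(scf_seq[id]))
    }
  }
  # duplicated amplicons planted by corrupt(): append to random scaffolds
  extra <- attr(derived, "extra_blocks")
  if (!is.null(extra) && length(extra) > 0) {
    tgt <- sample(names(scf_seq), length(extra), replace = TRUE)
    for (k in seq_along(extra)) {
      scf_seq[tgt[k]] <- paste0(scf_seq[tgt[k]], extra[[k]])
    }
  }
  scaffolds <- Biostrings::DNAStringSet(scf_seq)
  attr(scaffolds, "name") <- "simulated"
  derived$scaffolds <- scaffolds
  derived$scaffold_truth <- dplyr::bind_rows(scf_truth)
  derived$marker_scaffold <- dplyr::bind_rows(marker_rows)
  derived
}

#' Planted correspondence table of a derived genome
#'
#' The chromosome-correspondence truth implied by the scenario's segment
#' list, in the same two-view layout as [correspondence_table()].
#'
#' @param derived A `derived_genome`.
#' @param min_markers Segments with fewer planted markers are ignored.
#' @return Tibble `view`, `chromosome`, `partners`, `partners_label`.
#' @export
planted_correspondence <- function(derived, min_markers = 2) {
  s <- derived$segments %>% filter(.data$n_markers >= min_markers)
  src <- s %>% group_by(chromosome = .data$source_chrom) %>%
    summarise(partners = list(chrom_sort(unique(.data$chrom)))) %>%
    mutate(view = "source")
  tgt <- s %>% group_by(chromosome = .data$chrom) %>%
    summarise(partners = list(chrom_sort(unique(.data$source_chrom)))) %>%
    mutate(view = "target")
  dplyr::bind_rows(src, tgt) %>%
    mutate(partners_label = vapply(.data$partners, paste, character(1),
                                   collapse = ", ")) %>%
    group_by(.data$view) %>%
    dplyr::arrange(match(.data$chromosome,
                         chrom_sort(unique(.data$chromosome))),
                   .by_group = TRUE) %>%
    ungroup() %>%
    select("view", "chromosome", "partners", "partners_label")
}

#' Degrade a marker panel for robustness testing
#'
#' Randomly corrupts planted markers of a derived genome: `no_hit`
#' replaces the marker's primer landing sites with random sequence (the
#' primer pair no longer amplifies), `multi_copy` plants a second copy of
#' the amplicon elsewhere in the genome, `mis_anchor` moves the marker's
#' physical block to a random other chromosome (its map position is
#' untouched, so downstream anchoring is wrong in a known way).  Truth
#' labels are retained in the `corruption` column and scaffolds are
#' rebuilt.
#'
#' @param derived A `derived_genome`.
#' @param rates Named numeric: `no_hit`, `multi_copy`, `mis_anchor`
#'   probabilities (sum <= 1).
#' @param seed Optional RNG seed.
#' @return The degraded `derived_genome`.
#' @export
corrupt <- function(derived, rates = c(no_hit = 0, multi_copy = 0,
                                       mis_anchor = 0), seed = NULL) {
  rates <- rates[c("no_hit", "multi_copy", "mis_anchor")]
  rates[is.na(rates)] <- 0
  stopifnot(all(rates >= 0), sum(rates) <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (sum(rates) == 0) return(derived)
  mk <- derived$markers
  u <- runif(nrow(mk))
  cls <- rep("none", nrow(mk))
  cls[u < rates["no_hit"]] <- "no_hit"
  cls[u >= rates["no_hit"] & u < sum(rates[1:2])] <- "multi_copy"
  cls[u >= sum(rates[1:2]) & u < sum(rates)] <- "mis_anchor"
  mk$corruption <- cls

  extra <- list()
  for (i in which(cls != "none")) {
    if (cls[i] == "no_hit") {
      # scramble both primer landing sites inside the block
      b <- mk$block_seq[i]
      b <- sub(mk$fwd[i], rand_dna(nchar(mk$fwd[i])), b, fixed = TRUE)
      b <- sub(revcomp(mk$rev[i]), rand_dna(nchar(mk$rev[i])), b,
               fixed = TRUE)
      mk$block_seq[i] <- b
    } else if (cls[i] == "multi_copy") {
      extra[[length(extra) + 1]] <- mk$block_seq[i]
    } else {
      mk$chrom[i] <- sample(setdiff(unique(mk$chrom), mk$chrom[i]), 1)
      mk$cM[i] <- runif(1, 0, max(mk$cM[mk$chrom == mk$chrom[i]]))
    }
  }
  mk <- mk %>% arrange(match(.data$chrom, unique(.data$chrom)), .data$cM) %>%
    group_by(.data$chrom) %>% mutate(order = dplyr::row_number()) %>%
    ungroup()
  derived$markers <- mk
  attr(derived, "extra_blocks") <- extra
  assemble_scaffolds(derived)
}

#' Simulate a mapping population
#'
#' Generates genotypes by a no-interference (Haldane) crossover process
#' along each chromosome of a genetic map: adjacent loci recombine with
#' probability `haldane_inverse(d)`.  `"f2"` individuals are the product
#' of two independent F1 meioses; `"ril"` lines are selfed for
#' `generations` rounds from the F1 (F8 by default), leaving residual
#' heterozygosity of about `(1/2)^generations` per locus.
#'
#' @param map Tibble `marker_id`, `chrom`, `cM`.
#' @param population `"f2"` or `"ril"`.
#' @param n Individuals / lines.
#' @param seed Optional RNG seed.
#' @param missing_rate Uniform missing-call rate.
#' @param generations Selfing meiosis rounds for RILs (default 7).
#' @return Genotype tibble: `id` plus one `A`/`H`/`B` column per marker
#'   in map order.
#' @export
simulate_population <- function(map, population = c("f2", "ril"), n,
                                seed = NULL, missing_rate = 0.02,
                                generations = 7) {
  population <- match.arg(population)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1, all(c("marker_id", "chrom", "cM") %in% names(map)))
  cols <- list()
  for (ch in unique(map$chrom)) {
    d <- map[map$chrom == ch, ]
    d <- d[order(d$cM), ]
    r_adj <- haldane_inverse(diff(d$cM))
    m <- nrow(d)
    gamete <- function(hA, hB) {
      phase <- matrix(0L, n, m)
      phase[, 1] <- rbinom(n, 1, 0.5)
      if (m > 1) {
        for (j in 2:m) {
          phase[, j] <- (phase[, j - 1] + rbinom(n, 1, r_adj[j - 1])) %% 2L
        }
      }
      ifelse(phase == 0L, hA, hB)
    }
    zero <- matrix(0L, n, m); one <- matrix(1L, n, m)
    if (population == "f2") {
      g <- gamete(zero, one) + gamete(zero, one)
    } else {
      hA <- zero; hB <- one
      for (gen in seq_len(generations)) {
        nA <- gamete(hA, hB)
        nB <- gamete(hA, hB)
        hA <- nA; hB <- nB
      }
      g <- hA + hB
    }
    calls <- matrix(c("A", "H", "B")[g + 1L], n, m)
    colnames(calls) <- d$marker_id
    cols[[ch]] <- calls
  }
  calls <- do.call(cbind, cols)
  calls <- calls[, map$marker_id[order(match(map$chrom, unique(map$chrom)),
                                       map$cM)], drop = FALSE]
  if (missing_rate > 0) {
    calls[matrix(runif(length(calls)) < missing_rate, nrow(calls))] <- NA
  }
  dplyr::bind_cols(tibble(id = sprintf("ind%04d", seq_len(n))),
                   as_tibble(calls))
}

#' Simulate a complete comparative-mapping study
#'
#' One call generating every input of the pipeline under a single seed:
#' the ancestral genome and marker panel, the rearranged derived genome
#' with scaffolds, F2 and RIL genotype tables over
#' population-specific polymorphic marker subsets, the target-genome
#' reference map (a fraction of panel markers mapped directly, plus
#' target-genome-only reference markers on every scaffold), linkage-group
#' label anchors for the source genome, and the planted truth.
#'
#' @param seed RNG seed driving the whole study.
#' @param scenario Rearrangement scenario (default [default_scenario()]).
#' @param n_f2,n_ril Population sizes (defaults 91 and 80, the scale the
#'   package is calibrated to).
#' @param p_f2,p_ril Probability a panel marker is polymorphic (hence
#'   genotyped) in each population.
#' @param p_direct_ref Fraction of panel markers also present on the
#'   target reference map.
#' @param ref_per_scaffold Target-only reference markers per scaffold.
#' @param n_label_anchors Source-map label anchors per chromosome.
#' @param rates Corruption rates passed to [corrupt()].
#' @param missing_rate Missing-genotype rate.
#' @param n_chrom,chrom_lengths_cM,markers_per_chrom Genome scale,
#'   passed to [simulate_ancestral_genome()] (defaults: the
#'   12-chromosome, 401-locus preset).
#' @return A `synmap_study` list: `ancestral`, `derived`, `panel`
#'   (primers), `geno_f2`, `geno_ril`, `reference_map`, `lg_labels`,
#'   `truth` (planted correspondence and segments).
#' @export
simulate_study <- function(seed = 1, scenario = default_scenario(),
                           n_f2 = 91, n_ril = 80,
                           p_f2 = 0.8, p_ril = 0.65,
                           p_direct_ref = 0.2, ref_per_scaffold = 3,
                           n_label_anchors = 5,
                           rates = c(no_hit = 0, multi_copy = 0,
                                     mis_anchor = 0),
                           missing_rate = 0.02,
                           n_chrom = 12, chrom_lengths_cM = NULL,
                           markers_per_chrom = NULL) {
  anc <- simulate_ancestral_genome(n_chrom = n_chrom,
                                   chrom_lengths_cM = chrom_lengths_cM,
                                   markers_per_chrom = markers_per_chrom,
                                   seed = seed)
  der <- apply_rearrangements(anc, scenario)
  if (sum(rates) > 0) der <- corrupt(der, rates)

  mk <- anc$markers
  in_f2 <- runif(nrow(mk)) < p_f2
  in_ril <- runif(nrow(mk)) < p_ril
  # guarantee anchors: at least 3 shared markers per chromosome
  for (ch in unique(mk$chrom)) {
    idx <- which(mk$chrom == ch)
    shared <- idx[in_f2[idx] & in_ril[idx]]
    if (length(shared) < 3) {
      pick <- sample(idx, min(3, length(idx)))
      in_f2[pick] <- TRUE; in_ril[pick] <- TRUE
    }
  }
  src_map <- mk[, c("marker_id", "chrom", "cM")]
  geno_f2 <- simulate_population(src_map[in_f2, ], "f2", n_f2,
                                 missing_rate = missing_rate)
  geno_ril <- simulate_population(src_map[in_ril, ], "ril", n_ril,
                                  missing_rate = missing_rate)

  dmk <- der$markers
  dmk <- dplyr::left_join(dmk, der$marker_scaffold, by = "marker_id")
  direct <- runif(nrow(dmk)) < p_direct_ref
  ref_direct <- tibble(marker_id = dmk$marker_id[direct],
                       chromosome = dmk$chrom[direct],
                       position_cM = dmk$cM[direct],
                       scaffold = dmk$scaffold[direct])
  ref_only <- list()
  for (sc in unique(der$scaffold_truth$scaffold)) {
    on_sc <- dmk[dmk$scaffold %in% sc, ]
    if (nrow(on_sc) == 0) next
    ch <- der$scaffold_truth$chrom[der$scaffold_truth$scaffold == sc]
    span <- range(on_sc$cM)
    ref_only[[sc]] <- tibble(
      marker_id = sprintf("TR%s_%d", sub("^scf", "", sc),
                          seq_len(ref_per_scaffold)),
      chromosome = ch,
      position_cM = runif(ref_per_scaffold, span[1], span[2]),
      scaffold = sc)
  }
  reference_map <- dplyr::bind_rows(ref_direct, dplyr::bind_rows(ref_only))

  lab <- mk[in_f2 | in_ril, ]
  lg_labels <- lab %>% group_by(.data$chrom) %>%
    dplyr::slice_sample(n = n_label_anchors) %>% ungroup() %>%
    dplyr::transmute(marker_id = .data$marker_id, chromosome = .data$chrom)

  structure(list(
    ancestral = anc, derived = der,
    panel = mk[, c("marker_id", "chrom", "cM", "fwd", "rev")],
    geno_f2 = geno_f2, geno_ril = geno_ril,
    reference_map = reference_map, lg_labels = lg_labels,
    truth = list(correspondence = planted_correspondence(der),
                 segments = der$segments),
    seed = seed
  ), class = "synmap_study")
}
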