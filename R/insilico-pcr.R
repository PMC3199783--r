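#' Load a scaffold assembly
#'
#' Reads (or validates) a scaffold-level assembly as a
#' [Biostrings::DNAStringSet], rejecting sequences with letters outside
#' `ACGTN` and duplicated scaffold ids.
#'
#' @param x Path to a FASTA file (gzip allowed) or a `DNAStringSet` /
#'   named character vector.
#' @param name Assembly name (e.g. `"Gy14"`); defaults to the file name.
#' @return A `DNAStringSet` with a `name` attribute.
#' @export
load_assembly <- function(x, name = NULL) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    if (is.null(name)) name <- sub("\\.(fa|fasta)(\\.gz)?$", "", basename(x))
    x <- Biostrings::readDNAStringSet(x)
  } else if (is.character(x)) {
    x <- Biostrings::DNAStringSet(x)
  }
  stopifnot(methods::is(x, "DNAStringSet"))
  if (is.null(names(x)) || anyDuplicated(names(x)) > 0) {
    stop("scaffold ids must be present and unique")
  }
  freq <- Biostrings::alphabetFrequency(x, collapse = TRUE)
  extra <- sum(freq) - sum(freq[c("A", "C", "G", "T", "N")])
  if (extra > 0) stop("assembly contains letters outside ACGTN")
  attr(x, "name") <- if (is.null(name)) "assembly" else name
  x
}

#' @noRd
#' IUPAC-aware mismatch count between a primer and equal-length subject
#' strings ('N' in the subject never matches).
iupac_mismatches <- function(primer, subject_strings) {
  exp_sets <- Biostrings::IUPAC_CODE_MAP
  pc <- strsplit(primer, "")[[1]]
  if (!all(pc %in% names(exp_sets))) {
    stop("primer contains non-IUPAC symbol: ",
         paste(setdiff(pc, names(exp_sets)), collapse = ","))
  }
  sc <- strsplit(subject_strings, "")
  vapply(sc, function(s) {
    sum(!mapply(function(p, b) b != "N" && grepl(b, exp_sets[[p]], fixed = TRUE),
                pc, s))
  }, numeric(1))
}

#' @noRd
#' All forward-strand sites of `primer` in a scaffold set with at most
#' `max_mm` mismatches and zero mismatches within `clamp` bases of the
#' primer's 3' end (`three_prime = "right"` when the 3' end maps to the
#' right end of the site, `"left"` when it maps to the left).
primer_sites <- function(primer, scaffolds, max_mm, clamp,
                         three_prime = c("right", "left")) {
  three_prime <- match.arg(three_prime)
  pat <- Biostrings::DNAString(primer)
  hits <- Biostrings::vmatchPattern(pat, scaffolds, max.mismatch = max_mm,
                                    fixed = "subject")
  out <- list()
  for (i in seq_along(hits)) {
    ir <- hits[[i]]
    if (length(ir) == 0) next
    # drop sites running off the scaffold (vmatchPattern allows overhangs
    # when max.mismatch > 0)
    ok <- IRanges::start(ir) >= 1 &
      IRanges::end(ir) <= Biostrings::width(scaffolds)[i]
    ir <- ir[ok]
    if (length(ir) == 0) next
    segs <- as.character(Biostrings::extractAt(scaffolds[[i]], ir))
    if (clamp > 0) {
      w <- nchar(primer)
      idx <- if (three_prime == "right") (w - clamp + 1):w else 1:clamp
      clamp_ok <- vapply(segs, function(s) {
        iupac_mismatches(substr(primer, min(idx), max(idx)),
                         substr(s, min(idx), max(idx))) == 0
      }, logical(1))
    } else {
      clamp_ok <- rep(TRUE, length(segs))
    }
    mm <- iupac_mismatches(primer, segs)
    keep <- clamp_ok & mm <= max_mm
    if (any(keep)) {
      out[[length(out) + 1]] <- tibble(
        scaffold = names(scaffolds)[i],
        start = IRanges::start(ir)[keep],
        end = IRanges::end(ir)[keep]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(scaffold = character(0), start = integer(0),
                  end = integer(0)))
  }
  dplyr::bind_rows(out)
}

#' In silico (virtual) PCR
#'
#' Scans a scaffold assembly for all sites where a primer pair would
#' amplify: the forward primer matches one strand and the reverse
#' primer's reverse complement matches downstream on the same strand,
#' with the product size inside `[min_size, max_size]`.  Each primer may
#' carry up to `max_mismatch` mismatches (IUPAC codes in primers expand
#' to their base sets) but none within the `clamp3` bases at its 3' end.
#' Sites where the two primers would overlap (product shorter than the
#' summed primer lengths) are skipped.  Hits are reported in
#' forward-strand coordinates (1-based inclusive), sorted by scaffold and
#' start; `strand` is the strand matched by the forward primer and
#' `product_seq` is the amplicon as amplified (starting with the forward
#' primer).
#'
#' @param primers Data frame with columns `marker_id`, `fwd`, `rev`
#'   (IUPAC primer strings, length >= 15).
#' @param assembly A `DNAStringSet` from [load_assembly()].
#' @param max_mismatch,clamp3,min_size,max_size Matching parameters.
#' @param with_sequence Include the product sequence column (default
#'   TRUE).
#' @return Tibble of hits: `marker_id`, `assembly`, `scaffold`, `start`,
#'   `end`, `strand`, `product_size`, `product_seq`.
#' @export
virtual_pcr <- function(primers, assembly, max_mismatch = 1, clamp3 = 3,
                        min_size = 40, max_size = 5000,
                        with_sequence = TRUE) {
  stopifnot(all(c("marker_id", "fwd", "rev") %in% names(primers)))
  if (any(nchar(primers$fwd) < 15 | nchar(primers$rev) < 15)) {
    stop("primers must be at least 15 nt")
  }
  asm_name <- attr(assembly, "name") %||% "assembly"
  widths <- setNames(Biostrings::width(assembly), names(assembly))

  one_strand <- function(fwd, rev, strand) {
    # forward primer on this strand; reverse primer anneals downstream, so
    # its reverse complement must match the same strand
    rc_rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rev)))
    f_sites <- primer_sites(fwd, assembly, max_mismatch, clamp3, "right")
    if (strand == "-") {
      # mirror to minus-strand coordinates later; search on plus strand of
      # the reverse-complemented assembly
      return(NULL)  # handled by caller via revcomp assembly
    }
    r_sites <- primer_sites(rc_rev, assembly, max_mismatch, clamp3, "left")
    pair_sites(f_sites, r_sites, nchar(fwd), nchar(rev))
  }

  pair_sites <- function(f_sites, r_sites, lf, lr) {
    if (nrow(f_sites) == 0 || nrow(r_sites) == 0) {
      return(tibble(scaffold = character(0), start = integer(0),
                    end = integer(0)))
    }
    out <- list()
    for (sc in intersect(unique(f_sites$scaffold), unique(r_sites$scaffold))) {
      fs <- f_sites[f_sites$scaffold == sc, ]
      rs <- r_sites[r_sites$scaffold == sc, ]
      grid <- expand.grid(fi = seq_len(nrow(fs)), ri = seq_len(nrow(rs)))
      size <- rs$end[grid$ri] - fs$start[grid$fi] + 1
      keep <- size >= max(min_size, lf + lr) & size <= max_size &
        rs$start[grid$ri] >= fs$start[grid$fi]
      if (any(keep)) {
        out[[length(out) + 1]] <- tibble(
          scaffold = sc,
          start = fs$start[grid$fi[keep]],
          end = rs$end[grid$ri[keep]]
        )
      }
    }
    if (length(out) == 0) {
      return(tibble(scaffold = character(0), start = integer(0),
                    end = integer(0)))
    }
    dplyr::bind_rows(out)
  }

  rc_assembly <- Biostrings::reverseComplement(assembly)
  names(rc_assembly) <- names(assembly)
  attr(rc_assembly, "name") <- asm_name

  res <- list()
  for (k in seq_len(nrow(primers))) {
    fwd <- toupper(primers$fwd[k]); rev <- toupper(primers$rev[k])
    plus <- one_strand(fwd, rev, "+")
    # minus strand: same search on the reverse-complemented assembly, then
    # mirror coordinates back to the forward strand
    rc_rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rev)))
    f_sites <- primer_sites(fwd, rc_assembly, max_mismatch, clamp3, "right")
    r_sites <- primer_sites(rc_rev, rc_assembly, max_mismatch, clamp3, "left")
    minus <- pair_sites(f_sites, r_sites, nchar(fwd), nchar(rev))
    if (nrow(minus) > 0) {
      w <- widths[minus$scaffold]
      new_start <- w - minus$end + 1
      new_end <- w - minus$start + 1
      minus$start <- as.integer(new_start)
      minus$end <- as.integer(new_end)
    }
    both <- dplyr::bind_rows(
      if (nrow(plus) > 0) mutate(plus, strand = "+") else NULL,
      if (nrow(minus) > 0) mutate(minus, strand = "-") else NULL
    )
    if (!is.null(both) && nrow(both) > 0) {
      both <- dplyr::distinct(both)
      both$marker_id <- primers$marker_id[k]
      res[[length(res) + 1]] <- both
    }
  }

  if (length(res) == 0) {
    return(tibble(marker_id = character(0), assembly = character(0),
                  scaffold = character(0), start = integer(0),
                  end = integer(0), strand = character(0),
                  product_size = integer(0), product_seq = character(0)))
  }
  hits <- dplyr::bind_rows(res) %>%
    mutate(assembly = asm_name,
           product_size = as.integer(.data$end - .data$start + 1)) %>%
    arrange(.data$marker_id, .data$scaffold, .data$start)
  if (with_sequence) {
    seqs <- vapply(seq_len(nrow(hits)), function(i) {
      s <- Biostrings::subseq(assembly[[hits$scaffold[i]]],
                              hits$start[i], hits$end[i])
      if (hits$strand[i] == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1))
    hits$product_seq <- seqs
  } else {
    hits$product_seq <- NA_character_
  }
  select(hits, "marker_id", "assembly", "scaffold", "start", "end",
         "strand", "product_size", "product_seq")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify virtual-PCR hits per marker
#'
#' Labels each marker `no_hit` (no product genome-wide), `unique`
#' (exactly one), or `multi_copy` (two or more).  A unique hit whose
#' product overlaps a provided repeat interval is classified
#' `repeat_region` and excluded from anchoring.  Interval overlap is
#' tested half-open internally; repeat intervals are taken 1-based
#' inclusive (use [read_bed()] for BED input, which converts).
#'
#' @param hits Hit table from [virtual_pcr()].
#' @param marker_ids All marker ids screened (so no-hit markers appear).
#' @param repeats Optional repeat annotation: `scaffold`, `start`, `end`
#'   (1-based inclusive).
#' @return Tibble `marker_id`, `assembly`, `n_hits`, `class`.
#' @export
classify_hits <- function(hits, marker_ids, repeats = NULL) {
  asm <- unique(hits$assembly)
  if (length(asm) == 0) asm <- "assembly"
  stopifnot(length(asm) == 1)
  tab <- hits %>% group_by(.data$marker_id) %>%
    summarise(n_hits = dplyr::n())
  out <- tibble(marker_id = marker_ids) %>%
    dplyr::left_join(tab, by = "marker_id") %>%
    mutate(n_hits = ifelse(is.na(.data$n_hits), 0L, .data$n_hits),
           assembly = asm,
           class = dplyr::case_when(
             .data$n_hits == 0 ~ "no_hit",
             .data$n_hits == 1 ~ "unique",
             TRUE ~ "multi_copy"
           ))
  if (!is.null(repeats) && nrow(repeats) > 0) {
    uni <- out$marker_id[out$class == "unique"]
    h <- hits[hits$marker_id %in% uni, ]
    in_rep <- vapply(seq_len(nrow(h)), function(i) {
      r <- repeats[repeats$scaffold == h$scaffold[i], , drop = FALSE]
      # half-open overlap on [start, end + 1)
      any(h$start[i] < r$end + 1 & r$start < h$end[i] + 1)
    }, logical(1))
    out$class[out$marker_id %in% h$marker_id[in_rep]] <- "repeat_region"
  }
  select(out, "marker_id", "assembly", "n_hits", "class")
}

#' Anchor a source sequence on an assembly by seed-and-extend
#'
#' Gapless seed-and-extend placement of a marker's source sequence (e.g.
#' gene or EST) on a scaffold assembly: every `seed_len`-mer of the query
#' sampled at `seed_step` is located exactly in the assembly (both
#' strands); each distinct (scaffold, strand, offset) candidate is scored
#' by gapless identity times query coverage, and the best-scoring
#' location wins provided identity and coverage clear their thresholds.
#' Ties between distinct best locations are reported as `multi_copy`.
#'
#' @param query Nucleotide string, length >= 100.
#' @param assembly `DNAStringSet` from [load_assembly()].
#' @param seed_len Exact seed length (default 31).
#' @param min_identity,min_cov Acceptance thresholds.
#' @param seed_step Query positions between successive seeds.
#' @return One-row tibble: `scaffold`, `start`, `end`, `strand`,
#'   `identity`, `coverage`, `class` (`unique`, `multi_copy` or
#'   `no_hit`; coordinates `NA` unless unique).
#' @export
anchor_by_sequence <- function(query, assembly, seed_len = 31,
                               min_identity = 0.9, min_cov = 0.5,
                               seed_step = 10) {
  query <- toupper(query)
  if (nchar(query) < seed_len) stop("sequence shorter than seed")
  if (nchar(query) < 100) stop("source sequence must be >= 100 nt")
  no_hit <- tibble(scaffold = NA_character_, start = NA_integer_,
                   end = NA_integer_, strand = NA_character_,
                   identity = NA_real_, coverage = NA_real_,
                   class = "no_hit")

  candidates <- list()
  scan <- function(q, strand) {
    starts <- unique(c(seq(1, nchar(q) - seed_len + 1, by = seed_step),
                       nchar(q) - seed_len + 1))
    for (sp in starts) {
      seed <- substr(q, sp, sp + seed_len - 1)
      if (grepl("[^ACGT]", seed)) next
      m <- Biostrings::vmatchPattern(Biostrings::DNAString(seed), assembly)
      for (i in seq_along(m)) {
        ir <- m[[i]]
        if (length(ir) == 0) next
        for (st in IRanges::start(ir)) {
          candidates[[length(candidates) + 1]] <<-
            c(scaffold = names(assembly)[i], strand = strand,
              offset = st - sp)
        }
      }
    }
  }
  scan(query, "+")
  rc_query <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(query)))
  scan(rc_query, "-")
  if (length(candidates) == 0) return(no_hit)

  cand <- unique(do.call(rbind, candidates))
  qlen <- nchar(query)
  scores <- lapply(seq_len(nrow(cand)), function(i) {
    sc <- cand[i, "scaffold"]
    off <- as.integer(cand[i, "offset"])
    q <- if (cand[i, "strand"] == "+") query else rc_query
    slen <- Biostrings::width(assembly)[match(sc, names(assembly))]
    q_from <- max(1, 1 - off)
    q_to <- min(qlen, slen - off)
    if (q_to < q_from) return(NULL)
    sub_s <- as.character(Biostrings::subseq(assembly[[sc]],
                                             q_from + off, q_to + off))
    sub_q <- substr(q, q_from, q_to)
    matches <- sum(strsplit(sub_q, "")[[1]] == strsplit(sub_s, "")[[1]])
    ov <- q_to - q_from + 1
    tibble(scaffold = unname(sc), start = q_from + off, end = q_to + off,
           strand = unname(cand[i, "strand"]),
           identity = matches / ov, coverage = ov / qlen)
  })
  scores <- dplyr::bind_rows(scores)
  if (nrow(scores) == 0) return(no_hit)
  scores$score <- scores$identity * scores$coverage
  scores <- scores %>%
    filter(.data$identity >= min_identity, .data$coverage >= min_cov)
  if (nrow(scores) == 0) return(no_hit)
  best <- max(scores$score)
  top <- scores[scores$score >= best - 1e-9, ]
  top <- dplyr::distinct(top, .data$scaffold, .data$start, .data$strand,
                         .keep_all = TRUE)
  if (nrow(top) > 1) {
    out <- no_hit
    out$class <- "multi_copy"
    return(out)
  }
  mutate(select(top, -"score"), class = "unique")
}

#' Read a BED file of repeat intervals
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention.
#'
#' @param path BED file path (first three columns used).
#' @return Tibble `scaffold`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  tibble(scaffold = x[[1]], start = x[[2]] + 1L, end = x[[3]])
}
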