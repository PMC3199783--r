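# Independent oracles used across the suite.  Each reimplements the
# quantity it checks by a different route (enumeration, brute force,
# closed form), never by calling the code path under test.

# -- F2 two-point likelihood, written from the genotype-class
#    probabilities directly (not via the package's f2_loglik) -------------
oracle_f2_loglik <- function(r, counts) {
  r <- min(max(r, 1e-12), 0.5)
  p <- matrix(0, 3, 3)
  p[1, 1] <- p[3, 3] <- ((1 - r) / 2)^2
  p[1, 3] <- p[3, 1] <- (r / 2)^2
  p[1, 2] <- p[2, 1] <- p[2, 3] <- p[3, 2] <- r * (1 - r) / 2
  p[2, 2] <- ((1 - r)^2 + r^2) / 2
  sum(ifelse(counts > 0, counts * log(p), 0))
}

# grid-search MLE over r in {0, 1e-4, ..., 0.5}
oracle_grid_mle_f2 <- function(counts, step = 1e-4) {
  rs <- seq(0, 0.5, by = step)
  ll <- vapply(rs, oracle_f2_loglik, numeric(1), counts = counts)
  rs[which.max(ll)]
}

# -- brute-force virtual PCR ---------------------------------------------
oracle_primer_sites <- function(seqv, primer, max_mm, clamp, three_prime) {
  iup <- Biostrings::IUPAC_CODE_MAP
  pc <- strsplit(primer, "")[[1]]
  L <- length(pc)
  n <- length(seqv)
  if (n < L) return(integer(0))
  npos <- n - L + 1
  mm <- matrix(FALSE, npos, L)
  for (k in seq_len(L)) {
    allowed <- strsplit(iup[[pc[k]]], "")[[1]]
    mm[, k] <- !(seqv[k:(k + npos - 1)] %in% allowed)
  }
  tot <- rowSums(mm)
  cl <- if (three_prime == "right") {
    rowSums(mm[, (L - clamp + 1):L, drop = FALSE])
  } else {
    rowSums(mm[, 1:clamp, drop = FALSE])
  }
  which(tot <= max_mm & cl == 0)
}

oracle_vpcr <- function(seq_str, fwd, rev, max_mm = 1, clamp = 3,
                        min_size = 40, max_size = 5000) {
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  sv <- strsplit(seq_str, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sv else strsplit(rc(seq_str), "")[[1]]
    fs <- oracle_primer_sites(s, fwd, max_mm, clamp, "right")
    rs <- oracle_primer_sites(s, rc(rev), max_mm, clamp, "left")
    for (i in fs) for (j in rs) {
      size <- j + nchar(rev) - i
      if (j >= i && size >= max(min_size, nchar(fwd) + nchar(rev)) &&
          size <= max_size) {
        st <- i; en <- j + nchar(rev) - 1
        if (strand == "-") {
          n <- length(sv)
          tmp <- n - en + 1; en <- n - st + 1; st <- tmp
        }
        hits[[length(hits) + 1]] <-
          data.frame(start = st, end = en, strand = strand)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  out <- do.call(rbind, hits)
  unique(out[order(out$start, out$end, out$strand), ])
}

# -- block segmentation by interval enumeration --------------------------
# From each start, the block is the longest interval whose endpoints carry
# the start's target and whose off-target count is within budget.
oracle_segment <- function(targets, budget) {
  n <- length(targets)
  out <- list()
  i <- 1L
  while (i <= n) {
    t <- targets[i]
    best_j <- i
    for (j in i:n) {
      if (targets[j] == t && sum(targets[i:j] != t) <= budget) best_j <- j
    }
    members <- which(targets[i:best_j] == t) + i - 1L
    out[[length(out) + 1]] <- list(target = t, members = members,
                                   n_discordant = best_j - i + 1L -
                                     length(members))
    i <- best_j + 1L
  }
  out
}

# -- connected components by repeated closure ----------------------------
oracle_components <- function(nodes, from, to) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_along(from)) {
      a <- comp[from[k]]; b <- comp[to[k]]
      if (a != b) {
        comp[comp == b] <- a
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# -- exhaustive permutations (small n) -----------------------------------
oracle_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_permutations(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = k)
    }
  }
  out
}

# -- Kendall tau by O(n^2) pair counting (tie-corrected) -----------------
oracle_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# -- small deterministic genotype fixture --------------------------------
sim_pair_geno <- function(n, r, population = "f2", seed = 1) {
  map <- tibble::tibble(marker_id = c("ma", "mb"), chrom = "c1",
                        cM = c(0, haldane_distance(r)))
  simulate_population(map, population, n, seed = seed, missing_rate = 0)
}
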