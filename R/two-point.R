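#' @noRd
#' Joint F2 two-locus genotype class log-likelihood.
#'
#' `counts` is a 3x3 matrix (rows locus A classes A/H/B, cols locus B) of
#' individuals; `r` the recombination fraction.  Classes and their
#' probabilities under random union of two independent meioses:
#' non-recombinant corner classes ((1-r)/2)^2, single-recombinant classes
#' r(1-r)/2, double-recombinant corners (r/2)^2, and the phase-ambiguous
#' double heterozygote ((1-r)^2 + r^2)/2.  Constant multinomial coefficient
#' dropped.
f2_loglik <- function(r, counts) {
  r <- pmin(pmax(r, 1e-12), 0.5)
  p_par <- ((1 - r) / 2)^2              # AA, BB
  p_one <- r * (1 - r) / 2              # AH, HA, HB, BH
  p_two <- (r / 2)^2                    # AB, BA
  p_hh  <- ((1 - r)^2 + r^2) / 2        # HH
  n_par <- counts[1, 1] + counts[3, 3]
  n_one <- counts[1, 2] + counts[2, 1] + counts[2, 3] + counts[3, 2]
  n_two <- counts[1, 3] + counts[3, 1]
  n_hh  <- counts[2, 2]
  term <- function(n, p) if (n > 0) n * log(p) else 0
  term(n_par, p_par) + term(n_one, p_one) + term(n_two, p_two) +
    term(n_hh, p_hh)
}

#' @noRd
#' Single-table EM for the F2 recombination fraction.  The E-step resolves
#' the double-heterozygote phase ambiguity (expected recombinant gametes
#' 2 r^2 / ((1-r)^2 + r^2)); the M-step divides expected recombinant
#' gametes by total gametes.  Returns r_hat, lod, n and the log-likelihood
#' trace (one entry per iteration, evaluated at the current r).
rf_em_f2_counts <- function(counts, max_iter = 200, tol = 1e-9) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(3, 3)),
            all(counts >= 0))
  n <- sum(counts)
  s_known <- counts[1, 2] + counts[2, 1] + counts[2, 3] + counts[3, 2] +
    2 * (counts[1, 3] + counts[3, 1])
  n_hh <- counts[2, 2]
  r <- 0.25
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    trace <- c(trace, f2_loglik(r, counts))
    w <- r^2 / ((1 - r)^2 + r^2)
    r_new <- (s_known + 2 * w * n_hh) / (2 * n)
    r_new <- min(max(r_new, 0), 0.5)
    if (abs(r_new - r) < tol) {
      r <- r_new
      break
    }
    r <- r_new
  }
  lod <- (f2_loglik(r, counts) - f2_loglik(0.5, counts)) / log(10)
  list(r_hat = if (r < 1e-8) 0 else r, lod = max(lod, 0), n = n,
       loglik_trace = trace)
}

#' @noRd
#' RIL (selfed, treated as fully inbred) two-point estimate from k observed
#' recombinant (discordant A/B) lines out of n informative.  The observed
#' fraction R is corrected to the meiotic scale with the
#' Haldane--Waddington relation r = R / (2 - 2R).
rf_ril_counts <- function(k, n) {
  stopifnot(k >= 0, n > 0, k <= n)
  big_r <- k / n
  if (big_r >= 0.5) {
    return(list(r_hat = 0.5, lod = 0, n = n, R = big_r))
  }
  r <- big_r / (2 - 2 * big_r)
  rc <- min(max(big_r, 1e-12), 1 - 1e-12)
  lod <- (k * log(rc) + (n - k) * log(1 - rc) - n * log(0.5)) / log(10)
  list(r_hat = r, lod = max(lod, 0), n = n, R = big_r)
}

#' Two-point recombination-fraction estimates
#'
#' Estimates the recombination fraction and LOD score for marker pairs.
#' `estimate_rf()` computes all pairwise estimates for a genotype table;
#' `estimate_rf_f2()` and `estimate_rf_ril()` handle a single pair of call
#' vectors.
#'
#' For F2 populations the maximum-likelihood estimate is found by EM over
#' the 3x3 joint genotype table (the double-heterozygote class is a phase
#' mixture, handled in the E-step), clamped to `[0, 0.5]`.  For selfed RILs
#' heterozygous calls are treated as missing, the observed recombinant
#' fraction R among A/B-typed pairs is computed, and the meiotic-scale
#' estimate is the Haldane--Waddington correction `r = R / (2 - 2R)`
#' (treating F8 lines as fully inbred).  In both cases
#' `LOD = log10 L(r_hat) - log10 L(0.5)`, floored at 0, and estimates with
#' fewer than `min_informative` jointly typed individuals are flagged
#' `reliable = FALSE` (they are excluded from linkage grouping).
#'
#' @param geno Genotype table: first column individual id, one column per
#'   marker with calls in `{A,H,B,NA,-}`.
#' @param population `"f2"` or `"ril"`.
#' @param min_informative Minimum jointly typed individuals for a pair to
#'   be considered reliable.
#' @param calls_a,calls_b Character vectors of calls for one marker each.
#' @return A tibble with one row per marker pair: `marker_a`, `marker_b`,
#'   `r_hat`, `lod`, `n_informative`, `reliable`.  For RIL pairs an extra
#'   column `n_rec` holds the observed recombinant count.
#' @examples
#' geno <- tibble::tibble(id = 1:6,
#'                        m1 = c("A", "A", "H", "H", "B", "B"),
#'                        m2 = c("A", "A", "H", "B", "B", "B"))
#' estimate_rf(geno, "f2", min_informative = 2)
#' @export
estimate_rf <- function(geno, population = c("f2", "ril"),
                        min_informative = 10) {
  population <- match.arg(population)
  m <- as_geno_matrix(geno)
  if (population == "f2") {
    est <- rf_all_pairs_f2(m)
  } else {
    est <- rf_all_pairs_ril(m)
  }
  est$reliable <- est$n_informative >= min_informative
  est
}

#' @noRd
#' Vectorised all-pairs F2 EM: the nine joint-class count matrices are
#' formed by indicator cross-products, then the EM update runs elementwise
#' on whole matrices.
rf_all_pairs_f2 <- function(m) {
  ia <- (m == "A") & !is.na(m); ih <- (m == "H") & !is.na(m)
  ib <- (m == "B") & !is.na(m)
  storage.mode(ia) <- storage.mode(ih) <- storage.mode(ib) <- "double"
  n_aa <- crossprod(ia, ia); n_ah <- crossprod(ia, ih)
  n_ab <- crossprod(ia, ib); n_ha <- crossprod(ih, ia)
  n_hh <- crossprod(ih, ih); n_hb <- crossprod(ih, ib)
  n_ba <- crossprod(ib, ia); n_bh <- crossprod(ib, ih)
  n_bb <- crossprod(ib, ib)
  n <- n_aa + n_ah + n_ab + n_ha + n_hh + n_hb + n_ba + n_bh + n_bb
  s_known <- n_ah + n_ha + n_hb + n_bh + 2 * (n_ab + n_ba)
  n_pos <- pmax(n, 1)

  r <- matrix(0.25, nrow(n), ncol(n))
  for (it in 1:200) {
    w <- r^2 / ((1 - r)^2 + r^2)
    r_new <- pmin(pmax((s_known + 2 * w * n_hh) / (2 * n_pos), 0), 0.5)
    delta <- max(abs(r_new - r))
    r <- r_new
    if (delta < 1e-9) break
  }

  ll <- function(r) {
    rc <- pmin(pmax(r, 1e-12), 0.5)
    n_par <- n_aa + n_bb
    n_one <- n_ah + n_ha + n_hb + n_bh
    n_two <- n_ab + n_ba
    tm <- function(nn, p) ifelse(nn > 0, nn * log(p), 0)
    tm(n_par, ((1 - rc) / 2)^2) + tm(n_one, rc * (1 - rc) / 2) +
      tm(n_two, (rc / 2)^2) + tm(n_hh, ((1 - rc)^2 + rc^2) / 2)
  }
  lod <- pmax((ll(r) - ll(matrix(0.5, nrow(n), ncol(n)))) / log(10), 0)
  r[r < 1e-8] <- 0

  pairs_from_matrices(colnames(m), r_hat = r, lod = lod, n_informative = n)
}

#' @noRd
rf_all_pairs_ril <- function(m) {
  ia <- (m == "A") & !is.na(m); ib <- (m == "B") & !is.na(m)
  storage.mode(ia) <- storage.mode(ib) <- "double"
  conc <- crossprod(ia, ia) + crossprod(ib, ib)
  disc <- crossprod(ia, ib) + crossprod(ib, ia)
  n <- conc + disc
  big_r <- disc / pmax(n, 1)
  r <- ifelse(big_r >= 0.5, 0.5, big_r / (2 - 2 * big_r))
  rc <- pmin(pmax(big_r, 1e-12), 1 - 1e-12)
  lod <- (disc * log(rc) + conc * log(1 - rc) - n * log(0.5)) / log(10)
  lod <- pmax(ifelse(big_r >= 0.5, 0, lod), 0)
  pairs_from_matrices(colnames(m), r_hat = r, lod = lod, n_informative = n,
                      n_rec = disc)
}

#' @noRd
#' Assemble upper-triangle entries of per-pair statistic matrices into a
#' tidy pair table (marker order = column order of the genotype matrix).
pairs_from_matrices <- function(ids, ...) {
  mats <- list(...)
  k <- length(ids)
  idx <- which(upper.tri(matrix(0, k, k)))
  row_i <- ((idx - 1) %% k) + 1
  col_j <- ((idx - 1) %/% k) + 1
  out <- tibble(marker_a = ids[row_i], marker_b = ids[col_j])
  for (nm in names(mats)) out[[nm]] <- mats[[nm]][idx]
  out
}

#' @rdname estimate_rf
#' @export
estimate_rf_f2 <- function(calls_a, calls_b, min_informative = 10) {
  stopifnot(length(calls_a) == length(calls_b))
  counts <- joint_counts_f2(calls_a, calls_b)
  fit <- rf_em_f2_counts(counts)
  tibble(marker_a = "a", marker_b = "b", r_hat = fit$r_hat, lod = fit$lod,
         n_informative = fit$n, reliable = fit$n >= min_informative)
}

#' @rdname estimate_rf
#' @export
estimate_rf_ril <- function(calls_a, calls_b, min_informative = 10) {
  stopifnot(length(calls_a) == length(calls_b))
  a <- ifelse(calls_a %in% c("A", "B"), calls_a, NA)
  b <- ifelse(calls_b %in% c("A", "B"), calls_b, NA)
  ok <- !is.na(a) & !is.na(b)
  fit <- rf_ril_counts(sum(a[ok] != b[ok]), max(sum(ok), 1))
  tibble(marker_a = "a", marker_b = "b", r_hat = fit$r_hat, lod = fit$lod,
         n_informative = sum(ok), n_rec = fit$R * max(sum(ok), 1),
         reliable = sum(ok) >= min_informative)
}

#' @noRd
joint_counts_f2 <- function(calls_a, calls_b) {
  lv <- c("A", "H", "B")
  ok <- calls_a %in% lv & calls_b %in% lv
  table(factor(calls_a[ok], lv), factor(calls_b[ok], lv)) |>
    unclass() |> matrix(nrow = 3, ncol = 3)
}
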