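#' Chi-square segregation screening
#'
#' Tests every marker's observed genotype counts for goodness-of-fit to its
#' Mendelian expectation: 1:2:1 (A:H:B, df = 2) in an F2 population, or 1:1
#' (A:B, df = 1, heterozygotes ignored) in a selfed-RIL population.  A
#' marker is flagged as showing segregation distortion at P < 0.01 (no
#' multiple-testing correction is applied; the raw per-marker cutoff is the
#' screening rule).
#'
#' For RILs, residual heterozygosity is expected to be small (about
#' \eqn{(1/2)^7} after selfing to F8); markers whose observed H fraction
#' exceeds `max_ril_het` trigger a warning and their H calls are excluded
#' from the 1:1 test.
#'
#' @param counts A data frame with columns `marker_id`, `n_a`, `n_h`,
#'   `n_b`, e.g. from [count_genotypes()].
#' @param population `"f2"` or `"ril"`.
#' @param alpha Significance level for the distortion flag.
#' @param max_ril_het Tolerated RIL heterozygote fraction before warning.
#' @return A tibble with columns `marker_id`, `n_a`, `n_h`, `n_b`, `chi2`,
#'   `df`, `p_value`, `distorted`.
#' @examples
#' counts <- tibble::tibble(marker_id = c("m1", "m2"),
#'                          n_a = c(25, 10), n_h = c(50, 50), n_b = c(25, 40))
#' test_segregation(counts, "f2")
#' @export
test_segregation <- function(counts, population = c("f2", "ril"),
                             alpha = 0.01, max_ril_het = 0.05) {
  population <- match.arg(population)
  stopifnot(all(c("marker_id", "n_a", "n_h", "n_b") %in% names(counts)))
  n_a <- as.numeric(counts$n_a)
  n_h <- as.numeric(counts$n_h)
  n_b <- as.numeric(counts$n_b)
  if (any(n_a < 0 | n_h < 0 | n_b < 0)) stop("negative genotype counts")
  total <- n_a + n_h + n_b
  if (any(total == 0)) {
    stop("empty marker: ", paste(counts$marker_id[total == 0], collapse = ", "))
  }

  if (population == "f2") {
    e_a <- total / 4
    e_h <- total / 2
    chi2 <- (n_a - e_a)^2 / e_a + (n_h - e_h)^2 / e_h + (n_b - e_a)^2 / e_a
    df <- 2L
  } else {
    het_frac <- n_h / total
    high <- het_frac > max_ril_het
    if (any(high)) {
      warning(sum(high), " RIL marker(s) with heterozygote fraction > ",
              max_ril_het, "; H calls excluded from the 1:1 test")
    }
    n_ab <- n_a + n_b
    if (any(n_ab == 0)) {
      stop("empty marker (no A/B calls): ",
           paste(counts$marker_id[n_ab == 0], collapse = ", "))
    }
    chi2 <- (n_a - n_b)^2 / n_ab
    df <- 1L
  }

  tibble(
    marker_id = counts$marker_id,
    n_a = counts$n_a, n_h = counts$n_h, n_b = counts$n_b,
    chi2 = chi2,
    df = df,
    p_value = pchisq(chi2, df = df, lower.tail = FALSE),
    distorted = pchisq(chi2, df = df, lower.tail = FALSE) < alpha
  )
}
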