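#' Genotype tables
#'
#' A genotype table holds one mapping population: one row per individual,
#' first column `id`, remaining columns one per marker with calls coded
#' `"A"` (parent-1 homozygote), `"H"` (heterozygote), `"B"` (parent-2
#' homozygote) or missing (`NA` or `"-"`).  Two population types are
#' supported: `"f2"` (codominant F2, segregating 1:2:1) and `"ril"`
#' (recombinant inbred lines by repeated selfing, segregating ~1:1 with
#' only residual heterozygosity).
#'
#' @param x A data frame in the layout above.
#' @return `as_geno_matrix()` returns a character matrix (individuals x
#'   markers, dimnames set) with `"-"` normalised to `NA`.
#' @keywords internal
as_geno_matrix <- function(x) {
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- as.character(x[[1]])
  m[m == "-"] <- NA_character_
  bad <- setdiff(unique(m[!is.na(m)]), c("A", "H", "B"))
  if (length(bad) > 0) {
    stop("invalid genotype codes: ", paste(bad, collapse = ", "))
  }
  m
}

#' Count genotype classes per marker
#'
#' Tallies the A/H/B calls of every marker in a genotype table, the first
#' step of segregation screening.
#'
#' @param geno Genotype table (see [as_geno_matrix()] layout): first column
#'   individual id, remaining columns marker calls in `{A,H,B,NA,-}`.
#' @return A tibble with columns `marker_id`, `n_a`, `n_h`, `n_b`,
#'   `n_missing`.
#' @examples
#' geno <- tibble::tibble(id = paste0("i", 1:4),
#'                        m1 = c("A", "H", "H", "B"),
#'                        m2 = c("A", "A", NA, "B"))
#' count_genotypes(geno)
#' @export
count_genotypes <- function(geno) {
  m <- as_geno_matrix(geno)
  tibble(
    marker_id = colnames(m),
    n_a = unname(colSums(m == "A", na.rm = TRUE)),
    n_h = unname(colSums(m == "H", na.rm = TRUE)),
    n_b = unname(colSums(m == "B", na.rm = TRUE)),
    n_missing = unname(colSums(is.na(m)))
  )
}
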