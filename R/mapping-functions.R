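#' Map-distance functions
#'
#' Convert between recombination fractions and genetic map distances.
#' `kosambi_distance()` and `kosambi_inverse()` implement the Kosambi
#' mapping function, which allows for partial crossover interference and is
#' the transform used when map positions are reported.  `haldane_distance()`
#' and `haldane_inverse()` implement the Haldane (no-interference) function,
#' which is the model under which meioses are simulated.
#'
#' Kosambi: \eqn{d = 25 \ln((1+2r)/(1-2r))} cM, with inverse
#' \eqn{r = \tanh(2d/100)/2}.  Haldane: \eqn{d = -50 \ln(1-2r)} cM, with
#' inverse \eqn{r = (1 - e^{-2d/100})/2}.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Map distance(s) in centiMorgans, `>= 0`.
#' @return A numeric vector: distances in cM, or recombination fractions.
#' @examples
#' kosambi_distance(0.2)           # 21.18 cM
#' kosambi_inverse(kosambi_distance(0.3))
#' @export
kosambi_distance <- function(r) {
  stopifnot(is.numeric(r), all(r >= 0))
  if (any(r >= 0.5)) stop("unlinked pair in ordered group (r >= 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_distance
#' @export
kosambi_inverse <- function(d) {
  stopifnot(is.numeric(d), all(d >= 0))
  0.5 * tanh(2 * d / 100)
}

#' @rdname kosambi_distance
#' @export
haldane_distance <- function(r) {
  stopifnot(is.numeric(r), all(r >= 0), all(r < 0.5))
  -50 * log(1 - 2 * r)
}

#' @rdname kosambi_distance
#' @export
haldane_inverse <- function(d) {
  stopifnot(is.numeric(d), all(d >= 0))
  0.5 * (1 - exp(-2 * d / 100))
}
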