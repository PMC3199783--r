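#' Read and write the pipeline's tab-separated formats
#'
#' Genotype tables: first column `id`, header row of marker ids, calls in
#' `{A,H,B,-}`.  Maps: `group`, `chromosome` (if labelled), `marker_id`,
#' `position_cM` (written to one decimal).  Primers: `marker_id`, `fwd`,
#' `rev`.  Reference maps: `marker_id`, `chromosome`, `position_cM`,
#' `scaffold`.
#'
#' @param path File path.
#' @name synmap_io
NULL

#' @rdname synmap_io
#' @export
read_genotypes <- function(path) {
  as_tibble(utils::read.delim(path, check.names = FALSE,
                              colClasses = "character",
                              na.strings = c("NA", "-", "")))
}

#' @rdname synmap_io
#' @param geno Genotype table.
#' @export
write_genotypes <- function(geno, path) {
  out <- geno
  out[is.na(out)] <- "-"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname synmap_io
#' @export
read_map <- function(path) {
  x <- as_tibble(utils::read.delim(path, check.names = FALSE))
  x$group <- as.character(x$group)
  new_genetic_map(x)
}

#' @rdname synmap_io
#' @param map A `genetic_map`.
#' @export
write_map <- function(map, path) {
  out <- as_tibble(unclass(map))
  out$position_cM <- sprintf("%.1f", out$position_cM)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname synmap_io
#' @export
read_primers <- function(path) {
  as_tibble(utils::read.delim(path, check.names = FALSE,
                              colClasses = "character"))
}

#' @rdname synmap_io
#' @export
read_reference_map <- function(path) {
  x <- as_tibble(utils::read.delim(path, check.names = FALSE))
  x$chromosome <- as.character(x$chromosome)
  x
}

#' @rdname synmap_io
#' @param x Any data frame.
#' @export
write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
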