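#' Published diagnostic target sequences for 13 fungal species
#'
#' Returns the species-specific Cas12a target sequences reported for 13
#' fungal species (one per species), as shipped in
#' `inst/extdata/table1_targets.tsv`. Two entries are typographically
#' irregular as printed (one 26-nt, one with an internal space); the
#' `sequence` column is the whitespace-stripped form and `irregular_length`
#' flags rows whose cleaned length differs from 25.
#'
#' @return data.frame with `species`, `abbrev`, `sequence_printed`,
#'   `sequence`, `irregular_length`.
#' @export
published_targets <- function() {
  path <- system.file("extdata", "table1_targets.tsv", package = "pamscreen")
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  x$sequence <- gsub("\\s", "", x$sequence_printed)
  x$irregular_length <- nchar(x$sequence) != 25L
  x
}
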