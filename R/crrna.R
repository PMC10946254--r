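#' Derive crRNA spacers from targets
#'
#' The spacer is the target's protospacer (the k-mer with its PAM removed),
#' transcribed to the RNA alphabet. Advisory annotations are attached —
#' `homopolymer_run_ge5` (a single-base run of 5+ in the spacer) and
#' `extreme_gc` (GC fraction outside \[0.2, 0.8\]) — but nothing is filtered:
#' flags inform guide choice, they do not veto it. No scaffold/repeat
#' sequence is emitted; callers who need a full guide can prepend their own
#' via `scaffold`.
#'
#' @param targets data.frame from [enumerate_targets()] or
#'   [target_from_sequence()] (any number of rows).
#' @param scaffold optional 5' scaffold string (RNA) prepended to
#'   `spacer_rna` in an extra `guide_rna` column.
#' @return data.frame with `crrna_id`, `target_id`, `spacer_dna`,
#'   `spacer_rna`, `gc_fraction`, `flags` (comma-separated, "" when none).
#' @examples
#' t1 <- target_from_sequence("TTTGTAGGCTTGGACTTGGAGGCTT")
#' design_crrna(t1)$spacer_rna
#' @export
design_crrna <- function(targets, scaffold = NULL) {
  spacer_dna <- targets$protospacer
  spacer_rna <- chartr("T", "U", spacer_dna)
  n <- nchar(spacer_dna)
  gc <- (nchar(gsub("[^GC]", "", spacer_dna))) / n
  homop <- grepl("A{5}|C{5}|G{5}|T{5}", spacer_dna)
  xgc <- gc < 0.2 | gc > 0.8
  flags <- mapply(function(h, x) {
    paste(c(if (h) "homopolymer_run_ge5", if (x) "extreme_gc"),
          collapse = ",")
  }, homop, xgc, USE.NAMES = FALSE)
  flags <- as.character(flags)
  out <- data.frame(crrna_id = paste0("crRNA_", targets$target_id),
                    target_id = targets$target_id,
                    spacer_dna = spacer_dna, spacer_rna = spacer_rna,
                    gc_fraction = gc, flags = flags,
                    stringsAsFactors = FALSE)
  if (!is.null(scaffold))
    out$guide_rna <- paste0(scaffold, out$spacer_rna)
  out
}
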