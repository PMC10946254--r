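# Qualitative in-silico model of Cas12a target recognition. Cas12a cleaves
# (and so reports, via collateral ssDNA cleavage) only when the crRNA finds
# a PAM-adjacent site sufficiently close to its spacer on either strand of
# the double-stranded substrate. Observed behavior: activation at 0
# mismatches, no activation at 3; the default activation threshold of 2 is
# the largest value consistent with both observations and is an
# extrapolation for distances 1-2 (configurable).

#' Simulate a Cas12a detection assay
#'
#' Scans both strands of the substrate for PAM-matched sites (the same
#' semantics as [find_offtargets()] with the crRNA's spacer as protospacer),
#' takes the minimum-mismatch site (ties broken by leftmost forward-strand
#' coordinate, then '+' strand) and calls the assay activated when that best
#' hit is within `activation_max_mm` mismatches.
#'
#' @param crrna one-row data.frame from [design_crrna()], or a bare DNA
#'   spacer string.
#' @param substrate DNA string (forward strand of the amplicon or genomic
#'   slice; both strands are searched).
#' @param activation_max_mm largest mismatch count that still activates
#'   (default 2; activation at 0 and non-activation at 3 are the anchored
#'   observations).
#' @param require_pam require the TTTV PAM at the recognition site
#'   (default TRUE).
#' @return list of class `cas12a_detection`: `activated` (logical),
#'   `best_hit` (one-row data.frame or NULL), `rationale` (text).
#' @export
simulate_cas12a <- function(crrna, substrate, activation_max_mm = 2L,
                            require_pam = TRUE) {
  if (is.data.frame(crrna)) {
    stopifnot(nrow(crrna) == 1L)
    spacer <- crrna$spacer_dna
    id <- crrna$crrna_id
  } else {
    spacer <- toupper(chartr("U", "T", as.character(crrna)))
    id <- "crRNA"
  }
  stopifnot(activation_max_mm >= 0L, activation_max_mm <= nchar(spacer))
  substrate <- toupper(as.character(substrate))
  k <- nchar(spacer) + 4L
  if (nchar(substrate) < k) {
    return(structure(list(activated = FALSE, best_hit = NULL,
                          rationale = "substrate shorter than one full site"),
                     class = "cas12a_detection"))
  }
  g <- ps_genome(c(substrate = substrate), genome_id = "substrate")
  hits <- search_spacers(spacer, id, g, max_mm = nchar(spacer),
                         require_pam = require_pam)
  if (nrow(hits) == 0L) {
    return(structure(list(activated = FALSE, best_hit = NULL,
                          rationale = if (require_pam)
                            "no PAM-adjacent site in the substrate"
                          else "no comparable site in the substrate"),
                     class = "cas12a_detection"))
  }
  hits <- hits[order(hits$mismatches, hits$start, hits$strand), , drop = FALSE]
  best <- hits[1L, , drop = FALSE]
  rownames(best) <- NULL
  activated <- best$mismatches <= activation_max_mm
  structure(list(
    activated = activated, best_hit = best,
    rationale = sprintf("best site at %d mismatch(es) (%s strand, position %d); threshold %d: %s",
                        best$mismatches, best$strand, best$start,
                        as.integer(activation_max_mm),
                        if (activated) "collateral cleavage predicted"
                        else "no activation")),
    class = "cas12a_detection")
}

#' @export
print.cas12a_detection <- function(x, ...) {
  cat(sprintf("<cas12a_detection> activated: %s\n  %s\n",
              x$activated, x$rationale))
  invisible(x)
}

#' Simulate a detection panel
#'
#' Applies [simulate_cas12a()] to each substrate in turn — the in-silico
#' analogue of assaying one crRNA against amplicons from a panel of species.
#'
#' @inheritParams simulate_cas12a
#' @param substrates named character vector or named list of DNA strings.
#' @return data.frame with one row per substrate, in input order:
#'   `substrate`, `activated`, `best_mismatches` (NA when no site).
#' @export
simulate_panel <- function(crrna, substrates, activation_max_mm = 2L,
                           require_pam = TRUE) {
  substrates <- as.list(substrates)
  if (length(substrates) == 0L)
    return(data.frame(substrate = character(), activated = logical(),
                      best_mismatches = integer(), stringsAsFactors = FALSE))
  nm <- names(substrates)
  if (is.null(nm) || any(!nzchar(nm))) stop("substrates must be named")
  res <- lapply(substrates, simulate_cas12a, crrna = crrna,
                activation_max_mm = activation_max_mm,
                require_pam = require_pam)
  data.frame(substrate = nm,
             activated = vapply(res, `[[`, logical(1), "activated"),
             best_mismatches = vapply(res, function(r) {
               if (is.null(r$best_hit)) NA_integer_
               else as.integer(r$best_hit$mismatches)
             }, integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
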