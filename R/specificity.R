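# Cross-genome specificity screening: mismatch-tolerant, PAM-anchored search
# of target protospacers against comparator genomes, per-genome mismatch
# histograms, and specificity classification.

# Internal: run the compiled search for a set of protospacers against a
# genome and decorate the raw hits with names and site sequences.
search_spacers <- function(spacers, target_ids, genome, max_mm = 5L,
                           require_pam = TRUE, pam = "TTTV") {
  stopifnot(methods::is(genome, "ps_genome"))
  hits <- cpp_search_offtargets(unname(contig_chars(genome)),
                                as.character(spacers), pam,
                                as.integer(max_mm), isTRUE(require_pam))
  cnames <- names(genome$contigs)
  k <- nchar(pam) + nchar(spacers[1])
  site <- character(nrow(hits))
  if (nrow(hits) > 0L) {
    chars <- contig_chars(genome)
    site <- substr(chars[hits$contig], hits$start + 1L, hits$start + k)
    minus <- hits$strand == "-"
    if (any(minus)) site[minus] <- revcomp(site[minus])
    site <- unname(site)
  }
  data.frame(target_id = target_ids[hits$query],
             genome_id = rep(genome$genome_id, nrow(hits)),
             contig = cnames[hits$contig],
             start = hits$start,
             strand = hits$strand,
             site_sequence = site,
             mismatches = hits$mismatches,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Find off-target sites of a target in a comparator genome
#'
#' Scans both strands of `comparator` for k-bp windows whose PAM matches
#' TTTV (when `require_pam`) and whose post-PAM segment is within Hamming
#' distance `max_mm` of the target's protospacer. Mismatches are counted
#' over the protospacer only; the PAM must match the pattern exactly
#' (the convention of PAM-aware off-target searchers). Windows containing
#' N never match.
#'
#' The search uses pigeonhole seeding with an exact verification step and is
#' output-equivalent to [brute_force_offtargets()]; the test suite asserts
#' exact set equality of the two on randomized instances.
#'
#' @param target one-row target data.frame ([enumerate_targets()] row or
#'   [target_from_sequence()]).
#' @param comparator a [ps_genome] to search.
#' @param max_mm maximum Hamming distance reported (default 5, the
#'   five-mismatch screening window).
#' @param require_pam require the TTTV PAM at candidate sites (default
#'   TRUE). With FALSE every N-free window is compared over its post-PAM
#'   segment regardless of its leading bases.
#' @param pam IUPAC PAM pattern (default `"TTTV"`).
#' @return data.frame of hits sorted by (contig, start, strand): `target_id`,
#'   `genome_id`, `contig`, `start` (0-based), `strand`, `site_sequence`
#'   (k-mer, PAM first), `mismatches`.
#' @export
find_offtargets <- function(target, comparator, max_mm = 5L,
                            require_pam = TRUE, pam = "TTTV") {
  stopifnot(nrow(target) == 1L)
  search_spacers(target$protospacer, target$target_id, comparator,
                 max_mm = max_mm, require_pam = require_pam, pam = pam)
}

#' Brute-force off-target scan (reference implementation)
#'
#' Same contract as [find_offtargets()], implemented as a plain scan of
#' every window of the comparator with positionwise base comparison over raw
#' byte vectors. It shares no code with the seeded search and serves as the
#' independent oracle in the test suite; a size cap keeps accidental use on
#' large genomes in check.
#'
#' @inheritParams find_offtargets
#' @param cap maximum comparator length in bp (default 1e6).
#' @return data.frame in the same format and order as [find_offtargets()].
#' @export
brute_force_offtargets <- function(target, comparator, max_mm = 5L,
                                   require_pam = TRUE, cap = 1e6) {
  stopifnot(nrow(target) == 1L)
  if (comparator$total_length > cap)
    stop("comparator exceeds the brute-force cap (", format(cap), " bp)")
  spacer <- target$protospacer
  S <- nchar(spacer)
  k <- S + 4L
  sp <- charToRaw(spacer)
  rcsp <- charToRaw(revcomp(spacer))
  rA <- charToRaw("A"); rC <- charToRaw("C"); rG <- charToRaw("G")
  rT <- charToRaw("T"); rN <- charToRaw("N")
  out <- list()
  chars <- contig_chars(comparator)
  for (ci in seq_along(chars)) {
    bytes <- charToRaw(chars[[ci]])
    L <- length(bytes)
    np <- L - k + 1L
    if (np <= 0L) next
    p <- 0:(np - 1L)                       # 0-based window starts
    ncum <- c(0L, cumsum(bytes == rN))
    ok <- (ncum[p + k + 1L] - ncum[p + 1L]) == 0L
    # PAM TTTV on the forward strand at window start
    pam_p <- bytes[p + 1L] == rT & bytes[p + 2L] == rT & bytes[p + 3L] == rT &
      (bytes[p + 4L] == rA | bytes[p + 4L] == rC | bytes[p + 4L] == rG)
    # PAM TTTV on the reverse-complement site: forward bases ...B,A,A,A at
    # the window's right end, B != A (and not N)
    b <- bytes[p + k - 3L]
    pam_m <- bytes[p + k] == rA & bytes[p + k - 1L] == rA &
      bytes[p + k - 2L] == rA & (b == rC | b == rG | b == rT)
    # positionwise comparison; with require_pam only PAM-matching windows
    # need their mismatch count
    wp <- if (require_pam) p[ok & pam_p] else p[ok]
    wm <- if (require_pam) p[ok & pam_m] else p[ok]
    mm_p <- integer(length(wp))
    mm_m <- integer(length(wm))
    for (t in seq_len(S)) {
      if (length(wp)) mm_p <- mm_p + as.integer(bytes[wp + 4L + t] != sp[t])
      if (length(wm)) mm_m <- mm_m + as.integer(bytes[wm + t] != rcsp[t])
    }
    sel_p <- mm_p <= max_mm
    sel_m <- mm_m <= max_mm
    rows <- list()
    if (any(sel_p))
      rows$p <- data.frame(contig = names(chars)[ci], start = wp[sel_p],
                           strand = "+", mismatches = mm_p[sel_p],
                           stringsAsFactors = FALSE)
    if (any(sel_m))
      rows$m <- data.frame(contig = names(chars)[ci], start = wm[sel_m],
                           strand = "-", mismatches = mm_m[sel_m],
                           stringsAsFactors = FALSE)
    if (length(rows)) out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  if (length(out) == 0L)
    return(data.frame(target_id = character(), genome_id = character(),
                      contig = character(), start = integer(),
                      strand = character(), site_sequence = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  hits <- do.call(rbind, out)
  cidx <- match(hits$contig, names(chars))
  hits <- hits[order(cidx, hits$start, hits$strand), , drop = FALSE]
  site <- substr(chars[match(hits$contig, names(chars))],
                 hits$start + 1L, hits$start + k)
  minus <- hits$strand == "-"
  if (any(minus)) site[minus] <- revcomp(site[minus])
  res <- data.frame(target_id = target$target_id,
                    genome_id = comparator$genome_id,
                    contig = hits$contig, start = hits$start,
                    strand = hits$strand, site_sequence = site,
                    mismatches = hits$mismatches, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Mismatch histogram of a target against a genome
#'
#' Counts off-target hits of a target at each Hamming distance 0..`max_mm`
#' in a genome — the per-species "similar sequences by mismatch number"
#' profile. When the genome is the target's own and `exclude_self_site` is
#' TRUE, the target's own locus (identified by coordinates, not sequence,
#' so duplicated copies elsewhere still count) is removed from the
#' distance-0 bin.
#'
#' @inheritParams find_offtargets
#' @param exclude_self_site drop the target's own locus from the 0 bin when
#'   screening its own genome (default TRUE).
#' @return named integer vector of counts, names `"0"`..`"max_mm"`.
#' @export
mismatch_histogram <- function(target, comparator, max_mm = 5L,
                               exclude_self_site = TRUE, require_pam = TRUE) {
  hits <- find_offtargets(target, comparator, max_mm = max_mm,
                          require_pam = require_pam)
  if (exclude_self_site &&
      identical(comparator$genome_id, target$genome_id) &&
      !is.na(target$start)) {
    self <- hits$contig == target$contig & hits$start == target$start &
      hits$strand == target$strand
    hits <- hits[!self, , drop = FALSE]
  }
  counts <- tabulate(hits$mismatches + 1L, nbins = max_mm + 1L)
  stats::setNames(as.integer(counts), as.character(0:max_mm))
}

#' Screen targets for cross-genome specificity
#'
#' Builds a per-comparator mismatch histogram for every target and assigns a
#' specificity class:
#' \describe{
#'   \item{ultra_specific}{no comparator has any PAM-bearing site within
#'     `max_mm` mismatches — the strictest selection, used for diagnostic
#'     targets between closely related species.}
#'   \item{specific}{every comparator's closest site is at distance >=
#'     `specific_min_distance` (default 3, the experimentally supported
#'     non-activation distance for Cas12a).}
#'   \item{non_specific}{some comparator has a closer site.}
#' }
#'
#' @param targets data.frame from [enumerate_targets()] (or rows built with
#'   [target_from_sequence()]).
#' @param comparators a [ps_genome] or list of them; must be non-empty.
#' @inheritParams find_offtargets
#' @param specific_min_distance minimum closest-site distance for the
#'   `specific` class (default 3).
#' @return object of class `specificity_screen`: list with `profiles`
#'   (data.frame target_id x comparator with histogram columns `mm0`..,
#'   and `min_distance`, NA when no hit), `classification` (data.frame
#'   `target_id`, `min_cross_distance`, `specificity_class`) and `params`.
#' @export
screen_specific <- function(targets, comparators, max_mm = 5L,
                            specific_min_distance = 3L, require_pam = TRUE,
                            pam = "TTTV") {
  if (methods::is(comparators, "ps_genome")) comparators <- list(comparators)
  if (length(comparators) == 0L) stop("no comparators")
  if (specific_min_distance > max_mm + 1L)
    stop("specific_min_distance must be <= max_mm + 1")
  if (nrow(targets) == 0L) stop("no targets to screen")
  nt <- nrow(targets)
  mm_cols <- paste0("mm", 0:max_mm)
  profiles <- vector("list", length(comparators))
  for (gi in seq_along(comparators)) {
    cmp <- comparators[[gi]]
    hits <- search_spacers(targets$protospacer, targets$target_id, cmp,
                           max_mm = max_mm, require_pam = require_pam,
                           pam = pam)
    counts <- matrix(0L, nrow = nt, ncol = max_mm + 1L,
                     dimnames = list(NULL, mm_cols))
    if (nrow(hits) > 0L) {
      ti <- match(hits$target_id, targets$target_id)
      tb <- table(factor(ti, levels = seq_len(nt)),
                  factor(hits$mismatches, levels = 0:max_mm))
      counts[] <- as.integer(tb)
    }
    mind <- apply(counts, 1L, function(cc) {
      nz <- which(cc > 0L)
      if (length(nz)) nz[1L] - 1L else NA_integer_
    })
    profiles[[gi]] <- data.frame(target_id = targets$target_id,
                                 comparator = cmp$genome_id,
                                 counts, min_distance = as.integer(mind),
                                 stringsAsFactors = FALSE)
  }
  prof <- do.call(rbind, profiles)
  rownames(prof) <- NULL
  md <- matrix(prof$min_distance, nrow = nt)   # targets x comparators
  any_hit <- apply(md, 1L, function(d) any(!is.na(d)))
  min_cross <- apply(md, 1L, function(d) if (all(is.na(d))) NA_integer_
                     else min(d, na.rm = TRUE))
  cls <- ifelse(!any_hit, "ultra_specific",
                ifelse(min_cross >= specific_min_distance,
                       "specific", "non_specific"))
  structure(list(
    profiles = prof,
    classification = data.frame(target_id = targets$target_id,
                                min_cross_distance = min_cross,
                                specificity_class = cls,
                                stringsAsFactors = FALSE),
    params = list(max_mm = as.integer(max_mm),
                  specific_min_distance = as.integer(specific_min_distance),
                  require_pam = require_pam, pam = pam,
                  comparators = vapply(comparators, function(g) g$genome_id,
                                       character(1)))),
    class = "specificity_screen")
}

#' @export
print.specificity_screen <- function(x, ...) {
  tab <- table(factor(x$classification$specificity_class,
                      levels = c("ultra_specific", "specific", "non_specific")))
  cat(sprintf("<specificity_screen> %d target(s) vs %d comparator(s) (max_mm = %d)\n",
              nrow(x$classification), length(x$params$comparators),
              x$params$max_mm))
  cat(sprintf("  ultra_specific: %d | specific: %d | non_specific: %d\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Long-format histogram table of a specificity screen
#'
#' One row per target x comparator x distance, matching the structure of a
#' per-species mismatch-count figure.
#'
#' @param x a `specificity_screen`.
#' @param ... unused.
#' @return data.frame with `target_id`, `genome_id`, `distance`, `count`.
#' @export
as.data.frame.specificity_screen <- function(x, ...) {
  prof <- x$profiles
  mm_cols <- grep("^mm[0-9]+$", names(prof), value = TRUE)
  long <- do.call(rbind, lapply(mm_cols, function(cc) {
    data.frame(target_id = prof$target_id, genome_id = prof$comparator,
               distance = as.integer(sub("mm", "", cc)),
               count = prof[[cc]], stringsAsFactors = FALSE)
  }))
  long <- long[order(match(long$target_id, unique(prof$target_id)),
                     match(long$genome_id, unique(prof$comparator)),
                     long$distance), , drop = FALSE]
  rownames(long) <- NULL
  long
}
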