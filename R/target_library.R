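#' Enumerate PAM-anchored candidate targets
#'
#' Scans both strands of every contig for k-mers whose first bases match the
#' PAM pattern (default the Cas12a TTTV motif: TTT then A/C/G) and returns
#' one record per site. This is the sliding-window enumeration of all
#' (L - k + 1) k-mers per strand, keeping those that start with the PAM;
#' overlapping windows are all kept and windows containing N are skipped.
#'
#' `copy_number` is the number of occurrences of each returned k-mer in the
#' whole source genome, counting both strands, so a unique site has
#' copy_number 1 (itself).
#'
#' @param genome a [ps_genome].
#' @param k target length in bp (PAM included); the Cas12a screen uses 25.
#' @param pam IUPAC pattern anchoring the k-mer start; default `"TTTV"`.
#' @return data.frame with one row per site, sorted by (contig, start,
#'   strand), columns `target_id`, `genome_id`, `contig`, `start` (0-based,
#'   leftmost forward-strand coordinate of the k-bp window), `strand`,
#'   `sequence` (k-mer, PAM first; reverse-complemented for minus-strand
#'   sites), `pam`, `protospacer` (k-mer minus its PAM), `copy_number`.
#' @examples
#' g <- ps_genome(c(c1 = paste0("TTTG", strrep("A", 21))), "demo")
#' enumerate_targets(g)
#' @export
enumerate_targets <- function(genome, k = 25L, pam = "TTTV") {
  stopifnot(methods::is(genome, "ps_genome"))
  k <- as.integer(k)
  plen <- nchar(pam)
  if (k < 5L) stop("k must be >= 5")
  if (k < plen + 1L) stop("k must exceed the PAM length")
  if (k > 32L) stop("k must be <= 32")

  pampat <- Biostrings::DNAString(pam)
  rows <- vector("list", 2L * length(genome$contigs))
  ri <- 0L
  for (ci in seq_along(genome$contigs)) {
    cname <- names(genome$contigs)[ci]
    sq <- genome$contigs[[ci]]
    L <- length(sq)
    if (L < k) next
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") sq else Biostrings::reverseComplement(sq)
      m <- Biostrings::matchPattern(pampat, subj, fixed = "subject")
      s1 <- BiocGenerics::start(m)                  # 1-based PAM start
      s1 <- s1[s1 + k - 1L <= L]
      if (length(s1) == 0L) next
      wins <- as.character(Biostrings::extractAt(
        subj, IRanges::IRanges(start = s1, width = k)))
      keep <- !grepl("N", wins, fixed = TRUE)
      s1 <- s1[keep]; wins <- wins[keep]
      if (length(s1) == 0L) next
      start0 <- if (strand == "+") s1 - 1L else L - (s1 - 1L) - k
      ri <- ri + 1L
      rows[[ri]] <- data.frame(genome_id = genome$genome_id, contig = cname,
                               start = start0, strand = strand,
                               sequence = wins, stringsAsFactors = FALSE)
    }
  }
  if (ri == 0L) {
    out <- data.frame(target_id = character(), genome_id = character(),
                      contig = character(), start = integer(),
                      strand = character(), sequence = character(),
                      pam = character(), protospacer = character(),
                      copy_number = integer(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  cidx <- match(out$contig, names(genome$contigs))
  out <- out[order(cidx, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$pam <- substr(out$sequence, 1L, plen)
  out$protospacer <- substr(out$sequence, plen + 1L, k)
  out$target_id <- sprintf("%s:%s:%d:%s", out$genome_id, out$contig,
                           out$start, out$strand)
  out$copy_number <- count_occurrences(out$sequence, genome)
  out[, c("target_id", "genome_id", "contig", "start", "strand",
          "sequence", "pam", "protospacer", "copy_number")]
}

# Exact occurrence count of each k-mer over both strands of a genome.
count_occurrences <- function(sequences, genome) {
  if (length(sequences) == 0L) return(integer(0))
  uniq <- unique(sequences)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(uniq))
  fwd <- rowSums(Biostrings::vcountPDict(pd, genome$contigs))
  rev <- rowSums(Biostrings::vcountPDict(
    pd, Biostrings::reverseComplement(genome$contigs)))
  (fwd + rev)[match(sequences, uniq)]
}

#' Library-level target statistics
#'
#' Summarizes an enumerated target library: number of sites (positions on
#' either strand), number of distinct k-mer sequences, and the mean spacing
#' `total_length / n_target_sites` — the "one target per X bp" density.
#'
#' @param genome the [ps_genome] the targets were enumerated from.
#' @param targets output of [enumerate_targets()].
#' @return one-row data.frame with `genome_id`, `n_target_sites`,
#'   `n_distinct_sequences`, `mean_spacing_bp` (NA when there are no sites).
#' @export
library_stats <- function(genome, targets) {
  n <- nrow(targets)
  data.frame(genome_id = genome$genome_id,
             n_target_sites = n,
             n_distinct_sequences = length(unique(targets$sequence)),
             mean_spacing_bp = if (n > 0L) genome$total_length / n else NA_real_,
             stringsAsFactors = FALSE)
}

#' Restrict targets to annotated regions
#'
#' Keeps the targets whose whole k-bp window is contained in at least one
#' region (partial overlap is not enough: a diagnostic amplicon must carry
#' the complete site). Order is preserved.
#'
#' @param targets output of [enumerate_targets()].
#' @param regions data.frame from [read_regions()].
#' @param genome optional [ps_genome]; when supplied, regions naming unknown
#'   contigs raise a warning and are ignored.
#' @return the filtered target data.frame.
#' @export
filter_by_region <- function(targets, regions, genome = NULL) {
  if (nrow(targets) == 0L || nrow(regions) == 0L)
    return(targets[integer(0), , drop = FALSE])
  if (!is.null(genome)) {
    unknown <- !(regions$contig %in% names(genome$contigs))
    if (any(unknown)) {
      warning("ignoring region(s) on unknown contig(s): ",
              paste(unique(regions$contig[unknown]), collapse = ", "))
      regions <- regions[!unknown, , drop = FALSE]
    }
  }
  k <- nchar(targets$sequence)
  keep <- rep(FALSE, nrow(targets))
  for (i in seq_len(nrow(regions))) {
    keep <- keep | (targets$contig == regions$contig[i] &
                      targets$start >= regions$start[i] &
                      targets$start + k <= regions$end[i])
  }
  out <- targets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract a target with flanking sequence
#'
#' Returns the forward-strand slice covering the target window plus `flank`
#' bp on each side — the context used to design amplification primers around
#' a diagnostic site. The slice is clipped at contig ends and flagged.
#'
#' @param genome the [ps_genome] the target belongs to.
#' @param target one-row data.frame (a row of [enumerate_targets()] output).
#' @param flank bp of context on each side (default 500).
#' @return list with `contig`, `start`, `end` (0-based half-open),
#'   `sequence` (forward strand) and `clipped` (logical).
#' @export
extract_flanks <- function(genome, target, flank = 500L) {
  stopifnot(nrow(target) == 1L)
  if (!identical(target$genome_id, genome$genome_id))
    stop("target does not belong to genome '", genome$genome_id, "'")
  ci <- match(target$contig, names(genome$contigs))
  if (is.na(ci)) stop("target contig '", target$contig, "' not in genome")
  L <- BiocGenerics::width(genome$contigs)[ci]
  k <- nchar(target$sequence)
  s <- max(0L, target$start - as.integer(flank))
  e <- min(L, target$start + k + as.integer(flank))
  list(contig = target$contig, start = s, end = e,
       sequence = as.character(Biostrings::subseq(genome$contigs[[ci]],
                                                  start = s + 1L, end = e)),
       clipped = (s > target$start - flank) || (e < target$start + k + flank))
}

#' Build a target record from a bare sequence
#'
#' Wraps a user-supplied PAM-anchored sequence (e.g. a published diagnostic
#' target) in the record structure used by the screening and detection
#' functions. The sequence must start with the PAM pattern.
#'
#' @param sequence k-mer DNA string beginning with the PAM.
#' @param genome_id,target_id labels; `target_id` defaults to the sequence.
#' @param pam IUPAC PAM pattern (default `"TTTV"`).
#' @return one-row target data.frame (positional fields NA).
#' @export
target_from_sequence <- function(sequence, genome_id = "query",
                                 target_id = NULL, pam = "TTTV") {
  sequence <- toupper(gsub("\\s", "", sequence))
  plen <- nchar(pam)
  if (nchar(sequence) < plen + 1L) stop("sequence shorter than PAM + 1")
  if (grepl("[^ACGT]", sequence)) stop("sequence must be over A/C/G/T")
  head <- substr(sequence, 1L, plen)
  if (length(Biostrings::matchPattern(Biostrings::DNAString(pam),
                                      Biostrings::DNAString(head),
                                      fixed = "subject")) == 0L)
    stop("sequence does not start with PAM pattern ", pam)
  if (is.null(target_id)) target_id <- sequence
  data.frame(target_id = target_id, genome_id = genome_id,
             contig = NA_character_, start = NA_integer_,
             strand = NA_character_, sequence = sequence, pam = head,
             protospacer = substr(sequence, plen + 1L, nchar(sequence)),
             copy_number = NA_integer_, stringsAsFactors = FALSE)
}
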