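#' Genome container
#'
#' A genome is a labelled, ordered set of contigs held as a
#' [Biostrings::DNAStringSet]. Sequences are uppercase over A/C/G/T/N;
#' coordinates throughout the package are 0-based, half-open (BED native).
#'
#' @param contigs named character vector or `DNAStringSet` of contig
#'   sequences; names must be unique.
#' @param genome_id species/sample label attached to every record derived
#'   from this genome.
#' @param iupac_to_n map IUPAC ambiguity codes other than N to N instead of
#'   raising an error. Defaults to `FALSE`: silent conversion can hide
#'   assembly artifacts.
#' @return An object of class `ps_genome` with elements `genome_id`,
#'   `contigs` (DNAStringSet) and `total_length` (bp).
#' @examples
#' g <- ps_genome(c(c1 = "ACGTTTGA"), "demo")
#' g$total_length
#' @export
ps_genome <- function(contigs, genome_id = "genome", iupac_to_n = FALSE) {
  if (is.character(contigs)) {
    if (is.null(names(contigs)) || anyNA(names(contigs)) || any(names(contigs) == ""))
      stop("contigs must be named")
    contigs <- Biostrings::DNAStringSet(toupper(contigs))
  }
  if (!methods::is(contigs, "DNAStringSet"))
    stop("contigs must be a character vector or DNAStringSet")
  if (length(contigs) == 0L) stop("no sequences")
  nm <- names(contigs)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) stop("contigs must be named")
  if (anyDuplicated(nm)) stop("duplicate contig names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  af <- Biostrings::alphabetFrequency(contigs, baseOnly = TRUE)
  n_other <- af[, "other"] - Biostrings::letterFrequency(contigs, "N")[, 1]
  if (any(n_other > 0)) {
    if (iupac_to_n) {
      contigs <- Biostrings::replaceAmbiguities(contigs, new = "N")
    } else {
      bad <- which(n_other > 0)[1]
      pos <- regexpr("[^ACGTN]", as.character(contigs[[bad]]))
      stop(sprintf("contig '%s' has a non-ACGTN residue at position %d (use iupac_to_n = TRUE to map to N)",
                   nm[bad], as.integer(pos)))
    }
  }
  structure(list(genome_id = as.character(genome_id),
                 contigs = contigs,
                 total_length = sum(BiocGenerics::width(contigs))),
            class = "ps_genome")
}

#' @export
print.ps_genome <- function(x, ...) {
  cat(sprintf("<ps_genome> %s: %d contig(s), %s bp\n", x$genome_id,
              length(x$contigs), format(x$total_length, big.mark = ",")))
  invisible(x)
}

# contig sequences as plain character, named
contig_chars <- function(genome) {
  stats::setNames(as.character(genome$contigs), names(genome$contigs))
}

#' Read a genome from FASTA
#'
#' Sequences are normalized to uppercase. Residues other than A/C/G/T/N are
#' rejected with an error naming the contig and position unless
#' `iupac_to_n = TRUE`.
#'
#' @param path FASTA file.
#' @param genome_id label for the genome; defaults to the file name without
#'   extension.
#' @inheritParams ps_genome
#' @return A [ps_genome] with contigs in file order. FASTA headers are
#'   truncated at the first whitespace.
#' @export
read_fasta <- function(path, genome_id = NULL, iupac_to_n = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("no sequences in ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate FASTA headers in ", path, ": ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (is.null(genome_id))
    genome_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  ps_genome(x, genome_id = genome_id, iupac_to_n = iupac_to_n)
}

#' Write a genome (or named sequences) to FASTA
#'
#' @param x a [ps_genome] or named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (methods::is(x, "ps_genome")) x$contigs
          else Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read region annotations from BED or GFF3
#'
#' Regions (e.g. ITS coordinates) are returned in the package's internal
#' convention: 0-based, half-open. BED is used as-is; GFF3 1-based inclusive
#' starts are converted by subtracting 1.
#'
#' @param path BED or GFF3 file.
#' @param format `"BED"` or `"GFF3"`; guessed from the file extension when
#'   missing.
#' @return data.frame with columns `contig`, `start`, `end`, `label`.
#' @export
read_regions <- function(path, format = c("auto", "BED", "GFF3")) {
  format <- match.arg(toupper(format[1]), c("AUTO", "BED", "GFF3"))
  if (format == "AUTO") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "GFF3" else "BED"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "BED") {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
    lines <- lines[keep]
    if (length(lines) == 0L)
      return(data.frame(contig = character(), start = integer(),
                        end = integer(), label = character(),
                        stringsAsFactors = FALSE))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
      stop("malformed BED line ", which(keep)[which(nf < 3L)[1]],
           " in ", path, " (fewer than 3 fields)")
    starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    if (anyNA(starts) || anyNA(ends))
      stop("malformed BED line ", which(keep)[which(is.na(starts) | is.na(ends))[1]],
           " in ", path, " (non-numeric coordinates)")
    if (any(starts < 0L) || any(ends <= starts))
      stop("malformed BED line ", which(keep)[which(starts < 0L | ends <= starts)[1]],
           " in ", path, " (requires 0 <= start < end)")
    data.frame(contig = vapply(fields, `[[`, "", 1L),
               start = starts, end = ends,
               label = ifelse(nf >= 4L,
                              vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "", ""),
                              ""),
               stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    lab <- gr$Name
    if (is.null(lab)) lab <- gr$ID
    if (is.null(lab)) lab <- as.character(gr$type)
    data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr),
               label = ifelse(is.na(lab) | lab == "", as.character(gr$type), lab),
               stringsAsFactors = FALSE)
  }
}

#' Write a target table (TSV + BED6 companion)
#'
#' Writes a tab-separated table with a header. When the input carries genomic
#' positions (the output of [enumerate_targets()]), a BED6 companion file is
#' also written (contig, start, end, target_id, copy_number as score, strand).
#'
#' @param x data.frame of targets ([enumerate_targets()]) or long-format
#'   profiles ([as.data.frame.specificity_screen()]).
#' @param path output TSV path; the BED companion replaces the extension
#'   with `.bed`.
#' @return invisibly, the path(s) written.
#' @export
write_targets_table <- function(x, path) {
  if (methods::is(x, "specificity_screen")) x <- as.data.frame(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- path
  if (all(c("contig", "start", "strand", "target_id") %in% names(x))) {
    bed_path <- sub("\\.[^.]*$", "", path)
    bed_path <- paste0(bed_path, ".bed")
    k <- if ("sequence" %in% names(x) && nrow(x) > 0) nchar(x$sequence) else integer(0)
    score <- if ("copy_number" %in% names(x)) x$copy_number else rep(0L, nrow(x))
    bed <- data.frame(x$contig, x$start, x$start + k, x$target_id, score,
                      x$strand, stringsAsFactors = FALSE)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    out <- c(out, bed_path)
  }
  invisible(out)
}
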