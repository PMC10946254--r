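#' Pipeline run configuration
#'
#' Bundles and validates every parameter of the end-to-end workflow. The
#' target length `k` may range over 23-27 (protospacer length is re-derived
#' as `k - 4`); 25 is the default everywhere.
#'
#' @param focal path to the focal-species genome FASTA (or a [ps_genome]).
#' @param comparators character vector of comparator FASTA paths (or list
#'   of [ps_genome]s); may be empty to skip screening.
#' @param out_dir output directory, created if missing.
#' @param k target length in bp (23-27; default 25).
#' @param pam PAM pattern (default "TTTV").
#' @param max_mm off-target search radius (default 5).
#' @param specific_min_distance `specific` class threshold (default 3).
#' @param activation_max_mm Cas12a activation threshold (default 2).
#' @param flank amplicon context in bp for flank extraction (default 500).
#' @param regions optional BED/GFF3 path (or regions data.frame) restricting
#'   the library, e.g. ITS coordinates.
#' @param substrates optional FASTA path (or named character vector) of
#'   substrates for the detection stage.
#' @param iupac_to_n residue policy passed to [read_fasta()].
#' @return a validated list of class `ps_run_config`.
#' @export
run_config <- function(focal, comparators = character(), out_dir = "pamscreen_out",
                       k = 25L, pam = "TTTV", max_mm = 5L,
                       specific_min_distance = 3L, activation_max_mm = 2L,
                       flank = 500L, regions = NULL, substrates = NULL,
                       iupac_to_n = FALSE) {
  k <- as.integer(k)
  if (k < 23L || k > 27L) stop("k must be in 23..27")
  if (max_mm < 0L || max_mm > k - nchar(pam)) stop("max_mm out of range")
  if (specific_min_distance > max_mm + 1L)
    stop("specific_min_distance must be <= max_mm + 1")
  if (activation_max_mm < 0L || activation_max_mm > k - nchar(pam))
    stop("activation_max_mm out of range")
  if (flank < 0L) stop("flank must be >= 0")
  structure(list(focal = focal, comparators = comparators, out_dir = out_dir,
                 k = k, pam = pam, max_mm = as.integer(max_mm),
                 specific_min_distance = as.integer(specific_min_distance),
                 activation_max_mm = as.integer(activation_max_mm),
                 flank = as.integer(flank), regions = regions,
                 substrates = substrates, iupac_to_n = iupac_to_n),
            class = "ps_run_config")
}

#' Run the full screening workflow
#'
#' Executes build-library, the optional region filter, cross-genome
#' screening, crRNA design and the optional detection simulation, writing
#' TSV/BED outputs plus a machine-readable JSON manifest (parameters, input
#' checksums, package version, stages run). Reports contain no timestamps,
#' so reruns on identical inputs are byte-identical.
#'
#' @param config a [run_config()].
#' @return invisibly, a named list of output paths (plus the in-memory
#'   results as attribute `"results"`).
#' @export
run_pipeline <- function(config) {
  stopifnot(methods::is(config, "ps_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  checksums <- list()
  load_genome <- function(x, role) {
    if (methods::is(x, "ps_genome")) return(x)
    checksums[[paste0(role, ":", basename(x))]] <<- unname(tools::md5sum(x))
    read_fasta(x, iupac_to_n = config$iupac_to_n)
  }

  message("[build-library] enumerating targets")
  focal <- load_genome(config$focal, "focal")
  targets <- enumerate_targets(focal, k = config$k, pam = config$pam)
  stats <- library_stats(focal, targets)
  stages <- c(stages, "build-library")

  if (!is.null(config$regions)) {
    message("[filter-regions] restricting to annotated regions")
    regions <- if (is.data.frame(config$regions)) config$regions
               else read_regions(config$regions)
    targets <- filter_by_region(targets, regions, genome = focal)
    stages <- c(stages, "filter-regions")
  }

  paths <- list(targets = file.path(config$out_dir, "targets.tsv"),
                stats = file.path(config$out_dir, "library_stats.tsv"))
  write_targets_table(targets, paths$targets)
  utils::write.table(stats, paths$stats, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  screen <- NULL
  if (length(config$comparators) > 0L) {
    message("[screen] screening ", nrow(targets), " target(s) against ",
            length(config$comparators), " comparator genome(s)")
    if (nrow(targets) == 0L) stop("stage screen: no targets to screen")
    comparators <- lapply(config$comparators, load_genome, role = "comparator")
    screen <- screen_specific(targets, comparators, max_mm = config$max_mm,
                              specific_min_distance = config$specific_min_distance,
                              pam = config$pam)
    paths$profiles <- file.path(config$out_dir, "profiles.tsv")
    paths$histograms <- file.path(config$out_dir, "mismatch_histograms.tsv")
    paths$classification <- file.path(config$out_dir, "classification.tsv")
    utils::write.table(screen$profiles, paths$profiles, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(screen), paths$histograms, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(screen$classification, paths$classification,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages <- c(stages, "screen")
  }

  message("[design-crrna] deriving spacers")
  keep <- targets
  if (!is.null(screen)) {
    ok_ids <- screen$classification$target_id[
      screen$classification$specificity_class != "non_specific"]
    keep <- targets[targets$target_id %in% ok_ids, , drop = FALSE]
  }
  crrnas <- design_crrna(keep)
  paths$crrnas <- file.path(config$out_dir, "crrnas.tsv")
  utils::write.table(crrnas, paths$crrnas, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  stages <- c(stages, "design-crrna")

  verdicts <- NULL
  if (!is.null(config$substrates) && nrow(crrnas) > 0L) {
    message("[simulate-detect] predicting activation")
    subs <- config$substrates
    if (is.character(subs) && length(subs) == 1L && file.exists(subs)) {
      checksums[[paste0("substrates:", basename(subs))]] <-
        unname(tools::md5sum(subs))
      sg <- read_fasta(subs, iupac_to_n = config$iupac_to_n)
      subs <- contig_chars(sg)
    }
    verdicts <- simulate_panel(crrnas[1L, , drop = FALSE], subs,
                               activation_max_mm = config$activation_max_mm)
    paths$verdicts <- file.path(config$out_dir, "verdicts.tsv")
    utils::write.table(verdicts, paths$verdicts, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stages <- c(stages, "simulate-detect")
  }

  manifest <- list(
    tool = "pamscreen",
    version = as.character(utils::packageVersion("pamscreen")),
    parameters = list(k = config$k, pam = config$pam, max_mm = config$max_mm,
                      specific_min_distance = config$specific_min_distance,
                      activation_max_mm = config$activation_max_mm,
                      flank = config$flank),
    input_checksums = checksums,
    stages = stages,
    outputs = lapply(paths, basename))
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  out <- paths
  attr(out, "results") <- list(targets = targets, stats = stats,
                               screen = screen, crrnas = crrnas,
                               verdicts = verdicts)
  invisible(out)
}
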