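# Seeded generators of fixture genomes, planted targets/decoys and
# related-genome pairs. Backgrounds are i.i.d. bases (no repeat families or
# GC skew): enough to test search correctness with planted truth. A
# tandem-duplicated "repeats" preset stresses the seed index with
# near-duplicate blocks, which real fungal genomes do contain.

#' Generate a random genome with optional planted sequences
#'
#' Bases are drawn i.i.d. with P(G) + P(C) = `gc` (split equally within GC
#' and within AT). Planted sequences are written over the background at
#' their positions (reverse-complemented first for strand "-") and must not
#' overlap one another. Fully reproducible from `seed`.
#'
#' @param length contig length(s) in bp; a vector makes a multi-contig
#'   genome (contigs named `c1`, `c2`, ... unless `length` is named).
#' @param gc GC fraction in (0, 1), default 0.5.
#' @param seed integer seed.
#' @param plants optional data.frame with columns `sequence`, `contig`,
#'   `start` (0-based), `strand`.
#' @param genome_id label, default "synthetic".
#' @return a [ps_genome].
#' @export
make_genome <- function(length, gc = 0.5, seed = 1L, plants = NULL,
                        genome_id = "synthetic") {
  stopifnot(all(length >= 1L), gc > 0, gc < 1)
  nm <- names(length)
  if (is.null(nm)) nm <- paste0("c", seq_along(length))
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- with_seed(seed, {
    vapply(length, function(L) {
      paste(sample(names(prob), L, replace = TRUE, prob = prob),
            collapse = "")
    }, character(1))
  })
  names(seqs) <- nm
  if (!is.null(plants) && nrow(plants) > 0L) {
    plants$end <- plants$start + nchar(plants$sequence)
    for (cn in unique(plants$contig)) {
      pc <- plants[plants$contig == cn, , drop = FALSE]
      if (!cn %in% nm) stop("plant on unknown contig: ", cn)
      pc <- pc[order(pc$start), , drop = FALSE]
      if (nrow(pc) > 1L && any(pc$start[-1L] < pc$end[-nrow(pc)]))
        stop("planted intervals overlap on contig ", cn)
      if (any(pc$start < 0L) || any(pc$end > nchar(seqs[[cn]])))
        stop("plant outside contig bounds on ", cn)
      for (i in seq_len(nrow(pc))) {
        ins <- toupper(pc$sequence[i])
        if (identical(pc$strand[i], "-")) ins <- revcomp(ins)
        substr(seqs[[cn]], pc$start[i] + 1L, pc$end[i]) <- ins
      }
    }
  }
  ps_genome(seqs, genome_id = genome_id)
}

#' Make a decoy site at an exact mismatch distance from a target
#'
#' Returns a k-mer whose post-PAM segment is at Hamming distance exactly
#' `n_mismatch` from the target's protospacer. Substituted positions are
#' drawn without replacement and each substituted base differs from the
#' original. With `preserve_pam` the target's own PAM is kept; otherwise
#' the PAM is forced to TTTT, which fails the TTTV pattern, so a
#' PAM-requiring search must never report the decoy.
#'
#' @param target one-row target data.frame.
#' @param n_mismatch desired distance (0..protospacer length).
#' @param preserve_pam keep the PAM intact (default TRUE).
#' @param seed integer seed.
#' @return the decoy k-mer as a character string.
#' @export
make_decoy <- function(target, n_mismatch, preserve_pam = TRUE, seed = 1L) {
  stopifnot(nrow(target) == 1L)
  spacer <- strsplit(target$protospacer, "", fixed = TRUE)[[1]]
  S <- length(spacer)
  if (n_mismatch < 0L || n_mismatch > S)
    stop("n_mismatch must be in 0..", S)
  others <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
  mutated <- with_seed(seed, {
    pos <- if (n_mismatch > 0L) sample.int(S, n_mismatch) else integer(0)
    for (i in pos) spacer[i] <- sample(others[[spacer[i]]], 1L)
    spacer
  })
  pam <- if (preserve_pam) target$pam else strrep("T", nchar(target$pam))
  paste0(pam, paste(mutated, collapse = ""))
}

#' Generate a pair of closely related genomes
#'
#' Emulates a focal species and a close relative: the relative is the focal
#' background with each base independently substituted with probability
#' `1 - identity` (to a uniformly random different base; substitution-only,
#' matching the Hamming-distance world of the screen). Optionally a unique
#' PAM-anchored island is planted in the focal genome only; the island is
#' verified against the finished relative with the brute-force scan
#' (resampled under the seeded stream until it has no site within `max_mm`
#' mismatches), so its target is ultra-specific by construction.
#'
#' @param length genome length in bp (single contig), default 1e5.
#' @param gc GC fraction, default 0.5.
#' @param identity per-base identity of the pair in (0, 1], default 0.9.
#' @param seed integer seed.
#' @param plant_island plant a verified-unique k-bp island in the focal
#'   genome (default FALSE).
#' @param island_pos 0-based island start; default: contig midpoint.
#' @param k island length (default 25).
#' @param max_mm uniqueness window for island verification (default 5).
#' @param genome_ids labels for the two genomes.
#' @return list with `focal` and `relative` ([ps_genome]s) and `truth`
#'   (list: `island`, `island_pos`, `island_contig`, or NULL).
#' @export
make_related_pair <- function(length = 1e5, gc = 0.5, identity = 0.9,
                              seed = 1L, plant_island = FALSE,
                              island_pos = NULL, k = 25L, max_mm = 5L,
                              genome_ids = c("focal", "relative")) {
  stopifnot(identity > 0, identity <= 1, length >= k)
  base <- make_genome(length, gc = gc, seed = seed, genome_id = genome_ids[1])
  bg <- as.character(base$contigs[[1]])
  others <- matrix(c("C", "G", "T",  "A", "G", "T",
                     "A", "C", "T",  "A", "C", "G"),
                   nrow = 4L, byrow = TRUE,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  rel_chars <- with_seed(seed + 1L, {
    ch <- strsplit(bg, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length) < 1 - identity)
    if (length(hit)) {
      pick <- sample.int(3L, length(hit), replace = TRUE)
      ch[hit] <- others[cbind(match(ch[hit], rownames(others)), pick)]
    }
    ch
  })
  relative <- ps_genome(stats::setNames(paste(rel_chars, collapse = ""), "c1"),
                        genome_id = genome_ids[2])
  truth <- NULL
  focal_seq <- bg
  if (plant_island) {
    if (is.null(island_pos)) island_pos <- as.integer(length %/% 2)
    stopifnot(island_pos >= 0L, island_pos + k <= length)
    island <- with_seed(seed + 2L, {
      repeat {
        cand <- paste0("TTT", sample(c("A", "C", "G"), 1L),
                       paste(sample(c("A", "C", "G", "T"), k - 4L,
                                    replace = TRUE), collapse = ""))
        probe <- target_from_sequence(cand, genome_id = genome_ids[1])
        hits <- brute_force_offtargets(probe, relative, max_mm = max_mm,
                                       require_pam = TRUE,
                                       cap = relative$total_length)
        if (nrow(hits) == 0L) break
      }
      cand
    })
    substr(focal_seq, island_pos + 1L, island_pos + k) <- island
    truth <- list(island = island, island_pos = as.integer(island_pos),
                  island_contig = "c1")
  }
  focal <- ps_genome(stats::setNames(focal_seq, "c1"),
                     genome_id = genome_ids[1])
  list(focal = focal, relative = relative, truth = truth)
}

#' Named fixture presets
#'
#' Bundled generator scenarios used by the command line and the test suite:
#' \describe{
#'   \item{basic}{one 20-kb genome, GC 0.5.}
#'   \item{decoys}{a 50-kb comparator carrying one planted copy of a target
#'     and decoys at distances 1..5 (PAM intact) plus one PAM-broken decoy;
#'     the truth table lists every plant with its distance.}
#'   \item{related_pair}{a 100-kb pair at identity 0.9 with one planted
#'     unique island in the focal genome.}
#'   \item{repeats}{a 20-kb genome in which a 2-kb block is tandem-duplicated
#'     three times (near-identical copies at identity 0.98).}
#' }
#'
#' @param preset one of `"basic"`, `"decoys"`, `"related_pair"`, `"repeats"`.
#' @param seed integer seed.
#' @return list with `genomes` (named list of [ps_genome]) and `truth`
#'   (data.frame or list; NULL for presets without planted truth).
#' @export
synth_preset <- function(preset = c("basic", "decoys", "related_pair",
                                    "repeats"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    basic = list(genomes = list(basic = make_genome(20000L, seed = seed,
                                                    genome_id = "basic")),
                 truth = NULL),
    decoys = {
      target_seq <- paste0("TTTG", with_seed(seed, paste(
        sample(c("A", "C", "G", "T"), 21L, replace = TRUE), collapse = "")))
      tgt <- target_from_sequence(target_seq, genome_id = "focal",
                                  target_id = "planted")
      dist <- 1:5
      decs <- vapply(dist, function(d)
        make_decoy(tgt, d, preserve_pam = TRUE, seed = seed + d), character(1))
      broken <- make_decoy(tgt, 2L, preserve_pam = FALSE, seed = seed + 99L)
      pos <- seq(1000L, by = 2000L, length.out = 7L)
      plants <- data.frame(
        sequence = c(target_seq, decs, broken), contig = "c1", start = pos,
        strand = rep(c("+", "-"), length.out = 7L), stringsAsFactors = FALSE)
      g <- make_genome(50000L, seed = seed + 1L, plants = plants,
                       genome_id = "decoys")
      list(genomes = list(decoys = g),
           truth = data.frame(plants,
                              distance = c(0L, dist, 2L),
                              pam_intact = c(rep(TRUE, 6L), FALSE),
                              target = target_seq, stringsAsFactors = FALSE))
    },
    related_pair = {
      pair <- make_related_pair(1e5, identity = 0.9, seed = seed,
                                plant_island = TRUE)
      list(genomes = list(focal = pair$focal, relative = pair$relative),
           truth = pair$truth)
    },
    repeats = {
      core <- make_genome(c(c1 = 20000L), seed = seed, genome_id = "repeats")
      block <- substr(as.character(core$contigs[[1]]), 5001L, 7000L)
      copies <- with_seed(seed + 1L, vapply(1:3, function(i) {
        ch <- strsplit(block, "", fixed = TRUE)[[1]]
        hit <- which(stats::runif(2000L) < 0.02)
        others <- matrix(c("C", "G", "T",  "A", "G", "T",
                           "A", "C", "T",  "A", "C", "G"),
                         nrow = 4L, byrow = TRUE,
                         dimnames = list(c("A", "C", "G", "T"), NULL))
        if (length(hit))
          ch[hit] <- others[cbind(match(ch[hit], rownames(others)),
                                  sample.int(3L, length(hit), replace = TRUE))]
        paste(ch, collapse = "")
      }, character(1)))
      seqs <- c(c1 = paste0(as.character(core$contigs[[1]]),
                            paste(copies, collapse = "")))
      list(genomes = list(repeats = ps_genome(seqs, genome_id = "repeats")),
           truth = NULL)
    })
}
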