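# Shared fixtures and independent oracles for the test suite.

bases <- c("A", "C", "G", "T")

# a random PAM-anchored target record (TTTV + random protospacer)
random_target <- function(seed, S = 21L, genome_id = "query") {
  seq <- withr::with_seed(seed, paste0(
    "TTT", sample(c("A", "C", "G"), 1L),
    paste(sample(bases, S, replace = TRUE), collapse = "")))
  target_from_sequence(seq, genome_id = genome_id,
                       target_id = paste0("rt", seed))
}

# reverse complement, independent of the package's helper
rc_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Independent window-scan oracle for PAM-site enumeration: counts (and
# locates) k-mers starting with TTT[ACG] and free of N on both strands,
# via plain substring extraction.
oracle_enumerate <- function(genome, k = 25L) {
  out <- list()
  for (ci in seq_along(genome$contigs)) {
    sq <- as.character(genome$contigs[[ci]])
    L <- nchar(sq)
    if (L < k) next
    for (st in c("+", "-")) {
      s <- if (st == "+") sq else rc_chr(sq)
      wins <- substring(s, 1:(L - k + 1L), k:L)
      hit <- grepl("^TTT[ACG]", wins) & !grepl("N", wins, fixed = TRUE)
      idx <- which(hit)
      if (length(idx))
        out[[length(out) + 1L]] <- data.frame(
          contig = names(genome$contigs)[ci],
          start = if (st == "+") idx - 1L else L - (idx - 1L) - k,
          strand = st, sequence = wins[idx], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), start = integer(),
                      strand = character(), sequence = character()))
  do.call(rbind, out)
}

# Batched pure-R oracle: for each spacer, the minimum protospacer Hamming
# distance over all TTTV-PAM, N-free windows of a single-contig genome
# (both strands); Inf when no PAM window exists. Independent of the seeded
# search and of brute_force_offtargets.
oracle_min_pam_distance <- function(spacers, genome) {
  stopifnot(length(genome$contigs) == 1L)
  S <- nchar(spacers[1])
  ch <- strsplit(as.character(genome$contigs[[1]]), "", fixed = TRUE)[[1]]
  L <- length(ch)
  k <- S + 4L
  np <- L - k + 1L
  p <- 0:(np - 1L)
  cs <- c(0L, cumsum(ch == "N"))
  okN <- (cs[p + k + 1L] - cs[p + 1L]) == 0L
  pam_p <- ch[p + 1L] == "T" & ch[p + 2L] == "T" & ch[p + 3L] == "T" &
    ch[p + 4L] %in% c("A", "C", "G")
  b <- ch[p + k - 3L]
  pam_m <- ch[p + k] == "A" & ch[p + k - 1L] == "A" &
    ch[p + k - 2L] == "A" & b %in% c("C", "G", "T")
  wp <- p[okN & pam_p]
  wm <- p[okN & pam_m]
  TMp <- if (length(wp)) t(matrix(ch[outer(wp, 4L + seq_len(S), "+")],
                                  nrow = length(wp))) else NULL
  TMm <- if (length(wm)) t(matrix(ch[outer(wm, seq_len(S), "+")],
                                  nrow = length(wm))) else NULL
  vapply(spacers, function(sp) {
    s <- strsplit(sp, "", fixed = TRUE)[[1]]
    rcs <- strsplit(rc_chr(sp), "", fixed = TRUE)[[1]]
    dp <- if (is.null(TMp)) Inf else min(colSums(TMp != s))
    dm <- if (is.null(TMm)) Inf else min(colSums(TMm != rcs))
    min(dp, dm)
  }, numeric(1), USE.NAMES = FALSE)
}

expect_same_hits <- function(fast, brute) {
  expect_identical(fast[, c("contig", "start", "strand", "mismatches")],
                   brute[, c("contig", "start", "strand", "mismatches")])
}
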