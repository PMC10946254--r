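test_that("enumeration is forced by the PAM pattern on tiny genomes", {
  g <- ps_genome(c(c1 = paste0("TTTG", strrep("A", 21))), "t")
  t <- enumerate_targets(g)
  expect_equal(nrow(t), 1L)
  expect_equal(t$strand, "+")
  expect_equal(t$start, 0L)
  expect_equal(t$sequence, paste0("TTTG", strrep("A", 21)))
  expect_equal(t$pam, "TTTG")
  expect_equal(t$protospacer, strrep("A", 21))
  expect_equal(t$copy_number, 1L)

  # all-T contig: forward windows start TTTT (V fails), reverse strand is
  # all A -> no targets at all
  g2 <- ps_genome(c(c1 = strrep("T", 30)), "t")
  expect_equal(nrow(enumerate_targets(g2)), 0L)

  # contig shorter than k contributes nothing, k < 5 errors
  g3 <- ps_genome(c(c1 = "TTTGAAAA"), "t")
  expect_equal(nrow(enumerate_targets(g3)), 0L)
  expect_error(enumerate_targets(g, k = 4), "k must be")
})

test_that("windows containing N are never enumerated", {
  g <- ps_genome(c(c1 = paste0("TTTG", strrep("A", 10), "N",
                               strrep("A", 10), "CCCC")), "t")
  t <- enumerate_targets(g)
  expect_false(any(grepl("N", t$sequence)))
  expect_false(any(t$start <= 4L))  # every window over the N is excluded
})

test_that("every published diagnostic target passes the PAM filter and is
           recovered verbatim from a PAM-free background", {
  tab <- published_targets()
  expect_equal(nrow(tab), 13L)
  expect_true(all(grepl("^TTT[ACG]", tab$sequence)))
  expect_equal(sum(tab$irregular_length), 1L)  # one 26-nt row as printed
  bg_left <- strrep("AC", 60)
  bg_right <- strrep("CA", 60)
  for (i in seq_len(nrow(tab))) {
    sq <- tab$sequence[i]
    g <- ps_genome(c(c1 = paste0(bg_left, sq, bg_right)), tab$abbrev[i])
    t <- enumerate_targets(g, k = nchar(sq))
    hit <- t[t$strand == "+" & t$start == 120L, ]
    expect_equal(hit$sequence, sq)
    expect_equal(hit$copy_number, 1L)
  }
})

test_that("enumeration agrees with a window-scan oracle on random genomes", {
  g <- make_genome(10000, gc = 0.5, seed = 42)
  t <- enumerate_targets(g)
  o <- oracle_enumerate(g)
  expect_equal(nrow(t), nrow(o))
  key <- function(d) sort(paste(d$contig, d$start, d$strand, d$sequence))
  expect_equal(key(t), key(o))

  # multi-contig, shifted GC
  g2 <- make_genome(c(a = 4000L, b = 2500L), gc = 0.35, seed = 9)
  expect_equal(nrow(enumerate_targets(g2)), nrow(oracle_enumerate(g2)))
})

test_that("enumeration is strand-symmetric", {
  for (seed in c(3, 14)) {
    g <- make_genome(5000, seed = seed)
    grc <- ps_genome(
      stats::setNames(as.character(
        Biostrings::reverseComplement(g$contigs)), names(g$contigs)),
      genome_id = g$genome_id)
    t1 <- enumerate_targets(g)
    t2 <- enumerate_targets(grc)
    L <- g$total_length
    key1 <- sort(paste(t1$sequence, t1$strand, t1$start))
    key2 <- sort(paste(t2$sequence, ifelse(t2$strand == "+", "-", "+"),
                       L - t2$start - 25L))
    expect_equal(key1, key2)
  }
})

test_that("copy_number counts planted copies across both strands", {
  tgt <- random_target(5)
  plants <- data.frame(sequence = tgt$sequence, contig = "c1",
                       start = c(100L, 900L, 2000L),
                       strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  # PAM-free alternating background so only the plants carry the sequence
  bg <- ps_genome(c(c1 = strrep("AC", 1500)), "bg")
  seqchr <- as.character(bg$contigs[[1]])
  for (i in seq_len(nrow(plants))) {
    ins <- if (plants$strand[i] == "-") rc_chr(plants$sequence[i]) else plants$sequence[i]
    substr(seqchr, plants$start[i] + 1L, plants$start[i] + 25L) <- ins
  }
  g <- ps_genome(c(c1 = seqchr), "planted")
  t <- enumerate_targets(g)
  planted <- t[t$start %in% plants$start & t$sequence == tgt$sequence, ]
  expect_equal(nrow(planted), 3L)
  expect_equal(planted$copy_number, rep(3L, 3L))
})

test_that("library statistics follow the site-count definition", {
  g <- make_genome(1000, seed = 2)
  t <- enumerate_targets(g)
  fake <- t[rep(1L, 10L), ]
  st <- library_stats(g, fake)
  expect_equal(st$n_target_sites, 10L)
  expect_equal(st$mean_spacing_bp, 100)
  st0 <- library_stats(g, t[integer(0), ])
  expect_true(is.na(st0$mean_spacing_bp))
  expect_equal(st0$n_target_sites, 0L)
})

test_that("region filtering requires full window containment", {
  g <- make_genome(3000, seed = 21)
  tgt <- random_target(6)
  plants <- data.frame(sequence = c(tgt$sequence, random_target(7)$sequence,
                                    random_target(8)$sequence),
                       contig = "c1", start = c(100L, 1000L, 2000L),
                       strand = "+", stringsAsFactors = FALSE)
  g <- make_genome(3000, seed = 21, plants = plants)
  t <- enumerate_targets(g)

  reg_exact <- data.frame(contig = "c1", start = 100L, end = 125L,
                          label = "ITS", stringsAsFactors = FALSE)
  kept <- filter_by_region(t, reg_exact)
  expect_true(any(kept$start == 100L & kept$strand == "+"))
  expect_true(all(kept$start >= 100L & kept$start + 25L <= 125L))

  reg_partial <- data.frame(contig = "c1", start = 101L, end = 300L,
                            label = "x", stringsAsFactors = FALSE)
  expect_false(any(filter_by_region(t, reg_partial)$start == 100L))

  # only the target inside the synthetic "ITS" region survives
  its <- data.frame(contig = "c1", start = 990L, end = 1040L, label = "ITS",
                    stringsAsFactors = FALSE)
  inside <- filter_by_region(t, its)
  expect_true(all(inside$start >= 990L & inside$start + 25L <= 1040L))
  expect_true(any(inside$start == 1000L))

  expect_warning(
    filter_by_region(t, data.frame(contig = "nope", start = 0L, end = 100L,
                                   label = "", stringsAsFactors = FALSE),
                     genome = g),
    "unknown contig")
})

test_that("flank extraction clips at contig ends and flags it", {
  g <- make_genome(2000, seed = 30,
                   plants = data.frame(sequence = random_target(31)$sequence,
                                       contig = "c1", start = 600L,
                                       strand = "+"))
  t <- enumerate_targets(g)
  tg <- t[t$start == 600L & t$strand == "+", ]
  fl <- extract_flanks(g, tg, flank = 500L)
  expect_equal(c(fl$start, fl$end), c(100L, 1125L))
  expect_equal(nchar(fl$sequence), 1025L)
  expect_false(fl$clipped)

  g2 <- make_genome(2000, seed = 30,
                    plants = data.frame(sequence = random_target(31)$sequence,
                                        contig = "c1", start = 10L,
                                        strand = "+"))
  t2 <- enumerate_targets(g2)
  tg2 <- t2[t2$start == 10L & t2$strand == "+", ]
  fl2 <- extract_flanks(g2, tg2, flank = 500L)
  expect_equal(c(fl2$start, fl2$end), c(0L, 535L))
  expect_true(fl2$clipped)

  fl0 <- extract_flanks(g, tg, flank = 0L)
  expect_equal(fl0$sequence, tg$sequence)
})

test_that("k is configurable over 23-27 with invariants re-derived", {
  g <- make_genome(5000, seed = 12)
  for (k in c(23L, 25L, 27L)) {
    t <- enumerate_targets(g, k = k)
    expect_true(all(nchar(t$sequence) == k))
    expect_true(all(nchar(t$protospacer) == k - 4L))
    expect_true(all(grepl("^TTT[ACG]", t$sequence)))
    expect_true(all(substr(t$sequence, 5L, k) == t$protospacer))
  }
})
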