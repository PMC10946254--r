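test_that("a target planted verbatim is found at distance zero at its locus", {
  tgt <- random_target(101)
  cmp <- make_genome(20000, seed = 55, genome_id = "cmp",
                     plants = data.frame(sequence = tgt$sequence,
                                         contig = "c1", start = 7000L,
                                         strand = "+"))
  hits <- find_offtargets(tgt, cmp, max_mm = 5)
  self <- hits[hits$start == 7000L & hits$strand == "+", ]
  expect_equal(nrow(self), 1L)
  expect_equal(self$mismatches, 0L)
  expect_equal(self$site_sequence, tgt$sequence)
})

test_that("decoys report their construction distance; a broken PAM hides them", {
  tgt <- random_target(102)
  dec2 <- make_decoy(tgt, 2L, preserve_pam = TRUE, seed = 9)
  dec2_nopam <- make_decoy(tgt, 2L, preserve_pam = FALSE, seed = 9)
  cmp <- make_genome(10000, seed = 56, genome_id = "cmp",
                     plants = data.frame(sequence = c(dec2, dec2_nopam),
                                         contig = "c1",
                                         start = c(2000L, 5000L),
                                         strand = c("+", "-")))
  hits <- find_offtargets(tgt, cmp, max_mm = 5)
  at2000 <- hits[hits$start == 2000L, ]
  expect_equal(at2000$mismatches, 2L)
  expect_false(any(hits$start == 5000L))  # PAM TTTT fails TTTV
  # without the PAM requirement the broken-PAM decoy reappears
  hits_nopam <- find_offtargets(tgt, cmp, max_mm = 5, require_pam = FALSE)
  expect_true(any(hits_nopam$start == 5000L & hits_nopam$strand == "-" &
                    hits_nopam$mismatches == 2L))
})

test_that("the decoys preset exercises every mismatch class and matches truth", {
  px <- synth_preset("decoys", seed = 4)
  tr <- px$truth
  tgt <- target_from_sequence(tr$target[1], target_id = "planted")
  hits <- find_offtargets(tgt, px$genomes$decoys, max_mm = 5)
  found <- merge(tr[tr$pam_intact, c("start", "distance")],
                 hits[, c("start", "mismatches")], by = "start")
  expect_equal(nrow(found), sum(tr$pam_intact))
  expect_equal(found$mismatches, found$distance)
  expect_setequal(found$distance, 0:5)
  expect_false(any(hits$start %in% tr$start[!tr$pam_intact]))
})

test_that("seeded search equals the brute-force oracle on randomized instances", {
  set.seed(20)
  for (i in 1:20) {
    L <- sample(1000:10000, 1)
    g <- make_genome(L, gc = runif(1, 0.3, 0.7), seed = 3000 + i,
                     genome_id = "cmp")
    tgt <- random_target(4000 + i)
    mm <- sample(0:5, 1)
    rp <- sample(c(TRUE, FALSE), 1)
    fast <- find_offtargets(tgt, g, max_mm = mm, require_pam = rp)
    brute <- brute_force_offtargets(tgt, g, max_mm = mm, require_pam = rp)
    expect_identical(fast, brute)
  }
})

test_that("hit sets are monotone in max_mm and shrink under the PAM filter", {
  g <- make_genome(30000, seed = 77, genome_id = "cmp")
  tgt <- random_target(103)
  key <- function(h) paste(h$contig, h$start, h$strand)
  prev <- character(0)
  for (mm in 0:5) {
    h <- find_offtargets(tgt, g, max_mm = mm, require_pam = FALSE)
    expect_true(all(prev %in% key(h)))
    prev <- key(h)
  }
  withpam <- find_offtargets(tgt, g, max_mm = 5, require_pam = TRUE)
  nopam <- find_offtargets(tgt, g, max_mm = 5, require_pam = FALSE)
  expect_true(all(key(withpam) %in% key(nopam)))
})

test_that("reverse-complementing the comparator mirrors hits exactly", {
  tgt <- random_target(104)
  g <- make_genome(20000, seed = 78, genome_id = "cmp",
                   plants = data.frame(sequence = c(tgt$sequence,
                                                    make_decoy(tgt, 3L, seed = 2)),
                                       contig = "c1",
                                       start = c(4000L, 9000L),
                                       strand = c("+", "-")))
  grc <- ps_genome(stats::setNames(as.character(
    Biostrings::reverseComplement(g$contigs)), names(g$contigs)), "cmp")
  h1 <- find_offtargets(tgt, g, max_mm = 5)
  h2 <- find_offtargets(tgt, grc, max_mm = 5)
  L <- g$total_length
  k1 <- sort(paste(h1$start, h1$strand, h1$mismatches))
  k2 <- sort(paste(L - h2$start - 25L, ifelse(h2$strand == "+", "-", "+"),
                   h2$mismatches))
  expect_equal(k1, k2)
})

test_that("mismatch histograms count constructed sites and conserve totals", {
  tgt <- random_target(105)
  dec3 <- make_decoy(tgt, 3L, seed = 3)
  # PAM-free alternating background: the two plants are the only sites
  bg <- strrep("AC", 5000)
  substr(bg, 3001L, 3025L) <- tgt$sequence
  substr(bg, 8001L, 8025L) <- dec3
  cmp <- ps_genome(c(c1 = bg), "cmp")
  h <- mismatch_histogram(tgt, cmp, max_mm = 5)
  expect_equal(unname(h), c(1L, 0L, 0L, 1L, 0L, 0L))
  expect_equal(sum(h), nrow(find_offtargets(tgt, cmp, max_mm = 5)))

  # own-genome histogram of a unique planted target with self-exclusion
  own <- make_genome(20000, seed = 61, genome_id = "own",
                     plants = data.frame(sequence = tgt$sequence,
                                         contig = "c1", start = 5000L,
                                         strand = "+"))
  t_own <- enumerate_targets(own)
  row <- t_own[t_own$start == 5000L & t_own$strand == "+", ]
  h_own <- mismatch_histogram(row, own, max_mm = 5, exclude_self_site = TRUE)
  h_all <- mismatch_histogram(row, own, max_mm = 5, exclude_self_site = FALSE)
  expect_equal(unname(h_all["0"] - h_own["0"]), 1L)
  expect_equal(sum(h_all) - sum(h_own), 1L)
})

test_that("specificity classes follow the distance thresholds", {
  pair <- make_related_pair(30000, identity = 0.9, seed = 8,
                            plant_island = TRUE)
  targets <- enumerate_targets(pair$focal)
  expect_error(screen_specific(targets, list()), "no comparators")

  # identical comparator: every target non_specific via its own exact copy
  self_cmp <- ps_genome(stats::setNames(as.character(pair$focal$contigs),
                                        names(pair$focal$contigs)), "twin")
  sc_self <- screen_specific(targets[1:50, ], self_cmp)
  expect_true(all(sc_self$classification$specificity_class == "non_specific"))
  expect_true(all(sc_self$classification$min_cross_distance == 0L))

  sc <- screen_specific(targets, pair$relative)
  cls <- sc$classification
  island <- cls$target_id[targets$start == pair$truth$island_pos &
                            targets$strand == "+"]
  expect_equal(cls$specificity_class[cls$target_id == island],
               "ultra_specific")

  # histogram-derived min distances are consistent with the classes
  md <- sc$profiles$min_distance
  expect_true(all(is.na(md[cls$specificity_class == "ultra_specific"])))
  expect_true(all(md[cls$specificity_class == "non_specific"] < 3L,
                  na.rm = TRUE))

  # a target whose only comparator hit is at distance 3 is specific but
  # not ultra_specific
  tgt <- random_target(106)
  cmp3 <- make_genome(20000, seed = 62, genome_id = "cmp3",
                      plants = data.frame(
                        sequence = make_decoy(tgt, 3L, seed = 7),
                        contig = "c1", start = 6000L, strand = "+"))
  sc3 <- screen_specific(tgt, cmp3)
  expect_equal(sc3$classification$specificity_class, "specific")
  expect_equal(sc3$classification$min_cross_distance, 3L)
})

test_that("no off-target within the window yields an empty hit list", {
  # the selection condition used for adulterant discrimination: a target
  # with no comparator site within five mismatches
  pair <- make_related_pair(30000, identity = 0.9, seed = 15,
                            plant_island = TRUE)
  row <- target_from_sequence(pair$truth$island, genome_id = "focal")
  expect_equal(nrow(find_offtargets(row, pair$relative, max_mm = 5)), 0L)
})

test_that("brute force degenerate parameterizations behave as specified", {
  tgt <- random_target(107)
  tiny <- ps_genome(c(c1 = "ACGT"), "tiny")
  expect_equal(nrow(brute_force_offtargets(tgt, tiny)), 0L)

  # max_mm = 0, require_pam = FALSE: exact protospacer match preceded by
  # any four bases
  cmp <- make_genome(5000, seed = 63, genome_id = "cmp",
                     plants = data.frame(
                       sequence = paste0("GGGG", tgt$protospacer),
                       contig = "c1", start = 1000L, strand = "+"))
  h <- brute_force_offtargets(tgt, cmp, max_mm = 0, require_pam = FALSE)
  expect_true(any(h$start == 1000L & h$mismatches == 0L))

  big <- make_genome(2000, seed = 1)
  expect_error(brute_force_offtargets(tgt, big, cap = 1000), "cap")
})
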