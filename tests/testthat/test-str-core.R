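test_that("exact occurrence search finds every motif at every offset", {
  s <- parse_structure("[AATG]n")
  occ <- find_exact_occurrences("AATGAATG", s)
  expect_equal(occ$offset, c(0L, 4L))

  s2 <- parse_structure("[TCTA]n [TCTG]n")
  occ2 <- find_exact_occurrences("TCTATCTG", s2)
  expect_equal(occ2$offset, c(0L, 4L))
  expect_equal(occ2$element_index, c(1L, 2L))

  expect_equal(nrow(find_exact_occurrences("CCCCCCCC", s)), 0L)

  # overlapping occurrences are all reported
  s3 <- parse_structure("[ATA]n")
  occ3 <- find_exact_occurrences("ATATA", s3)
  expect_equal(occ3$offset, c(0L, 2L))
})

test_that("the longest tiled interval is the longest contiguous chain, leftmost on ties", {
  s <- parse_structure("[AATG]n")
  read <- "AATGAATGCCAATG"
  iv <- longest_tiled_interval(find_exact_occurrences(read, s), read)
  expect_equal(c(iv$start, iv$end), c(0L, 8L))
  expect_equal(nrow(iv$tiles), 2L)

  # equal-length chains -> leftmost wins
  read2 <- "AATGCCCCAATG"
  iv2 <- longest_tiled_interval(find_exact_occurrences(read2, s), read2)
  expect_equal(c(iv2$start, iv2$end), c(0L, 4L))

  expect_null(longest_tiled_interval(find_exact_occurrences("CCCC", s), "CCCC"))
})

test_that("tiled-interval search equals exhaustive chain enumeration on random reads", {
  set.seed(101)
  for (i in 1:300) {
    s <- random_motif_structure()
    read <- random_dna(sample(10:60, 1))
    occ <- find_exact_occurrences(read, s)
    iv <- longest_tiled_interval(occ, read)
    oracle <- brute_longest_chain(occ, read)
    if (is.null(oracle)) {
      expect_null(iv)
    } else {
      expect_equal(iv$end - iv$start, oracle$len, label = read)
      expect_equal(iv$start, oracle$start, label = read)
    }
  }
})

test_that("flanks anchor at the minimal-mismatch offsets around the interval", {
  locus <- test_locus()
  region <- paste0(strrep("AATG", 6), "ATG", strrep("AATG", 3))
  read <- spanning_read(locus, region, pad5 = "GGC", pad3 = "TCG")
  occ <- find_exact_occurrences(read$sequence, locus$structure)
  iv <- longest_tiled_interval(occ, read$sequence)
  fl <- match_flanks(read$sequence, iv, locus)
  expect_equal(fl$flank5$mismatches, 0L)
  expect_equal(fl$flank3$mismatches, 0L)
  expect_equal(fl$flank5$offset, 3L)
  expect_equal(fl$flank3$offset, 3L + nchar(locus$flank5) + nchar(region))

  # single substitution inside the 20 bp flank (fraction 0.05) is accepted
  seq2 <- read$sequence
  substr(seq2, 5L, 5L) <- setdiff(c("A", "C", "G", "T"),
                                  substr(seq2, 5L, 5L))[1]
  fl2 <- match_flanks(seq2, iv, locus)
  expect_equal(fl2$flank5$mismatches, 1L)
  oracle <- brute_flank_scan(seq2, locus$flank5, 0, iv$start - nchar(locus$flank5))
  expect_equal(fl2$flank5$mismatches, oracle$min)
  expect_true(fl2$flank5$offset %in% oracle$offsets)

  # truncated read: 3' flank missing entirely
  trunc <- substr(read$sequence, 1, 3 + nchar(locus$flank5) + nchar(region) + 4)
  occ3 <- find_exact_occurrences(trunc, locus$structure)
  iv3 <- longest_tiled_interval(occ3, trunc)
  fl3 <- match_flanks(trunc, iv3, locus)
  expect_s3_class(fl3, "flank_failure")
  expect_equal(fl3$side, "3prime")
})

test_that("call_read composes the three steps and counts in-region INDELs", {
  # the canonical worked example: [TTCC]15 TT between flanks -> 15.2
  locus <- locus_config("D1S1677like", "chrSim", 1000, 1061, "[TTCC]n",
                        flank5 = "GATCGGAAGTCAGGCAAGAG",
                        flank3 = "ATGAAGACAGGAGTTGGCAT")
  region <- paste0(strrep("TTCC", 15), "TT")
  read <- spanning_read(locus, region)
  call <- call_read(read, locus)
  expect_s3_class(call, "read_allele_call")
  expect_identical(format(call$designation), "15.2")
  expect_identical(call$region_sequence, region)
  expect_equal(call$dist_5p, nchar(locus$flank5))
  expect_equal(call$dist_3p, nchar(locus$flank3))
  expect_equal(call$mean_region_quality, 35)

  # no motif anywhere -> the read is discarded
  junk <- list(read_id = "j", sequence = strrep("GA", 40),
               qualities = rep(30L, 80))
  rej <- call_read(junk, locus)
  expect_s3_class(rej, "read_rejection")
  expect_equal(rej$reason, "no_motif")

  # 3'-truncated read must not yield a (mis-designated, shorter) call
  read3 <- list(read_id = "t", sequence = paste0(locus$flank5, region),
                qualities = rep(30L, nchar(locus$flank5) + nchar(region)))
  rej3 <- call_read(read3, locus)
  expect_equal(rej3$reason, "no_flank3")
})

test_that("every read yields exactly one outcome: a call or a single rejection reason", {
  set.seed(77)
  locus <- test_locus()
  outcomes <- character(0)
  for (i in 1:60) {
    kind <- sample(c("spanning", "trunc3", "trunc5", "junk"), 1)
    seq <- switch(kind,
      spanning = spanning_read(locus, expand_designation(
        new_designation(sample(3:10, 1)), locus$structure))$sequence,
      trunc3 = paste0(locus$flank5, strrep("AATG", 6)),
      trunc5 = paste0(strrep("AATG", 6), locus$flank3),
      junk = random_dna(60)
    )
    res <- call_read(list(read_id = "r", sequence = seq,
                          qualities = rep(30L, nchar(seq))), locus)
    is_call <- inherits(res, "read_allele_call")
    is_rej <- inherits(res, "read_rejection")
    expect_true(xor(is_call, is_rej))
    if (is_rej) expect_true(res$reason %in%
      c("no_motif", "no_flank5", "no_flank3", "empty_region"))
    outcomes <- c(outcomes, if (is_call) "call" else res$reason)
  }
  expect_true(all(c("call", "no_flank3", "no_flank5", "no_motif") %in% outcomes))
})

test_that("noise-free simulated spanning reads reproduce the simulated truth", {
  set.seed(13)
  for (i in 1:5) {
    locus <- sim_locus(sprintf("L%d", i))
    truth <- new_designation(sample(5:14, 1), sample(0:(locus$structure$period - 1), 1))
    sim <- simulate_reads(sim_spec(locus, list(truth), depth = 20,
                                   stutter_rate = 0, error_rate = 0,
                                   read_length = 140, seed = i))
    cr <- call_reads(sim$reads, locus)
    expect_equal(length(cr$calls), nrow(sim$reads))
    for (cl in cr$calls) expect_true(cl$designation == truth)
  }
})

test_that("inserting k extra bases into the region shifts the designation by k mod period", {
  locus <- test_locus()     # period 4
  base_region <- expand_designation(new_designation(8), locus$structure)
  for (k in 1:3) {
    ins <- substr("AAT", 1, k)  # prefix of the reference motif
    region <- paste0(base_region, ins)
    call <- call_read(spanning_read(locus, region), locus)
    expect_equal(call$designation$full, 8L)
    expect_equal(call$designation$partial, k)
  }
  # a full extra motif carries into the repeat count
  region4 <- paste0(base_region, "AATG")
  call4 <- call_read(spanning_read(locus, region4), locus)
  expect_true(call4$designation == new_designation(9))
})
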