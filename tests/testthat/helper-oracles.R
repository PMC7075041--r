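# Independent oracle for the longest motif-tiled interval: top-down
# memoised recursion over read positions, enumerating every chain of
# occurrences (a chain continues with any occurrence starting exactly
# where the previous tile ends). Returns list(start, len) of the longest
# chain, leftmost on ties, or NULL when there are no occurrences.
brute_longest_chain <- function(occurrences, read_seq) {
  if (!nrow(occurrences)) return(NULL)
  n <- nchar(read_seq)
  starts_at <- vector("list", n + 1L)  # occurrence lengths starting at pos (0-based)
  for (i in seq_len(nrow(occurrences))) {
    o <- occurrences$offset[i]
    starts_at[[o + 1L]] <- c(starts_at[[o + 1L]], occurrences$length[i])
  }
  memo <- rep(NA_integer_, n + 2L)
  longest_from <- function(pos) {  # pos 0-based
    if (!is.na(memo[pos + 1L])) return(memo[pos + 1L])
    best <- 0L
    for (k in unique(starts_at[[pos + 1L]])) {
      cand <- k + longest_from(pos + k)
      if (cand > best) best <- cand
    }
    memo[pos + 1L] <<- best
    best
  }
  best_len <- -1L
  best_start <- NA_integer_
  for (pos in sort(unique(occurrences$offset))) {
    L <- longest_from(pos)
    if (L > best_len) {
      best_len <- L
      best_start <- pos
    }
  }
  list(start = best_start, len = best_len)
}

# Brute-force best flank placement: scan every in-bounds offset in
# [lo, hi], return minimal Hamming mismatches and all argmin offsets.
brute_flank_scan <- function(read_seq, flank, lo, hi) {
  m <- nchar(flank)
  offs <- seq.int(lo, hi)
  offs <- offs[offs >= 0 & offs + m <= nchar(read_seq)]
  if (!length(offs)) return(NULL)
  mm <- vapply(offs, function(o) {
    sum(strsplit(substr(read_seq, o + 1, o + m), "")[[1]] !=
          strsplit(flank, "")[[1]])
  }, 0L)
  list(min = min(mm), offsets = offs[mm == min(mm)])
}

# Random structure over 1-3 motifs of length 2-4 (all bracketed), for
# property tests of the tiling search.
random_motif_structure <- function(n_motifs = sample(1:3, 1)) {
  motifs <- character(0)
  while (length(motifs) < n_motifs) {
    k <- sample(2:4, 1)
    m <- random_dna(k)
    if (length(unique(strsplit(m, "")[[1]])) >= 2 && !m %in% motifs) {
      motifs <- c(motifs, m)
    }
  }
  parse_structure(paste(sprintf("[%s]n", motifs), collapse = " "))
}

# Build a small coordinate-sorted, indexed BAM from alignment tuples.
# Alignments use simple full-match CIGARs; seq/qual are stored in
# reference orientation as in a real BAM.
make_test_bam <- function(alignments, chrom = "chrSim", chrom_len = 100000L,
                          dir = withr::local_tempdir(.local_envir = parent.frame())) {
  alignments <- alignments[order(vapply(alignments, `[[`, 0L, "pos"))]
  sam <- file.path(dir, "fixture.sam")
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len),
    vapply(alignments, function(a) {
      seq <- a$seq
      qual <- a$qual %||% strrep("I", nchar(seq))
      paste(a$qname, a$flag %||% 0L, chrom, a$pos, 60,
            paste0(nchar(seq), "M"), "*", 0, 0, seq, qual,
            sep = "\t")
    }, "")
  )
  writeLines(lines, sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "fixture"), overwrite = TRUE)
  bam
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A fixed, deterministic locus for unit tests: TH01-style compound
# structure with hand-written flanks that cannot extend the repeat.
test_locus <- function(marker = "TH01like", orientation = "forward",
                       chrom_class = "autosomal") {
  locus_config(
    marker = marker, chrom = "chrSim",
    repeat_start = 5001, repeat_end = 5039,
    structure = "[AATG]n ATG [AATG]n",
    orientation = orientation,
    flank5 = "GTCCTTGTCAGCGTTTATTT",
    flank3 = "CCTTCCTTCCTTTCCTTCCT",
    chrom_class = chrom_class
  )
}

# Build a spanning read for a locus from a region sequence.
spanning_read <- function(locus, region, pad5 = "", pad3 = "", id = "r1",
                          base_q = 35L) {
  seq <- paste0(pad5, locus$flank5, region, locus$flank3, pad3)
  list(read_id = id, sequence = seq, qualities = rep(base_q, nchar(seq)))
}
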