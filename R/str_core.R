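#' Find all exact motif occurrences in a read
#'
#' Every bracketed or counted motif of the structure is matched against
#' the read with no mismatch permitted; all occurrences at all offsets
#' (overlaps allowed) are returned. Reads with no occurrence of any motif
#' are discarded upstream.
#'
#' @param read_seq Upper-case read sequence.
#' @param structure An `str_structure`.
#' @return Data frame with columns `element_index`, `offset` (0-based)
#'   and `length`, sorted by offset then element index.
#' @export
find_exact_occurrences <- function(read_seq, structure) {
  if (!inherits(structure, "str_structure")) stop("structure must be an str_structure")
  el <- structure$elements
  idx <- which(el$kind != "uncounted")
  n <- nchar(read_seq)
  eidx <- integer(0)
  offs <- integer(0)
  lens <- integer(0)
  for (j in idx) {
    m <- el$motif[j]
    k <- nchar(m)
    if (k > n) next
    starts <- which(substring(read_seq, 1:(n - k + 1L), k:n) == m)
    if (length(starts)) {
      eidx <- c(eidx, rep.int(j, length(starts)))
      offs <- c(offs, starts - 1L)
      lens <- c(lens, rep.int(k, length(starts)))
    }
  }
  o <- order(offs, eidx)
  fast_df(element_index = eidx[o], offset = offs[o], length = lens[o])
}

#' Longest contiguous motif-tiled interval of a read
#'
#' Among all intervals expressible as a contiguous chain of exact motif
#' occurrences (each tile beginning exactly where the previous one ends),
#' returns the longest in bases. Ties are broken towards the leftmost
#' start, then towards fewer tiles, so output is deterministic across
#' platforms.
#'
#' @param occurrences Output of [find_exact_occurrences()].
#' @param read_seq The read sequence the occurrences refer to.
#' @return `NULL` when there are no occurrences; otherwise a
#'   `tiled_interval`: list with `start`, `end` (0-based half-open read
#'   coordinates) and `tiles` (the chained occurrence rows in order).
#' @export
longest_tiled_interval <- function(occurrences, read_seq) {
  no <- nrow(occurrences)
  if (!no) return(NULL)
  n <- nchar(read_seq)
  # best chain ending at each position 0..n (array index pos+1)
  clen <- rep(-1L, n + 1L)
  cstart <- rep(NA_integer_, n + 1L)
  ctiles <- rep(0L, n + 1L)
  clast <- rep(0L, n + 1L)   # occurrence row whose tile ends the chain
  prev_occ <- integer(no)    # predecessor occurrence in the best incoming chain

  off <- occurrences$offset
  len <- occurrences$length
  for (i in seq_len(no)) {
    o <- off[i]
    e <- o + len[i]
    if (clen[o + 1L] > 0L) {
      cand_len <- clen[o + 1L] + len[i]
      cand_start <- cstart[o + 1L]
      cand_tiles <- ctiles[o + 1L] + 1L
      prev_occ[i] <- clast[o + 1L]
    } else {
      cand_len <- len[i]
      cand_start <- o
      cand_tiles <- 1L
      prev_occ[i] <- 0L
    }
    cur <- clen[e + 1L]
    better <- cand_len > cur ||
      (cand_len == cur && (cand_start < cstart[e + 1L] ||
        (cand_start == cstart[e + 1L] && cand_tiles < ctiles[e + 1L])))
    if (better) {
      clen[e + 1L] <- cand_len
      cstart[e + 1L] <- cand_start
      ctiles[e + 1L] <- cand_tiles
      clast[e + 1L] <- i
    }
  }

  ends <- which(clen > 0L)
  best <- ends[order(-clen[ends], cstart[ends], ctiles[ends])][1]
  tiles_idx <- integer(ctiles[best])
  j <- clast[best]
  for (t in seq.int(ctiles[best], 1L)) {
    tiles_idx[t] <- j
    j <- prev_occ[j]
  }
  structure(
    list(
      start = cstart[best],
      end = best - 1L,
      tiles = fast_df(
        element_index = occurrences$element_index[tiles_idx],
        offset = off[tiles_idx],
        length = len[tiles_idx]
      )
    ),
    class = "tiled_interval"
  )
}

#' Anchor the configured flanks around a tiled interval
#'
#' Each flank is slid over the read restricted to its proper side of the
#' interval: the 5' flank must end at or before the interval start, the
#' 3' flank must start at or after the interval end. The offset with
#' minimal Hamming mismatches wins, ties broken by proximity to the
#' interval, and a placement is accepted only when its mismatch count is
#' at most `ceiling(max_mismatch_frac * flank length)`.
#'
#' @param read_seq Read sequence.
#' @param interval A `tiled_interval`.
#' @param locus An `str_locus` supplying `flank5`/`flank3`.
#' @param max_mismatch_frac Mismatch tolerance as a fraction of flank
#'   length (default 0.1, i.e. up to 2 mismatches in a 20 bp flank).
#' @return On success, a list with elements `flank5` and `flank3`, each a
#'   list of `offset` (0-based start in the read) and `mismatches`.
#'   On failure, an object of class `flank_failure` with element `side`
#'   (`"5prime"` or `"3prime"`).
#' @export
match_flanks <- function(read_seq, interval, locus, max_mismatch_frac = 0.1) {
  if (!inherits(interval, "tiled_interval") || !inherits(locus, "str_locus")) {
    stop("match_flanks() expects a tiled_interval and an str_locus")
  }
  rl <- nchar(read_seq)
  r <- utf8ToInt(read_seq)

  scan_side <- function(flank, lo, hi, prefer_high) {
    m <- nchar(flank)
    if (hi < lo) return(NULL)
    offs <- seq.int(lo, hi)
    offs <- offs[offs >= 0L & offs + m <= rl]
    if (!length(offs)) return(NULL)
    mm <- hamming_at_offsets(r, utf8ToInt(flank), offs)
    cand <- offs[mm == min(mm)]
    list(offset = if (prefer_high) max(cand) else min(cand), mismatches = min(mm))
  }

  m5 <- nchar(locus$flank5)
  f5 <- scan_side(locus$flank5, 0L, interval$start - m5, prefer_high = TRUE)
  if (is.null(f5) || f5$mismatches > ceiling(max_mismatch_frac * m5)) {
    return(structure(list(side = "5prime"), class = "flank_failure"))
  }
  m3 <- nchar(locus$flank3)
  f3 <- scan_side(locus$flank3, interval$end, rl - m3, prefer_high = FALSE)
  if (is.null(f3) || f3$mismatches > ceiling(max_mismatch_frac * m3)) {
    return(structure(list(side = "3prime"), class = "flank_failure"))
  }
  list(flank5 = f5, flank3 = f3)
}

rejection_reasons <- c("no_motif", "no_flank5", "no_flank3", "empty_region")

new_rejection <- function(reason) {
  structure(list(reason = reason), class = "read_rejection")
}

#' Call the STR allele supported by one read
#'
#' Composes the three per-read steps: exact motif search, longest
#' motif-tiled interval, and flank anchoring. The repeat region is every
#' base strictly between the end of the 5' flank match and the start of
#' the 3' flank match, so insertions, deletions and interstitial bases in
#' the region are all counted, and the region is then decomposed and
#' designated. Reads failing a step yield exactly one rejection reason
#' (`no_motif`, `no_flank5`, `no_flank3`, or `empty_region`) for QC
#' accounting.
#'
#' @param read A single-read list with `read_id`, `sequence` and
#'   optionally `qualities`, already oriented per the locus.
#' @param locus An `str_locus`.
#' @param params List of tunables; currently `flank_max_mismatch_frac`
#'   (default 0.1).
#' @return A `read_allele_call` (with region coordinates, decomposition,
#'   designation, flank matches, read-end distances and mean region
#'   quality), or a `read_rejection`.
#' @export
call_read <- function(read, locus, params = list()) {
  if (!inherits(locus, "str_locus")) stop("locus must be an str_locus")
  frac <- params$flank_max_mismatch_frac %||% 0.1
  st <- locus$structure

  occ <- find_exact_occurrences(read$sequence, st)
  if (!nrow(occ)) return(new_rejection("no_motif"))
  iv <- longest_tiled_interval(occ, read$sequence)
  fl <- match_flanks(read$sequence, iv, locus, max_mismatch_frac = frac)
  if (inherits(fl, "flank_failure")) {
    return(new_rejection(if (fl$side == "5prime") "no_flank5" else "no_flank3"))
  }
  rs <- fl$flank5$offset + nchar(locus$flank5)  # region start, 0-based
  re <- fl$flank3$offset                        # region end, 0-based exclusive
  if (re <= rs) return(new_rejection("empty_region"))
  region <- substr(read$sequence, rs + 1L, re)
  dec <- decompose_region(region, st)
  des <- designate(dec, st)
  qual <- if (is.list(read$qualities)) read$qualities[[1]] else read$qualities
  structure(
    list(
      read_id = read$read_id %||% NA_character_,
      region_start = rs, region_end = re,
      region_sequence = region,
      decomposition = format(dec),
      designation = des,
      flank5 = fl$flank5, flank3 = fl$flank3,
      dist_5p = rs, dist_3p = nchar(read$sequence) - re,
      mean_region_quality = if (!is.null(qual)) mean(qual[(rs + 1L):re]) else NA_real_
    ),
    class = "read_allele_call"
  )
}

#' Call every read allocated to a locus
#'
#' @param reads A reads data frame, oriented per the locus.
#' @param locus An `str_locus`.
#' @param params See [call_read()].
#' @return A list with `calls` (list of `read_allele_call`) and
#'   `rejections` (named integer vector over all rejection reasons).
#' @export
call_reads <- function(reads, locus, params = list()) {
  calls <- list()
  rej <- setNames(integer(length(rejection_reasons)), rejection_reasons)
  for (i in seq_len(nrow(reads))) {
    res <- call_read(
      list(read_id = reads$read_id[i], sequence = reads$sequence[i],
           qualities = reads$qualities[[i]]),
      locus, params
    )
    if (inherits(res, "read_rejection")) {
      rej[res$reason] <- rej[res$reason] + 1L
    } else {
      calls[[length(calls) + 1L]] <- res
    }
  }
  list(calls = calls, rejections = rej)
}

#' Assign unaligned reads to panel loci by flank detection
#'
#' In FASTQ mode (no alignment available) a read is attributed to the
#' unique locus whose two flanks both match somewhere in the read, on
#' either strand; reads whose flanks match two or more loci are rejected
#' as ambiguous. The returned reads are already in locus read
#' orientation (the matching strand).
#'
#' @param reads A reads data frame.
#' @param configs List of `str_locus`.
#' @param max_mismatch_frac Per-flank mismatch tolerance.
#' @return List with `assigned` (named list of reads data frames, one per
#'   marker), `ambiguous` and `unassigned` read counts.
#' @export
assign_reads_to_loci <- function(reads, configs, max_mismatch_frac = 0.1) {
  n <- nrow(reads)
  hit_lists <- lapply(configs, function(x) integer(0))
  strand_flip <- lapply(configs, function(x) logical(0))
  fwd <- reads$sequence
  rev <- if (n) reverse_complement(fwd) else character(0)

  for (i in seq_len(n)) {
    fi <- utf8ToInt(fwd[i])
    ri <- utf8ToInt(rev[i])
    for (jn in seq_along(configs)) {
      loc <- configs[[jn]]
      f5 <- utf8ToInt(loc$flank5)
      f3 <- utf8ToInt(loc$flank3)
      tol5 <- ceiling(max_mismatch_frac * length(f5))
      tol3 <- ceiling(max_mismatch_frac * length(f3))
      both <- function(s) {
        rl <- length(s)
        ok <- TRUE
        for (fl in list(list(f5, tol5), list(f3, tol3))) {
          m <- length(fl[[1]])
          if (rl < m || min(hamming_at_offsets(s, fl[[1]], 0:(rl - m))) > fl[[2]]) {
            ok <- FALSE
            break
          }
        }
        ok
      }
      if (both(fi)) {
        hit_lists[[jn]] <- c(hit_lists[[jn]], i)
        strand_flip[[jn]] <- c(strand_flip[[jn]], FALSE)
      } else if (both(ri)) {
        hit_lists[[jn]] <- c(hit_lists[[jn]], i)
        strand_flip[[jn]] <- c(strand_flip[[jn]], TRUE)
      }
    }
  }

  n_hits <- integer(n)
  for (jn in seq_along(configs)) n_hits[hit_lists[[jn]]] <- n_hits[hit_lists[[jn]]] + 1L
  assigned <- setNames(vector("list", length(configs)),
                       vapply(configs, `[[`, "", "marker"))
  for (jn in seq_along(configs)) {
    keep <- n_hits[hit_lists[[jn]]] == 1L
    idx <- hit_lists[[jn]][keep]
    flip <- strand_flip[[jn]][keep]
    sub <- reads[idx, , drop = FALSE]
    if (any(flip)) {
      sub$sequence[flip] <- reverse_complement(sub$sequence[flip])
      sub$qualities[flip] <- lapply(sub$qualities[flip], rev)
    }
    assigned[[jn]] <- sub
  }
  list(
    assigned = assigned,
    ambiguous = sum(n_hits > 1L),
    unassigned = sum(n_hits == 0L)
  )
}
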