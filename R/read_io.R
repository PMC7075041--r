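#' Reverse complement of DNA sequences
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Vectorised over a
#' character vector. Characters outside A/C/G/T/N are an error.
#'
#' @param seq Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  if (!length(seq)) return(character(0))
  if (!all(is_dna(seq, allow_n = TRUE))) {
    stop("sequence contains characters outside ACGTN")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

new_reads <- function(read_id = character(0), sequence = character(0),
                      qualities = list(), mate = rep(NA_integer_, length(read_id))) {
  df <- data.frame(read_id = read_id, sequence = sequence, mate = mate,
                   stringsAsFactors = FALSE)
  df$qualities <- qualities
  df
}

#' Extract reads overlapping a locus repeat region from a BAM file
#'
#' Returns all primary, non-duplicate, non-supplementary mapped reads
#' whose alignment overlaps the configured repeat region (a single base
#' of overlap suffices), with sequences in reference orientation as
#' stored in the BAM. An empty result is a value, not an error.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param locus An `str_locus`.
#' @return A reads data frame (columns `read_id`, `sequence`, `mate` and
#'   list-column `qualities` of integer Phred scores).
#' @export
extract_locus_reads <- function(bam, locus) {
  stopifnot(inherits(locus, "str_locus"))
  if (!file.exists(bam)) stop(sprintf("BAM file not found: %s", bam))
  idx <- paste0(bam, ".bai")
  if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", bam))) {
    stop(sprintf("missing BAM index for %s (expected %s)", bam, idx))
  }
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!locus$chrom %in% names(targets)) {
    stop(sprintf("locus %s: chromosome '%s' not present in BAM header",
                 locus$marker, locus$chrom))
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE, isDuplicate = FALSE
    ),
    which = GenomicRanges::GRanges(
      locus$chrom,
      IRanges::IRanges(locus$repeat_start, locus$repeat_end)
    ),
    what = c("qname", "seq", "qual", "flag")
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$qname)
  if (!n) return(new_reads())
  mate <- rep(NA_integer_, n)
  mate[bitwAnd(res$flag, 64L) > 0L] <- 1L
  mate[bitwAnd(res$flag, 128L) > 0L] <- 2L
  new_reads(
    read_id = res$qname,
    sequence = as.character(res$seq),
    qualities = lapply(methods::as(res$qual, "IntegerList"), as.integer),
    mate = mate
  )
}

#' Orient reads to the original reading sequence of a locus
#'
#' For loci configured as `reverse`, every read sequence is
#' reverse-complemented and its quality vector reversed in lockstep;
#' forward loci pass through unchanged.
#'
#' @param reads A reads data frame.
#' @param locus An `str_locus`.
#' @return The oriented reads data frame.
#' @export
orient_reads <- function(reads, locus) {
  stopifnot(inherits(locus, "str_locus"))
  if (locus$orientation == "reverse" && nrow(reads)) {
    reads$sequence <- reverse_complement(reads$sequence)
    reads$qualities <- lapply(reads$qualities, rev)
  }
  reads
}

#' Merge an overlapping read pair into a single fused read
#'
#' The mate is reverse-complemented, then all overlap lengths of at least
#' `min_overlap` between the end of read 1 and the start of the flipped
#' mate are scored by mismatch fraction; the best overlap (ties broken
#' towards the longer overlap) is accepted when its mismatch fraction is
#' at most `max_mismatch_frac`. Disagreeing overlap bases take the
#' higher-quality base (ties favour read 1). A failed merge returns
#' `NULL`; callers then use both reads individually.
#'
#' @param r1,r2 Single-read lists/rows with `sequence` and `qualities`
#'   (and optionally `read_id`).
#' @param min_overlap Minimum overlap length in bases.
#' @param max_mismatch_frac Maximum tolerated mismatch fraction in the
#'   overlap.
#' @return A fused read list, or `NULL` when no acceptable overlap exists.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10L, max_mismatch_frac = 0.1) {
  s1 <- r1$sequence
  q1 <- if (is.list(r1$qualities)) r1$qualities[[1]] else r1$qualities
  s2 <- reverse_complement(r2$sequence)
  q2r <- if (is.list(r2$qualities)) r2$qualities[[1]] else r2$qualities
  q2 <- rev(q2r)
  n1 <- nchar(s1)
  n2 <- nchar(s2)
  if (min(n1, n2) < min_overlap) return(NULL)
  a <- utf8ToInt(s1)
  b <- utf8ToInt(s2)
  best <- NULL
  for (L in seq.int(min(n1, n2), min_overlap)) {
    mm <- sum(a[(n1 - L + 1L):n1] != b[1:L])
    fr <- mm / L
    if (is.null(best) || fr < best$fr) best <- list(L = L, fr = fr)
  }
  if (best$fr > max_mismatch_frac) return(NULL)
  L <- best$L
  ov_seq <- integer(L)
  ov_q <- integer(L)
  for (i in seq_len(L)) {
    i1 <- n1 - L + i
    if (a[i1] == b[i] || q1[i1] >= q2[i]) {
      ov_seq[i] <- a[i1]
      ov_q[i] <- max(q1[i1], q2[i])
    } else {
      ov_seq[i] <- b[i]
      ov_q[i] <- q2[i]
    }
  }
  list(
    read_id = r1$read_id %||% NA_character_,
    sequence = paste0(substr(s1, 1L, n1 - L), intToUtf8(ov_seq),
                      substr(s2, L + 1L, n2)),
    qualities = c(q1[seq_len(n1 - L)], ov_q, q2[seq.int(L + 1L, length.out = n2 - L)]),
    mate = NA_integer_
  )
}

#' Read a FASTQ file into a reads data frame
#'
#' @param path FASTQ path (optionally gzip-compressed).
#' @param mate Optional mate number (1 or 2) recorded on every read.
#' @return A reads data frame.
#' @export
read_fastq <- function(path, mate = NA_integer_) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  quals <- as.character(S4Vectors::mcols(x)$qualities)
  new_reads(
    read_id = names(x),
    sequence = as.character(x),
    qualities = lapply(quals, string_to_phred),
    mate = rep(as.integer(mate), length(x))
  )
}

#' Write a reads data frame as FASTQ
#'
#' @param reads A reads data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (!nrow(reads)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  recs <- vapply(seq_len(nrow(reads)), function(i) {
    paste(paste0("@", reads$read_id[i]), reads$sequence[i], "+",
          phred_to_string(reads$qualities[[i]]), sep = "\n")
  }, "")
  writeLines(recs, path)
  invisible(path)
}
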