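#' Specify an amplicon read simulation for one locus
#'
#' The simulator emulates targeted amplicon sequencing of a locus with a
#' known genotype: reads carry the repeat region between the configured
#' flanks, PCR stutter perturbs the repeat count of a read by one unit
#' (predominantly minus one, matching polymerase slippage during
#' extension), and sequencing noise is a flat per-base substitution
#' model. Platform-specific error profiles (homopolymer errors, quality
#' decay) are deliberately not modelled.
#'
#' @param locus An `str_locus`.
#' @param truth One or two allele designations (strings or
#'   `str_designation`) -- the genotype to simulate. Pass the same
#'   designation twice for a homozygote.
#' @param depth Reads per allele.
#' @param stutter_rate Probability that a read shows a one-repeat-unit
#'   slippage artifact.
#' @param stutter_dir_minus Probability that a stutter event removes
#'   (rather than adds) one repeat unit.
#' @param error_rate Per-base substitution probability.
#' @param read_length Emitted read length; must exceed the combined
#'   flank length so spanning reads are possible.
#' @param mode `"single"` or `"paired"`.
#' @param fragment_length Total fragment length; fragments shorter than
#'   this are padded at the 3' end with random context. Defaults to the
#'   unpadded fragment length.
#' @param seed Integer seed; identical specs give byte-identical output.
#' @return A `sim_spec` object for [simulate_reads()].
#' @export
sim_spec <- function(locus, truth, depth = 200L, stutter_rate = 0.1,
                     stutter_dir_minus = 0.9, error_rate = 0.005,
                     read_length = 150L, mode = c("single", "paired"),
                     fragment_length = NA_integer_, seed = 1L) {
  stopifnot(inherits(locus, "str_locus"))
  mode <- match.arg(mode)
  for (p in c(stutter_rate, stutter_dir_minus, error_rate)) {
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1) {
      stop("probabilities must lie in [0, 1]")
    }
  }
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) stop("depth must be >= 1")
  read_length <- as.integer(read_length)
  if (read_length <= nchar(locus$flank5) + nchar(locus$flank3)) {
    stop("read_length must exceed the combined flank length")
  }
  if (!is.list(truth)) truth <- as.list(truth)
  if (!length(truth) %in% c(1L, 2L)) stop("truth must hold one or two alleles")
  truth <- lapply(truth, as_designation)
  for (d in truth) expand_designation(d, locus$structure)  # feasibility check
  structure(
    list(locus = locus, truth = truth, depth = depth,
         stutter_rate = stutter_rate, stutter_dir_minus = stutter_dir_minus,
         error_rate = error_rate, read_length = read_length, mode = mode,
         fragment_length = as.integer(fragment_length), seed = as.integer(seed)),
    class = "sim_spec"
  )
}

#' Simulate amplicon reads with known STR genotype
#'
#' For each read an allele is picked uniformly from the truth genotype;
#' with probability `stutter_rate` the repeat count is perturbed by one
#' unit (direction per `stutter_dir_minus`; a slip below zero repeats is
#' redirected to +1). The fragment is `flank5 + region + flank3`, padded
#' with random context to `fragment_length`, and substitution errors are
#' applied at `error_rate` (substituted bases get a reduced quality
#' score). Single-end reads are the fragment 5' prefix; paired mode
#' additionally emits the reverse-complemented 3' end as mate 2. Read
#' names encode the truth (`marker|allele|designation|stutter|serial`)
#' so tests can assert against it white-box.
#'
#' @param spec A `sim_spec`.
#' @param out_prefix Optional path prefix; when given, FASTQ
#'   (`<prefix>.fastq`, or `_1/_2.fastq` in paired mode) and a truth
#'   table (`<prefix>.truth.tsv`) are written.
#' @return List with `reads` (single mode) or `reads1`/`reads2` (paired
#'   mode) reads data frames, and `truth` (data frame: `read_id`,
#'   `marker`, `true_allele`, `sim_allele`, `stutter`).
#' @export
simulate_reads <- function(spec, out_prefix = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  loc <- spec$locus
  st <- loc$structure
  nal <- length(spec$truth)
  total <- spec$depth * nal
  base_q <- 35L
  err_q <- 12L

  allele_idx <- sample.int(nal, total, replace = TRUE)
  is_stutter <- stats::runif(total) < spec$stutter_rate
  minus <- stats::runif(total) < spec$stutter_dir_minus
  delta <- ifelse(is_stutter, ifelse(minus, -1L, 1L), 0L)

  # redirect impossible minus-slips (zero-repeat alleles) to +1
  for (i in which(delta == -1L)) {
    if (spec$truth[[allele_idx[i]]]$full == 0L) delta[i] <- 1L
  }

  # cache fragments per (allele, delta) variant
  frag_cache <- new.env(parent = emptyenv())
  fragment_for <- function(ai, dl) {
    key <- paste0(ai, ":", dl)
    if (!is.null(frag_cache[[key]])) return(frag_cache[[key]])
    d <- spec$truth[[ai]]
    sim_d <- new_designation(d$full + dl, d$partial)
    region <- expand_designation(sim_d, st)
    frag <- paste0(loc$flank5, region, loc$flank3)
    frag_cache[[key]] <- list(frag = frag, designation = sim_d)
    frag_cache[[key]]
  }
  # pad fragments deterministically per variant (context is locus
  # context, identical across reads of the same variant)
  pad_cache <- new.env(parent = emptyenv())
  padded_fragment <- function(ai, dl) {
    key <- paste0(ai, ":", dl)
    if (!is.null(pad_cache[[key]])) return(pad_cache[[key]])
    fr <- fragment_for(ai, dl)
    frag <- fr$frag
    if (!is.na(spec$fragment_length) && nchar(frag) < spec$fragment_length) {
      frag <- paste0(frag, random_dna(spec$fragment_length - nchar(frag)))
    }
    pad_cache[[key]] <- list(frag = frag, designation = fr$designation)
    pad_cache[[key]]
  }

  bases <- c("A", "C", "G", "T")
  substitute_errors <- function(seq, qual) {
    n <- nchar(seq)
    hit <- which(stats::runif(n) < spec$error_rate)
    if (length(hit)) {
      ch <- strsplit(seq, "", fixed = TRUE)[[1]]
      for (p in hit) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
      seq <- paste(ch, collapse = "")
      qual[hit] <- err_q
    }
    list(seq = seq, qual = qual)
  }

  ids <- character(total)
  seq1 <- character(total)
  qual1 <- vector("list", total)
  seq2 <- character(total)
  qual2 <- vector("list", total)
  sim_allele <- character(total)

  for (i in seq_len(total)) {
    pf <- padded_fragment(allele_idx[i], delta[i])
    frag <- pf$frag
    flen <- nchar(frag)
    sim_allele[i] <- format(pf$designation)
    ids[i] <- sprintf("%s|a%d|%s|%+d|%06d", loc$marker, allele_idx[i],
                      sim_allele[i], delta[i], i)
    rl <- min(spec$read_length, flen)
    r1 <- substitute_errors(substr(frag, 1L, rl), rep(base_q, rl))
    seq1[i] <- r1$seq
    qual1[i] <- list(r1$qual)
    if (spec$mode == "paired") {
      r2seq <- reverse_complement(substr(frag, flen - rl + 1L, flen))
      r2 <- substitute_errors(r2seq, rep(base_q, rl))
      seq2[i] <- r2$seq
      qual2[i] <- list(r2$qual)
    }
  }

  truth_tab <- data.frame(
    read_id = ids, marker = loc$marker,
    true_allele = vapply(spec$truth, format, "")[allele_idx],
    sim_allele = sim_allele, stutter = delta,
    stringsAsFactors = FALSE
  )
  out <- list(truth = truth_tab)
  if (spec$mode == "single") {
    out$reads <- new_reads(ids, seq1, qual1, rep(NA_integer_, total))
  } else {
    out$reads1 <- new_reads(ids, seq1, qual1, rep(1L, total))
    out$reads2 <- new_reads(ids, seq2, qual2, rep(2L, total))
  }

  if (!is.null(out_prefix)) {
    if (spec$mode == "single") {
      write_fastq(out$reads, paste0(out_prefix, ".fastq"))
    } else {
      write_fastq(out$reads1, paste0(out_prefix, "_1.fastq"))
      write_fastq(out$reads2, paste0(out_prefix, "_2.fastq"))
    }
    utils::write.table(truth_tab, paste0(out_prefix, ".truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

# A flank may not continue the repeat across the region boundary,
# otherwise motif tiling absorbs flank bases and anchoring fails; reject
# candidate flanks whose boundary-side bases could complete a motif copy.
flank5_compatible <- function(flank, motifs) {
  nf <- nchar(flank)
  for (m in motifs) {
    for (t in seq_len(min(nchar(m), nf))) {
      if (substr(flank, nf - t + 1L, nf) == substr(m, 1L, t)) return(FALSE)
    }
  }
  TRUE
}

flank3_compatible <- function(flank, motifs) {
  for (m in motifs) {
    k <- nchar(m)
    for (t in seq_len(min(k, nchar(flank)))) {
      if (substr(flank, 1L, t) == substr(m, k - t + 1L, k)) return(FALSE)
    }
  }
  TRUE
}

#' Generate a synthetic STR locus for simulation studies
#'
#' Draws a random repeat structure (a single bracketed motif, or two
#' same-length bracketed motifs separated by nothing, as in compound
#' forensic loci) of period 3-5 and random 20 bp flanks, rejecting
#' flanks whose boundary bases could extend the repeat tiling across the
#' region boundary. Coordinates are placeholder values on a synthetic
#' contig; draws come from the caller's RNG stream.
#'
#' @param marker Marker name for the synthetic locus.
#' @param n_flank Flank length in bp.
#' @param compound_prob Probability of drawing a two-motif compound
#'   structure.
#' @return An `str_locus`.
#' @export
sim_locus <- function(marker = "sim1", n_flank = 20L, compound_prob = 0.3) {
  period <- sample(3:5, 1L)
  draw_motif <- function() {
    repeat {
      m <- random_dna(period)
      # a motif that is a rotation of a single base (homopolymer) tiles
      # ambiguously; keep at least two distinct bases
      if (length(unique(strsplit(m, "", fixed = TRUE)[[1]])) >= 2L) return(m)
    }
  }
  m1 <- draw_motif()
  if (stats::runif(1) < compound_prob) {
    repeat {
      m2 <- draw_motif()
      if (m2 != m1) break
    }
    text <- sprintf("[%s]n [%s]n", m1, m2)
    motifs <- c(m1, m2)
  } else {
    text <- sprintf("[%s]n", m1)
    motifs <- m1
  }
  repeat {
    f5 <- random_dna(n_flank)
    if (flank5_compatible(f5, motifs)) break
  }
  repeat {
    f3 <- random_dna(n_flank)
    if (flank3_compatible(f3, motifs)) break
  }
  locus_config(
    marker = marker, chrom = "chrSim",
    repeat_start = 1001L, repeat_end = 1001L + 12L * period - 1L,
    structure = text, orientation = "forward",
    flank5 = f5, flank3 = f3, chrom_class = "autosomal"
  )
}
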