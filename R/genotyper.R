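#' Tally per-read allele calls at one locus
#'
#' Counts calls by (designation, decomposition string): two
#' sequence-distinct alleles with the same CE designation are kept as
#' separate entries here and only merge later for genotype ranking.
#' Entries are ordered by count (descending), then by designation
#' (larger, i.e. longer, allele first), then by decomposition string.
#'
#' @param calls List of `read_allele_call` from one locus.
#' @return An `allele_tally`: list with `entries` (data frame of
#'   `designation`, `decomposition`, `count`), `total` (pre-filter total
#'   called reads) and `removed_reads` (0 until noise filtering).
#' @export
tally_alleles <- function(calls) {
  if (!length(calls)) {
    return(structure(
      list(entries = data.frame(designation = character(),
                                decomposition = character(),
                                count = integer(),
                                stringsAsFactors = FALSE),
           total = 0L, removed_reads = 0L),
      class = "allele_tally"
    ))
  }
  des <- vapply(calls, function(x) format(x$designation), "")
  dec <- vapply(calls, function(x) x$decomposition, "")
  key <- paste(des, dec, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  entries <- data.frame(
    designation = vapply(parts, `[`, "", 1L),
    decomposition = vapply(parts, `[`, "", 2L),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  dk <- vapply(entries$designation, function(d) designation_key(parse_designation(d)), 0)
  entries <- entries[order(-entries$count, -dk, entries$decomposition), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries, total = length(calls), removed_reads = 0L),
            class = "allele_tally")
}

#' Remove low-frequency noise alleles from a tally
#'
#' Noise alleles are those supported by no more than `noise_frac` of the
#' locus's total called reads (the boundary itself is removed: an entry
#' at exactly 1% of reads counts as noise under the default). The
#' threshold is computed against the pre-filter total, and the removed
#' read mass is recorded so that kept + removed always reconstructs the
#' pre-filter total.
#'
#' @param tally An `allele_tally`.
#' @param noise_frac Noise fraction in (0, 1); default 0.01.
#' @return The filtered `allele_tally`.
#' @export
filter_noise <- function(tally, noise_frac = 0.01) {
  stopifnot(inherits(tally, "allele_tally"))
  if (!is.numeric(noise_frac) || noise_frac <= 0 || noise_frac >= 1) {
    stop("noise_frac must lie in (0, 1)")
  }
  cutoff <- noise_frac * tally$total
  keep <- tally$entries$count > cutoff
  removed <- sum(tally$entries$count[!keep])
  tally$entries <- tally$entries[keep, , drop = FALSE]
  rownames(tally$entries) <- NULL
  tally$removed_reads <- tally$removed_reads + removed
  tally
}

# Merge tally entries that share a CE designation (sequence variants of
# one CE allele pool their depth), preserving rank order semantics.
merge_by_designation <- function(tally) {
  e <- tally$entries
  if (!nrow(e)) {
    return(data.frame(designation = character(), depth = integer(),
                      sequences = character(), stringsAsFactors = FALSE))
  }
  depth <- tapply(e$count, e$designation, sum)
  seqs <- tapply(e$decomposition, e$designation, function(x) paste(x, collapse = ";"))
  out <- data.frame(
    designation = names(depth),
    depth = as.integer(depth),
    sequences = as.character(seqs[names(depth)]),
    stringsAsFactors = FALSE
  )
  dk <- vapply(out$designation, function(d) designation_key(parse_designation(d)), 0)
  out <- out[order(-out$depth, -dk), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call the locus genotype from a noise-filtered tally
#'
#' Diploid loci report the two most-supported CE designations. The
#' stutter ratio is the depth of the second allele over the depth of the
#' first; when it is strictly below `stutter_threshold` the second allele
#' is deemed a PCR stutter artifact and the locus is reported homozygous
#' (the correction is flagged). Haploid loci (X/Y in a male sample)
#' report the modal allele only; everything else is stutter. An empty
#' tally yields status `"NA"` (no call).
#'
#' Depth ties between candidate alleles are broken towards the larger
#' designation: stutter is predominantly one repeat unit shorter than
#' the parent allele, so preferring the longer of two tied alleles is
#' the conservative heterozygote call.
#'
#' @param tally A noise-filtered `allele_tally`.
#' @param ploidy `"diploid"` or `"haploid"`.
#' @param stutter_threshold Analytical stutter-ratio threshold in (0, 1);
#'   default 0.5.
#' @return A `genotype_call`: list with `marker` (filled by the pipeline),
#'   `status`, `allele1`, `allele2`, `depth1`, `depth2`, `stutter_ratio`,
#'   `correction_applied` and `sequences`.
#' @examples
#' calls <- rep(list(structure(list(designation = new_designation(8),
#'   decomposition = "[AATG]8"), class = "read_allele_call")), 3)
#' call_genotype(tally_alleles(calls), "diploid")
#' @export
call_genotype <- function(tally, ploidy = c("diploid", "haploid"),
                          stutter_threshold = 0.5) {
  stopifnot(inherits(tally, "allele_tally"))
  ploidy <- match.arg(ploidy)
  if (!is.numeric(stutter_threshold) || stutter_threshold <= 0 || stutter_threshold >= 1) {
    stop("stutter_threshold must lie in (0, 1)")
  }
  merged <- merge_by_designation(tally)
  if (!nrow(merged)) {
    return(structure(
      list(marker = NA_character_, status = "NA",
           allele1 = NA_character_, allele2 = NA_character_,
           depth1 = NA_integer_, depth2 = NA_integer_,
           stutter_ratio = NA_real_, correction_applied = FALSE,
           sequences = character(0)),
      class = "genotype_call"
    ))
  }
  a1 <- merged$designation[1]
  d1 <- merged$depth[1]
  second <- if (nrow(merged) >= 2L) merged[2, ] else NULL

  if (ploidy == "haploid") {
    gt <- list(
      marker = NA_character_, status = "called",
      allele1 = a1, allele2 = NA_character_,
      depth1 = d1,
      depth2 = if (is.null(second)) NA_integer_ else second$depth,
      stutter_ratio = if (is.null(second)) NA_real_ else second$depth / d1,
      correction_applied = FALSE,
      sequences = merged$sequences[1]
    )
    return(structure(gt, class = "genotype_call"))
  }

  if (is.null(second)) {
    gt <- list(
      marker = NA_character_, status = "called",
      allele1 = a1, allele2 = a1,
      depth1 = d1, depth2 = NA_integer_,
      stutter_ratio = NA_real_, correction_applied = FALSE,
      sequences = merged$sequences[1]
    )
    return(structure(gt, class = "genotype_call"))
  }

  ratio <- second$depth / d1
  corrected <- ratio < stutter_threshold
  gt <- list(
    marker = NA_character_, status = "called",
    allele1 = a1,
    allele2 = if (corrected) a1 else second$designation,
    depth1 = d1, depth2 = second$depth,
    stutter_ratio = ratio,
    correction_applied = corrected,
    sequences = if (corrected) merged$sequences[1] else
      c(merged$sequences[1], second$sequences)
  )
  structure(gt, class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  if (x$status == "NA") {
    cat(sprintf("<genotype> %s: NA (no call)\n", x$marker %||% "?"))
  } else {
    cat(sprintf(
      "<genotype> %s: (%s, %s) depths (%s, %s) stutter ratio %s%s\n",
      ifelse(is.na(x$marker), "?", x$marker), x$allele1,
      ifelse(is.na(x$allele2), "-", x$allele2),
      x$depth1, ifelse(is.na(x$depth2), "-", x$depth2),
      ifelse(is.na(x$stutter_ratio), "-", sprintf("%.3f", x$stutter_ratio)),
      if (isTRUE(x$correction_applied)) " [stutter-corrected]" else ""
    ))
  }
  invisible(x)
}

genotype_row <- function(gt) {
  data.frame(
    marker = gt$marker, status = gt$status,
    allele1 = gt$allele1 %||% NA_character_,
    allele2 = gt$allele2 %||% NA_character_,
    depth1 = gt$depth1, depth2 = gt$depth2,
    stutter_ratio = gt$stutter_ratio,
    correction_applied = gt$correction_applied,
    sequences = paste(gt$sequences, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

multi_allele_rows <- function(marker, tally, gt) {
  e <- tally$entries
  if (!nrow(e)) {
    return(data.frame(marker = character(), allele = character(),
                      reads = integer(), role = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  gt_alleles <- unique(c(gt$allele1, gt$allele2))
  gt_alleles <- gt_alleles[!is.na(gt_alleles)]
  data.frame(
    marker = marker, allele = e$designation, reads = e$count,
    role = ifelse(e$designation %in% gt_alleles, "allele", "stutter"),
    sequence = e$decomposition, stringsAsFactors = FALSE
  )
}

#' Write the three report tables
#'
#' Produces `genotypes.tsv` (one row per marker, including `"NA"`
#' no-call loci), `multiple_alleles.tsv` (one row per allele surviving
#' the noise filter, labelled `allele` or `stutter` relative to the
#' final genotype) and `qc_matrix.tsv`. Output is deterministic given
#' the inputs; columns are documented in the README.
#'
#' @param genotypes List of `genotype_call` (with `marker` filled in).
#' @param tallies Named list of noise-filtered `allele_tally`, parallel
#'   to `genotypes`.
#' @param qc_records Data frame of QC records ([compute_qc()]).
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_reports <- function(genotypes, tallies, qc_records, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory: %s", out_dir))
  }
  gdf <- if (length(genotypes)) {
    do.call(rbind, lapply(genotypes, genotype_row))
  } else {
    genotype_row(structure(list(marker = NA_character_, status = "NA",
                                allele1 = NA_character_, allele2 = NA_character_,
                                depth1 = NA_integer_, depth2 = NA_integer_,
                                stutter_ratio = NA_real_, correction_applied = FALSE,
                                sequences = character(0)),
                           class = "genotype_call"))[0, ]
  }
  adf <- if (length(genotypes)) {
    do.call(rbind, lapply(seq_along(genotypes), function(i) {
      multi_allele_rows(genotypes[[i]]$marker, tallies[[i]], genotypes[[i]])
    }))
  } else {
    data.frame(marker = character(), allele = character(), reads = integer(),
               role = character(), sequence = character(), stringsAsFactors = FALSE)
  }
  paths <- c(
    genotypes = file.path(out_dir, "genotypes.tsv"),
    multiple_alleles = file.path(out_dir, "multiple_alleles.tsv"),
    qc_matrix = file.path(out_dir, "qc_matrix.tsv")
  )
  utils::write.table(gdf, paths["genotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(adf, paths["multiple_alleles"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(qc_records, paths["qc_matrix"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(paths)
}
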