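#' Compute the per-locus quality-control record
#'
#' Summarises sequence properties of a locus/sample combination: total
#' bases and mean quality over allocated reads, read accounting
#' (allocated = called + rejected, by reason), per-allele read depths,
#' the stutter ratio, and the mean distances from the region boundaries
#' of each genotype allele's supporting reads to the read ends. Short
#' 3'-end distances flag reads that barely span the repeat region, a
#' known driver of miscalled (truncated) alleles.
#'
#' @param marker Marker name.
#' @param reads Reads data frame allocated to the locus.
#' @param calls List of `read_allele_call` for the locus.
#' @param rejections Named integer vector of per-reason rejection counts.
#' @param genotype The locus `genotype_call`.
#' @param sample Sample identifier.
#' @return A one-row data frame (a QC record).
#' @export
compute_qc <- function(marker, reads, calls, rejections, genotype,
                       sample = "sample") {
  n_alloc <- nrow(reads)
  total_bases <- if (n_alloc) sum(nchar(reads$sequence)) else 0L
  mean_q <- if (n_alloc) {
    per_read <- vapply(reads$qualities, function(q) {
      if (is.null(q) || !length(q)) NA_real_ else mean(q)
    }, 0)
    if (all(is.na(per_read))) NA_real_ else mean(per_read, na.rm = TRUE)
  } else {
    NA_real_
  }

  des <- vapply(calls, function(x) format(x$designation), character(1))
  allele_dist <- function(allele) {
    if (is.na(allele)) return(c(NA_real_, NA_real_))
    sel <- which(des == allele)
    if (!length(sel)) return(c(NA_real_, NA_real_))
    c(mean(vapply(calls[sel], `[[`, 0, "dist_5p")),
      mean(vapply(calls[sel], `[[`, 0, "dist_3p")))
  }
  a1 <- if (genotype$status == "called") genotype$allele1 else NA_character_
  # For the distance features allele 2 is the second *observed* allele;
  # a stutter-corrected homozygote has no distinct allele-2 reads.
  a2 <- if (genotype$status == "called" && !is.na(genotype$allele2) &&
            !isTRUE(genotype$correction_applied) &&
            !identical(genotype$allele2, genotype$allele1)) {
    genotype$allele2
  } else {
    NA_character_
  }
  d1 <- allele_dist(a1)
  d2 <- allele_dist(a2)

  rej <- setNames(integer(length(rejection_reasons)), rejection_reasons)
  if (length(rejections)) rej[names(rejections)] <- as.integer(rejections)

  data.frame(
    sample = sample, marker = marker,
    total_bases = total_bases, mean_quality = mean_q,
    n_allocated = n_alloc, n_called = length(calls),
    rej_no_motif = rej[["no_motif"]],
    rej_no_flank5 = rej[["no_flank5"]],
    rej_no_flank3 = rej[["no_flank3"]],
    rej_empty_region = rej[["empty_region"]],
    depth1 = genotype$depth1, depth2 = genotype$depth2,
    stutter_ratio = genotype$stutter_ratio,
    dis1_mean_5 = d1[1], dis1_mean_3 = d1[2],
    dis2_mean_5 = d2[1], dis2_mean_3 = d2[2],
    stringsAsFactors = FALSE
  )
}

#' Export QC records as a feature table
#'
#' One row per (sample, marker); identifier columns plus numeric
#' features, with missing values encoded as empty fields. The schema is
#' the integration point for an external genotype-quality classifier
#' (e.g. gradient-boosted trees trained on CE-concordance labels);
#' training such a model is out of scope here.
#'
#' @param records Data frame of QC records (rbind of [compute_qc()] rows).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_feature_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read back an exported feature table
#'
#' @param path TSV path written by [export_feature_table()].
#' @return Data frame with empty fields decoded as `NA`.
#' @export
read_feature_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
}
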