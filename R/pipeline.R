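#' Ploidy of a locus given the sample sex
#'
#' Autosomal loci are diploid. X loci are haploid in males, diploid
#' otherwise. Y loci are haploid in males, absent (`"none"`) in females;
#' for unknown sex they are called haploid with a warning.
#'
#' @param chrom_class `"autosomal"`, `"X"` or `"Y"`.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @return `"diploid"`, `"haploid"` or `"none"`.
#' @export
locus_ploidy <- function(chrom_class, sex = c("unknown", "male", "female")) {
  sex <- match.arg(sex)
  switch(chrom_class,
    autosomal = "diploid",
    X = if (sex == "male") "haploid" else "diploid",
    Y = switch(sex,
      male = "haploid",
      female = "none",
      unknown = {
        warning("Y locus called haploid for sample of unknown sex")
        "haploid"
      }
    ),
    stop(sprintf("unknown chrom_class '%s'", chrom_class))
  )
}

na_genotype <- function(marker) {
  structure(
    list(marker = marker, status = "NA",
         allele1 = NA_character_, allele2 = NA_character_,
         depth1 = NA_integer_, depth2 = NA_integer_,
         stutter_ratio = NA_real_, correction_applied = FALSE,
         sequences = character(0)),
    class = "genotype_call"
  )
}

# Per-locus unit of work shared by BAM and FASTQ modes: reads must
# already be oriented to the locus reading sequence.
process_locus <- function(locus, reads, sex, params, sample) {
  ploidy <- locus_ploidy(locus$chrom_class, sex)
  if (ploidy == "none") {
    gt <- na_genotype(locus$marker)
    tl <- tally_alleles(list())
    qc <- compute_qc(locus$marker, new_reads(), list(),
                     setNames(integer(0), character(0)), gt, sample)
    return(list(genotype = gt, tally = tl, qc = qc))
  }
  cr <- call_reads(reads, locus, params)
  tl <- tally_alleles(cr$calls)
  tl <- filter_noise(tl, params$noise_frac %||% 0.01)
  gt <- if (nrow(tl$entries)) {
    call_genotype(tl, ploidy, params$stutter_threshold %||% 0.5)
  } else {
    na_genotype(locus$marker)
  }
  gt$marker <- locus$marker
  qc <- compute_qc(locus$marker, reads, cr$calls, cr$rejections, gt, sample)
  list(genotype = gt, tally = tl, qc = qc)
}

#' Run the targeted STR profiling pipeline
#'
#' Processes every locus of the panel independently (optionally in
#' parallel; results are merged in configuration order so output is
#' identical for any thread count) and writes the three report tables:
#' genotypes, multiple alleles, and the QC matrix.
#'
#' Input may be a coordinate-sorted indexed BAM (reads are allocated to
#' loci by the repeat-region coordinates) or FASTQ file(s) (reads are
#' allocated by detecting both locus flanks; reads matching several loci
#' are dropped as ambiguous). Paired FASTQ reads can be overlap-merged
#' first; pairs that fail to merge are processed individually.
#'
#' @param config Path to a panel TSV, or a list of `str_locus`.
#' @param input BAM path, or FASTQ path (read 1).
#' @param input2 Optional FASTQ path for read 2.
#' @param out_dir Optional output directory for the three reports.
#' @param sample Sample identifier used in reports.
#' @param sex Sample sex: `"unknown"`, `"male"` or `"female"`.
#' @param stutter_threshold Stutter-ratio threshold (default 0.5).
#' @param noise_frac Noise fraction (default 0.01).
#' @param flank_max_mismatch_frac Flank mismatch tolerance (default 0.1).
#' @param merge Merge overlapping read pairs (paired FASTQ mode only).
#' @param threads Worker processes for per-locus parallelism.
#' @return Invisibly, a list with `genotypes`, `alleles` and `qc` data
#'   frames (and the report paths when `out_dir` is given).
#' @export
run_str_pipeline <- function(config, input, input2 = NULL, out_dir = NULL,
                             sample = "sample",
                             sex = c("unknown", "male", "female"),
                             stutter_threshold = 0.5, noise_frac = 0.01,
                             flank_max_mismatch_frac = 0.1,
                             merge = FALSE, threads = 1L) {
  sex <- match.arg(sex)
  configs <- if (is.character(config)) read_locus_config(config) else config
  stopifnot(all(vapply(configs, inherits, TRUE, "str_locus")))
  params <- list(stutter_threshold = stutter_threshold,
                 noise_frac = noise_frac,
                 flank_max_mismatch_frac = flank_max_mismatch_frac)

  is_bam <- grepl("\\.bam$", input, ignore.case = TRUE)
  locus_reads <- if (is_bam) {
    lapply(configs, function(loc) {
      orient_reads(extract_locus_reads(input, loc), loc)
    })
  } else {
    reads <- read_fastq(input, mate = 1L)
    if (!is.null(input2)) {
      reads2 <- read_fastq(input2, mate = 2L)
      if (merge) {
        merged <- vector("list", nrow(reads))
        leftover <- list()
        for (i in seq_len(nrow(reads))) {
          m <- merge_pairs(reads[i, ], reads2[i, ])
          if (is.null(m)) {
            leftover[[length(leftover) + 1L]] <- reads[i, ]
            leftover[[length(leftover) + 1L]] <- reads2[i, ]
          } else {
            merged[[i]] <- m
          }
        }
        merged <- merged[!vapply(merged, is.null, TRUE)]
        reads <- do.call(rbind, c(
          lapply(merged, function(m) new_reads(m$read_id, m$sequence,
                                               list(m$qualities), NA_integer_)),
          leftover
        ))
      } else {
        reads <- rbind(reads, reads2)
      }
    }
    assign_reads_to_loci(reads, configs, flank_max_mismatch_frac)$assigned
  }

  worker <- function(i) {
    process_locus(configs[[i]], locus_reads[[i]], sex, params, sample)
  }
  results <- if (threads > 1L) {
    parallel::mclapply(seq_along(configs), worker, mc.cores = threads)
  } else {
    lapply(seq_along(configs), worker)
  }

  for (i in seq_along(results)) {
    message(sprintf(
      "locus %s: %d reads allocated, %d called, %d rejected",
      configs[[i]]$marker, results[[i]]$qc$n_allocated,
      results[[i]]$qc$n_called,
      results[[i]]$qc$n_allocated - results[[i]]$qc$n_called
    ))
  }

  genotypes <- lapply(results, `[[`, "genotype")
  tallies <- lapply(results, `[[`, "tally")
  qc <- do.call(rbind, lapply(results, `[[`, "qc"))
  out <- list(
    genotypes = do.call(rbind, lapply(genotypes, genotype_row)),
    alleles = do.call(rbind, lapply(seq_along(genotypes), function(i) {
      multi_allele_rows(genotypes[[i]]$marker, tallies[[i]], genotypes[[i]])
    })),
    qc = qc
  )
  if (!is.null(out_dir)) {
    out$paths <- write_reports(genotypes, tallies, qc, out_dir)
  }
  invisible(out)
}
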