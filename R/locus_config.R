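#' Construct a single STR locus configuration
#'
#' Describes one marker of a targeted panel: where its repeat region sits
#' in the reference, its sequence-structure nomenclature, the original
#' reading orientation of the STR, and the fixed flanking sequences
#' (given in read orientation, i.e. after any orientation flip)
#' immediately adjacent to the repeat region that delimit it within a
#' read. Flanks of 10-30 bp are recommended; adjacency to a reference
#' genome is the user's responsibility and is not checked here.
#'
#' @param marker Marker name (unique within a panel).
#' @param chrom Reference sequence name.
#' @param repeat_start,repeat_end 1-based inclusive reference coordinates
#'   of the repeat region.
#' @param structure Sequence-structure string (see [parse_structure()]),
#'   or a pre-parsed `str_structure`.
#' @param orientation `"forward"` or `"reverse"`: the original reading
#'   sequence of the STR relative to the reference.
#' @param flank5,flank3 Upper-case ACGT flanking sequences adjacent to the
#'   repeat region, in read orientation.
#' @param chrom_class `"autosomal"`, `"X"` or `"Y"`; explicit rather than
#'   inferred from `chrom` because panel naming of sex chromosomes varies.
#' @return An object of class `str_locus`.
#' @export
locus_config <- function(marker, chrom, repeat_start, repeat_end, structure,
                         orientation = "forward", flank5, flank3,
                         chrom_class = "autosomal") {
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  if (!is.character(marker) || length(marker) != 1L || !nzchar(marker)) {
    note("marker: must be a non-empty string")
  }
  repeat_start <- suppressWarnings(as.integer(repeat_start))
  repeat_end <- suppressWarnings(as.integer(repeat_end))
  if (is.na(repeat_start) || is.na(repeat_end) || repeat_start < 1L) {
    note("repeat_start/repeat_end: must be positive integers")
  } else if (repeat_start > repeat_end) {
    note("repeat_start must be <= repeat_end")
  }
  if (!orientation %in% c("forward", "reverse")) {
    note(sprintf("orientation: '%s' is not 'forward' or 'reverse'", orientation))
  }
  if (!chrom_class %in% c("autosomal", "X", "Y")) {
    note(sprintf("chrom_class: '%s' is not 'autosomal', 'X' or 'Y'", chrom_class))
  }
  for (fl in c("flank5", "flank3")) {
    v <- get(fl)
    if (!is.character(v) || length(v) != 1L || !nzchar(v) || !is_dna(v)) {
      note(sprintf("%s: must be a non-empty upper-case ACGT string", fl))
    }
  }
  st <- NULL
  if (inherits(structure, "str_structure")) {
    st <- structure
  } else {
    st <- tryCatch(parse_structure(structure), error = function(e) {
      note(sprintf("structure: %s", conditionMessage(e)))
      NULL
    })
  }
  if (length(errs)) {
    stop(sprintf("invalid locus configuration for '%s': %s",
                 as.character(marker)[1], paste(errs, collapse = "; ")))
  }
  base::structure(
    list(
      marker = marker, chrom = chrom,
      repeat_start = repeat_start, repeat_end = repeat_end,
      structure_text = format(st), structure = st,
      orientation = orientation, flank5 = flank5, flank3 = flank3,
      chrom_class = chrom_class
    ),
    class = "str_locus"
  )
}

#' @export
print.str_locus <- function(x, ...) {
  cat(sprintf("<STR locus> %s %s:%d-%d (%s, %s)\n  structure: %s\n",
              x$marker, x$chrom, x$repeat_start, x$repeat_end,
              x$orientation, x$chrom_class, x$structure_text))
  invisible(x)
}

config_columns <- c("marker", "chrom", "repeat_start", "repeat_end",
                    "structure", "orientation", "flank5", "flank3",
                    "chrom_class")

#' Read a panel configuration file
#'
#' The panel is a tab-separated table with a header row naming the fields
#' of [locus_config()]. Every structure string is parsed eagerly so that
#' configuration errors surface before any read processing; duplicate
#' marker names are rejected.
#'
#' @param path Path to the TSV file.
#' @return A named list of `str_locus` objects in file order.
#' @export
read_locus_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("configuration file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(config_columns, names(df))
  if (length(missing)) {
    stop(sprintf("configuration file misses column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  errs <- character(0)
  configs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    configs[[i]] <- tryCatch(
      locus_config(
        marker = df$marker[i], chrom = df$chrom[i],
        repeat_start = df$repeat_start[i], repeat_end = df$repeat_end[i],
        structure = df$structure[i], orientation = df$orientation[i],
        flank5 = df$flank5[i], flank3 = df$flank3[i],
        chrom_class = df$chrom_class[i]
      ),
      error = function(e) {
        errs <<- c(errs, sprintf("row %d: %s", i, conditionMessage(e)))
        NULL
      }
    )
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  markers <- vapply(configs, `[[`, "", "marker")
  dup <- unique(markers[duplicated(markers)])
  if (length(dup)) {
    stop(sprintf("duplicate marker name(s): %s", paste(dup, collapse = ", ")))
  }
  names(configs) <- markers
  configs
}

#' Write a panel configuration file
#'
#' Inverse of [read_locus_config()]: serializing and re-reading a panel
#' yields identical configurations.
#'
#' @param configs A list of `str_locus` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_locus_config <- function(configs, path) {
  df <- do.call(rbind, lapply(configs, function(x) {
    data.frame(
      marker = x$marker, chrom = x$chrom,
      repeat_start = x$repeat_start, repeat_end = x$repeat_end,
      structure = x$structure_text, orientation = x$orientation,
      flank5 = x$flank5, flank3 = x$flank3, chrom_class = x$chrom_class,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(df)) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(config_columns)),
                                 config_columns))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
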