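#' Allele designations
#'
#' A capillary-electrophoresis (CE) compatible allele label for an STR
#' locus: an integer count of full repeat units plus a partial-repeat
#' remainder of leftover bases, printed as `"N"` or `"N.x"` (e.g. the
#' well-known TH01 `9.3` allele carries nine full repeats and three
#' leftover bases).
#'
#' @param full Non-negative integer count of full repeat units.
#' @param partial Integer number of leftover bases, `0 <= partial < period`
#'   of the locus structure.
#' @return An object of class `str_designation`.
#' @examples
#' format(new_designation(9, 3))   # "9.3"
#' parse_designation("15.2")
#' @export
new_designation <- function(full, partial = 0L) {
  full <- as.integer(full)
  partial <- as.integer(partial)
  if (is.na(full) || full < 0L) stop("full repeat count must be a non-negative integer")
  if (is.na(partial) || partial < 0L || partial > 9L) {
    stop("partial base count must be an integer in [0, 9]")
  }
  structure(list(full = full, partial = partial), class = "str_designation")
}

#' @rdname new_designation
#' @param text A designation string, `"N"` or `"N.x"`.
#' @export
parse_designation <- function(text) {
  text <- as.character(text)
  if (length(text) != 1L || is.na(text) || !grepl("^[0-9]+(\\.[0-9])?$", text)) {
    stop(sprintf("not a valid allele designation: '%s'", text))
  }
  parts <- strsplit(text, ".", fixed = TRUE)[[1]]
  new_designation(as.integer(parts[1]), if (length(parts) == 2L) as.integer(parts[2]) else 0L)
}

as_designation <- function(x) {
  if (inherits(x, "str_designation")) x else parse_designation(x)
}

#' @export
format.str_designation <- function(x, ...) {
  if (x$partial == 0L) as.character(x$full) else paste0(x$full, ".", x$partial)
}

#' @export
print.str_designation <- function(x, ...) {
  cat("<allele designation>", format(x), "\n")
  invisible(x)
}

#' @export
as.character.str_designation <- function(x, ...) format(x)

#' @export
Ops.str_designation <- function(e1, e2) {
  if (!.Generic %in% c("==", "!=")) {
    stop(sprintf("operation '%s' not defined for allele designations", .Generic))
  }
  e1 <- as_designation(e1)
  e2 <- as_designation(e2)
  eq <- (e1$full == e2$full) && (e1$partial == e2$partial)
  if (.Generic == "==") eq else !eq
}

# Numeric sort key; partial is a single digit so full + partial/10 orders
# designations lexicographically on (full, partial).
designation_key <- function(x) x$full + x$partial / 10

#' Parse a forensic STR sequence-structure string
#'
#' The repeat region of an STR locus is described by an ordered,
#' space-separated list of tokens following the forensic sequence-structure
#' convention: repeating motifs are bracketed with the suffix `n`
#' (`[TCTA]n`), non-repetitive but counted tracts are unbracketed upper
#' case (`ACT`), and tracts that are present but never counted are lower
#' case (`tccata`).
#'
#' @param text A sequence-structure string, e.g.
#'   `"[AATG]n ATG [AATG]n"`.
#' @return An object of class `str_structure` with components
#'   `elements` (data frame of `kind` and `motif` in token order),
#'   `period` (motif length of the first bracketed element, the reference
#'   repeat-unit size used for partial-repeat arithmetic) and
#'   `counted_motifs` (unique bracketed motifs).
#' @examples
#' s <- parse_structure("[AATG]n ATG [AATG]n")
#' s$period
#' format(s)
#' @export
parse_structure <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("empty sequence-structure string")
  }
  tokens <- strsplit(trimws(text), " ", fixed = TRUE)[[1]]
  if (any(!nzchar(tokens))) {
    stop("structure tokens must be separated by single spaces")
  }
  parsed <- lapply(tokens, function(tok) {
    if (grepl("[][]", tok)) {
      m <- regmatches(tok, regexec("^\\[([ACGT]+)\\]n$", tok))[[1]]
      if (length(m) < 2L) {
        stop(sprintf("malformed bracketed token '%s' (expected [MOTIF]n)", tok))
      }
      if (nchar(m[2]) > 6L) {
        stop(sprintf("repeat motif '%s' longer than 6 bp", m[2]))
      }
      list(kind = "bracketed", motif = m[2])
    } else if (grepl("^[ACGT]+$", tok)) {
      list(kind = "counted", motif = tok)
    } else if (grepl("^[acgt]+$", tok)) {
      list(kind = "uncounted", motif = toupper(tok))
    } else {
      stop(sprintf("invalid token '%s': mixed case or non-ACGT characters", tok))
    }
  })
  kinds <- vapply(parsed, `[[`, "", "kind")
  motifs <- vapply(parsed, `[[`, "", "motif")
  if (!any(kinds == "bracketed")) {
    stop("structure must contain at least one bracketed repeat element")
  }
  period <- nchar(motifs[which(kinds == "bracketed")[1]])
  structure(
    list(
      text = paste(tokens, collapse = " "),
      elements = data.frame(kind = kinds, motif = motifs, stringsAsFactors = FALSE),
      period = period,
      counted_motifs = unique(motifs[kinds == "bracketed"])
    ),
    class = "str_structure"
  )
}

#' @export
format.str_structure <- function(x, ...) {
  el <- x$elements
  tok <- character(nrow(el))
  tok[el$kind == "bracketed"] <- paste0("[", el$motif[el$kind == "bracketed"], "]n")
  tok[el$kind == "counted"] <- el$motif[el$kind == "counted"]
  tok[el$kind == "uncounted"] <- tolower(el$motif[el$kind == "uncounted"])
  paste(tok, collapse = " ")
}

#' @export
print.str_structure <- function(x, ...) {
  cat("<STR structure>", format(x), sprintf("(period %d)\n", x$period))
  invisible(x)
}

#' Decompose a repeat-region sequence against a locus structure
#'
#' Performs a deterministic greedy left-to-right tiling of `region`:
#' elements are tried in structure order compatible with progress through
#' the structure; a bracketed repeat consumes as many consecutive exact
#' motif copies as possible (and may be re-entered after an interruption),
#' counted/uncounted tracts consume one exact literal occurrence, and
#' bases matching no element are emitted as residual runs. Residual runs
#' that themselves tile exactly with a bracketed (counted) motif are
#' re-labelled as extra copies of that motif, so alleles longer than the
#' reference structure decompose cleanly.
#'
#' @param region Upper-case A/C/G/T string (may be empty).
#' @param structure An `str_structure` from [parse_structure()].
#' @return An `str_decomposition`: list with `segments` (data frame with
#'   columns `element`, `kind`, `motif`, `copies`, `offset`, `seq`,
#'   `relabelled`), `region`, and `residual_bases`.
#' @examples
#' s <- parse_structure("[TTCC]n")
#' d <- decompose_region(paste0(strrep("TTCC", 15), "TT"), s)
#' format(designate(d, s))   # "15.2"
#' @export
decompose_region <- function(region, structure) {
  if (!inherits(structure, "str_structure")) stop("structure must be an str_structure")
  if (is.na(region)) stop("region must not be NA")
  n <- nchar(region)
  if (n > 0L && !is_dna(region)) stop("region must be upper-case ACGT")
  el <- structure$elements
  ne <- nrow(el)
  kinds <- el$kind
  motifs <- el$motif
  klen <- nchar(motifs)

  # vector accumulators: one slot per emitted segment
  s_el <- integer(0)
  s_kind <- character(0)
  s_motif <- character(0)
  s_copies <- integer(0)
  s_off <- integer(0)
  s_seq <- character(0)
  res_start <- NA_integer_
  pos <- 1L
  p <- 1L

  emit <- function(element, kind, motif, copies, offset, seq) {
    s_el[length(s_el) + 1L] <<- element
    s_kind[length(s_kind) + 1L] <<- kind
    s_motif[length(s_motif) + 1L] <<- motif
    s_copies[length(s_copies) + 1L] <<- copies
    s_off[length(s_off) + 1L] <<- offset
    s_seq[length(s_seq) + 1L] <<- seq
  }
  flush_residual <- function(upto) {
    # residual run covers [res_start, upto] (1-based inclusive)
    if (!is.na(res_start)) {
      emit(NA_integer_, "residual", NA_character_, 0L, res_start - 1L,
           substr(region, res_start, upto))
      res_start <<- NA_integer_
    }
  }

  while (pos <= n) {
    matched <- FALSE
    if (p <= ne) {
      for (j in seq.int(p, ne)) {
        k <- klen[j]
        m <- motifs[j]
        if (kinds[j] == "bracketed") {
          cnt <- 0L
          while (pos + (cnt + 1L) * k - 1L <= n &&
                 substr(region, pos + cnt * k, pos + (cnt + 1L) * k - 1L) == m) {
            cnt <- cnt + 1L
          }
          if (cnt > 0L) {
            flush_residual(pos - 1L)
            emit(j, "bracketed", m, cnt, pos - 1L,
                 substr(region, pos, pos + cnt * k - 1L))
            pos <- pos + cnt * k
            p <- j            # bracketed elements may be re-entered
            matched <- TRUE
            break
          }
        } else {
          if (pos + k - 1L <= n && substr(region, pos, pos + k - 1L) == m) {
            flush_residual(pos - 1L)
            emit(j, kinds[j], m, 1L, pos - 1L, substr(region, pos, pos + k - 1L))
            pos <- pos + k
            p <- j + 1L       # tracts consume exactly one occurrence
            matched <- TRUE
            break
          }
        }
      }
    }
    if (!matched) {
      if (is.na(res_start)) res_start <- pos
      pos <- pos + 1L
    }
  }
  flush_residual(n)

  # Re-label residual runs that tile exactly with a counted (bracketed)
  # motif as extra repeat copies; ties between motifs broken by structure
  # (counted_motifs) order.
  relab <- rep(FALSE, length(s_seq))
  residual_bases <- 0L
  for (i in seq_along(s_seq)) {
    if (s_kind[i] != "residual") next
    run <- s_seq[i]
    L <- nchar(run)
    done <- FALSE
    for (m in structure$counted_motifs) {
      k <- nchar(m)
      if (L >= k && L %% k == 0L && run == strrep(m, L %/% k)) {
        s_kind[i] <- "bracketed"
        s_motif[i] <- m
        s_copies[i] <- L %/% k
        relab[i] <- TRUE
        done <- TRUE
        break
      }
    }
    if (!done) residual_bases <- residual_bases + L
  }

  structure(
    list(
      segments = fast_df(
        element = s_el, kind = s_kind, motif = s_motif, copies = s_copies,
        offset = s_off, seq = s_seq, relabelled = relab
      ),
      region = region,
      residual_bases = residual_bases
    ),
    class = "str_decomposition"
  )
}

#' @export
format.str_decomposition <- function(x, ...) {
  s <- x$segments
  if (!nrow(s)) return("")
  tok <- character(nrow(s))
  for (i in seq_len(nrow(s))) {
    tok[i] <- switch(s$kind[i],
      bracketed = paste0("[", s$motif[i], "]", s$copies[i]),
      counted = s$seq[i],
      uncounted = tolower(s$seq[i]),
      residual = s$seq[i]
    )
  }
  paste(tok, collapse = " ")
}

#' @export
print.str_decomposition <- function(x, ...) {
  cat("<STR decomposition>", format(x),
      sprintf("(%d residual bases)\n", x$residual_bases))
  invisible(x)
}

#' Derive the CE-compatible allele designation of a decomposition
#'
#' Counts every base that falls inside the repeat region, matching how CE
#' sizes alleles: each bracketed (or re-labelled) motif copy contributes
#' one full repeat; each counted tract contributes `floor(len/period)`
#' full repeats plus `len %% period` leftover bases; residual bases are
#' leftover in full. Pooled leftover bases carry into the full-repeat
#' count in units of the reference period, the remainder becoming the
#' partial (decimal) part. Uncounted (lower-case) tracts contribute
#' nothing.
#'
#' @param decomp An `str_decomposition` produced against `structure`.
#' @param structure The `str_structure` used for the decomposition.
#' @return An `str_designation`.
#' @export
designate <- function(decomp, structure) {
  if (!inherits(decomp, "str_decomposition") || !inherits(structure, "str_structure")) {
    stop("designate() expects an str_decomposition and its str_structure")
  }
  s <- decomp$segments
  period <- structure$period
  kind <- s$kind
  len <- nchar(s$seq)
  full <- sum(s$copies[kind == "bracketed"]) +
    sum(len[kind == "counted"] %/% period)
  leftover <- sum(len[kind == "counted"] %% period) +
    sum(len[kind == "residual"])
  full <- full + leftover %/% period
  new_designation(full, leftover %% period)
}

#' Expand an allele designation into a canonical region sequence
#'
#' The canonical inverse of decompose-and-designate, used by the read
#' simulator. All full repeat copies are assigned to the last bracketed
#' element of the structure; partial bases are appended as a prefix of the
#' reference (first bracketed) motif. Any designation with a non-negative
#' full-repeat count and a partial-base count below the period is
#' feasible under this convention.
#'
#' @param designation An `str_designation`, or a string such as `"9.3"`.
#' @param structure An `str_structure`.
#' @return A region sequence string whose decompose/designate round trip
#'   reproduces `designation`.
#' @examples
#' s <- parse_structure("[TTCC]n")
#' expand_designation("2.2", s)   # "TTCCTTCCTT"
#' @export
expand_designation <- function(designation, structure) {
  stopifnot(inherits(structure, "str_structure"))
  d <- as_designation(designation)
  if (d$partial >= structure$period) {
    stop(sprintf(
      "designation %s infeasible: partial bases must be below the period (%d)",
      format(d), structure$period
    ))
  }
  br <- which(structure$elements$kind == "bracketed")
  last_motif <- structure$elements$motif[br[length(br)]]
  ref_motif <- structure$elements$motif[br[1]]
  paste0(strrep(last_motif, d$full), substr(ref_motif, 1L, d$partial))
}
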