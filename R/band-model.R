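#' Keyl-style band labels and arm reference orders
#'
#' A polytene chromosome arm is read as a linear series of bands labelled by a
#' major number (Keyl region) plus an optional lowercase subband letter run
#' ("3", "17b"). The *reference order* of an arm is the standard band order
#' against which every banding sequence of that arm is written; it is a
#' character vector of band labels sorted lexicographically by
#' (major, subletters).
#'
#' @param labels character vector of band labels, e.g. `c("1a","1b","2","3")`.
#' @return the validated label vector (class `band_ref`).
#' @examples
#' band_ref(c("1", "2", "3a", "3b", "4"))
#' @export
band_ref <- function(labels) {
  if (!is.character(labels) || length(labels) == 0L) {
    kb_validation_error("reference order must be a non-empty character vector")
  }
  parsed <- parse_band_labels(labels)
  if (anyDuplicated(labels)) {
    kb_validation_error(paste0(
      "duplicated band label(s) in reference order: ",
      paste(unique(labels[duplicated(labels)]), collapse = ", ")
    ))
  }
  key <- order(parsed$major, parsed$sub)
  if (!all(key == seq_along(labels))) {
    kb_validation_error(
      "reference order must be sorted by (major number, subband letters)"
    )
  }
  structure(labels, class = "band_ref")
}

# Vectorised parse of band labels into major (integer) and sub (string).
parse_band_labels <- function(labels) {
  m <- regmatches(labels, regexec("^([0-9]+)([a-z]*)$", labels))
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad)) {
    kb_parse_error(paste0(
      "malformed band label(s): ", paste(labels[bad], collapse = ", ")
    ))
  }
  major <- vapply(m, function(x) as.integer(x[2]), 0L)
  if (any(major < 1L)) {
    kb_validation_error("band major numbers must be >= 1")
  }
  sub <- vapply(m, function(x) x[3], "")
  list(major = major, sub = sub)
}

#' Arm banding sequences
#'
#' An `arm_sequence` holds one banding sequence of one chromosome arm of one
#' species: an ordered series of oriented band intervals that partitions the
#' arm's reference band set. Internally the sequence is stored as its *signed
#' expansion*: a signed permutation of the reference ordinals `1..N`, read
#' from the (conventional) distal end, negative entries marking bands lying
#' in inverted segments. "Not mapped" arms (known monomorphic but without a
#' photomap) carry a code and a `NULL` expansion.
#'
#' @param code sequence code, e.g. `"allC1"`: species tag + arm letter +
#'   serial. The arm letter must match `arm`.
#' @param arm arm letter, one of A-G.
#' @param reference [band_ref()] reference order, or `NULL` for unmapped.
#' @param signed integer vector, signed expansion; `NULL` for unmapped arms.
#' @param annotations list of `list(feature=, position=)` records; features
#'   are cytological landmarks (`nucleolus`, `balbiani_ring`, `puff`,
#'   `centromere`).
#' @return object of class `arm_sequence`.
#' @export
arm_sequence <- function(code, arm, reference = NULL, signed = NULL,
                         annotations = list()) {
  if (!is.character(arm) || length(arm) != 1L || !arm %in% LETTERS[1:7]) {
    kb_validation_error("arm must be a single letter A-G")
  }
  if (!is.character(code) || length(code) != 1L || !nzchar(code)) {
    kb_validation_error("sequence code must be a non-empty string")
  }
  if (!grepl(arm, code, fixed = TRUE)) {
    kb_validation_error(sprintf(
      "sequence code '%s' does not contain its arm letter '%s'", code, arm
    ))
  }
  if (!is.null(signed)) {
    if (is.null(reference)) {
      kb_validation_error("a mapped sequence needs a reference order")
    }
    reference <- band_ref(unclass(reference))
    n <- length(reference)
    if (!setequal(abs(signed), seq_len(n)) || length(signed) != n) {
      miss <- setdiff(seq_len(n), abs(signed))
      dup <- unique(abs(signed)[duplicated(abs(signed))])
      kb_validation_error(paste0(
        "expansion is not a permutation of the reference bands",
        if (length(miss)) paste0("; missing: ",
                                 paste(reference[miss], collapse = ", ")),
        if (length(dup)) paste0("; duplicated: ",
                                paste(reference[dup], collapse = ", "))
      ))
    }
    signed <- as.integer(signed)
  }
  structure(
    list(code = code, arm = arm, reference = reference, signed = signed,
         annotations = annotations),
    class = "arm_sequence"
  )
}

is_mapped <- function(seq) !is.null(seq$signed)

# The signed expansion is kept exact; Keyl text is a lossy projection of it.
# A lone inverted band between two breakpoints is cytologically invisible
# (no subband order to read its direction from), so a singleton run prints
# as an unsigned label and a parsed singleton token is always forward.
# Consequently parse(format(s)) == s exactly when s has no hidden singleton
# inversions — true of everything born from text — and parse o format is an
# idempotent projection for all sequences.

# The same physical arm read from the opposite end: reverse the expansion
# and flip every orientation.
flip_arm <- function(seq) {
  out <- seq
  out$signed <- rev(-seq$signed)
  out
}

# Decompose a signed expansion into maximal monotone runs:
# ascending runs of positives and descending runs of negatives.
signed_runs <- function(signed) {
  n <- length(signed)
  from <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    if (signed[i] > 0L) {
      while (j < n && signed[j + 1L] == signed[j] + 1L && signed[j] > 0L) {
        j <- j + 1L
      }
    } else {
      while (j < n && signed[j + 1L] == signed[j] + 1L && signed[j + 1L] < 0L) {
        j <- j + 1L
      }
    }
    from <- c(from, i)
    i <- j + 1L
  }
  to <- c(from[-1L] - 1L, n)
  data.frame(from = from, to = to, len = to - from + 1L)
}

#' Parse a Keyl-notation banding formula
#'
#' Formulas are whitespace-separated interval tokens `X` or `X-Y` over band
#' labels (`"1-7 15-12 8-11 16-19"`). A descending token (`15-12`) denotes an
#' inverted segment; a single-band token is always forward. The intervals
#' must cover the reference order exactly once.
#'
#' @param text formula string.
#' @param arm arm letter A-G.
#' @param reference [band_ref()] giving the arm's reference band order.
#' @param code sequence code; defaults to a placeholder built from `arm`.
#' @param annotations optional annotation list, stored as-is.
#' @return an [arm_sequence()].
#' @examples
#' ref <- band_ref(as.character(1:19))
#' parse_band_sequence("1-7 15-12 8-11 16-19", "A", ref, code = "exA1")
#' @export
parse_band_sequence <- function(text, arm, reference, code = NULL,
                                annotations = list()) {
  if (!is.character(text) || length(text) != 1L) {
    kb_parse_error("formula must be a single string")
  }
  reference <- band_ref(unclass(reference))
  code <- code %||% paste0("seq", arm, "1")
  tokens <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  if (length(tokens) == 0L || !nzchar(tokens[1])) {
    kb_parse_error("empty formula")
  }
  ord <- function(label, tok_index) {
    i <- match(label, reference)
    if (is.na(i)) {
      kb_validation_error(sprintf(
        "unknown band '%s' in token %d ('%s')", label, tok_index,
        tokens[tok_index]
      ))
    }
    i
  }
  signed <- integer(0)
  for (t in seq_along(tokens)) {
    m <- regmatches(tokens[t],
                    regexec("^([0-9]+[a-z]*)(-([0-9]+[a-z]*))?$", tokens[t]))[[1]]
    if (length(m) == 0L) {
      kb_parse_error(sprintf("malformed token %d: '%s'", t, tokens[t]))
    }
    a <- ord(m[2], t)
    b <- if (nzchar(m[4])) ord(m[4], t) else a
    signed <- c(signed, if (a <= b) a:b else -(a:b))
  }
  cover <- abs(signed)
  if (anyDuplicated(cover)) {
    dup <- unique(cover[duplicated(cover)])
    kb_validation_error(paste0(
      "band(s) covered more than once: ",
      paste(reference[dup], collapse = ", ")
    ))
  }
  if (length(cover) != length(reference)) {
    miss <- setdiff(seq_along(reference), cover)
    kb_validation_error(paste0(
      "gap: band(s) not covered: ", paste(reference[miss], collapse = ", ")
    ))
  }
  arm_sequence(code, arm, reference, signed, annotations)
}

#' Format an arm sequence back to Keyl notation
#'
#' Produces the maximal-interval formula: adjacent co-oriented bands are
#' merged, inverted runs print as descending tokens. `parse_band_sequence()`
#' of the result reproduces the sequence exactly.
#'
#' @param seq an [arm_sequence()]; must be mapped.
#' @return formula string.
#' @export
format_band_sequence <- function(seq) {
  stopifnot(inherits(seq, "arm_sequence"))
  if (!is_mapped(seq)) {
    kb_validation_error(sprintf("sequence '%s' is not mapped", seq$code))
  }
  runs <- signed_runs(seq$signed)
  ref <- seq$reference
  tokens <- character(nrow(runs))
  for (r in seq_len(nrow(runs))) {
    a <- abs(seq$signed[runs$from[r]])
    b <- abs(seq$signed[runs$to[r]])
    tokens[r] <- if (a == b) ref[a] else paste0(ref[a], "-", ref[b])
  }
  paste(tokens, collapse = " ")
}

#' Canonical reading direction of an arm
#'
#' Photomap orientation of a whole arm is a convention, not a rearrangement:
#' a sequence read end-to-end in reverse (reverse the expansion and flip all
#' orientations) describes the same chromosome. The canonical representative
#' is the reading whose first band has the smaller reference ordinal (ties
#' broken toward forward orientation). Comparisons additionally minimize
#' over the relative flip (see [arm_distance()]), so a whole-arm flip never
#' costs an inversion step.
#'
#' @param seq an [arm_sequence()].
#' @return the canonical [arm_sequence()].
#' @export
canonical_direction <- function(seq) {
  stopifnot(inherits(seq, "arm_sequence"))
  if (!is_mapped(seq)) return(seq)
  s <- seq$signed
  flipped <- rev(-s)
  keep <-
    if (abs(s[1]) != abs(flipped[1])) abs(s[1]) < abs(flipped[1])
    else s[1] > 0  # single-band arm or palindromic head: prefer forward
  out <- seq
  out$signed <- if (keep) s else flipped
  out
}

#' @export
print.arm_sequence <- function(x, ...) {
  cat(sprintf("<arm_sequence> %s (arm %s): %s\n", x$code, x$arm,
              if (is_mapped(x)) format_band_sequence(x)
              else "not mapped"))
  invisible(x)
}

#' @export
format.arm_sequence <- function(x, ...) {
  if (is_mapped(x)) format_band_sequence(x) else NA_character_
}

# Identity of canonical formulas; the distance-0 predicate of the band model.
same_sequence <- function(a, b) {
  if (!is_mapped(a) || !is_mapped(b)) return(FALSE)
  if (!identical(unclass(a$reference), unclass(b$reference))) return(FALSE)
  identical(canonical_direction(a)$signed, canonical_direction(b)$signed)
}
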