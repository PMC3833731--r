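#' Reduce two arm sequences to common oriented blocks
#'
#' Two banding sequences over the same band set are cut at every breakpoint
#' present in either sequence; the pieces are the maximal segments read
#' identically (up to joint inversion) in both. These common blocks, not raw
#' bands, are the elements of the signed permutation handed to the distance
#' engine, which keeps permutations short and makes distances invariant to
#' subband granularity. Both inputs are put into canonical reading direction
#' first, so a whole-arm flip of the photomap never produces spurious blocks.
#'
#' @param a,b mapped [arm_sequence()] objects over identical references.
#' @return data.frame with one row per block: `id` (order in `a`),
#'   `bands` (labels in `a`'s reading order, collapsed with `,`),
#'   `orientation_in_a` (always `"forward"`: the block is recorded as read in
#'   `a`), `orientation_in_b` (orientation in `b` relative to `a`).
#' @export
refine_to_blocks <- function(a, b) {
  block_table(block_partition(a, b))
}

block_table <- function(pp) {
  data.frame(
    id = seq_along(pp$starts_a),
    bands = vapply(seq_along(pp$starts_a), function(i) {
      idx <- pp$starts_a[i]:pp$ends_a[i]
      paste(unclass(pp$a$reference)[abs(pp$a$signed[idx])], collapse = ",")
    }, ""),
    orientation_in_a = "forward",
    orientation_in_b = ifelse(pp$rel[pp$starts_a] > 0, "forward", "inverted")
  )
}

# Shared core: canonicalize, check comparability, locate block boundaries.
block_partition <- function(a, b, canonicalize = TRUE) {
  stopifnot(inherits(a, "arm_sequence"), inherits(b, "arm_sequence"))
  if (!is_mapped(a) || !is_mapped(b)) {
    kb_validation_error("both sequences must be mapped to compare them")
  }
  ra <- unclass(a$reference)
  rb <- unclass(b$reference)
  if (!identical(ra, rb)) {
    only_a <- setdiff(ra, rb)
    only_b <- setdiff(rb, ra)
    kb_validation_error(paste0(
      "incomparable arms: band sets differ",
      if (length(only_a)) paste0("; only in ", a$code, ": ",
                                 paste(only_a, collapse = ", ")),
      if (length(only_b)) paste0("; only in ", b$code, ": ",
                                 paste(only_b, collapse = ", ")),
      if (!length(only_a) && !length(only_b))
        " (same labels, different order)"
    ))
  }
  if (canonicalize) {
    a <- canonical_direction(a)
    b <- canonical_direction(b)
  }
  sa <- a$signed
  sb <- b$signed
  n <- length(sa)
  pos_b <- integer(n)   # position of each band in b
  sgn_b <- integer(n)   # sign of each band in b
  pos_b[abs(sb)] <- seq_len(n)
  sgn_b[abs(sb)] <- sign(sb)
  # relative orientation of band at a-position i
  rel <- sgn_b[abs(sa)] * sign(sa)
  qb <- pos_b[abs(sa)]
  # cut between a-positions i, i+1 unless the signed adjacency carries over
  if (n > 1L) {
    i <- seq_len(n - 1L)
    joined <- rel[i + 1L] == rel[i] & qb[i + 1L] == qb[i] + rel[i]
    starts_a <- c(1L, which(!joined) + 1L)
  } else {
    starts_a <- 1L
  }
  ends_a <- c(starts_a[-1L] - 1L, n)
  list(a = a, b = b, starts_a = starts_a, ends_a = ends_a,
       rel = rel, qb = qb)
}

#' Signed block permutation of one sequence relative to another
#'
#' Blocks are numbered `1..m` by their order in `a`; the result lists the
#' blocks in `b`'s reading order, a negative sign marking blocks that `b`
#' carries inverted relative to `a`. Identical (canonical) sequences give the
#' identity permutation of length 1.
#'
#' @inheritParams refine_to_blocks
#' @return a `signed_permutation`: integer vector whose absolute values are a
#'   permutation of `1..m`.
#' @export
to_signed_permutation <- function(a, b) {
  signed_perm_from_partition(block_partition(a, b))
}

signed_perm_from_partition <- function(pp) {
  m <- length(pp$starts_a)
  # block id of each a-position
  block_of <- rep.int(seq_len(m), pp$ends_a - pp$starts_a + 1L)
  # leftmost b-position of each block (block occupies a contiguous b-run)
  first_b <- vapply(seq_len(m), function(i) {
    min(pp$qb[pp$starts_a[i]:pp$ends_a[i]])
  }, 0L)
  sign_b <- pp$rel[pp$starts_a]
  ord <- order(first_b)
  signed_permutation(sign_b[ord] * seq_len(m)[ord])
}

#' Signed permutations
#'
#' @param x integer vector with `abs(x)` a permutation of `1..n`.
#' @return validated `signed_permutation`.
#' @export
signed_permutation <- function(x) {
  x <- as.integer(x)
  n <- length(x)
  if (n == 0L || any(x == 0L) || !setequal(abs(x), seq_len(n))) {
    kb_validation_error(
      "elements must be nonzero and their absolute values a permutation of 1..n"
    )
  }
  structure(x, class = "signed_permutation")
}

#' @export
print.signed_permutation <- function(x, ...) {
  cat("<signed_permutation> (",
      paste(ifelse(unclass(x) > 0, paste0("+", unclass(x)), unclass(x)),
            collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# Apply b's block permutation to a's block list; used by tests to confirm
# the permutation reconstructs b.
apply_block_permutation <- function(a, b) {
  pp <- block_partition(a, b)
  p <- to_signed_permutation(a, b)
  pieces <- lapply(seq_along(pp$starts_a), function(i) {
    pp$a$signed[pp$starts_a[i]:pp$ends_a[i]]
  })
  out <- integer(0)
  for (e in unclass(p)) {
    out <- c(out, if (e > 0) pieces[[e]] else rev(-pieces[[abs(e)]]))
  }
  out
}

# TSV debug dump of the block table.
write_block_tsv <- function(a, b, path = "") {
  tab <- refine_to_blocks(a, b)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
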