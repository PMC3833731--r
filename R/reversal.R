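#' Exact inversion-step distance for signed permutations
#'
#' The minimal number of reversals (paracentric inversion steps) sorting a
#' signed permutation is computed by the classical breakpoint-graph formula
#' `d = (n + 1) - cycles + hurdles + fortress`, evaluated on the permutation
#' framed by virtual end markers `0` and `n + 1` (telomere and centromere, so
#' terminal reversals are counted correctly). An optimal scenario is
#' reconstructed greedily: at every step the lexicographically smallest
#' reversal interval that lowers the distance by one is applied, which makes
#' scenarios deterministic.
#'
#' @param p a [signed_permutation()] (or plain integer vector).
#' @param scenario if `TRUE` (default) also reconstruct one optimal reversal
#'   scenario; quadratic in `n` per step, so disable for very long
#'   permutations when only the distance is needed.
#' @return object of class `distance_result`: list with `distance`,
#'   `breakpoints`, `cycles`, `hurdles`, `fortress` and `scenario` (a
#'   data.frame of 1-based inclusive reversal intervals `(i, j)`).
#' @examples
#' signed_reversal_distance(signed_permutation(c(1, -3, -2, 4)))
#' @export
signed_reversal_distance <- function(p, scenario = TRUE) {
  p <- as_signed_perm(p)
  st <- bg_stats(p)
  steps <- if (scenario) greedy_scenario(p, st$distance) else NULL
  structure(
    list(distance = st$distance, breakpoints = st$breakpoints,
         cycles = st$cycles, hurdles = st$hurdles, fortress = st$fortress,
         scenario = steps),
    class = "distance_result"
  )
}

as_signed_perm <- function(p) {
  if (inherits(p, "signed_permutation")) as.integer(unclass(p))
  else as.integer(unclass(signed_permutation(p)))
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf(
    "<distance_result> distance=%d (breakpoints=%d cycles=%d hurdles=%d fortress=%d)\n",
    x$distance, x$breakpoints, x$cycles, x$hurdles, x$fortress))
  if (!is.null(x$scenario) && nrow(x$scenario)) {
    cat("  scenario:",
        paste(sprintf("(%d,%d)", x$scenario$i, x$scenario$j), collapse = " "),
        "\n")
  }
  invisible(x)
}

# Breakpoint-graph statistics of a signed permutation.
#
# The permutation is doubled into 2n+2 unsigned points (x -> 2x-1,2x when
# forward; 2|x|,2|x|-1 when inverted) framed by 0 and 2n+1. Black edges join
# point positions (2t, 2t+1), gray edges join values (2k, 2k+1); both
# pairings are "xor 1" in 0-based coordinates. Cycles alternate black/gray.
# A gray edge at positions i < j is oriented iff i + j is even; a cycle is
# oriented iff it has an oriented gray edge. Components join cycles whose
# gray edges interleave; unoriented non-trivial components whose endpoints
# form one contiguous run in the circular scan of all unoriented-component
# endpoints are hurdles. A fortress adds 1 when the hurdle count is odd and
# every hurdle protects another unoriented component (superhurdle).
bg_stats <- function(p) {
  n <- length(p)
  v <- integer(2L * n + 2L)
  v[1L] <- 0L
  v[2L * n + 2L] <- 2L * n + 1L
  pos_i <- seq_len(n)
  v[2L * pos_i] <- ifelse(p > 0L, 2L * p - 1L, -2L * p)
  v[2L * pos_i + 1L] <- ifelse(p > 0L, 2L * p, -2L * p - 1L)

  pos <- integer(2L * n + 2L)         # 0-based position of each value
  pos[v + 1L] <- 0:(2L * n + 1L)

  # breakpoints of the framed permutation
  e <- c(0L, p, n + 1L)
  breakpoints <- sum(e[-1L] != e[-length(e)] + 1L)

  # gray edge k joins values 2k and 2k+1 (k = 0..n)
  g1 <- pos[2L * (0:n) + 1L]
  g2 <- pos[2L * (0:n) + 2L]
  lo <- pmin(g1, g2)
  hi <- pmax(g1, g2)
  edge_oriented <- ((g1 + g2) %% 2L) == 0L

  # trace alternating cycles; label each gray edge with its cycle
  gray_of_pos <- integer(2L * n + 2L)  # gray edge index by 0-based position
  gray_of_pos[c(g1, g2) + 1L] <- c(0:n, 0:n) + 1L
  cyc_of_edge <- integer(n + 1L)
  visited <- logical(2L * n + 2L)
  cycles <- 0L
  for (start in 0:(2L * n + 1L)) {
    if (visited[start + 1L]) next
    cycles <- cycles + 1L
    q <- start
    repeat {
      visited[q + 1L] <- TRUE
      qb <- bitwXor(q, 1L)            # black partner
      visited[qb + 1L] <- TRUE
      wg <- bitwXor(v[qb + 1L], 1L)   # gray partner value
      qg <- pos[wg + 1L]
      cyc_of_edge[gray_of_pos[qg + 1L]] <- cycles
      q <- qg
      if (q == start) break
    }
  }

  cyc_oriented <- as.logical(tapply(edge_oriented, cyc_of_edge, any))
  cyc_trivial <- as.logical(tapply(hi == lo + 1L, cyc_of_edge, all))

  # components: union cycles sharing a cycle id or with interleaving edges
  parent <- seq_len(cycles)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  m <- n + 1L
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if ((lo[i] < lo[j] & lo[j] < hi[i] & hi[i] < hi[j]) ||
            (lo[j] < lo[i] & lo[i] < hi[j] & hi[j] < hi[i])) {
          ri <- find(cyc_of_edge[i])
          rj <- find(cyc_of_edge[j])
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  comp_of_cycle <- vapply(seq_len(cycles), find, 0L)
  comp_ids <- unique(comp_of_cycle)
  comp_unoriented <- vapply(comp_ids, function(cp) {
    members <- which(comp_of_cycle == cp)
    all(!cyc_oriented[members]) && !all(cyc_trivial[members])
  }, TRUE)
  uc <- comp_ids[comp_unoriented]

  hres <- hurdle_analysis(uc, comp_of_cycle, cyc_of_edge, lo, hi)

  distance <- (n + 1L) - cycles + hres$hurdles + hres$fortress
  list(distance = distance, breakpoints = breakpoints, cycles = cycles,
       hurdles = hres$hurdles, fortress = hres$fortress)
}

# Hurdles and fortress from the circular scan of unoriented-component
# endpoints. `uc` holds the component ids of unoriented non-trivial
# components.
hurdle_analysis <- function(uc, comp_of_cycle, cyc_of_edge, lo, hi) {
  if (length(uc) == 0L) return(list(hurdles = 0L, fortress = 0L))
  comp_of_edge <- comp_of_cycle[cyc_of_edge]
  keep <- comp_of_edge %in% uc
  ends <- c(lo[keep], hi[keep])
  labels <- rep.int(comp_of_edge[keep], 2L)
  labels <- labels[order(ends)]

  hurdles_in <- function(labs) {
    present <- unique(labs)
    if (length(present) == 1L) return(present)
    present[vapply(present, function(cp) {
      idx <- which(labs == cp)
      gaps <- diff(idx)
      wrap <- idx[1L] + length(labs) - idx[length(idx)]
      sum(c(gaps, wrap) != 1L) <= 1L
    }, TRUE)]
  }

  hs <- hurdles_in(labels)
  n_h <- length(hs)
  fortress <- 0L
  if (n_h %% 2L == 1L && n_h >= 3L) {
    super <- vapply(hs, function(h) {
      rest <- labels[labels != h]
      if (length(rest) == 0L) return(FALSE)
      new_h <- hurdles_in(rest)
      length(setdiff(new_h, hs)) > 0L
    }, TRUE)
    if (all(super)) fortress <- 1L
  }
  list(hurdles = n_h, fortress = fortress)
}

# Reversal of the inclusive interval [i, j] of a signed vector.
reverse_segment <- function(p, i, j) {
  p[i:j] <- -rev(p[i:j])
  p
}

# Deterministic optimal scenario: repeatedly apply the lexicographically
# smallest (i, j) whose reversal decreases the distance. A distance-reducing
# reversal always exists for a non-sorted permutation.
greedy_scenario <- function(p, d) {
  steps_i <- integer(0)
  steps_j <- integer(0)
  n <- length(p)
  while (d > 0L) {
    found <- FALSE
    for (i in seq_len(n)) {
      for (j in i:n) {
        q <- reverse_segment(p, i, j)
        if (bg_stats(q)$distance == d - 1L) {
          steps_i <- c(steps_i, i)
          steps_j <- c(steps_j, j)
          p <- q
          d <- d - 1L
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) stop("internal error: no distance-reducing reversal found")
  }
  data.frame(i = steps_i, j = steps_j)
}

#' Brute-force distance oracle (breadth-first search)
#'
#' Independent check of the breakpoint-graph distance: exact distance by
#' breadth-first search over all reversal moves, feasible for `n <= 8`
#' (`2^n * n!` states). Tables are computed once per `n` (in compiled code)
#' and cached for the session.
#'
#' @param p a [signed_permutation()] with at most `max_n` elements.
#' @param max_n refusal threshold, at most 8.
#' @return exact integer distance.
#' @export
bfs_oracle_distance <- function(p, max_n = 8L) {
  p <- as_signed_perm(p)
  n <- length(p)
  if (max_n > 8L) kb_validation_error("max_n must be <= 8")
  if (n > max_n) {
    kb_validation_error(sprintf(
      "n = %d exceeds the oracle's limit (%d): state space too large", n, max_n
    ))
  }
  tab <- oracle_table(n)
  tab[oracle_state_index(p) + 1L]
}

oracle_cache <- new.env(parent = emptyenv())

oracle_table <- function(n) {
  key <- as.character(n)
  if (is.null(oracle_cache[[key]])) {
    oracle_cache[[key]] <- bfs_distance_table_cpp(n)
  }
  oracle_cache[[key]]
}

# Mixed-radix state index: Lehmer rank of |p| times 2^n plus sign bits;
# must mirror the encoding in the compiled BFS.
oracle_state_index <- function(p) {
  n <- length(p)
  a <- abs(p)
  rank <- 0
  for (i in seq_len(n)) {
    smaller <- sum(a[-seq_len(i)] < a[i])
    rank <- rank * (n - i + 1) + smaller
  }
  bits <- sum(as.double(2^(seq_len(n) - 1)) * (p < 0))
  rank * 2^n + bits
}

#' Distance bounds
#'
#' `breakpoint_lower_bound()` is `ceiling(breakpoints / 2)` (a reversal can
#' heal at most two breakpoints); `trivial_upper_bound()` is `n + 1`. The
#' exact distance always lies between the two.
#'
#' @inheritParams signed_reversal_distance
#' @return integer bound.
#' @export
breakpoint_lower_bound <- function(p) {
  p <- as_signed_perm(p)
  e <- c(0L, p, length(p) + 1L)
  as.integer(ceiling(sum(e[-1L] != e[-length(e)] + 1L) / 2))
}

#' @rdname breakpoint_lower_bound
#' @export
trivial_upper_bound <- function(p) length(as_signed_perm(p)) + 1L

#' Inversion-step distance between two arm sequences
#'
#' Composition of block refinement and the signed reversal distance: the
#' minimal number of paracentric inversions converting one banding sequence
#' into the other. Because the end-to-end reading direction of a photomap is
#' a convention, the distance is minimized over the relative whole-arm flip
#' of one input, so a flip costs nothing. Symmetric, zero iff the canonical
#' formulas are identical.
#'
#' @inheritParams refine_to_blocks
#' @param scenario reconstruct an optimal reversal scenario over blocks?
#' @return a `distance_result` (see [signed_reversal_distance()]); the
#'   scenario intervals index block positions, and the block table of the
#'   chosen orientation is attached as attribute `"blocks"`.
#' @export
arm_distance <- function(a, b, scenario = FALSE) {
  pp1 <- block_partition(a, b, canonicalize = FALSE)
  p1 <- signed_perm_from_partition(pp1)
  r1 <- signed_reversal_distance(p1, scenario = FALSE)
  b2 <- flip_arm(b)
  pp2 <- block_partition(a, b2, canonicalize = FALSE)
  p2 <- signed_perm_from_partition(pp2)
  r2 <- signed_reversal_distance(p2, scenario = FALSE)
  use_flip <- r2$distance < r1$distance
  res <- if (scenario) {
    signed_reversal_distance(if (use_flip) p2 else p1, scenario = TRUE)
  } else if (use_flip) r2 else r1
  attr(res, "blocks") <- block_table(if (use_flip) pp2 else pp1)
  res
}
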