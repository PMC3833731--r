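#' Inversion-step distance matrix over a set of arm sequences
#'
#' Pairwise minimal inversion-step distances between banding sequences of
#' one arm (networks are always per-arm; sequences of different arms are
#' never concatenated). The result is a symmetric integer matrix with zero
#' diagonal; the triangle inequality is checked and a warning raised on
#' violation (impossible for true reversal distances, kept as a guard for
#' user-edited matrices).
#'
#' @param seqs list of mapped [arm_sequence()] objects, all of the same arm
#'   and pairwise comparable.
#' @return symmetric integer matrix with sequence codes as dimnames.
#' @export
distance_matrix <- function(seqs) {
  if (length(seqs) == 0L) kb_validation_error("need at least one sequence")
  arms <- vapply(seqs, function(s) s$arm, "")
  if (length(unique(arms)) != 1L) {
    kb_validation_error(paste0(
      "all sequences must be of the same arm; got: ",
      paste(unique(arms), collapse = ", ")
    ))
  }
  labels <- vapply(seqs, function(s) s$code, "")
  n <- length(seqs)
  m <- matrix(0L, n, n, dimnames = list(labels, labels))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- tryCatch(
          arm_distance(seqs[[i]], seqs[[j]])$distance,
          kb_error = function(e) {
            kb_validation_error(sprintf(
              "incomparable pair (%s, %s): %s", labels[i], labels[j],
              conditionMessage(e)
            ))
          }
        )
        m[i, j] <- d
        m[j, i] <- d
      }
    }
  }
  check_triangle(m)
  m
}

check_triangle <- function(m) {
  n <- nrow(m)
  if (n < 3L) return(invisible(TRUE))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (any(m[i, j] > m[i, ] + m[, j])) {
        warning(sprintf("triangle inequality violated at (%s, %s)",
                        rownames(m)[i], colnames(m)[j]))
        return(invisible(FALSE))
      }
    }
  }
  invisible(TRUE)
}

#' Minimal-step network (minimum spanning tree)
#'
#' Star-like relation diagrams connecting observed and basic sequences by
#' minimal total inversion steps. Kruskal's algorithm with a deterministic
#' tie-break: edges are taken in order of (weight, from-label, to-label),
#' labels within an edge sorted alphabetically. Hypothetical intermediate
#' sequences are never inferred; only the supplied sequences are nodes.
#'
#' @param m distance matrix from [distance_matrix()].
#' @return data.frame of MST edges: `from`, `to`, `weight`.
#' @export
mst_network <- function(m) {
  labels <- rownames(m)
  n <- length(labels)
  if (n < 2L) kb_validation_error("need at least two labels for a network")
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  from <- pmin(labels[pairs[, 1L]], labels[pairs[, 2L]])
  to <- pmax(labels[pairs[, 1L]], labels[pairs[, 2L]])
  w <- m[pairs]
  ord <- order(w, from, to)
  parent <- stats::setNames(seq_len(n), labels)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- logical(length(ord))
  taken <- 0L
  for (e in ord) {
    ri <- find(match(from[e], labels))
    rj <- find(match(to[e], labels))
    if (ri != rj) {
      parent[ri] <- rj
      keep[e] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  edges <- data.frame(from = from[keep], to = to[keep], weight = w[keep])
  edges[order(edges$weight, edges$from, edges$to), , drop = FALSE]
}

#' Neighbor-joining tree from an inversion-step matrix
#'
#' Standard neighbor joining (via \pkg{ape}); an additive input matrix is
#' recovered exactly (path lengths on the tree reproduce the matrix).
#'
#' @param m distance matrix with at least 3 labels.
#' @return list with `tree` (an \pkg{ape} `phylo`) and `newick` (string with
#'   branch lengths).
#' @export
nj_tree <- function(m) {
  if (nrow(m) < 3L) {
    kb_validation_error("neighbor joining needs at least 3 labels")
  }
  tree <- ape::nj(m)
  list(tree = tree, newick = ape::write.tree(tree))
}

#' Exporters: PHYLIP matrix, Newick tree, DOT network
#'
#' `write_phylip()` writes the square PHYLIP distance-matrix format;
#' `write_newick()` writes a Newick string (or `phylo`); `write_dot()`
#' renders an MST edge list as an undirected Graphviz graph with step
#' counts as edge labels.
#'
#' @param m distance matrix.
#' @param path output path.
#' @param header optional `#`-prefixed comment lines (DOT uses `//`).
#' @return the path, invisibly.
#' @export
write_phylip <- function(m, path) {
  labels <- rownames(m)
  lines <- c(sprintf("%5d", nrow(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste0(formatC(labels[i], width = -10),
                      paste(sprintf("%6d", m[i, ]), collapse = ""))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip
#' @param tree `phylo` object, or the list returned by [nj_tree()].
#' @export
write_newick <- function(tree, path) {
  if (is.list(tree) && !inherits(tree, "phylo")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_phylip
#' @param edges MST edge list from [mst_network()].
#' @param name graph name.
#' @export
write_dot <- function(edges, path, name = "steps", header = character(0)) {
  lines <- c(
    if (length(header)) paste0("// ", header),
    sprintf("graph %s {", name),
    "  node [shape=ellipse];",
    sprintf('  "%s" -- "%s" [label="%d"];', edges$from, edges$to,
            edges$weight),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}
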