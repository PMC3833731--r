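#' Canonical form of a whole-arm combination
#'
#' Arm letters within a group are sorted alphabetically and groups are sorted
#' by their first arm, so `"EA DC FB G"` and `"AE CD BF G"` canonicalize to
#' the same string. The canonical string is the identity used by the
#' cytocomplex registry and the translocation-distance search.
#'
#' @param combination combination string or list of arm-letter vectors.
#' @return canonical combination string.
#' @examples
#' canonicalize_combination("EA DC FB G")
#' @export
canonicalize_combination <- function(combination) {
  groups <- if (is.character(combination) && length(combination) == 1L) {
    parse_combination(combination)
  } else {
    lapply(combination, as.character)
  }
  arms <- unlist(groups)
  missing <- setdiff(ARM_LETTERS, arms)
  dup <- unique(arms[duplicated(arms)])
  extra <- setdiff(arms, ARM_LETTERS)
  if (length(missing) || length(dup) || length(extra)) {
    kb_validation_error(paste0(
      "invalid arm combination",
      if (length(missing)) paste0("; missing: ",
                                  paste(missing, collapse = ", ")),
      if (length(dup)) paste0("; duplicated: ", paste(dup, collapse = ", ")),
      if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", "))
    ))
  }
  sorted <- lapply(groups, function(g) paste(sort(g), collapse = ""))
  paste(sort(unlist(sorted)), collapse = " ")
}

#' Cytocomplex reference registry
#'
#' Chironomus species fall into cytocomplexes by which arms are fused into
#' which chromosomes (products of whole-arm translocations). The registry
#' maps canonical combinations to complex names; it is data-driven (JSON) so
#' further complexes can be added without code changes. The shipped registry
#' holds pseudothummi (`AE CD BF G`), thummi (`AB CD EF G`) and parathummi
#' (`AC BF DE G`); fused variants such as `AB CD FEG` are recognized by
#' splitting, not stored.
#'
#' @param path registry JSON (array of `{"name", "combination"}`); default
#'   the shipped file.
#' @return data.frame with `name` and canonical `combination`.
#' @export
read_cytocomplex_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cytocomplexes.json",
                                package = "karyoband")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  data.frame(
    name = vapply(raw, function(x) x$name, ""),
    combination = vapply(raw, function(x) canonicalize_combination(x$combination), "")
  )
}

#' Classify a whole-arm combination into a cytocomplex
#'
#' The canonical form is looked up in the registry. If it is absent and the
#' input has fewer groups than a registered complex, every way of splitting
#' one group into two is tried; a split that reproduces a registered
#' combination identifies the input as a fused ("modified") variant of that
#' complex, with the reduced haploid number reported. Unknown combinations
#' return `name = "unrecognized"` rather than an error.
#'
#' @param combination combination string or group list.
#' @param registry registry table from [read_cytocomplex_registry()].
#' @return `cytocomplex_call`: list with `name` (e.g. `"modified thummi"`),
#'   `base` (registered name or `NA`), `modified` flag, `matched_reference`
#'   (canonical registered combination or `NA`) and `haploid_n`.
#' @examples
#' classify_cytocomplex("AE CD BF G")
#' classify_cytocomplex("AB CD FEG")
#' @export
classify_cytocomplex <- function(combination,
                                 registry = read_cytocomplex_registry()) {
  canon <- canonicalize_combination(combination)
  groups <- parse_combination(canon)
  n <- length(groups)
  call_obj <- function(name, base, modified, ref) {
    structure(list(name = name, base = base, modified = modified,
                   matched_reference = ref, haploid_n = n),
              class = "cytocomplex_call")
  }
  hit <- match(canon, registry$combination)
  if (!is.na(hit)) {
    return(call_obj(registry$name[hit], registry$name[hit], FALSE,
                    registry$combination[hit]))
  }
  # try splitting one fused group into two
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    if (length(g) < 2L) next
    for (mask in seq_len(2^length(g) - 2L)) {
      part1 <- g[bitwAnd(mask, 2^(seq_along(g) - 1L)) > 0L]
      if (length(part1) == 0L || length(part1) == length(g)) next
      part2 <- setdiff(g, part1)
      split_groups <- c(groups[-gi], list(part1), list(part2))
      split_canon <- canonicalize_combination(split_groups)
      hit <- match(split_canon, registry$combination)
      if (!is.na(hit)) {
        return(call_obj(paste("modified", registry$name[hit]),
                        registry$name[hit], TRUE, registry$combination[hit]))
      }
    }
  }
  call_obj("unrecognized", NA_character_, FALSE, NA_character_)
}

#' @export
print.cytocomplex_call <- function(x, ...) {
  cat(sprintf("<cytocomplex_call> %s (n=%d%s)\n", x$name, x$haploid_n,
              if (!is.na(x$matched_reference))
                paste0(", reference ", x$matched_reference) else ""))
  invisible(x)
}

#' Haploid chromosome number of a combination
#'
#' The haploid number is the number of arm groups (linkage groups).
#'
#' @inheritParams canonicalize_combination
#' @return integer.
#' @examples
#' haploid_number("AE CD BF G")   # 4
#' haploid_number("AB CD FEG")    # 3
#' @export
haploid_number <- function(combination) {
  canonicalize_combination(combination)  # validates
  groups <- if (is.character(combination) && length(combination) == 1L) {
    parse_combination(combination)
  } else {
    combination
  }
  length(groups)
}

#' Whole-arm rearrangement distance between combinations
#'
#' Minimal number of moves transforming one whole-arm combination into
#' another, where a move is a whole-arm translocation (repartition the arms
#' of two chromosomes into two new chromosomes), a fusion (merge two
#' chromosomes) or a fission (split one chromosome), each costing 1.
#' Computed exactly by breadth-first search over the partition lattice of
#' the seven arms (877 states).
#'
#' @param c1,c2 combination strings or group lists.
#' @return integer distance.
#' @examples
#' translocation_distance("AE CD BF G", "AB CD EF G")  # one E/B exchange
#' @export
translocation_distance <- function(c1, c2) {
  start <- canonicalize_combination(c1)
  goal <- canonicalize_combination(c2)
  if (start == goal) return(0L)
  dist <- new.env(parent = emptyenv())
  assign(start, 0L, envir = dist)
  frontier <- start
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- character(0)
    for (state in frontier) {
      for (nb in combination_moves(state)) {
        if (!exists(nb, envir = dist, inherits = FALSE)) {
          if (nb == goal) return(d)
          assign(nb, d, envir = dist)
          nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- nxt
  }
  stop("internal error: partition graph is connected; goal not reached")
}

# All canonical combinations one move away.
combination_moves <- function(state) {
  groups <- parse_combination(state)
  m <- length(groups)
  out <- character(0)
  # fission
  for (gi in seq_len(m)) {
    g <- groups[[gi]]
    if (length(g) < 2L) next
    for (mask in seq_len(2^length(g) - 2L)) {
      part1 <- g[bitwAnd(mask, 2^(seq_along(g) - 1L)) > 0L]
      if (!length(part1) || length(part1) == length(g)) next
      out <- c(out, canonicalize_combination(
        c(groups[-gi], list(part1), list(setdiff(g, part1)))))
    }
  }
  if (m > 1L) {
    for (gi in seq_len(m - 1L)) {
      for (gj in (gi + 1L):m) {
        merged <- c(groups[[gi]], groups[[gj]])
        rest <- groups[-c(gi, gj)]
        # fusion
        out <- c(out, canonicalize_combination(c(rest, list(merged))))
        # translocation: repartition the union into two non-empty groups
        for (mask in seq_len(2^length(merged) - 2L)) {
          part1 <- merged[bitwAnd(mask, 2^(seq_along(merged) - 1L)) > 0L]
          if (!length(part1) || length(part1) == length(merged)) next
          out <- c(out, canonicalize_combination(
            c(rest, list(part1), list(setdiff(merged, part1)))))
        }
      }
    }
  }
  unique(out)
}
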