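ARM_LETTERS <- LETTERS[1:7]
ANNOTATION_FEATURES <- c("nucleolus", "balbiani_ring", "puff", "centromere")

#' Species karyotype records
#'
#' A `karyotype` bundles everything recorded for one species: the haploid
#' chromosome number, the whole-arm combination (which arms are fused into
#' which chromosomes, e.g. `"AE CD BF G"`), the per-arm pool of named banding
#' sequences, the per-arm reference band orders those sequences are written
#' against, and free-text notes. Arms known to be monomorphic but never
#' photomapped are held as an empty pool or as coded entries without a
#' formula.
#'
#' @param species species name.
#' @param haploid_n haploid chromosome number (number of arm groups).
#' @param arm_combination combination string, groups separated by spaces,
#'   arms within a group concatenated in conventional order (`"AE CD BF G"`).
#' @param pool named list (names among A-G) of lists of [arm_sequence()].
#' @param references named list (names among A-G) of [band_ref()] orders.
#' @param notes free text.
#' @return object of class `karyotype`.
#' @export
karyotype <- function(species, haploid_n, arm_combination, pool = list(),
                      references = list(), notes = "") {
  k <- structure(
    list(species = species, haploid_n = as.integer(haploid_n),
         arm_combination = arm_combination,
         references = references,
         pool = fill_pool(pool), notes = notes),
    class = "karyotype"
  )
  problems <- validate_karyotype(k)
  if (length(problems)) {
    kb_validation_error(paste0(
      "invalid karyotype for '", species, "':\n  - ",
      paste(problems, collapse = "\n  - ")
    ))
  }
  k
}

fill_pool <- function(pool) {
  out <- stats::setNames(vector("list", 7L), ARM_LETTERS)
  for (a in ARM_LETTERS) out[[a]] <- pool[[a]] %||% list()
  out
}

#' Parse an arm-combination string into groups
#'
#' @param text e.g. `"AE CD BF G"`.
#' @return list of character vectors of arm letters.
#' @export
parse_combination <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    kb_parse_error("arm combination must be a non-empty string")
  }
  groups <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  lapply(groups, function(g) {
    arms <- strsplit(g, "")[[1]]
    bad <- setdiff(arms, ARM_LETTERS)
    if (length(bad)) {
      kb_validation_error(paste0(
        "unknown arm letter(s): ", paste(bad, collapse = ", ")
      ))
    }
    arms
  })
}

# Collect every violated invariant (not just the first).
validate_karyotype <- function(k) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  groups <- tryCatch(parse_combination(k$arm_combination),
                     kb_error = function(e) {
                       note(conditionMessage(e))
                       NULL
                     })
  if (!is.null(groups)) {
    arms <- unlist(groups)
    for (a in ARM_LETTERS) {
      cnt <- sum(arms == a)
      if (cnt == 0L) note(sprintf("arm %s missing from combination", a))
      if (cnt > 1L) note(sprintf("arm %s appears in %d groups", a, cnt))
    }
    extra <- setdiff(arms, ARM_LETTERS)
    if (length(extra)) {
      note(paste0("unknown arms in combination: ", paste(extra, collapse = ", ")))
    }
    if (length(groups) != k$haploid_n) {
      note(sprintf("haploid_n = %d but combination has %d groups",
                   k$haploid_n, length(groups)))
    }
  }
  codes <- character(0)
  for (a in names(k$pool)) {
    if (!a %in% ARM_LETTERS) {
      note(sprintf("pool arm '%s' is not a valid arm letter", a))
      next
    }
    for (s in k$pool[[a]]) {
      if (!inherits(s, "arm_sequence")) {
        note(sprintf("pool entry on arm %s is not an arm_sequence", a))
        next
      }
      codes <- c(codes, s$code)
      if (s$arm != a) {
        note(sprintf("sequence '%s' has arm %s but sits in pool slot %s",
                     s$code, s$arm, a))
      }
      if (is_mapped(s) && !is.null(k$references[[a]]) &&
          !identical(unclass(s$reference), unclass(k$references[[a]]))) {
        note(sprintf("sequence '%s' uses a different reference order than arm %s",
                     s$code, a))
      }
    }
  }
  if (anyDuplicated(codes)) {
    note(paste0("duplicated sequence code(s): ",
                paste(unique(codes[duplicated(codes)]), collapse = ", ")))
  }
  problems
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("<karyotype> %s  n=%d  [%s]\n", x$species, x$haploid_n,
              x$arm_combination))
  for (a in ARM_LETTERS) {
    seqs <- x$pool[[a]]
    desc <- if (length(seqs) == 0L) "(unmapped, monomorphic)" else {
      paste(vapply(seqs, function(s) {
        paste0(s$code, if (!is_mapped(s)) "*")
      }, ""), collapse = ", ")
    }
    cat(sprintf("  arm %s: %s\n", a, desc))
  }
  if (nzchar(x$notes)) cat("  notes:", x$notes, "\n")
  invisible(x)
}

#' Read / write karyotype records (JSON dialect)
#'
#' The on-disk format is a small JSON dialect:
#' ```
#' {"species": "...", "haploid_n": 4, "arm_combination": "AE CD BF G",
#'  "references": {"A": ["1","2",...]},
#'  "arms": {"A": [{"code": "allA1", "formula": "1-19",
#'                  "annotations": [{"feature": "nucleolus",
#'                                   "position": "17-19"}]}],
#'           "B": []},
#'  "notes": "...", "synthetic_formulas": true}
#' ```
#' `"formula": null` marks an unmapped (monomorphic, no photomap) entry.
#' Reading validates every karyotype invariant; the error message lists all
#' violations. Writing is deterministic: write-then-read-then-write is
#' byte-identical.
#'
#' @param path file path.
#' @return `read_karyotype()` a [karyotype()]; `write_karyotype()` the path,
#'   invisibly.
#' @export
read_karyotype <- function(path) {
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) kb_parse_error(paste0("cannot parse JSON: ",
                                              conditionMessage(e)))
  )
  required <- c("species", "haploid_n", "arm_combination", "arms")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    kb_validation_error(paste0("missing field(s): ",
                               paste(missing, collapse = ", ")))
  }
  refs <- lapply(raw$references %||% list(),
                 function(r) band_ref(unlist(r, use.names = FALSE)))
  pool <- list()
  for (a in names(raw$arms)) {
    pool[[a]] <- lapply(raw$arms[[a]], function(e) {
      ann <- lapply(e$annotations %||% list(), function(x) {
        list(feature = x$feature, position = x$position %||% "")
      })
      if (is.null(e$formula) || (length(e$formula) == 1L && is.na(e$formula))) {
        arm_sequence(e$code, a, annotations = ann)
      } else {
        if (is.null(refs[[a]])) {
          kb_validation_error(sprintf(
            "arm %s has formulas but no reference order", a
          ))
        }
        parse_band_sequence(e$formula, a, refs[[a]], code = e$code,
                            annotations = ann)
      }
    })
  }
  karyotype(raw$species, raw$haploid_n, raw$arm_combination,
            pool = pool, references = refs, notes = raw$notes %||% "")
}

#' @rdname read_karyotype
#' @param k a [karyotype()].
#' @export
write_karyotype <- function(k, path) {
  stopifnot(inherits(k, "karyotype"))
  arms <- list()
  for (a in ARM_LETTERS) {
    arms[[a]] <- lapply(k$pool[[a]], function(s) {
      list(code = s$code,
           formula = if (is_mapped(s)) format_band_sequence(s)
                     else NA_character_,
           annotations = lapply(s$annotations, function(x) {
             list(feature = x$feature, position = x$position)
           }))
    })
  }
  refs <- lapply(k$references, function(r) as.character(unclass(r)))
  obj <- list(species = k$species, haploid_n = k$haploid_n,
              arm_combination = k$arm_combination,
              references = refs, arms = arms, notes = k$notes)
  json <- jsonlite::toJSON(obj, pretty = TRUE, auto_unbox = TRUE,
                           na = "null", digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Flat TSV export of sequence pools
#'
#' One row per sequence (unmapped monomorphic arms with no named sequence
#' get a placeholder row), for spreadsheet use.
#'
#' @param records a [karyotype()] or list of them.
#' @param path output path, or `""` for stdout.
#' @return the table, invisibly.
#' @export
write_pool_tsv <- function(records, path = "") {
  if (inherits(records, "karyotype")) records <- list(records)
  rows <- list()
  for (k in records) {
    for (a in ARM_LETTERS) {
      seqs <- k$pool[[a]]
      if (length(seqs) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          species = k$species, haploid_n = k$haploid_n,
          arm_combination = k$arm_combination, arm = a,
          code = NA_character_, mapped = FALSE, formula = NA_character_
        )
      } else {
        for (s in seqs) {
          rows[[length(rows) + 1L]] <- data.frame(
            species = k$species, haploid_n = k$haploid_n,
            arm_combination = k$arm_combination, arm = a,
            code = s$code, mapped = is_mapped(s),
            formula = if (is_mapped(s)) format_band_sequence(s)
                      else NA_character_
          )
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
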