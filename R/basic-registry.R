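#' Registry of basic and standard banding sequences
#'
#' Comparative work anchors each arm to known reference sequences: the
#' *cosmopolitan basic* sequences (shared across species and continents,
#' presumed to predate cytocomplex separation, e.g. holA1, lonC1, lonE1,
#' aciE1, aprE1) and the *Chironomus piger* standard (pigST), used when no
#' basic sequence is known for an arm. A registry is a named collection of
#' such sequences with a scope tag.
#'
#' @param entries list of entries; each a list with `name`, `arm`, `scope`
#'   (`"cosmopolitan_basic"` or `"reference_standard"`) and `sequence`
#'   (an [arm_sequence()], possibly unmapped for name-only stubs).
#' @return object of class `basic_registry`.
#' @export
basic_registry <- function(entries = list()) {
  nms <- vapply(entries, function(e) e$name, "")
  if (anyDuplicated(nms)) {
    kb_validation_error(paste0(
      "duplicated registry name(s): ",
      paste(unique(nms[duplicated(nms)]), collapse = ", ")
    ))
  }
  for (e in entries) {
    if (!e$arm %in% ARM_LETTERS) {
      kb_validation_error(sprintf(
        "registry entry '%s': arm '%s' is not one of A-G", e$name, e$arm
      ))
    }
    if (!is.null(e$sequence) && !inherits(e$sequence, "arm_sequence")) {
      kb_validation_error(sprintf(
        "registry entry '%s': sequence is not an arm_sequence", e$name
      ))
    }
    if (!e$scope %in% c("cosmopolitan_basic", "reference_standard")) {
      kb_validation_error(sprintf(
        "registry entry '%s': unknown scope '%s'", e$name, e$scope
      ))
    }
  }
  structure(list(entries = entries), class = "basic_registry")
}

#' @export
print.basic_registry <- function(x, ...) {
  cat(sprintf("<basic_registry> %d entries\n", length(x$entries)))
  for (e in x$entries) {
    cat(sprintf("  %s (arm %s, %s)%s\n", e$name, e$arm, e$scope,
                if (is.null(e$sequence) || !is_mapped(e$sequence))
                  " [stub, no formula]" else ""))
  }
  invisible(x)
}

#' Read / write a basic-sequence registry (JSON)
#'
#' Format: array of `{"name", "arm", "scope", "formula", "reference"}`;
#' `"formula": null` makes a name-only stub (excluded from any distance
#' computation until a formula is supplied).
#'
#' @param path file path; `read_basic_registry()` defaults to the shipped
#'   synthetic registry.
#' @return a [basic_registry()].
#' @export
read_basic_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "basic_registry_synthetic.json",
                                package = "karyoband")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- lapply(raw, function(x) {
    seq <- if (is.null(x$formula) ||
               (length(x$formula) == 1L && is.na(x$formula))) {
      arm_sequence(x$name, x$arm)
    } else {
      ref <- band_ref(unlist(x$reference, use.names = FALSE))
      parse_band_sequence(x$formula, x$arm, ref, code = x$name)
    }
    list(name = x$name, arm = x$arm, scope = x$scope, sequence = seq)
  })
  basic_registry(entries)
}

#' @rdname read_basic_registry
#' @param reg a [basic_registry()].
#' @export
write_basic_registry <- function(reg, path) {
  stopifnot(inherits(reg, "basic_registry"))
  obj <- lapply(reg$entries, function(e) {
    mapped <- !is.null(e$sequence) && is_mapped(e$sequence)
    list(name = e$name, arm = e$arm, scope = e$scope,
         formula = if (mapped) format_band_sequence(e$sequence)
                   else NA_character_,
         reference = if (mapped) as.character(unclass(e$sequence$reference))
                     else list())
  })
  json <- jsonlite::toJSON(obj, pretty = TRUE, auto_unbox = TRUE,
                           na = "null", digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

# Mapped registry entries for one arm, optionally restricted by scope.
registry_entries_for_arm <- function(reg, arm, scope = NULL) {
  Filter(function(e) {
    e$arm == arm &&
      (is.null(scope) || e$scope %in% scope) &&
      !is.null(e$sequence) && is_mapped(e$sequence)
  }, reg$entries)
}
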