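#' @keywords internal
"_PACKAGE"

#' @useDynLib karyoband, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Classified conditions: parse errors (malformed text) vs validation errors
# (well-formed text violating a domain invariant). Both inherit "kb_error".
kb_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "kb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

kb_parse_error <- function(msg) kb_stop(msg, "kb_parse_error")
kb_validation_error <- function(msg) kb_stop(msg, "kb_validation_error")

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations thread an explicit integer seed through this;
# nothing in the package perturbs the global RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    kb_validation_error("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic stream of sub-seeds below 2^31, for fanning one user seed
# out to independent generator calls.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
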