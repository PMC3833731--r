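#' Generate a reference (ancestral) arm sequence
#'
#' Builds an arm of `n_bands` numbered Keyl regions; each region
#' independently carries 2-3 lettered subbands with probability
#' `subband_rate` (a region without subbands is a single band). The returned
#' sequence is the identity arrangement over that reference order — the
#' stand-in for an ancestral photomap. Deterministic per seed; the caller's
#' RNG state is untouched.
#'
#' @param n_bands number of numbered regions, 10-30 (typical arms carry
#'   15-25).
#' @param subband_rate probability that a region is subdivided.
#' @param seed integer seed.
#' @param arm arm letter, default `"A"`.
#' @param code sequence code; default `"anc<arm>1"`.
#' @return an [arm_sequence()].
#' @examples
#' generate_ancestor(19, 0, seed = 1)   # formula "1-19"
#' @export
generate_ancestor <- function(n_bands, subband_rate, seed, arm = "A",
                              code = NULL) {
  if (!is.numeric(n_bands) || n_bands < 10L || n_bands > 30L) {
    kb_validation_error("n_bands must be between 10 and 30")
  }
  if (!is.numeric(subband_rate) || subband_rate < 0 || subband_rate > 1) {
    kb_validation_error("subband_rate must be a probability in [0, 1]")
  }
  labels <- with_seed(seed, {
    unlist(lapply(seq_len(n_bands), function(major) {
      if (stats::runif(1) < subband_rate) {
        nsub <- sample(2:3, 1L)
        paste0(major, letters[seq_len(nsub)])
      } else {
        as.character(major)
      }
    }))
  })
  ref <- band_ref(labels)
  arm_sequence(code %||% paste0("anc", arm, "1"), arm, ref,
               seq_along(labels))
}

#' Apply seeded random inversions to a sequence
#'
#' Draws `k` reversal intervals uniformly over internal band intervals of
#' the arm and applies them in order, emulating successive paracentric
#' inversions. Degenerate draws are rejected and redrawn: single-band
#' intervals (a lone flipped band is cytologically invisible) and the
#' whole-arm interval (a whole-arm flip is a reading convention, not an
#' inversion). The derived sequence together with the step list forms a
#' replayable evolution log.
#'
#' @param seq mapped [arm_sequence()] with at least 3 bands.
#' @param k number of inversions, `>= 0`.
#' @param seed integer seed.
#' @param code code for the derived sequence; default appends `.d`.
#' @return `evolution_log`: list with `ancestor`, `steps` (data.frame of
#'   1-based inclusive band-position intervals), `derived`, `seed`.
#' @export
evolve <- function(seq, k, seed, code = NULL) {
  stopifnot(inherits(seq, "arm_sequence"))
  if (!is_mapped(seq)) kb_validation_error("cannot evolve an unmapped sequence")
  if (!is.numeric(k) || k < 0L) kb_validation_error("k must be >= 0")
  n <- length(seq$signed)
  if (n < 3L) kb_validation_error("need at least 3 bands to draw inversions")
  steps <- with_seed(seed, {
    out <- matrix(0L, nrow = k, ncol = 2L)
    for (s in seq_len(k)) {
      repeat {
        i <- sample.int(n, 1L)
        j <- sample.int(n, 1L)
        if (i > j) { t <- i; i <- j; j <- t }
        if (j > i && !(i == 1L && j == n)) break
      }
      out[s, ] <- c(i, j)
    }
    out
  })
  signed <- seq$signed
  for (s in seq_len(k)) {
    signed <- reverse_segment(signed, steps[s, 1L], steps[s, 2L])
  }
  derived <- arm_sequence(code %||% paste0(seq$code, ".d"), seq$arm,
                          seq$reference, signed,
                          annotations = seq$annotations)
  structure(
    list(ancestor = seq, steps = data.frame(i = steps[, 1L], j = steps[, 2L]),
         derived = derived, seed = seed),
    class = "evolution_log"
  )
}

#' Replay an evolution log
#'
#' Applies the recorded reversal steps to the log's ancestor; by the log
#' invariant the result equals the recorded derived sequence.
#'
#' @param log an `evolution_log` from [evolve()].
#' @return an [arm_sequence()].
#' @export
replay_log <- function(log) {
  signed <- log$ancestor$signed
  for (s in seq_len(nrow(log$steps))) {
    signed <- reverse_segment(signed, log$steps$i[s], log$steps$j[s])
  }
  arm_sequence(log$derived$code, log$ancestor$arm, log$ancestor$reference,
               signed, annotations = log$ancestor$annotations)
}

#' Generate a synthetic study with known ground truth
#'
#' Emulates a multi-species comparative study at the scale of the real ones:
#' a handful of species spread over registered cytocomplexes, per-arm pools
#' of 1-3 sequences, each sequence derived from an arm-wide shared "basic"
#' ancestor by a small number of inversions. Defaults mirror the study
#' design the package targets: 6 species over
#' pseudothummi/thummi/parathummi (3/2/1), inversion polymorphism on a
#' minority of arms, 0-4 steps from the basic sequence.
#'
#' @param n_species number of species.
#' @param complex_mix named integer vector, species per registered complex;
#'   must sum to `n_species`.
#' @param polymorphism_rate probability that an arm carries a second
#'   sequence (and, at half that rate, a third).
#' @param step_range integer vector of candidate step counts from the basic
#'   ancestor, sampled uniformly.
#' @param n_bands,subband_rate forwarded to [generate_ancestor()].
#' @param seed integer seed.
#' @param registry cytocomplex registry table.
#' @return list with `records` (list of [karyotype()]), `registry` (a
#'   [basic_registry()] of the true basic sequences) and `truth`
#'   (data.frame: `species`, `arm`, `code`, `true_steps`, `basic`,
#'   `complex`).
#' @export
generate_study <- function(n_species = 6L,
                           complex_mix = c(pseudothummi = 3L, thummi = 2L,
                                           parathummi = 1L),
                           polymorphism_rate = 0.3,
                           step_range = 0:4,
                           n_bands = 20L, subband_rate = 0.15,
                           seed = 1L,
                           registry = read_cytocomplex_registry()) {
  if (sum(complex_mix) != n_species) {
    kb_validation_error("complex_mix must sum to n_species")
  }
  unknown <- setdiff(names(complex_mix), registry$name)
  if (length(unknown)) {
    kb_validation_error(paste0(
      "complex_mix names not in the cytocomplex registry: ",
      paste(unknown, collapse = ", ")
    ))
  }
  # shared basic ancestor per arm
  ancestors <- lapply(stats::setNames(seq_along(ARM_LETTERS), ARM_LETTERS),
                      function(ai) {
    generate_ancestor(n_bands, subband_rate, derive_seed(seed, ai),
                      arm = ARM_LETTERS[ai],
                      code = paste0("bas", ARM_LETTERS[ai], "1"))
  })
  reg <- basic_registry(lapply(ARM_LETTERS, function(a) {
    list(name = paste0("bas", a, "1"), arm = a,
         scope = "cosmopolitan_basic", sequence = ancestors[[a]])
  }))

  complexes <- rep(names(complex_mix), complex_mix)
  tags <- vapply(seq_len(n_species), function(i) {
    paste0(letters[(i - 1L) %/% 26L + 1L], letters[(i - 1L) %% 26L + 1L], "s")
  }, "")
  records <- vector("list", n_species)
  truth <- list()
  for (sp in seq_len(n_species)) {
    tag <- tags[sp]
    cx <- complexes[sp]
    combination <- registry$combination[match(cx, registry$name)]
    pool <- list()
    for (ai in seq_along(ARM_LETTERS)) {
      a <- ARM_LETTERS[ai]
      sseed <- derive_seed(seed, sp * 100L + ai)
      draws <- with_seed(sseed, {
        list(k = sample(step_range, 1L),
             extra = stats::runif(2) <
               c(polymorphism_rate, polymorphism_rate / 2))
      })
      n_seq <- 1L + sum(cumprod(draws$extra))  # third only if second drawn
      arm_pool <- list()
      base_code <- paste0(tag, a, 1L)
      log1 <- evolve(ancestors[[a]], draws$k,
                     derive_seed(sseed, 1L), code = base_code)
      arm_pool[[1L]] <- log1$derived
      truth[[length(truth) + 1L]] <- data.frame(
        species = tag, arm = a, code = base_code,
        true_steps = draws$k, basic = draws$k == 0L, complex = cx
      )
      prev <- log1$derived
      for (extra_i in seq_len(n_seq - 1L)) {
        code <- paste0(tag, a, extra_i + 1L)
        lg <- evolve(prev, 1L, derive_seed(sseed, 1L + extra_i), code = code)
        arm_pool[[extra_i + 1L]] <- lg$derived
        truth[[length(truth) + 1L]] <- data.frame(
          species = tag, arm = a, code = code,
          true_steps = draws$k + extra_i, basic = FALSE, complex = cx
        )
        prev <- lg$derived
      }
      pool[[a]] <- arm_pool
    }
    records[[sp]] <- karyotype(
      species = paste0("Synthetica ", tag), haploid_n = haploid_number(combination),
      arm_combination = combination, pool = pool,
      references = lapply(ancestors, function(x) x$reference),
      notes = sprintf("synthetic study member (seed %d)", seed)
    )
  }
  list(records = records, registry = reg,
       truth = do.call(rbind, truth))
}

#' Write a synthetic study to a directory
#'
#' Emits one karyotype JSON per species, the true basic registry, and a
#' `truth.tsv` ledger; every file carries a `#`-style provenance comment
#' where the format allows it (TSV only; JSON files are pure data).
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @param seed seed to stamp into the ledger header.
#' @return invisible vector of written paths.
#' @export
write_study <- function(study, dir, seed = NA_integer_) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (k in study$records) {
    p <- file.path(dir, paste0(gsub("[^A-Za-z0-9]+", "_", k$species), ".json"))
    write_karyotype(k, p)
    paths <- c(paths, p)
  }
  rp <- file.path(dir, "basic_registry.json")
  write_basic_registry(study$registry, rp)
  tp <- file.path(dir, "truth.tsv")
  con <- file(tp, "w")
  writeLines(sprintf("# karyoband %s truth ledger seed=%s",
                     as.character(utils::packageVersion("karyoband")),
                     as.character(seed)), con)
  utils::write.table(study$truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(c(paths, rp, tp))
}
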