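#' Summarize a species' banding-sequence pool
#'
#' The sequence pool of a species is counted arm by arm: an arm with named
#' sequences contributes their number, and an arm with no mapped or named
#' sequence (monomorphic, never photomapped) still contributes exactly one —
#' the counting rule that reproduces the published pool totals. Each mapped
#' sequence is classified *cosmopolitan basic* if its inversion-step
#' distance to a registry entry of scope `cosmopolitan_basic` is 0
#' ("identical"); everything else — including unmapped arms — counts as
#' endemic. Sequences 1-2 steps from a basic sequence are additionally
#' reported as `derived-from:<name>:<k>` but remain endemic.
#'
#' @param k a [karyotype()].
#' @param reg a [basic_registry()].
#' @return `pool_summary`: list with `species`, `per_arm_counts`,
#'   `total_sequences`, `polymorphic_arms`, `basic_count`, `endemic_count`,
#'   `basic_codes`, `near_basic` (named character vector code ->
#'   `derived-from:<name>:<k>`).
#' @export
pool_summary <- function(k, reg = basic_registry()) {
  stopifnot(inherits(k, "karyotype"), inherits(reg, "basic_registry"))
  per_arm <- vapply(ARM_LETTERS, function(a) length(k$pool[[a]]), 0L)
  total <- sum(pmax(1L, per_arm))
  polymorphic <- ARM_LETTERS[per_arm >= 2L]

  basic_codes <- character(0)
  near_basic <- character(0)
  n_named_basic <- 0L
  for (a in ARM_LETTERS) {
    basics <- registry_entries_for_arm(reg, a, scope = "cosmopolitan_basic")
    for (s in k$pool[[a]]) {
      if (!is_mapped(s) || length(basics) == 0L) next
      comparable <- Filter(function(e) {
        identical(unclass(e$sequence$reference), unclass(s$reference))
      }, basics)
      if (length(comparable) == 0L) next
      dists <- vapply(comparable, function(e) {
        arm_distance(s, e$sequence)$distance
      }, 0L)
      if (any(dists == 0L)) {
        basic_codes <- c(basic_codes, s$code)
        n_named_basic <- n_named_basic + 1L
      } else if (min(dists) <= 2L) {
        i <- which.min(dists)
        near_basic[s$code] <- sprintf("derived-from:%s:%d",
                                      comparable[[i]]$name, dists[i])
      }
    }
  }
  structure(
    list(species = k$species, per_arm_counts = per_arm,
         total_sequences = total, polymorphic_arms = polymorphic,
         basic_count = n_named_basic,
         endemic_count = total - n_named_basic,
         basic_codes = basic_codes, near_basic = near_basic),
    class = "pool_summary"
  )
}

#' @export
print.pool_summary <- function(x, ...) {
  cat(sprintf("<pool_summary> %s: %d sequences (%d basic, %d endemic)\n",
              x$species, x$total_sequences, x$basic_count, x$endemic_count))
  cat("  polymorphic arms:",
      if (length(x$polymorphic_arms)) paste(x$polymorphic_arms, collapse = ", ")
      else "none", "\n")
  if (length(x$basic_codes)) {
    cat("  basic:", paste(x$basic_codes, collapse = ", "), "\n")
  }
  if (length(x$near_basic)) {
    cat("  near-basic:",
        paste(sprintf("%s (%s)", names(x$near_basic), x$near_basic),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Parse a genotypic combination code
#'
#' Karyotype figures label genotypes as `"allC1.1"` (homozygote for allC1)
#' or `"allC1.2"` (heterozygote allC1/allC2): the serials after the arm
#' letter name the two homologous sequences. Genotype frequencies are out of
#' scope; this only resolves the pair of sequence codes.
#'
#' @param text genotype code, e.g. `"allC1.2"`.
#' @return character vector of the two sequence codes
#'   (e.g. `c("allC1", "allC2")`).
#' @export
genotype_pair <- function(text) {
  m <- regmatches(text, regexec("^([A-Za-z]+[A-G])([0-9]+)\\.([0-9]+)$",
                                text))[[1]]
  if (length(m) == 0L) {
    kb_parse_error(sprintf("malformed genotype code '%s'", text))
  }
  paste0(m[2], c(m[3], m[4]))
}

#' Arms with inversion polymorphism
#'
#' An arm is polymorphic when the species carries two or more named
#' sequences on it (alternative arrangements segregating in the population).
#'
#' @param k a [karyotype()].
#' @return character vector of arm letters.
#' @export
polymorphic_arms <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  ARM_LETTERS[vapply(ARM_LETTERS, function(a) length(k$pool[[a]]) >= 2L, TRUE)]
}

#' Study-level summary across species
#'
#' One row per species (cytocomplex call, haploid number, pool size,
#' polymorphic arms, basic/endemic split) plus aggregate counts of species
#' per cytocomplex. Fused variants aggregate with their base complex (a
#' modified thummi karyotype counts toward thummi).
#'
#' @param records list of [karyotype()] objects.
#' @param reg a [basic_registry()].
#' @param registry cytocomplex registry table.
#' @return `study_summary`: list with `species` (data.frame),
#'   `complex_counts` (named integer vector by base complex) and
#'   `n_complexes` (distinct base complexes).
#' @export
study_summary <- function(records, reg = basic_registry(),
                          registry = read_cytocomplex_registry()) {
  if (inherits(records, "karyotype")) records <- list(records)
  if (length(records) == 0L) kb_validation_error("need at least one record")
  rows <- lapply(records, function(k) {
    call <- classify_cytocomplex(k$arm_combination, registry)
    ps <- pool_summary(k, reg)
    data.frame(
      species = k$species,
      complex = call$name,
      base_complex = call$base %||% NA_character_,
      haploid_n = k$haploid_n,
      arm_combination = k$arm_combination,
      pool_size = ps$total_sequences,
      polymorphic_arms = paste(ps$polymorphic_arms, collapse = ","),
      basic = ps$basic_count,
      endemic = ps$endemic_count,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  base <- ifelse(is.na(tab$base_complex), "unrecognized", tab$base_complex)
  counts <- sort(table(base), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(
    list(species = tab, complex_counts = counts,
         n_complexes = length(setdiff(names(counts), "unrecognized"))),
    class = "study_summary"
  )
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("<study_summary> %d species, %d cytocomplex(es)\n",
              nrow(x$species), x$n_complexes))
  print(x$species, row.names = FALSE)
  cat("species per complex:",
      paste(sprintf("%s=%d", names(x$complex_counts), x$complex_counts),
            collapse = ", "), "\n")
  invisible(x)
}

#' @rdname study_summary
#' @param path output TSV path, or `""` for stdout.
#' @param header optional `#`-prefixed header lines written before the table.
#' @export
write_study_tsv <- function(records, path = "", reg = basic_registry(),
                            registry = read_cytocomplex_registry(),
                            header = character(0)) {
  s <- study_summary(records, reg, registry)
  con <- if (nzchar(path)) file(path, "w") else stdout()
  if (nzchar(path)) on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(s$species, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(s)
}
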