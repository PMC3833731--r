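# Shared test machinery: fixture paths, tiny references, random generators.

fixture_path <- function(name) {
  system.file("extdata", name, package = "karyoband")
}

species_fixtures <- function() {
  files <- c(alluaudi = "alluaudi_synthetic.json",
             transvaalensis = "transvaalensis_synthetic.json",
             nakuru = "nakuru_synthetic.json",
             formosipennis = "formosipennis_synthetic.json",
             pulcher = "pulcher_synthetic.json",
             kisumu = "kisumu_synthetic.json")
  lapply(files, function(f) read_karyotype(fixture_path(f)))
}

synthetic_registry <- function() {
  read_basic_registry(fixture_path("basic_registry_synthetic.json"))
}

ref19 <- band_ref(as.character(1:19))

# identity sequence over a plain 1..n reference
idseq <- function(n = 19, arm = "A", code = paste0("id", arm, "1")) {
  arm_sequence(code, arm, band_ref(as.character(seq_len(n))), seq_len(n))
}

# all signed permutations of 1..n (for exhaustive oracle comparisons)
all_signed_perms <- function(n) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (r in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], r)
    }
    out
  }
  out <- list()
  for (p in perms(seq_len(n))) {
    for (bits in 0:(2^n - 1L)) {
      s <- ifelse(bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0L, -1L, 1L) * p
      out[[length(out) + 1L]] <- s
    }
  }
  out
}

random_signed_perm <- function(n) {
  as.integer(sample(n) * sample(c(-1L, 1L), n, replace = TRUE))
}

# deterministic seed for the (k, replicate) grid of the recovery table
derive_seed_pair <- function(k, r) 20000L + k * 971L + r * 13L

# replay a scenario on a signed permutation
apply_scenario <- function(p, scenario) {
  for (s in seq_len(nrow(scenario))) {
    i <- scenario$i[s]
    j <- scenario$j[s]
    p[i:j] <- -rev(p[i:j])
  }
  p
}
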