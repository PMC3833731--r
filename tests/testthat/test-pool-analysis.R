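test_that("pool counting reproduces all five published totals", {
  k <- species_fixtures()
  reg <- synthetic_registry()
  totals <- vapply(k, function(x) pool_summary(x, reg)$total_sequences, 0L)
  expect_identical(totals[["alluaudi"]], 9L)
  expect_identical(totals[["transvaalensis"]], 10L)
  expect_identical(totals[["nakuru"]], 7L)
  expect_identical(totals[["pulcher"]], 8L)
  expect_identical(totals[["kisumu"]], 7L)
})

test_that("basic/endemic classification follows distance-0 to the registry", {
  k <- species_fixtures()
  reg <- synthetic_registry()
  all_ps <- pool_summary(k$alluaudi, reg)
  expect_identical(all_ps$basic_count, 3L)
  expect_identical(all_ps$endemic_count, 6L)
  expect_setequal(all_ps$basic_codes, c("allA1", "allE1", "allF1"))
  expect_identical(all_ps$basic_count + all_ps$endemic_count,
                   all_ps$total_sequences)
  # transvaalensis: all endemic, but trvA1/trvE1 flagged near-basic
  trv_ps <- pool_summary(k$transvaalensis, reg)
  expect_identical(trv_ps$basic_count, 0L)
  # holA1 and pigST_A hold the same formula; either attribution is right
  expect_match(trv_ps$near_basic[["trvA1"]],
               "^derived-from:(holA1|pigST_A):1$")
  # nakuru: exactly one basic arm (A)
  nak_ps <- pool_summary(k$nakuru, reg)
  expect_identical(nak_ps$basic_count, 1L)
})

test_that("basic_count is monotone in registry size", {
  k <- species_fixtures()$alluaudi
  reg <- synthetic_registry()
  sizes <- seq_along(reg$entries)
  prev <- 0L
  for (m in sizes) {
    sub <- basic_registry(reg$entries[seq_len(m)])
    cnt <- pool_summary(k, sub)$basic_count
    expect_gte(cnt, prev)
    prev <- cnt
  }
})

test_that("polymorphic arms are those with two or more sequences", {
  k <- species_fixtures()
  expect_setequal(polymorphic_arms(k$alluaudi), c("C", "G"))
  expect_setequal(polymorphic_arms(k$pulcher), "C")
  expect_length(polymorphic_arms(k$nakuru), 0L)
  # all-unmapped record: 7 singleton arms, none polymorphic
  bare <- karyotype("bare sp.", 4, "AE CD BF G")
  expect_identical(pool_summary(bare)$total_sequences, 7L)
  expect_length(polymorphic_arms(bare), 0L)
})

test_that("study summary reproduces composition and is order-invariant", {
  k <- species_fixtures()
  reg <- synthetic_registry()
  s <- study_summary(k, reg)
  expect_identical(nrow(s$species), 6L)
  expect_identical(s$complex_counts[["pseudothummi"]], 3L)
  expect_identical(s$complex_counts[["thummi"]], 2L)
  expect_identical(s$complex_counts[["parathummi"]], 1L)
  expect_identical(s$n_complexes, 3L)
  expect_identical(sum(s$species$complex == "modified thummi"), 1L)
  set.seed(51)
  s2 <- study_summary(k[sample(6)], reg)
  expect_identical(s2$complex_counts[names(s$complex_counts)],
                   s$complex_counts)
  expect_identical(s2$n_complexes, s$n_complexes)
  # single species
  s1 <- study_summary(k[1], reg)
  expect_identical(nrow(s1$species), 1L)
  expect_identical(s1$n_complexes, 1L)
})

test_that("genotype codes resolve to sequence pairs", {
  expect_identical(genotype_pair("allC1.2"), c("allC1", "allC2"))
  expect_identical(genotype_pair("allE1.1"), c("allE1", "allE1"))
  expect_error(genotype_pair("allC1"), class = "kb_parse_error")
  expect_error(genotype_pair("C.2"), class = "kb_parse_error")
})

test_that("synthetic study aggregates match generator ground truth", {
  mix <- c(pseudothummi = 4L, thummi = 3L, parathummi = 3L)
  study <- generate_study(n_species = 10, complex_mix = mix, seed = 99)
  s <- study_summary(study$records, study$registry)
  expect_identical(s$complex_counts[names(mix)][order(names(mix))],
                   mix[order(names(mix))])
  # ledger basic flags agree with pool_summary counts per species
  truth_basic <- tapply(study$truth$basic, study$truth$species, sum)
  for (k in study$records) {
    tag <- sub("^Synthetica ", "", k$species)
    ps <- pool_summary(k, study$registry)
    expect_identical(ps$basic_count, as.integer(truth_basic[[tag]]))
  }
})
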