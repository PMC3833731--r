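test_that("band references enforce label grammar and order", {
  expect_s3_class(band_ref(c("1", "2", "3a", "3b", "4")), "band_ref")
  expect_error(band_ref(c("2", "1")), class = "kb_validation_error")
  expect_error(band_ref(c("1", "1")), class = "kb_validation_error")
  expect_error(band_ref(c("1", "x2")), class = "kb_parse_error")
  expect_error(band_ref(c("0", "1")), class = "kb_validation_error")
  # subbands of the same major sit adjacent, after the bare major if mixed
  expect_error(band_ref(c("3b", "3a")), class = "kb_validation_error")
})

test_that("parsing splits tokens into oriented intervals", {
  s <- parse_band_sequence("1-7 15-12 8-11 16-19", "A", ref19, code = "exA1")
  runs <- refine_to_blocks(s, idseq(19, "A"))
  expect_identical(nrow(runs), 4L)
  expect_identical(runs$orientation_in_b,
                   c("forward", "inverted", "forward", "forward"))
  expect_identical(s$signed, c(1:7, -(15:12), 8:11, 16:19))

  ident <- parse_band_sequence("1-19", "A", ref19)
  expect_identical(ident$signed, 1:19)

  refG <- band_ref(c("1a", "1b", "2a", "2b", "2c", "3", "4", "5a"))
  g <- parse_band_sequence("1a-2c 4-3 5a", "G", refG, code = "exG1")
  # brute-force expansion: every reference band covered exactly once
  expect_setequal(abs(g$signed), 1:8)
  expect_identical(length(g$signed), 8L)
  expect_identical(g$signed, c(1:5, -7L, -6L, 8L))
})

test_that("parse errors are classified and name the offender", {
  expect_error(parse_band_sequence("1-7 9-19", "A", ref19),
               "8", class = "kb_validation_error")          # gap
  expect_error(parse_band_sequence("1-7 5-19", "A", ref19),
               class = "kb_validation_error")               # overlap
  expect_error(parse_band_sequence("1-25", "A", ref19),
               "25", class = "kb_validation_error")         # unknown band
  expect_error(parse_band_sequence("1-7 x 8-19", "A", ref19),
               "token 2", class = "kb_parse_error")         # malformed token
  expect_error(parse_band_sequence("", "A", ref19),
               class = "kb_parse_error")
})

test_that("formatting merges maximal intervals and round-trips", {
  expect_identical(format_band_sequence(idseq(19, "A")), "1-19")
  s <- parse_band_sequence("1-4 10-5 11-19", "A", ref19)
  expect_identical(format_band_sequence(s), "1-4 10-5 11-19")
  # exactly one descending token for a single inverted block
  toks <- strsplit(format_band_sequence(s), " ")[[1]]
  desc <- vapply(strsplit(toks, "-"), function(t) {
    length(t) == 2L && as.integer(t[1]) > as.integer(t[2])
  }, TRUE)
  expect_identical(sum(desc), 1L)
})

test_that("parse o format is identity on 1000 seeded text-born sequences", {
  set.seed(421)
  for (rep in 1:1000) {
    n_bands <- sample(10:30, 1)
    anc <- generate_ancestor(n_bands, runif(1, 0, 0.4), seed = rep)
    lg <- evolve(anc, sample(0:5, 1), seed = 10000 + rep)
    # project to text (drops hidden singleton inversions); the first parse
    # yields a text-born object on which parse o format is exact identity
    txt1 <- format_band_sequence(lg$derived)
    s1 <- parse_band_sequence(txt1, anc$arm, anc$reference)
    txt2 <- format_band_sequence(s1)
    s2 <- parse_band_sequence(txt2, anc$arm, anc$reference)
    expect_identical(s2$signed, s1$signed)
    expect_identical(format_band_sequence(s2), txt2)
  }
})

test_that("canonical direction picks the smaller-first-band reading", {
  s <- parse_band_sequence("19-1", "A", ref19)
  expect_identical(canonical_direction(s)$signed, 1:19)
  expect_identical(canonical_direction(idseq())$signed, 1:19)
  # canonicalization is an involution-invariant: both readings map to one
  t <- parse_band_sequence("5-1 6-19", "A", ref19)
  flipped <- parse_band_sequence("19-6 1-5", "A", ref19)
  expect_identical(canonical_direction(t)$signed,
                   canonical_direction(flipped)$signed)
})

test_that("arm sequences validate code and coverage", {
  expect_error(arm_sequence("allC1", "Z"), class = "kb_validation_error")
  expect_error(arm_sequence("allC1", "D", ref19, 1:19),
               class = "kb_validation_error")  # code lacks arm letter
  expect_error(arm_sequence("exA1", "A", ref19, c(1:18, 18L)),
               class = "kb_validation_error")  # not a permutation
  unmapped <- arm_sequence("allG1", "G")
  expect_false(karyoband:::is_mapped(unmapped))
})
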