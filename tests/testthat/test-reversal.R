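test_that("distance agrees with the BFS oracle exhaustively for n <= 5", {
  for (n in 1:5) {
    for (s in all_signed_perms(n)) {
      d <- signed_reversal_distance(s, scenario = FALSE)$distance
      expect_identical(d, bfs_oracle_distance(s))
    }
  }
})

test_that("known distances: identity, whole flip, classic hurdles", {
  expect_identical(signed_reversal_distance(1:7)$distance, 0L)
  expect_identical(signed_reversal_distance(-(7:1))$distance, 1L)
  expect_identical(signed_reversal_distance(c(2L, 1L))$distance, 3L)
  expect_identical(signed_reversal_distance(c(-1L))$distance, 1L)
  # two identical fixture sequences: zero steps (allE1 vs pigST arm E)
  k <- read_karyotype(fixture_path("alluaudi_synthetic.json"))
  reg <- synthetic_registry()
  pigE <- Filter(function(e) e$name == "pigST_E", reg$entries)[[1]]$sequence
  expect_identical(arm_distance(k$pool$E[[1]], pigE)$distance, 0L)
})

test_that("oracle refuses oversized inputs", {
  expect_error(bfs_oracle_distance(random_signed_perm(9)),
               class = "kb_validation_error")
  expect_error(bfs_oracle_distance(random_signed_perm(5), max_n = 4),
               class = "kb_validation_error")
})

test_that("scenarios sort the permutation in exactly distance steps", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    p <- random_signed_perm(n)
    res <- signed_reversal_distance(p, scenario = TRUE)
    expect_identical(nrow(res$scenario), res$distance)
    expect_identical(apply_scenario(p, res$scenario), seq_len(n))
  }
})

test_that("scenarios are deterministic (lexicographically smallest step)", {
  p <- c(3L, -1L, -2L)
  r1 <- signed_reversal_distance(p)
  r2 <- signed_reversal_distance(p)
  expect_identical(r1$scenario, r2$scenario)
  # first applicable step must be minimal in (i, j) among distance reducers
  d0 <- r1$distance
  first <- c(r1$scenario$i[1], r1$scenario$j[1])
  for (i in 1:3) {
    for (j in i:3) {
      if (i > first[1] || (i == first[1] && j >= first[2])) next
      q <- karyoband:::reverse_segment(p, i, j)
      expect_gte(signed_reversal_distance(q, scenario = FALSE)$distance,
                 d0)
    }
  }
})

test_that("bounds sandwich the distance on 500 seeded permutations", {
  set.seed(32)
  for (rep in 1:500) {
    n <- sample(1:8, 1)
    p <- random_signed_perm(n)
    d <- signed_reversal_distance(p, scenario = FALSE)$distance
    expect_lte(breakpoint_lower_bound(p), d)
    expect_lte(d, trivial_upper_bound(p))
  }
  expect_identical(breakpoint_lower_bound(1:6), 0L)
  expect_identical(trivial_upper_bound(1:6), 7L)
  expect_identical(breakpoint_lower_bound(c(1L, -2L, 3L)), 1L)
})

test_that("distance formula invariant holds on the result object", {
  set.seed(33)
  for (rep in 1:100) {
    n <- sample(1:8, 1)
    p <- random_signed_perm(n)
    r <- signed_reversal_distance(p, scenario = FALSE)
    expect_identical(r$distance,
                     (n + 1L) - r$cycles + r$hurdles + r$fortress)
  }
})

test_that("arm_distance is a flip-invariant metric on seeded sequences", {
  set.seed(34)
  anc <- generate_ancestor(15, 0.2, seed = 5)
  seqs <- c(list(anc), lapply(1:5, function(i) {
    evolve(anc, sample(1:4, 1), seed = 40 + i)$derived
  }))
  for (s in seqs) {
    expect_identical(arm_distance(s, s)$distance, 0L)
    flipped <- karyoband:::flip_arm(s)
    expect_identical(arm_distance(s, flipped)$distance, 0L)
  }
  for (i in 1:5) {
    a <- seqs[[sample(6, 1)]]
    b <- seqs[[sample(6, 1)]]
    c_ <- seqs[[sample(6, 1)]]
    dab <- arm_distance(a, b)$distance
    expect_identical(dab, arm_distance(b, a)$distance)
    expect_lte(arm_distance(a, c_)$distance,
               dab + arm_distance(b, c_)$distance)
  }
})

test_that("arm_distance equals the BFS oracle on small block counts", {
  set.seed(35)
  checked <- 0L
  for (rep in 1:60) {
    anc <- generate_ancestor(12, 0.1, seed = 70 + rep)
    b <- evolve(anc, 3, seed = 170 + rep)$derived
    # both relative orientations, without canonicalization (which would
    # collapse the flip onto one representative)
    raw_perm <- function(x, y) {
      karyoband:::signed_perm_from_partition(
        karyoband:::block_partition(x, y, canonicalize = FALSE))
    }
    p1 <- raw_perm(anc, b)
    p2 <- raw_perm(anc, karyoband:::flip_arm(b))
    if (length(p1) <= 8L && length(p2) <= 8L) {
      expect_identical(arm_distance(anc, b)$distance,
                       min(bfs_oracle_distance(p1), bfs_oracle_distance(p2)))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 30L)
})
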