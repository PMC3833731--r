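test_that("distance matrices: degenerate cases and duplicated codes", {
  anc <- generate_ancestor(15, 0.2, seed = 61)
  m1 <- distance_matrix(list(anc))
  expect_identical(dim(m1), c(1L, 1L))
  expect_identical(m1[1, 1], 0L)
  dup <- anc
  dup$code <- "ancA2"
  d1 <- evolve(anc, 2, seed = 62, code = "derA1")$derived
  m <- distance_matrix(list(anc, dup, d1))
  expect_identical(m["ancA1", ], m["ancA2", ], ignore_attr = TRUE)
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0L))
  expect_error(distance_matrix(list(anc, idseq(12, "B", "xB1"))),
               class = "kb_validation_error")
})

test_that("matrix entries stay below generator step counts", {
  anc <- generate_ancestor(20, 0.15, seed = 63)
  ks <- c(1L, 2L, 3L)
  seqs <- c(list(anc), lapply(seq_along(ks), function(i) {
    evolve(anc, ks[i], seed = 630 + i, code = paste0("dA", i + 1))$derived
  }))
  m <- distance_matrix(seqs)
  expect_true(all(m[1, -1] <= ks))
})

test_that("MST networks: star recovery and deterministic tie-breaks", {
  anc <- generate_ancestor(20, 0.15, seed = 64)
  hub <- anc
  leaves <- lapply(1:4, function(i) {
    evolve(hub, 1, seed = 640 + i, code = paste0("lvA", i))$derived
  })
  m <- distance_matrix(c(list(hub), leaves))
  mst <- mst_network(m)
  expect_identical(nrow(mst), 4L)
  deg <- table(c(mst$from, mst$to))
  expect_identical(as.integer(deg[["ancA1"]]), 4L)
  expect_identical(sum(mst$weight), 4L)
  # two labels -> single edge
  m2 <- distance_matrix(list(hub, leaves[[1]]))
  expect_identical(nrow(mst_network(m2)), 1L)
  # ties broken lexicographically: rerun is identical
  expect_identical(mst_network(m), mst_network(m))
  # MST weight never exceeds a path spanning tree
  path_w <- sum(vapply(seq_len(nrow(m) - 1),
                       function(i) m[i, i + 1], 0L))
  expect_lte(sum(mst$weight), path_w)
})

test_that("neighbor joining recovers additive matrices exactly", {
  set.seed(65)
  for (rep in 1:100) {
    ntax <- sample(5:8, 1)
    tree <- ape::rtree(ntax, br = function(n) sample(1:5, n, replace = TRUE))
    m <- ape::cophenetic.phylo(tree)
    res <- nj_tree(m)
    # path distances on the NJ tree reproduce the additive matrix
    back <- ape::cophenetic.phylo(res$tree)[rownames(m), colnames(m)]
    expect_lt(max(abs(back - m)), 1e-8)
    # topology identical to the generating tree
    expect_identical(as.numeric(ape::dist.topo(ape::unroot(tree),
                                               ape::unroot(res$tree))), 0)
  }
})

test_that("NJ rejects tiny inputs and collapses identical rows", {
  anc <- generate_ancestor(15, 0.1, seed = 66)
  d1 <- evolve(anc, 2, seed = 67, code = "dxA1")$derived
  expect_error(nj_tree(distance_matrix(list(anc, d1))),
               class = "kb_validation_error")
  dup <- d1
  dup$code <- "dxA2"
  m <- distance_matrix(list(anc, d1, dup))
  res <- nj_tree(m)
  back <- ape::cophenetic.phylo(res$tree)
  expect_identical(back["dxA1", "dxA2"], 0)
})

test_that("Newick output round-trips through ape's parser", {
  anc <- generate_ancestor(18, 0.15, seed = 68)
  seqs <- c(list(anc), lapply(1:4, function(i) {
    evolve(anc, i, seed = 680 + i, code = paste0("rtA", i + 1))$derived
  }))
  res <- nj_tree(distance_matrix(seqs))
  f <- tempfile(fileext = ".nwk")
  write_newick(res, f)
  reread <- ape::read.tree(f)
  expect_setequal(reread$tip.label, res$tree$tip.label)
  expect_identical(ape::write.tree(reread), res$newick)
})

test_that("PHYLIP and DOT writers emit well-formed text", {
  anc <- generate_ancestor(15, 0.1, seed = 69)
  seqs <- list(anc, evolve(anc, 1, seed = 70, code = "wA2")$derived,
               evolve(anc, 2, seed = 71, code = "wA3")$derived)
  m <- distance_matrix(seqs)
  fp <- tempfile(fileext = ".phy")
  write_phylip(m, fp)
  lines <- readLines(fp)
  expect_identical(as.integer(trimws(lines[1])), 3L)
  expect_length(lines, 4L)
  fd <- tempfile(fileext = ".dot")
  write_dot(mst_network(m), fd, header = "test")
  dot <- readLines(fd)
  expect_match(dot[1], "^// test")
  expect_match(dot[2], "^graph ")
  expect_identical(dot[length(dot)], "}")
})
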