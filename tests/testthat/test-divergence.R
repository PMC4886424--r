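test_that("p-distances follow the closed form with pairwise deletion", {
  aln <- mk_aln(c("MKRD", "MKRD"))
  D <- pdistance_matrix(aln, correction = "none")
  expect_equal(D[1, 2], 0)
  expect_equal(pdistance_matrix(aln)[1, 2], 0)  # poisson of 0 is 0

  aln <- mk_aln(c("AAAA", "AAAT"))
  expect_equal(pdistance_matrix(aln, correction = "none")[1, 2], 0.25)
  expect_equal(pdistance_matrix(aln, correction = "poisson")[1, 2],
               -log(0.75))

  # pairwise deletion: rows 1 and 2 share only their first two columns
  aln <- mk_aln(c("AA--", "AAT-", "AATT"))
  expect_equal(pdistance_matrix(aln, correction = "none")[1, 2], 0)
})

test_that("degenerate distances raise named errors", {
  aln <- mk_aln(c("AA--", "--TT"))
  expect_error(pdistance_matrix(aln), class = "cyclascan_no_shared_columns")
  aln <- mk_aln(c("AAAA", "TTTT"))
  expect_error(pdistance_matrix(aln, correction = "poisson"),
               class = "cyclascan_saturated_distance")
  expect_equal(pdistance_matrix(aln, correction = "none")[1, 2], 1)
})

test_that("complete deletion drops every gapped column first", {
  aln <- mk_aln(c("A-AT", "AWAA", "AWA-"))
  D <- pdistance_matrix(aln, correction = "none", deletion = "complete")
  # only columns 1 and 3 survive; all rows agree there
  expect_true(all(D == 0))
})

test_that("three-taxon trees use the closed-form star lengths", {
  D <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("a", "b", "c")], c(a = 0, b = 2, c = 4))
})

test_that("a two-taxon tree spans exactly the pairwise distance", {
  D <- matrix(c(0, 1.4, 1.4, 0), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  tr <- nj_tree(D)
  expect_equal(sum(tr$edge.length), 1.4)
  expect_setequal(tr$tip.label, c("x", "y"))
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(101)
  for (n in 4:8) {
    for (r in 1:10) {
      t0 <- ape::unroot(ape::rtree(n))
      D <- ape::cophenetic.phylo(t0)
      tr <- nj_tree(D)
      expect_equal(ape::dist.topo(tr, t0), 0, ignore_attr = TRUE)
      C <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
      expect_lt(max(abs(C - D)), 1e-9)
    }
  }
})

test_that("NJ agrees topologically with an independent implementation", {
  set.seed(103)
  sim <- simulate_two_clades(5, 150, n_fixed_diffs = 20, intra_rate = 0.05,
                             seed = 55)
  D <- pdistance_matrix(sim$alignment)
  expect_equal(ape::dist.topo(nj_tree(D), ape::nj(as.dist(D))), 0,
               ignore_attr = TRUE)
})

test_that("relabelling the matrix relabels the tree equivariantly", {
  set.seed(107)
  t0 <- ape::unroot(ape::rtree(6))
  D <- ape::cophenetic.phylo(t0)
  perm <- sample(rownames(D))
  D2 <- D[perm, perm]
  tr1 <- nj_tree(D)
  tr2 <- nj_tree(D2)
  expect_equal(ape::dist.topo(tr1, tr2), 0, ignore_attr = TRUE)
})

test_that("negative branch-length estimates are clamped to zero", {
  # a deliberately non-additive matrix known to produce negative estimates
  labs <- c("a", "b", "c", "d")
  D <- matrix(c(0, 1, 5, 4,
                1, 0, 4, 5,
                5, 4, 0, 1,
                4, 5, 1, 0) / 2, 4, 4, dimnames = list(labs, labs))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap output is deterministic for a fixed seed", {
  sim <- simulate_two_clades(4, 100, n_fixed_diffs = 10, intra_rate = 0.05,
                             seed = 77)
  b1 <- bootstrap_support(sim$alignment, n_reps = 20, seed = 5)
  b2 <- bootstrap_support(sim$alignment, n_reps = 20, seed = 5)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))
  expect_equal(b1$support, b2$support)
})

test_that("bootstrap supports are percentages and collapsing is effective", {
  sim <- simulate_two_clades(5, 150, n_fixed_diffs = 20, intra_rate = 0.08,
                             seed = 88)
  b <- bootstrap_support(sim$alignment, n_reps = 50, seed = 6, cutoff = 50)
  expect_true(all(b$support$support >= 0 & b$support$support <= 100))
  # every retained internal node label is a support >= cutoff
  labs <- suppressWarnings(as.numeric(b$tree$node.label))
  labs <- labs[!is.na(labs)]
  expect_true(all(labs >= b$cutoff))
  # collapsing cannot create internal edges: node count never exceeds full tree
  expect_lte(b$tree$Nnode, b$full_tree$Nnode)
})

test_that("an alignment of identical sequences yields one star polytomy", {
  aln <- mk_aln(rep("MKDE", 4), ids = c("a", "b", "c", "d"))
  b <- bootstrap_support(aln, n_reps = 10, seed = 1)
  expect_equal(b$tree$Nnode, 1L)
  expect_equal(nrow(b$support), 0L)
})

test_that("Newick round-trips preserve topology, lengths and supports", {
  sim <- simulate_two_clades(5, 150, n_fixed_diffs = 25, intra_rate = 0.03,
                             seed = 91)
  b <- bootstrap_support(sim$alignment, n_reps = 30, seed = 2)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(b$tree, file = f)
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(back, b$tree), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(b$tree$edge.length),
               tolerance = 1e-9)
  expect_identical(back$node.label, b$tree$node.label)
})

test_that("the separation statistic matches hand arithmetic", {
  labs <- c("a1", "a2", "b1", "b2")
  D <- matrix(1.0, 4, 4, dimnames = list(labs, labs))
  D[1, 2] <- D[2, 1] <- 0.1
  D[3, 4] <- D[4, 3] <- 0.1
  diag(D) <- 0
  part <- tibble::tibble(label = labs, block = c("A", "A", "B", "B"))
  out <- separation_statistic(D, part)
  expect_equal(out$s, 10)
  expect_equal(out$between_mean, 1)
  expect_equal(out$within_mean, 0.1)
})

test_that("identical within-block distances trigger the infinity sentinel", {
  labs <- c("a1", "a2", "b1", "b2")
  D <- matrix(0.5, 4, 4, dimnames = list(labs, labs))
  D[1, 2] <- D[2, 1] <- 0
  D[3, 4] <- D[4, 3] <- 0
  diag(D) <- 0
  part <- tibble::tibble(label = labs, block = c("A", "A", "B", "B"))
  expect_equal(separation_statistic(D, part)$s, Inf)
})

test_that("random partitions of an i.i.d. matrix give S near 1", {
  set.seed(113)
  vals <- numeric(100)
  for (r in 1:100) {
    n <- 12
    M <- matrix(0, n, n)
    M[upper.tri(M)] <- stats::runif(n * (n - 1) / 2, 0.5, 1.5)
    M <- M + t(M)
    dimnames(M) <- list(sprintf("t%02d", 1:n), sprintf("t%02d", 1:n))
    part <- tibble::tibble(label = rownames(M),
                           block = sample(rep(c("A", "B"), each = n / 2)))
    vals[r] <- separation_statistic(M, part)$s
  }
  expect_gt(mean(vals), 0.9)
  expect_lt(mean(vals), 1.1)
})

test_that("a singleton block is flagged and measured against the other block", {
  labs <- c("solo", "b1", "b2", "b3")
  D <- matrix(1, 4, 4, dimnames = list(labs, labs))
  D[2:4, 2:4] <- 0.2
  diag(D) <- 0
  part <- tibble::tibble(label = labs, block = c("A", "B", "B", "B"))
  out <- separation_statistic(D, part)
  expect_true(out$small_block)
  expect_equal(out$within_mean, 0.2)
  expect_equal(out$s, 5)
})
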