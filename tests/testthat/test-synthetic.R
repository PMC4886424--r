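test_that("every generator is a pure function of parameters and seed", {
  anc <- default_anchor()
  f1 <- simulate_family(8, 120, anc, "AC/GC", 0.2, 0.05, seed = 7)
  f2 <- simulate_family(8, 120, anc, "AC/GC", 0.2, 0.05, seed = 7)
  expect_identical(f1$alignment, f2$alignment)
  expect_identical(f1$truth, f2$truth)
  f3 <- simulate_family(8, 120, anc, "AC/GC", 0.2, 0.05, seed = 8)
  expect_false(identical(f1$alignment, f3$alignment))

  c1 <- simulate_two_clades(5, 100, 10, 0.02, seed = 3)
  c2 <- simulate_two_clades(5, 100, 10, 0.02, seed = 3)
  expect_identical(c1$alignment, c2$alignment)

  g1 <- simulate_genomes(3, planted_offset = 2, n_decoys = 5, seed = 11)
  g2 <- simulate_genomes(3, planted_offset = 2, n_decoys = 5, seed = 11)
  expect_identical(g1$genes, g2$genes)

  r1 <- simulate_redundant_set(10, 4, seed = 2)
  r2 <- simulate_redundant_set(10, 4, seed = 2)
  expect_identical(r1$records, r2$records)
})

test_that("family truth tables match the emitted alignment exactly", {
  anc <- default_anchor(ts2 = TRUE)
  fam <- simulate_family(12, 120, anc, "GC", mut_rate = 0.3,
                         key_mut_rate = 0.25, seed = 17)
  m <- do.call(rbind, strsplit(fam$alignment$seq, ""))
  rownames(m) <- fam$alignment$id
  # independent scan: observed residue at each recorded site
  for (k in seq_len(nrow(fam$truth))) {
    row <- fam$truth[k, ]
    expect_identical(unname(m[row$seq_id, row$site]), row$observed)
    expect_identical(row$mutated, row$observed != row$planted)
  }
  # reference row carries the canonical GC residues
  ref <- m[anc$ref_id, ]
  expect_equal(unname(ref[anc$positions[c("SS1", "SS2")]]), c("E", "K"))
  expect_equal(unname(ref[anc$positions[c("MB1", "MB2")]]), c("D", "D"))
  expect_equal(unname(ref[anc$positions["TS1"]]), "H")
})

test_that("degenerate family rates behave as documented", {
  anc <- default_anchor()
  fam0 <- simulate_family(5, 120, anc, "AC/GC", mut_rate = 0,
                          key_mut_rate = 0, seed = 1)
  expect_true(all(fam0$alignment$seq == fam0$alignment$seq[1]))
  famk <- simulate_family(20, 120, anc, "AC/GC", mut_rate = 0.3,
                          key_mut_rate = 0, seed = 2)
  expect_false(any(famk$truth$mutated))
})

test_that("tree evolution respects rate zero and the generating tree", {
  tr <- ape::rtree(6)
  root <- random_seq(80)
  aln0 <- evolve_on_tree(tr, root, rate = 0, seed = 5)
  expect_true(all(aln0$seq == root))
  set.seed(NULL)
  aln <- evolve_on_tree(tr, root, rate = 0.5, seed = 5)
  expect_equal(aln$id, tr$tip.label)
  expect_true(all(nchar(aln$seq) == 80))
})

test_that("a star tree yields exchangeable pairwise distances", {
  star <- ape::stree(6, type = "star")
  star$edge.length <- rep(0.3, nrow(star$edge))
  ps <- c()
  for (s in 1:10) {
    aln <- evolve_on_tree(star, random_seq(200), rate = 1, seed = s)
    D <- pdistance_matrix(aln, correction = "none")
    ps <- c(ps, D[upper.tri(D)])
  }
  # all pairs share the same expected p-distance; spread should be modest
  expect_lt(stats::sd(ps) / mean(ps), 0.25)
})

test_that("two planted clades are recovered by tree and bootstrap", {
  sim <- simulate_two_clades(6, 200, n_fixed_diffs = 30, intra_rate = 0.01,
                             seed = 23)
  expect_equal(nrow(sim$alignment), 12L)
  expect_equal(length(sim$truth$fixed_sites), 30L)
  D <- pdistance_matrix(sim$alignment)
  tr <- nj_tree(D)
  out <- separation_statistic(D, sim$truth$partition, tree = tr)
  expect_true(out$monophyletic)
  expect_gt(out$s, 2)
})

test_that("the no-divergence degenerate case reaches the sentinel path", {
  sim <- simulate_two_clades(3, 60, n_fixed_diffs = 0, intra_rate = 0,
                             seed = 31)
  D <- pdistance_matrix(sim$alignment)
  out <- separation_statistic(D, sim$truth$partition)
  expect_equal(out$s, Inf)
})

test_that("synthetic genomes satisfy the gene-table invariants", {
  sim <- simulate_genomes(4, planted_offset = 2, n_decoys = 12, seed = 37)
  genes <- sim$genes
  # table invariants are enforced by the io validator on write/read
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(genes, f)
  expect_silent(back <- read_gene_table(f))
  expect_equal(nrow(back), nrow(genes))
  # planted truth is verifiable by independent scan
  for (k in seq_len(nrow(sim$truth$planted))) {
    row <- sim$truth$planted[k, ]
    g <- genes[genes$genome_id == row$genome_id, ]
    expect_equal(abs(row$offset), 2)
    expect_equal(g$orthogroup[g$locus == row$partner_locus], "og_partner")
    expect_equal(g$architecture[[which(g$locus == row$partner_locus)]],
                 sim$planted_domain)
  }
  # decoy orthogroups never recur across genomes
  decoys <- genes$orthogroup[grepl("^og_dec_", genes$orthogroup)]
  expect_equal(anyDuplicated(decoys), 0L)
})

test_that("redundant sets plant the advertised duplicate structure", {
  sim <- simulate_redundant_set(n_unique = 20, n_dupes = 7, seed = 41)
  expect_equal(nrow(sim$records), 27L)
  seqs <- stats::setNames(sim$records$seq, sim$records$id)
  expect_identical(unname(seqs[sim$truth$dup_id]),
                   unname(seqs[sim$truth$original_id]))
  expect_equal(anyDuplicated(seqs[sprintf("u%03d", 1:20)]), 0L)
})
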