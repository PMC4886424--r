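mk_genome <- function(genome_id, orthogroups, archs = NULL) {
  n <- length(orthogroups)
  if (is.null(archs)) archs <- rep(list(character()), n)
  tibble::tibble(genome_id = genome_id, index = 0:(n - 1L),
                 locus = sprintf("%s_L%d", genome_id, 0:(n - 1L)),
                 strand = "+", protein_id = sprintf("%s_P%d", genome_id,
                                                    0:(n - 1L)),
                 architecture = archs, orthogroup = orthogroups)
}

test_that("neighbor windows are linear, exclusive and index-ordered", {
  g <- mk_genome("g1", sprintf("og%d", 1:5))
  nb <- neighbors(g, "g1_L2", window = 1)
  expect_equal(nb$index, c(1L, 3L))
  nb <- neighbors(g, "g1_L0", window = 3)
  expect_equal(nb$index, 1:3)  # no wraparound
  nb <- neighbors(g, "g1_L2", window = 100)
  expect_equal(nrow(nb), 4L)
  expect_error(neighbors(g, "nope", window = 1),
               class = "cyclascan_missing_locus")
})

test_that("conserved pairs require support in enough genomes", {
  gs <- dplyr::bind_rows(
    mk_genome("g1", c("og_q", "og_p", "og_x1")),
    mk_genome("g2", c("og_x2", "og_q", "og_p")),
    mk_genome("g3", c("og_p", "og_q", "og_x3")))
  pairs <- conserved_neighbor_pairs(gs, "og_q", window = 2, min_genomes = 2)
  expect_equal(pairs$partner_orthogroup, "og_p")
  expect_equal(pairs$n_genomes, 3L)
  expect_equal(nrow(pairs$support[[1]]), 3L)
  expect_true(all(pairs$support[[1]]$offset != 0))

  # a partner in one genome only is dropped at min_genomes = 2
  gs2 <- dplyr::bind_rows(
    mk_genome("g1", c("og_q", "og_once")),
    mk_genome("g2", c("og_q", "og_y")))
  pairs2 <- conserved_neighbor_pairs(gs2, "og_q", window = 2, min_genomes = 2)
  expect_equal(nrow(pairs2), 0L)
  expect_error(conserved_neighbor_pairs(gs2, "og_absent"),
               class = "cyclascan_missing_orthogroup")
})

test_that("non-recurring decoys never survive the conservation filter", {
  sim <- simulate_genomes(3, planted_offset = 2, n_decoys = 10, seed = 42)
  pairs <- conserved_neighbor_pairs(sim$genes, "og_query", window = 22,
                                    min_genomes = 2)
  expect_equal(pairs$partner_orthogroup, "og_partner")
  # brute force: enumerate all (query, neighbor-orthogroup) pairs per genome
  per_genome <- split(sim$genes, sim$genes$genome_id)
  seen <- purrr::map(per_genome, function(g) {
    qi <- g$index[g$orthogroup == "og_query"]
    g$orthogroup[abs(g$index - qi) <= 22 & g$orthogroup != "og_query" &
                   g$orthogroup != ""]
  })
  shared <- names(which(table(unlist(purrr::map(seen, unique))) >= 2))
  expect_setequal(shared, "og_partner")
})

test_that("co-occurring domains come only from cyclase-bearing architectures", {
  expect_equal(cooccurring_domains(
    list("CYC", c("CYC", "PF12697"), "PF00027"), "CYC"), "PF12697")
  expect_equal(cooccurring_domains(list("CYC", "CYC"), "CYC"), character())
  expect_equal(cooccurring_domains(
    list(c("PF00027", "CYC"), c("CYC", "PF00027", "PF01381")), "CYC"),
    c("PF00027", "PF01381"))
})

test_that("associations are emitted per co-occurring partner domain", {
  gs <- dplyr::bind_rows(
    mk_genome("g1", c("og_q", "og_p", "og_z"),
              list("CYC", c("PF12697", "PF00027"), "PF99999")),
    mk_genome("g2", c("og_p", "og_q", "og_z2"),
              list(c("PF12697", "PF00027"), "CYC", "PF99999")))
  pairs <- conserved_neighbor_pairs(gs, "og_q", window = 2, min_genomes = 2)
  cooc <- c("PF00027", "PF12697")
  fmap <- tibble::tibble(
    accession = "PF00027",
    category = "Signal transduction, regulatory processes")
  assoc <- rosetta_associations(pairs, gs, cooc, function_map = fmap)
  # both domains of each supporting partner emit one record each
  expect_equal(nrow(assoc), 4L)
  expect_setequal(assoc$partner_domain, cooc)
  expect_equal(
    unique(assoc$category[assoc$partner_domain == "PF00027"]),
    "Signal transduction, regulatory processes")
  expect_equal(unique(assoc$category[assoc$partner_domain == "PF12697"]),
               "uncategorized")
  # no leakage outside the co-occurring set
  expect_true(all(assoc$partner_domain %in% cooc))
})

test_that("partners whose domains are outside the set yield nothing", {
  gs <- dplyr::bind_rows(
    mk_genome("g1", c("og_q", "og_p"), list("CYC", "PF99999")),
    mk_genome("g2", c("og_q", "og_p"), list("CYC", "PF99999")))
  pairs <- conserved_neighbor_pairs(gs, "og_q", window = 1, min_genomes = 2)
  assoc <- rosetta_associations(pairs, gs, c("PF00027"))
  expect_equal(nrow(assoc), 0L)
})

test_that("association summaries count distinct entities", {
  assoc <- tibble::tibble(
    query_protein = c("P1", "P1", "P2"),
    query_locus = c("L1", "L1", "L2"),
    partner_locus = c("N1", "N2", "N3"),
    partner_domain = c("PF1", "PF2", "PF1"),
    category = "c")
  s <- rebuild_association_summary(assoc)
  expect_equal(s$n_associations, 3L)
  expect_equal(s$n_query_proteins, 2L)
  expect_equal(s$n_partner_domains, 2L)
  expect_equal(rebuild_association_summary(assoc[0, ]),
               tibble::tibble(n_associations = 0L, n_query_proteins = 0L,
                              n_partner_domains = 0L))
  # duplicated rows count once
  expect_equal(rebuild_association_summary(assoc[c(1, 1, 2, 3), ]),
               s)
})

test_that("widening the window never removes associations", {
  sim <- simulate_genomes(4, planted_offset = 3, n_decoys = 8, seed = 12)
  cooc <- sim$planted_domain
  get_assoc <- function(w) {
    pairs <- conserved_neighbor_pairs(sim$genes, "og_query", window = w,
                                      min_genomes = 2)
    rosetta_associations(pairs, sim$genes, cooc)
  }
  a_small <- get_assoc(3)
  a_big <- get_assoc(9)
  expect_true(nrow(a_big) >= nrow(a_small))
  expect_true(all(do.call(paste, a_small) %in% do.call(paste, a_big)))
  # below the planted offset there is nothing to find
  pairs_narrow <- conserved_neighbor_pairs(sim$genes, "og_query", window = 2,
                                           min_genomes = 2)
  expect_equal(nrow(rosetta_associations(pairs_narrow, sim$genes, cooc)), 0L)
})

test_that("results are invariant under genome input order", {
  sim <- simulate_genomes(3, planted_offset = 2, n_decoys = 6, seed = 19)
  genes_rev <- dplyr::arrange(sim$genes, dplyr::desc(genome_id), index)
  p1 <- conserved_neighbor_pairs(sim$genes, "og_query", window = 5,
                                 min_genomes = 2)
  p2 <- conserved_neighbor_pairs(genes_rev, "og_query", window = 5,
                                 min_genomes = 2)
  a1 <- rosetta_associations(p1, sim$genes, sim$planted_domain)
  a2 <- rosetta_associations(p2, genes_rev, sim$planted_domain)
  expect_equal(a1, a2)
})
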