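# Seeded synthetic-data generators. Each generator is a pure function of
# (parameters, seed) and returns ground truth alongside the data, so
# every analysis stage can be scored against planted features without
# external downloads.

random_protein <- function(length) {
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

mutate_residue <- function(res) {
  sample(setdiff(AA20, res), 1L)
}

# canonical planted residues for each class label
planted_residues <- function(class_label, has_ts2) {
  res <- switch(class_label,
    "AC/GC" = c(MB1 = "D", MB2 = "D", SS1 = "K", SS2 = "E", TS1 = "R", TS2 = "R"),
    "GC"    = c(MB1 = "D", MB2 = "D", SS1 = "E", SS2 = "K", TS1 = "H", TS2 = "R"),
    rlang::abort("class_label must be 'AC/GC' or 'GC'",
                 class = "cyclascan_bad_class"))
  if (!has_ts2) res <- res[names(res) != "TS2"]
  res
}

#' Simulate a gap-free protein family with planted catalytic residues
#'
#' The reference row carries the canonical residues of `class_label` at
#' the anchor positions (`AC/GC`: Asp-Asp metal binding, Lys-Glu
#' substrate pair, Arg transition state; `GC`: Asp-Asp, Glu-Lys, His(-Arg)).
#' Each query is a copy of the reference mutated i.i.d.: non-key sites
#' with probability `mut_rate`, key (anchored) sites with probability
#' `key_mut_rate`, always to a uniformly chosen different residue. No
#' indels are simulated, so alignment columns coincide with residue
#' positions.
#'
#' @param n Number of query sequences.
#' @param length Sequence length (default 250, a typical length for the
#'   single-domain proteins this emulates).
#' @param anchor An [anchor_config()]; positions must fit in `length`.
#' @param class_label `"AC/GC"` or `"GC"`.
#' @param mut_rate Per-site substitution probability at non-key sites.
#' @param key_mut_rate Per-site substitution probability at key sites.
#' @param seed Integer RNG seed (mandatory).
#' @return List of class `nc_sim_family`: `alignment` (reference row
#'   first), `truth` (tibble: `seq_id`, `position`, `site`, `planted`,
#'   `observed`, `mutated`), plus the generating parameters.
#' @export
simulate_family <- function(n, length = 250, anchor, class_label,
                            mut_rate = 0.2, key_mut_rate = 0, seed) {
  stopifnot(inherits(anchor, "anchor_config"),
            mut_rate >= 0, mut_rate <= 1, key_mut_rate >= 0, key_mut_rate <= 1)
  if (any(anchor$positions > length)) {
    rlang::abort("anchor positions exceed sequence length",
                 class = "cyclascan_position_out_of_range")
  }
  planted <- planted_residues(class_label, "TS2" %in% names(anchor$positions))
  planted <- planted[names(anchor$positions)]
  withr::with_seed(seed, {
    ref <- strsplit(random_protein(length), "", fixed = TRUE)[[1]]
    ref[anchor$positions] <- planted
    key_sites <- unname(anchor$positions)
    truth <- list()
    seqs <- character(n)
    ids <- sprintf("q%03d", seq_len(n))
    for (i in seq_len(n)) {
      s <- ref
      for (p in seq_len(length)) {
        rate <- if (p %in% key_sites) key_mut_rate else mut_rate
        if (rate > 0 && stats::runif(1) < rate) s[p] <- mutate_residue(s[p])
      }
      seqs[i] <- paste(s, collapse = "")
      truth[[i]] <- tibble::tibble(
        seq_id = ids[i], position = names(anchor$positions),
        site = key_sites, planted = unname(planted),
        observed = s[key_sites], mutated = s[key_sites] != unname(planted))
    }
  })
  aln <- tibble::tibble(id = c(anchor$ref_id, ids), desc = "",
                        seq = c(paste(ref, collapse = ""), seqs))
  structure(list(alignment = aln, truth = dplyr::bind_rows(truth),
                 anchor = anchor, class_label = class_label,
                 mut_rate = mut_rate, key_mut_rate = key_mut_rate,
                 seed = seed),
            class = "nc_sim_family")
}

#' Evolve a root sequence along a tree
#'
#' Simple Poisson-style substitution process: along a branch of length
#' `t` each site substitutes with probability `1 - exp(-rate * t)`,
#' uniformly to one of the other 19 residues. No indels; leaves are
#' emitted as an alignment. A uniform substitution model (no empirical
#' rate matrix) is deliberate - it is sufficient for the distance and
#' topology properties asserted downstream.
#'
#' @param tree An `ape::phylo` tree with non-negative branch lengths.
#' @param root_sequence Residue string at the root.
#' @param rate Substitution rate per site per unit branch length.
#' @param seed Integer RNG seed.
#' @return Alignment tibble with one row per tip, in tip order.
#' @export
evolve_on_tree <- function(tree, root_sequence, rate, seed) {
  stopifnot(inherits(tree, "phylo"), rate >= 0)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    rlang::abort("tree must have non-negative branch lengths",
                 class = "cyclascan_bad_tree")
  }
  n <- length(tree$tip.label)
  root <- n + 1L
  chars <- strsplit(toupper(root_sequence), "", fixed = TRUE)[[1]]
  seqs <- vector("list", n + tree$Nnode)
  seqs[[root]] <- chars
  edge_order <- ape::reorder.phylo(tree, "cladewise")
  withr::with_seed(seed, {
    for (e in seq_len(nrow(edge_order$edge))) {
      p <- edge_order$edge[e, 1]; ch <- edge_order$edge[e, 2]
      t <- edge_order$edge.length[e]
      s <- seqs[[p]]
      if (rate > 0 && t > 0) {
        psub <- 1 - exp(-rate * t)
        hit <- which(stats::runif(length(s)) < psub)
        for (k in hit) s[k] <- mutate_residue(s[k])
      }
      seqs[[ch]] <- s
    }
  })
  tibble::tibble(id = tree$tip.label, desc = "",
                 seq = purrr::map_chr(seqs[seq_len(n)], paste, collapse = ""))
}

#' Simulate two diverged clades
#'
#' Two ancestral sequences differ at exactly `n_fixed_diffs` sites; each
#' leaf mutates from its clade's ancestor i.i.d. at `intra_rate` per
#' site. This emulates the established-versus-predicted cyclase split:
#' fixed inter-clade differences on a long stem, light within-clade
#' variation.
#'
#' @param n_per_clade Leaves per clade.
#' @param length Sequence length (default 250).
#' @param n_fixed_diffs Number of sites at which the two ancestors differ.
#' @param intra_rate Per-site substitution probability within a clade.
#' @param seed Integer RNG seed.
#' @return List of class `nc_sim_clades`: `alignment` (clade A leaves
#'   then clade B), `truth` (list with `partition` tibble mapping
#'   `seq_id` to `clade`, and `fixed_sites`), and the parameters.
#' @export
simulate_two_clades <- function(n_per_clade, length = 250, n_fixed_diffs,
                                intra_rate, seed) {
  stopifnot(n_fixed_diffs <= length, n_fixed_diffs >= 0,
            intra_rate >= 0, intra_rate <= 1, n_per_clade >= 1)
  withr::with_seed(seed, {
    anc_a <- strsplit(random_protein(length), "", fixed = TRUE)[[1]]
    fixed_sites <- sort(sample.int(length, n_fixed_diffs))
    anc_b <- anc_a
    for (p in fixed_sites) anc_b[p] <- mutate_residue(anc_b[p])
    make_leaf <- function(anc) {
      s <- anc
      if (intra_rate > 0) {
        hit <- which(stats::runif(length) < intra_rate)
        for (k in hit) s[k] <- mutate_residue(s[k])
      }
      paste(s, collapse = "")
    }
    ids_a <- sprintf("A%02d", seq_len(n_per_clade))
    ids_b <- sprintf("B%02d", seq_len(n_per_clade))
    seqs_a <- vapply(seq_len(n_per_clade), function(i) make_leaf(anc_a), "")
    seqs_b <- vapply(seq_len(n_per_clade), function(i) make_leaf(anc_b), "")
  })
  aln <- tibble::tibble(id = c(ids_a, ids_b), desc = "",
                        seq = c(seqs_a, seqs_b))
  partition <- tibble::tibble(label = c(ids_a, ids_b),
                              block = rep(c("A", "B"), each = n_per_clade))
  structure(list(alignment = aln,
                 truth = list(partition = partition,
                              fixed_sites = fixed_sites),
                 n_per_clade = n_per_clade, length = length,
                 n_fixed_diffs = n_fixed_diffs, intra_rate = intra_rate,
                 seed = seed),
            class = "nc_sim_clades")
}

#' Simulate genomes with a planted conserved neighbor gene
#'
#' Each genome carries one query gene (orthogroup `og_query`, the cyclase
#' accession as its architecture), one partner gene at index offset
#' `planted_offset` (sign chosen at random) carrying `planted_domain`
#' (orthogroup `og_partner`), and `n_decoys` decoy genes whose
#' orthogroups never recur across genomes and whose domains are drawn
#' from a decoy pool disjoint from any co-occurring set. Remaining
#' positions, if any, are filler genes with no domain assignments.
#'
#' @param n_genomes Number of genomes.
#' @param genes_per_genome Genes per genome; default `n_decoys + 2`.
#' @param planted_offset Index distance between query and partner.
#' @param planted_domain Domain accession planted on the partner.
#' @param n_decoys Decoy genes per genome.
#' @param seed Integer RNG seed.
#' @param cyclase_accession Accession used for the query architecture.
#' @return List of class `nc_sim_genomes`: `genes` (gene-record tibble
#'   across all genomes), `truth` (tibble: `genome_id`, `query_locus`,
#'   `partner_locus`, `offset`; plus `decoy_orthogroups`), and the
#'   parameters.
#' @export
simulate_genomes <- function(n_genomes, genes_per_genome = NULL,
                             planted_offset = 2, planted_domain = "PF00027",
                             n_decoys = 20, seed,
                             cyclase_accession = "PF00211") {
  if (is.null(genes_per_genome)) genes_per_genome <- n_decoys + 2L
  stopifnot(planted_offset >= 1, planted_offset < genes_per_genome,
            n_decoys + 2L <= genes_per_genome, n_genomes >= 1)
  withr::with_seed(seed, {
    tables <- purrr::map(seq_len(n_genomes), function(g) {
      gid <- sprintf("g%02d", g)
      ng <- genes_per_genome
      # place query so that a partner at +/- planted_offset fits
      valid_q <- which(vapply(0:(ng - 1L), function(q) {
        (q - planted_offset >= 0L) || (q + planted_offset <= ng - 1L)
      }, logical(1))) - 1L
      qi <- valid_q[sample.int(length(valid_q), 1L)]
      dir <- sample(c(-1L, 1L), 1L)
      if (qi + dir * planted_offset < 0L || qi + dir * planted_offset > ng - 1L) {
        dir <- -dir
      }
      pi <- qi + dir * planted_offset
      idx <- 0:(ng - 1L)
      locus <- sprintf("%s_L%03d", gid, idx)
      arch <- rep(list(character()), ng)
      og <- sprintf("og_fill_%s_%03d", gid, idx)
      protein <- sprintf("%s_P%03d", gid, idx)
      arch[[qi + 1L]] <- cyclase_accession
      og[qi + 1L] <- "og_query"
      arch[[pi + 1L]] <- planted_domain
      og[pi + 1L] <- "og_partner"
      free <- setdiff(idx, c(qi, pi))
      decoy_slots <- free[sample.int(length(free), n_decoys)]
      for (k in seq_along(decoy_slots)) {
        slot <- decoy_slots[k] + 1L
        arch[[slot]] <- sprintf("PFDEC%03d", sample.int(500, 1L))
        og[slot] <- sprintf("og_dec_%s_%03d", gid, k)
      }
      tibble::tibble(genome_id = gid, index = idx, locus = locus,
                     strand = sample(c("+", "-"), ng, replace = TRUE),
                     protein_id = protein, architecture = arch,
                     orthogroup = og,
                     .query = idx == qi, .partner = idx == pi)
    })
  })
  genes <- dplyr::bind_rows(tables)
  truth <- genes |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(
      query_locus = .data$locus[.data$.query],
      partner_locus = .data$locus[.data$.partner],
      offset = .data$index[.data$.partner] - .data$index[.data$.query],
      .groups = "drop")
  decoys <- genes$orthogroup[grepl("^og_dec_", genes$orthogroup)]
  genes <- dplyr::select(genes, -".query", -".partner")
  validate_gene_table(genes)
  structure(list(genes = genes,
                 truth = list(planted = truth, decoy_orthogroups = decoys),
                 n_genomes = n_genomes, genes_per_genome = genes_per_genome,
                 planted_offset = planted_offset,
                 planted_domain = planted_domain, n_decoys = n_decoys,
                 cyclase_accession = cyclase_accession, seed = seed),
            class = "nc_sim_genomes")
}

#' Simulate a redundant sequence set with planted exact duplicates
#'
#' Generates `n_unique` distinct random sequences and adds `n_dupes`
#' exact copies (of uniformly chosen originals) under fresh ids, so the
#' set collapses back to exactly `n_unique` clusters under exact
#' deduplication. Defaults mirror the structure of building a
#' 53-protein non-redundant set from 84 retrieved records.
#'
#' @param n_unique Number of distinct sequences (default 53).
#' @param n_dupes Number of planted duplicates (default 31).
#' @param length Sequence length.
#' @param seed Integer RNG seed.
#' @return List of class `nc_sim_redundant`: `records` tibble and
#'   `truth` (tibble `dup_id` -> `original_id`).
#' @export
simulate_redundant_set <- function(n_unique = 53, n_dupes = 31, length = 120,
                                   seed) {
  withr::with_seed(seed, {
    repeat {
      seqs <- vapply(seq_len(n_unique), function(i) random_protein(length), "")
      if (!anyDuplicated(seqs)) break
    }
    origin <- sample.int(n_unique, n_dupes, replace = TRUE)
  })
  ids <- sprintf("u%03d", seq_len(n_unique))
  dup_ids <- sprintf("dup%03d", seq_len(n_dupes))
  records <- tibble::tibble(id = c(ids, dup_ids), desc = "",
                            seq = c(seqs, seqs[origin]))
  structure(list(records = records,
                 truth = tibble::tibble(dup_id = dup_ids,
                                        original_id = ids[origin]),
                 n_unique = n_unique, n_dupes = n_dupes, seed = seed),
            class = "nc_sim_redundant")
}
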