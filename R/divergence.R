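# Evolutionary divergence analysis: pairwise distances, neighbor-joining
# tree construction with deterministic tie-breaking, column-bootstrap
# support with collapsing, and a two-cluster separation statistic.

#' Pairwise distance matrix from an alignment
#'
#' Computes p-distances (proportion of mismatched residues over shared
#' non-gap columns) with optional Poisson correction
#' `d = -ln(1 - p)` for multiple hits. Gap handling is pairwise deletion
#' by default (each pair compared over the columns where both have
#' residues); complete deletion drops every column containing any gap
#' before comparison.
#'
#' @param aln Alignment tibble with at least two sequences.
#' @param correction `"poisson"` (default) or `"none"`.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return A symmetric numeric matrix with zero diagonal, labelled by
#'   sequence id.
#' @examples
#' aln <- tibble::tibble(id = c("a", "b"), seq = c("AAAA", "AAAT"))
#' pdistance_matrix(aln, correction = "none")
#' @export
pdistance_matrix <- function(aln, correction = c("poisson", "none"),
                             deletion = c("pairwise", "complete")) {
  correction <- match.arg(correction)
  deletion <- match.arg(deletion)
  check_sequence_table(aln, aligned = TRUE)
  if (nrow(aln) < 2L) {
    rlang::abort("need at least two sequences", class = "cyclascan_too_few")
  }
  m <- alignment_matrix(aln)
  if (deletion == "complete") {
    keep <- colSums(m == "-") == 0L
    if (!any(keep)) {
      rlang::abort("no gap-free columns under complete deletion",
                   class = "cyclascan_no_shared_columns")
    }
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- m[i, ] != "-" & m[j, ] != "-"
      ns <- sum(shared)
      if (ns == 0L) {
        rlang::abort(sprintf(
          "sequences '%s' and '%s' share no non-gap columns",
          rownames(m)[i], rownames(m)[j]),
          class = "cyclascan_no_shared_columns")
      }
      p <- sum(m[i, shared] != m[j, shared]) / ns
      if (correction == "poisson") {
        if (p >= 1) {
          rlang::abort(sprintf(
            "Poisson correction saturated (p = 1) for '%s' vs '%s'",
            rownames(m)[i], rownames(m)[j]),
            class = "cyclascan_saturated_distance")
        }
        d <- -log(1 - p)
      } else {
        d <- p
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

check_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D) || is.null(rownames(D))) {
    rlang::abort("distance matrix must be square with labels",
                 class = "cyclascan_bad_matrix")
  }
  if (max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0) || any(!is.finite(D)) ||
      any(D < 0)) {
    rlang::abort("distance matrix must be symmetric, finite, non-negative with zero diagonal",
                 class = "cyclascan_bad_matrix")
  }
  invisible(D)
}

fmt_len <- function(x) sprintf("%.12g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion. Ties in
#' the Q minimisation are broken by the smallest (i, j) pair in the
#' current node order, so the output is fully deterministic. Negative
#' branch-length estimates are clamped to 0 without redistribution. Two
#' taxa give a single cherry whose tip-to-tip path length equals their
#' distance; three taxa get the closed-form star lengths
#' `v_i = (d_ij + d_ik - d_jk) / 2`.
#'
#' @param D Labelled symmetric distance matrix (see [pdistance_matrix()]).
#' @return An unrooted `ape::phylo` tree with the matrix labels as tips.
#' @export
nj_tree <- function(D) {
  check_distance_matrix(D)
  labels <- rownames(D)
  n <- length(labels)
  if (n < 2L) rlang::abort("need at least two taxa", class = "cyclascan_too_few")
  if (n == 2L) {
    h <- D[1, 2] / 2
    txt <- sprintf("(%s:%s,%s:%s);", labels[1], fmt_len(h), labels[2], fmt_len(h))
    return(ape::read.tree(text = txt))
  }
  frags <- labels
  Dm <- unname(D)
  while (length(frags) > 3L) {
    m <- length(frags)
    R <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(R, R, "+")
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    d <- Dm[i, j]
    li <- max(0, d / 2 + (R[i] - R[j]) / (2 * (m - 2)))
    lj <- max(0, d - (d / 2 + (R[i] - R[j]) / (2 * (m - 2))))
    new_frag <- sprintf("(%s:%s,%s:%s)", frags[i], fmt_len(li),
                        frags[j], fmt_len(lj))
    others <- setdiff(seq_len(m), c(i, j))
    new_d <- (Dm[i, others] + Dm[j, others] - d) / 2
    Dm <- Dm[others, others, drop = FALSE]
    Dm <- rbind(cbind(Dm, new_d), c(new_d, 0))
    frags <- c(frags[others], new_frag)
  }
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  v <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  v <- pmax(v, 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", frags[1], fmt_len(v[1]),
                 frags[2], fmt_len(v[2]), frags[3], fmt_len(v[3]))
  ape::read.tree(text = txt)
}

# tip label sets under each node, rooted at the (trifurcating) root that
# ape assigns to an unrooted tree
node_tip_sets <- function(tr) {
  tr2 <- ape::reorder.phylo(tr, "postorder")
  n <- length(tr2$tip.label)
  sets <- vector("list", n + tr2$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tr2$tip.label[i]
  for (e in seq_len(nrow(tr2$edge))) {
    p <- tr2$edge[e, 1]; c <- tr2$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  sets
}

# canonical strings for the non-trivial bipartitions induced by internal
# edges; the stored block is the one not containing `ref_label`
tree_bipartitions <- function(tr, ref_label = NULL) {
  labs <- tr$tip.label
  if (is.null(ref_label)) ref_label <- sort(labs)[1]
  n <- length(labs)
  root <- n + 1L
  sets <- node_tip_sets(tr)
  internal <- setdiff(unique(tr$edge[, 1]), integer()) # all internal nodes
  out <- character()
  nodes <- integer()
  for (v in setdiff((n + 1L):(n + tr$Nnode), root)) {
    block <- sets[[v]]
    if (length(block) < 2L || length(block) > n - 2L) next
    if (ref_label %in% block) block <- setdiff(labs, block)
    out <- c(out, paste(sort(block), collapse = "|"))
    nodes <- c(nodes, v)
  }
  tibble::tibble(node = nodes, bipartition = out)
}

canonical_block <- function(block, labels, ref_label = NULL) {
  if (is.null(ref_label)) ref_label <- sort(labels)[1]
  if (ref_label %in% block) block <- setdiff(labels, block)
  paste(sort(block), collapse = "|")
}

# contract the internal edges ending in the given child nodes, producing
# polytomies; collapsed edge lengths are discarded
collapse_nodes <- function(tr, drop_nodes, node_labels = NULL) {
  n <- length(tr$tip.label)
  root <- n + 1L
  children <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  build <- function(v) {
    parts <- character()
    for (e in children[[as.character(v)]]) {
      ch <- tr$edge[e, 2]
      len <- tr$edge.length[e]
      if (ch <= n) {
        parts <- c(parts, sprintf("%s:%s", tr$tip.label[ch], fmt_len(len)))
      } else if (ch %in% drop_nodes) {
        parts <- c(parts, build_children(ch))
      } else {
        lab <- if (is.null(node_labels)) "" else node_labels[[as.character(ch)]]
        parts <- c(parts, sprintf("(%s)%s:%s",
                                  paste(build_list(ch), collapse = ","),
                                  lab, fmt_len(len)))
      }
    }
    parts
  }
  build_children <- function(v) paste(build(v), collapse = ",")
  build_list <- function(v) build(v)
  txt <- sprintf("(%s);", paste(build(root), collapse = ","))
  ape::read.tree(text = txt)
}

#' Neighbor-joining tree with column-bootstrap support
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement (to the original length) `n_reps` times, rebuilds the NJ
#' tree per replicate, and scores each internal edge of the full-data
#' tree by the percentage of replicate trees containing its bipartition.
#' Edges supported below `cutoff` are collapsed into polytomies.
#' Replicates whose resampled alignment yields an undefined distance
#' (no shared columns, or a saturated Poisson correction) are discarded
#' and counted; more than 50 percent discarded is an error.
#'
#' If every pairwise distance in the full data is zero the tree is
#' entirely unresolved: a single star polytomy is returned with no
#' support values.
#'
#' @param aln Alignment tibble.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed (mandatory; resampling is fully seeded).
#' @param correction Distance correction passed to [pdistance_matrix()].
#' @param cutoff Support percentage below which internal edges are
#'   collapsed (default 50).
#' @return Object of class `nc_boot`: list with `tree` (collapsed
#'   `phylo`, integer supports as internal node labels), `full_tree`,
#'   `support` (tibble of bipartitions and supports), `n_reps`,
#'   `n_discarded`, `cutoff` and `seed`. [tidy()] returns the support
#'   table, [glance()] a one-row summary.
#' @export
bootstrap_support <- function(aln, n_reps, seed,
                              correction = c("poisson", "none"), cutoff = 50) {
  correction <- match.arg(correction)
  stopifnot(n_reps >= 1)
  check_sequence_table(aln, aligned = TRUE)
  D <- pdistance_matrix(aln, correction = correction)
  if (all(D == 0)) {
    txt <- sprintf("(%s);",
                   paste(sprintf("%s:0", rownames(D)), collapse = ","))
    res <- structure(list(tree = ape::read.tree(text = txt), full_tree = NULL,
                          support = tibble::tibble(bipartition = character(),
                                                   support = double()),
                          n_reps = n_reps, n_discarded = 0L,
                          cutoff = cutoff, seed = seed),
                     class = "nc_boot")
    return(res)
  }
  full <- nj_tree(D)
  bip <- tree_bipartitions(full)
  counts <- stats::setNames(rep(0L, nrow(bip)), bip$bipartition)
  m <- alignment_matrix(aln)
  L <- ncol(m)
  discarded <- 0L
  withr::with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- matrix_to_alignment(m[, cols, drop = FALSE])
      Dr <- tryCatch(pdistance_matrix(rep_aln, correction = correction),
                     error = function(e) NULL)
      if (is.null(Dr)) {
        discarded <- discarded + 1L
        next
      }
      tr <- nj_tree(Dr)
      found <- tree_bipartitions(tr)$bipartition
      hit <- bip$bipartition %in% found
      counts[hit] <- counts[hit] + 1L
    }
  })
  if (discarded > n_reps / 2) {
    rlang::abort(sprintf(
      "%d of %d bootstrap replicates discarded (undefined distances)",
      discarded, n_reps), class = "cyclascan_bootstrap_degenerate")
  }
  used <- n_reps - discarded
  support <- 100 * counts / used
  bip$support <- unname(support)
  drop <- bip$node[bip$support < cutoff]
  node_labels <- stats::setNames(
    as.character(as.integer(round(bip$support))), as.character(bip$node))
  tree <- collapse_nodes(full, drop, node_labels = node_labels)
  structure(list(tree = tree, full_tree = full,
                 support = tibble::tibble(bipartition = bip$bipartition,
                                          support = bip$support),
                 n_reps = n_reps, n_discarded = discarded,
                 cutoff = cutoff, seed = seed),
            class = "nc_boot")
}

#' @export
print.nc_boot <- function(x, ...) {
  cat("<nc_boot>", length(x$tree$tip.label), "tips,", x$n_reps,
      "replicates (", x$n_discarded, "discarded ), cutoff", x$cutoff, "%\n")
  invisible(x)
}

#' Tidiers for bootstrap results
#'
#' @param x An `nc_boot` object.
#' @param ... Unused.
#' @return `tidy()` returns the bipartition/support tibble; `glance()` a
#'   one-row summary.
#' @method tidy nc_boot
#' @export
tidy.nc_boot <- function(x, ...) x$support

#' @rdname tidy.nc_boot
#' @method glance nc_boot
#' @export
glance.nc_boot <- function(x, ...) {
  tibble::tibble(n_tips = length(x$tree$tip.label), n_reps = x$n_reps,
                 n_discarded = x$n_discarded,
                 n_edges_tested = nrow(x$support),
                 n_edges_retained = sum(x$support$support >= x$cutoff),
                 mean_support = if (nrow(x$support)) mean(x$support$support) else NA_real_)
}

#' Plot a (bootstrap) tree
#'
#' Thin wrapper around `ape::plot.phylo` that shows support values on the
#' internal nodes.
#'
#' @param x An `nc_boot` object or `phylo` tree.
#' @param ... Passed to `ape::plot.phylo`.
#' @return The tree, invisibly.
#' @export
plot_tree <- function(x, ...) {
  tr <- if (inherits(x, "nc_boot")) x$tree else x
  ape::plot.phylo(tr, ...)
  if (!is.null(tr$node.label)) ape::nodelabels(tr$node.label, frame = "none")
  invisible(tr)
}

#' Two-cluster separation statistic
#'
#' `S = mean between-block distance / mean within-block distance` for a
#' two-block partition of the taxa. `S` near 1 indicates no separation;
#' large `S` indicates two well-separated clusters. If all within-block
#' distances are zero, `S` is reported as `Inf`. If one block has fewer
#' than two members, the within mean is computed over the other block
#' only and the result is flagged. When a tree is supplied, the verdict
#' states whether the partition coincides with one of its bipartitions
#' (i.e. both blocks are monophyletic).
#'
#' @param D Labelled distance matrix.
#' @param partition Tibble with columns `label` and `block` (exactly two
#'   distinct block values), or a named vector mapping label to block.
#' @param tree Optional `phylo` tree on the same labels.
#' @return One-row tibble: `s`, `between_mean`, `within_mean`,
#'   `monophyletic` (NA without a tree), `small_block`.
#' @export
separation_statistic <- function(D, partition, tree = NULL) {
  check_distance_matrix(D)
  if (!is.data.frame(partition)) {
    partition <- tibble::tibble(label = names(partition),
                                block = unname(partition))
  }
  stopifnot(all(c("label", "block") %in% names(partition)))
  blocks <- split(partition$label, partition$block)
  if (length(blocks) != 2L || any(lengths(blocks) == 0L)) {
    rlang::abort("partition must have exactly two non-empty blocks",
                 class = "cyclascan_bad_partition")
  }
  if (!all(partition$label %in% rownames(D))) {
    rlang::abort("partition labels missing from distance matrix",
                 class = "cyclascan_bad_partition")
  }
  a <- blocks[[1]]; b <- blocks[[2]]
  between <- mean(D[a, b, drop = FALSE])
  within_vals <- function(block) {
    if (length(block) < 2L) return(numeric())
    sub <- D[block, block, drop = FALSE]
    sub[upper.tri(sub)]
  }
  small_block <- min(lengths(blocks)) < 2L && max(lengths(blocks)) >= 2L
  wv <- c(within_vals(a), within_vals(b))
  within <- if (length(wv) == 0L) NA_real_ else mean(wv)
  s <- if (is.na(within)) NA_real_ else if (within == 0) Inf else between / within
  mono <- NA
  if (!is.null(tree)) {
    want <- canonical_block(a, rownames(D))
    mono <- want %in% tree_bipartitions(tree, ref_label = sort(rownames(D))[1])$bipartition
    # a two-block split where one block is a single leaf is trivially
    # compatible with any tree
    if (min(lengths(blocks)) == 1L) mono <- TRUE
  }
  tibble::tibble(s = s, between_mean = between, within_mean = within,
                 monophyletic = mono, small_block = small_block)
}
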