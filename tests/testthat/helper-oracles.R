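# Test fixtures built in code and independent brute-force oracles.

mk_aln <- function(seqs, ids = sprintf("s%d", seq_along(seqs))) {
  tibble::tibble(id = ids, desc = "", seq = seqs)
}

default_anchor <- function(ts2 = FALSE) {
  pos <- c(MB1 = 10, MB2 = 54, SS1 = 30, SS2 = 83, TS1 = 70)
  if (ts2) pos <- c(pos, TS2 = 95)
  anchor_config("REF", pos)
}

# brute-force motif scan: test every substring
brute_motif_scan <- function(seq, motif = "GGDEF") {
  k <- nchar(motif)
  n <- nchar(seq)
  if (n < k) return(integer())
  which(vapply(seq_len(n - k + 1L),
               function(i) substr(seq, i, i + k - 1L) == motif,
               logical(1)))
}

# brute-force global alignment at match +1 / mismatch 0 / linear gap -1:
# enumerates all alignments recursively, returning the optimal score and,
# among optimal alignments, the attainable (matches, length) pairs
brute_global <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$stats <- list()
  rec <- function(i, j, score, matches, len) {
    if (i > length(x) && j > length(y)) {
      if (score > best$score) {
        best$score <- score
        best$stats <- list(c(matches, len))
      } else if (score == best$score) {
        best$stats <- c(best$stats, list(c(matches, len)))
      }
      return(invisible())
    }
    if (i <= length(x) && j <= length(y)) {
      m <- x[i] == y[j]
      rec(i + 1L, j + 1L, score + m, matches + m, len + 1L)
    }
    if (i <= length(x)) rec(i + 1L, j, score - 1, matches, len + 1L)
    if (j <= length(y)) rec(i, j + 1L, score - 1, matches, len + 1L)
  }
  rec(1L, 1L, 0, 0L, 0L)
  list(score = best$score,
       stats = unique(best$stats))
}

random_seq <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                       "I", "K", "L", "M", "N", "P", "Q",
                                       "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# expected mislabel set from a simulate_family truth table: a query loses
# its planted label iff a substrate-specifying site mutated (a mutated
# residue can never equal the planted one) or both metal-binding
# aspartates were lost
expected_mislabels <- function(truth) {
  agg <- dplyr::group_by(truth, .data$seq_id)
  dplyr::summarise(agg,
    mislabel = any(.data$mutated[.data$position %in% c("SS1", "SS2")]) ||
      all(.data$mutated[.data$position %in% c("MB1", "MB2")]),
    .groups = "drop")
}

# canonical string for one block of a two-block split (mirrors the
# package's internal convention: the block without the alphabetically
# first label, sorted, pipe-joined)
canon_split <- function(block, labels) {
  ref <- sort(labels)[1]
  if (ref %in% block) block <- setdiff(labels, block)
  paste(sort(block), collapse = "|")
}
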