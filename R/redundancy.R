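# Exact and threshold-based sequence-identity clustering for building
# non-redundant and representative sequence sets.

#' Collapse exact duplicate sequences
#'
#' Groups records whose residue strings are identical (after uppercase
#' normalisation). The representative of each cluster is its
#' lexicographically smallest id; clusters are ordered by representative.
#'
#' @param records Tibble of unaligned sequences (`id`, `seq`).
#' @return A tibble with one row per cluster: `representative`, `members`
#'   (list-column of ids, representative included) and `n`.
#' @examples
#' recs <- tibble::tibble(id = c("a", "b", "c"), seq = c("MKR", "MKR", "MKD"))
#' dedup_exact(recs)
#' @export
dedup_exact <- function(records) {
  check_sequence_table(records, aligned = FALSE)
  key <- toupper(records$seq)
  groups <- split(records$id, key)
  out <- purrr::map(groups, function(ids) {
    ids <- sort(ids)
    tibble::tibble(representative = ids[1], members = list(ids),
                   n = length(ids))
  }) |> dplyr::bind_rows()
  dplyr::arrange(out, .data$representative)
}

# Needleman-Wunsch global alignment with match +1, mismatch 0, linear gap
# -1; returns the number of matched columns and the alignment length of
# one optimal alignment (deterministic traceback: diagonal > up > left).
nw_align_stats <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1] <- -(0:n)
  S[1, ] <- -(0:m)
  for (i in seq_len(n)) {
    diag_scores <- S[i, 1:m] + (x[i] == y)
    up0 <- S[i, 2:(m + 1)] - 1
    row <- numeric(m)
    prev <- S[i + 1L, 1L]
    for (j in seq_len(m)) {
      best <- max(diag_scores[j], up0[j], prev - 1)
      row[j] <- best
      prev <- best
    }
    S[i + 1L, 2:(m + 1)] <- row
  }
  # traceback
  i <- n; j <- m; matches <- 0L; len <- 0L
  while (i > 0L && j > 0L) {
    if (S[i + 1L, j + 1L] == S[i, j] + (x[i] == y[j])) {
      matches <- matches + (x[i] == y[j])
      i <- i - 1L; j <- j - 1L
    } else if (S[i + 1L, j + 1L] == S[i, j + 1L] - 1) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    len <- len + 1L
  }
  len <- len + i + j
  list(matches = as.integer(matches), length = as.integer(len),
       score = S[n + 1L, m + 1L])
}

#' Global percent identity between two sequences
#'
#' Aligns the sequences with the Needleman-Wunsch algorithm (match +1,
#' mismatch 0, linear gap penalty -1) and reports
#' `100 * matches / alignment length`. Using the alignment length as the
#' denominator is conservative and makes the measure symmetric.
#'
#' @param a,b Unaligned residue strings (non-empty).
#' @return Percent identity in `[0, 100]`.
#' @examples
#' global_identity("AAAA", "AATA")  # 75
#' @export
global_identity <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) {
    rlang::abort("cannot compute identity of an empty sequence",
                 class = "cyclascan_empty_sequence")
  }
  st <- nw_align_stats(toupper(a), toupper(b))
  100 * st$matches / st$length
}

#' Greedy identity clustering at a threshold
#'
#' A reproducible stand-in for centroid-style clustering tools: records
#' are processed in order of decreasing length (ties broken by id); each
#' record joins the first existing cluster whose representative shares at
#' least `threshold_pct` global identity with it, otherwise it founds a
#' new cluster.
#'
#' @param records Tibble of unaligned sequences (`id`, `seq`).
#' @param threshold_pct Identity threshold in `(0, 100]`.
#' @return A tibble of clusters as in [dedup_exact()].
#' @export
greedy_cluster <- function(records, threshold_pct) {
  stopifnot(threshold_pct > 0, threshold_pct <= 100)
  check_sequence_table(records, aligned = FALSE)
  ord <- order(-nchar(records$seq), records$id)
  recs <- records[ord, ]
  reps <- character()
  rep_seq <- character()
  members <- list()
  for (i in seq_len(nrow(recs))) {
    joined <- FALSE
    for (k in seq_along(reps)) {
      if (global_identity(recs$seq[i], rep_seq[k]) >= threshold_pct) {
        members[[k]] <- c(members[[k]], recs$id[i])
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, recs$id[i])
      rep_seq <- c(rep_seq, recs$seq[i])
      members <- c(members, list(recs$id[i]))
    }
  }
  out <- tibble::tibble(representative = reps,
                        members = purrr::map(members, sort),
                        n = lengths(members))
  dplyr::arrange(out, .data$representative)
}
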