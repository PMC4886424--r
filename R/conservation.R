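# Column conservation scoring (0-9 scale) and projection of reference
# catalytic positions through an alignment onto query sequences.

# Taylor-style physicochemical grouping used by the conservation score.
# Gaps belong to no class; 'X' is its own class.
PHYSCHEM_CLASSES <- list(
  aliphatic = c("A", "V", "L", "I", "M", "C"),
  aromatic  = c("F", "W", "Y", "H"),
  polar     = c("S", "T", "N", "Q"),
  acidic    = c("D", "E"),
  basic     = c("K", "R"),
  glycine   = "G",
  proline   = "P",
  unknown   = "X"
)

residue_class <- local({
  map <- character()
  for (nm in names(PHYSCHEM_CLASSES)) map[PHYSCHEM_CLASSES[[nm]]] <- nm
  map
})

#' Score per-column conservation of an alignment on a 0-9 scale
#'
#' A gap-free column containing a single residue type scores 9 (strict
#' conservation). Otherwise, with `n` rows, `g` gaps in the column and `f`
#' the largest fraction of rows falling into one physicochemical class
#' (class count / n; gaps count towards no class), the score is
#' `min(8, floor(9 * f * (1 - g/n) + 0.5))`, so similar, well-conserved
#' columns land in the 6-8 band and 9 is reserved for strict identity.
#'
#' @param aln Alignment tibble (see [read_fasta()] with `aligned = TRUE`).
#' @return A tibble of class `nc_conservation` with columns `column`
#'   (1-based), `score` (integer 0-9) and `consensus` (most frequent
#'   non-gap residue; ties broken alphabetically).
#' @examples
#' aln <- tibble::tibble(id = c("a", "b"), seq = c("MKD", "MKE"))
#' conservation_scores(aln)
#' @export
conservation_scores <- function(aln) {
  check_sequence_table(aln, aligned = TRUE)
  m <- alignment_matrix(aln)
  n <- nrow(m)
  res <- purrr::map(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    resid <- col[col != "-"]
    g <- n - length(resid)
    if (g == 0L && length(unique(resid)) == 1L) {
      score <- 9L
    } else {
      cls <- residue_class[resid]
      f <- max(table(cls)) / n
      score <- min(8L, as.integer(floor(9 * f * (1 - g / n) + 0.5)))
    }
    tab <- table(resid)
    top <- names(tab)[tab == max(tab)]
    tibble::tibble(column = j, score = score, consensus = sort(top)[1])
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("nc_conservation", class(out))
  out
}

#' Map a reference residue number to its alignment column
#'
#' Returns the alignment column (1-based) that holds the `ref_pos`-th
#' non-gap residue of the reference row.
#'
#' @param aln Alignment tibble.
#' @param ref_id Id of the reference sequence.
#' @param ref_pos 1-based ungapped residue number in the reference.
#' @return Integer column index.
#' @export
map_reference_position <- function(aln, ref_id, ref_pos) {
  i <- match(ref_id, aln$id)
  if (is.na(i)) {
    rlang::abort(paste0("reference id '", ref_id, "' not in alignment"),
                 class = "cyclascan_missing_reference")
  }
  chars <- strsplit(aln$seq[i], "", fixed = TRUE)[[1]]
  nongap <- chars != "-"
  ref_pos <- as.integer(ref_pos)
  if (ref_pos < 1L || ref_pos > sum(nongap)) {
    rlang::abort(sprintf(
      "reference position %d out of range (ungapped length %d)",
      ref_pos, sum(nongap)),
      class = "cyclascan_position_out_of_range")
  }
  which(cumsum(nongap) == ref_pos & nongap)[1]
}

#' Extract key-residue profiles at anchored catalytic positions
#'
#' Projects the anchor's reference positions through the alignment and
#' reads, for every non-reference row, the residue at each mapped column
#' (a gap is recorded as `-` and flags the profile as missing a key
#' residue).
#'
#' @param aln Alignment tibble containing the anchor's reference row.
#' @param anchor An [anchor_config()] object.
#' @return A tibble with one row per non-reference sequence: `seq_id`, one
#'   residue column per configured anchor position (`MB1`, `MB2`, `SS1`,
#'   `SS2`, `TS1`, optionally `TS2`), matching `col_*` alignment-column
#'   indices (1-based), and `missing_key` (TRUE if any anchored position is
#'   a gap in that row).
#' @export
extract_profiles <- function(aln, anchor) {
  stopifnot(inherits(anchor, "anchor_config"))
  check_sequence_table(aln, aligned = TRUE)
  cols <- vapply(anchor$positions, function(p) {
    map_reference_position(aln, anchor$ref_id, p)
  }, integer(1))
  m <- alignment_matrix(aln)
  queries <- setdiff(aln$id, anchor$ref_id)
  out <- purrr::map(queries, function(id) {
    resid <- m[id, cols]
    row <- tibble::tibble(seq_id = id)
    for (k in seq_along(cols)) row[[names(cols)[k]]] <- unname(resid[k])
    for (k in seq_along(cols)) row[[paste0("col_", names(cols)[k])]] <- unname(cols[k])
    row$missing_key <- any(resid == "-")
    row
  })
  dplyr::bind_rows(out)
}

#' @rdname autoplot-cyclascan
#' @method autoplot nc_conservation
#' @export
autoplot.nc_conservation <- function(object, highlight = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$column, y = .data$score)) +
    ggplot2::geom_col(fill = "grey40", width = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 9), breaks = 0:9) +
    ggplot2::labs(x = "alignment column", y = "conservation score (0-9)") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_col(
      data = dplyr::filter(object, .data$column %in% highlight),
      fill = "firebrick", width = 1)
  }
  p
}
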