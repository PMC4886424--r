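# Rule-based cyclase-type classification from key-residue profiles, plus
# GGDEF-motif and Kyte-Doolittle hydropathy screens.

# Kyte-Doolittle hydropathy scale; X (unknown residue) treated as neutral
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0)

#' Classify a key-residue profile as AC/GC, GC or unclassified
#'
#' Applies the substrate-specificity rule for class III nucleotide
#' cyclases. A Lys-Glu pair at the substrate-specifying positions marks a
#' putative adenylyl cyclase that may accept both ATP and GTP (label
#' `AC/GC`); a Glu-Lys or Glu-Arg pair marks a putative guanylyl cyclase
#' (`GC`); any other pair is `unclassified` - the rule set is closed-world
#' rather than guessing. Metal coordination by the two aspartates is
#' critical for catalysis: if neither metal-binding position carries an
#' aspartate the label is forced to `unclassified`; exactly one aspartate
#' keeps the substrate-rule label but sets `mb_ambiguous`. Transition-state
#' residues are recorded as supporting evidence only and never change the
#' label.
#'
#' @param mb Character vector of metal-binding residues (1 or 2 entries;
#'   `-` for a gap).
#' @param ss Character vector of the two substrate-specifying residues.
#' @param ts Character vector of transition-state residues (may be empty).
#' @return One-row tibble: `label`, `mb_ambiguous`, `rationale`.
#' @examples
#' classify_profile(c("D", "D"), c("K", "E"), "R")   # AC/GC
#' classify_profile(c("D", "D"), c("E", "K"), c("H", "R"))  # GC
#' @export
classify_profile <- function(mb, ss, ts = character()) {
  stopifnot(length(ss) == 2L)
  n_asp <- sum(mb == "D")
  if (identical(unname(ss[1]), "K") && identical(unname(ss[2]), "E")) {
    label <- "AC/GC"
    why <- "SS pair Lys-Glu: adenylyl-type; may confer specificity for both ATP and GTP"
  } else if (identical(unname(ss[1]), "E") && unname(ss[2]) %in% c("K", "R")) {
    label <- "GC"
    why <- sprintf("SS pair Glu-%s: guanylyl-type",
                   c(K = "Lys", R = "Arg")[[unname(ss[2])]])
  } else {
    label <- "unclassified"
    why <- sprintf("SS pair %s-%s matches no known specificity rule", ss[1], ss[2])
  }
  mb_ambiguous <- n_asp == 1L
  if (n_asp == 0L) {
    label <- "unclassified"
    why <- paste0(why, "; no metal-binding aspartate (metal coordination ",
                  "critical for cyclase activity)")
    mb_ambiguous <- FALSE
  } else if (mb_ambiguous) {
    why <- paste0(why, "; single metal-binding aspartate (ambiguous)")
  }
  if (length(ts) > 0) {
    why <- paste0(why, "; TS residues ", paste(ts, collapse = ","),
                  " recorded as supporting evidence")
  }
  tibble::tibble(label = label, mb_ambiguous = mb_ambiguous, rationale = why)
}

#' Find all occurrences of the GGDEF pentapeptide
#'
#' The Gly-Gly-Asp-Glu-Phe motif is diagnostic of diguanylate cyclases;
#' its absence argues against c-di-GMP synthase function. All (including
#' overlapping) exact occurrences are reported.
#'
#' @param sequence An unaligned protein sequence (string).
#' @return Integer vector of 1-based match start positions (possibly empty).
#' @examples
#' scan_ggdef("AAGGDEFAA")
#' @export
scan_ggdef <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  hits <- gregexpr("(?=GGDEF)", toupper(sequence), perl = TRUE)[[1]]
  if (hits[1] == -1L) integer() else as.integer(hits)
}

#' Screen for candidate transmembrane segments by mean hydropathy
#'
#' Slides a window over the Kyte-Doolittle hydropathy values of the
#' sequence and reports maximal runs of windows whose mean is at or above
#' the threshold, merged when overlapping. This is a simple hydropathy
#' screen for likely membrane-spanning stretches; an empty result is
#' consistent with a cytosolic protein.
#'
#' @param sequence Unaligned protein sequence (string).
#' @param window Window length in residues (default 19, a typical
#'   transmembrane-helix span).
#' @param threshold Minimum mean hydropathy for a candidate window
#'   (default 1.6).
#' @return Tibble with one row per merged candidate segment: `start`,
#'   `end` (1-based, inclusive) and `mean_hydropathy` over the segment.
#'   Sequences shorter than the window yield an empty result with a
#'   message, not an error.
#' @export
hydropathy_tm_screen <- function(sequence, window = 19, threshold = 1.6) {
  stopifnot(length(sequence) == 1L)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          mean_hydropathy = double())
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (length(chars) < window) {
    rlang::inform(sprintf(
      "sequence length %d shorter than window %d; no screen performed",
      length(chars), window))
    return(empty)
  }
  vals <- unname(KD_SCALE[chars])
  vals[is.na(vals)] <- 0
  csum <- cumsum(c(0, vals))
  starts <- seq_len(length(vals) - window + 1L)
  means <- (csum[starts + window] - csum[starts]) / window
  hit <- means >= threshold
  if (!any(hit)) return(empty)
  runs <- rle(hit)
  ends_run <- cumsum(runs$lengths)
  starts_run <- ends_run - runs$lengths + 1L
  keep <- which(runs$values)
  purrr::map(keep, function(k) {
    s <- starts[starts_run[k]]
    e <- starts[ends_run[k]] + window - 1L
    tibble::tibble(start = s, end = e,
                   mean_hydropathy = mean(vals[s:e]))
  }) |> dplyr::bind_rows()
}

#' Classify every sequence in an anchored alignment
#'
#' End-to-end classification: key-residue profiles are read at the
#' anchored catalytic columns, the substrate-specificity rule is applied
#' per sequence, and the degapped sequences are screened for the GGDEF
#' motif and candidate transmembrane segments. Lineage labels from
#' `metadata` drive the summary cross-tabulation; sequences without
#' metadata are summarised under lineage `"unknown"`.
#'
#' @param aln Alignment tibble containing the anchor's reference row.
#' @param anchor An [anchor_config()] object.
#' @param metadata Optional tibble with columns `seq_id` and `lineage`.
#' @param sequences Optional tibble of unaligned sequences (`id`, `seq`)
#'   for the GGDEF/hydropathy screens; defaults to the degapped alignment
#'   rows.
#' @return An object of class `nc_classification`: a list with
#'   `predictions` (one row per non-reference sequence, in input order)
#'   and `summary` (lineage x label counts). [tidy()] returns the
#'   predictions, [glance()] one row of totals.
#' @export
classify_set <- function(aln, anchor, metadata = NULL, sequences = NULL) {
  profiles <- extract_profiles(aln, anchor)
  if (is.null(sequences)) {
    sequences <- tibble::tibble(
      id = aln$id, seq = stringr::str_remove_all(aln$seq, "-"))
  }
  if (nrow(profiles) == 0L) {
    pred <- tibble::tibble(
      seq_id = character(), lineage = character(), mb = character(),
      ss = character(), ts = character(), label = character(),
      mb_ambiguous = logical(), missing_key = logical(),
      ggdef_hit = logical(), tm_candidate = logical(), rationale = character())
  } else {
    mb_cols <- intersect(c("MB1", "MB2"), names(profiles))
    ss_cols <- c("SS1", "SS2")
    ts_cols <- intersect(c("TS1", "TS2"), names(profiles))
    pred <- purrr::map(seq_len(nrow(profiles)), function(i) {
      row <- profiles[i, ]
      mb <- unlist(row[mb_cols], use.names = FALSE)
      ss <- unlist(row[ss_cols], use.names = FALSE)
      ts <- unlist(row[ts_cols], use.names = FALSE)
      cls <- classify_profile(mb, ss, ts)
      s <- sequences$seq[match(row$seq_id, sequences$id)]
      ggdef <- if (is.na(s)) NA else length(scan_ggdef(s)) > 0
      tmc <- if (is.na(s)) NA else nrow(suppressMessages(hydropathy_tm_screen(s))) > 0
      tibble::tibble(
        seq_id = row$seq_id,
        mb = paste(mb, collapse = ","), ss = paste(ss, collapse = ","),
        ts = paste(ts, collapse = ","), label = cls$label,
        mb_ambiguous = cls$mb_ambiguous, missing_key = row$missing_key,
        ggdef_hit = ggdef, tm_candidate = tmc, rationale = cls$rationale)
    }) |> dplyr::bind_rows()
    lineage <- if (is.null(metadata)) {
      rep("unknown", nrow(pred))
    } else {
      lg <- metadata$lineage[match(pred$seq_id, metadata$seq_id)]
      ifelse(is.na(lg), "unknown", lg)
    }
    pred <- dplyr::mutate(pred, lineage = lineage, .after = "seq_id")
  }
  summary <- dplyr::count(pred, .data$lineage, .data$label, name = "n")
  structure(list(predictions = pred, summary = summary),
            class = "nc_classification")
}

#' @export
print.nc_classification <- function(x, ...) {
  cat("<nc_classification>", nrow(x$predictions), "sequences\n")
  print(x$summary)
  invisible(x)
}

#' Tidiers for classification results
#'
#' @param x An `nc_classification` object.
#' @param ... Unused.
#' @return `tidy()` returns the per-sequence prediction tibble; `glance()`
#'   a one-row tibble with total counts per label.
#' @method tidy nc_classification
#' @export
tidy.nc_classification <- function(x, ...) x$predictions

#' @rdname tidy.nc_classification
#' @method glance nc_classification
#' @export
glance.nc_classification <- function(x, ...) {
  p <- x$predictions
  tibble::tibble(
    n = nrow(p),
    n_ac_gc = sum(p$label == "AC/GC"),
    n_gc = sum(p$label == "GC"),
    n_unclassified = sum(p$label == "unclassified"),
    n_mb_ambiguous = sum(p$mb_ambiguous),
    n_ggdef = sum(p$ggdef_hit, na.rm = TRUE),
    n_tm_candidate = sum(p$tm_candidate, na.rm = TRUE))
}

#' Plot methods for cyclascan result objects
#'
#' @param object A cyclascan result object.
#' @param highlight Optional columns to emphasise (conservation plot).
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-cyclascan
NULL

#' @rdname autoplot-cyclascan
#' @method autoplot nc_classification
#' @export
autoplot.nc_classification <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$lineage, y = .data$n, fill = .data$label)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "sequences", fill = "predicted class") +
    ggplot2::theme_minimal()
}
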