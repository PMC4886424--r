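# Readers and writers for the external formats the pipeline touches:
# FASTA (via Biostrings), Stockholm 1.0, genome gene tables (TSV) and
# anchor configurations (YAML). All readers validate strictly.

# normalise residue strings: uppercase; U/O/B/Z/J folded to X (warned once)
normalize_residues <- function(x, context = "sequence") {
  x <- toupper(x)
  hits <- stringr::str_detect(x, paste0("[", paste(AA_FOLD_TO_X, collapse = ""), "]"))
  if (any(hits)) {
    rlang::warn(sprintf(
      "%d %s(s) contained rare residue codes (U/O/B/Z/J); mapped to 'X'",
      sum(hits), context
    ))
    x <- stringr::str_replace_all(x, "[UOBZJ]", "X")
  }
  x
}

check_sequence_table <- function(tbl, aligned = FALSE, call = rlang::caller_env()) {
  stopifnot(all(c("id", "seq") %in% names(tbl)))
  if (anyDuplicated(tbl$id) > 0) {
    dup <- unique(tbl$id[duplicated(tbl$id)])
    rlang::abort(paste0("duplicate sequence id(s): ", paste(dup, collapse = ", ")),
                 class = "cyclascan_duplicate_id", call = call)
  }
  if (any(tbl$id == "")) {
    rlang::abort("empty sequence id", class = "cyclascan_bad_id", call = call)
  }
  if (any(nchar(tbl$seq) == 0L)) {
    rlang::abort("empty sequence(s)", class = "cyclascan_empty_sequence", call = call)
  }
  bad <- stringr::str_detect(tbl$seq, "[^ACDEFGHIKLMNPQRSTVWYX-]")
  if (any(bad)) {
    rlang::abort(paste0("invalid residue characters in: ",
                        paste(tbl$id[bad], collapse = ", ")),
                 class = "cyclascan_bad_residue", call = call)
  }
  if (aligned) {
    w <- nchar(tbl$seq)
    if (length(unique(w)) != 1L) {
      rlang::abort("aligned records have unequal lengths (ragged alignment)",
                   class = "cyclascan_ragged_alignment", call = call)
    }
    m <- alignment_matrix(tbl)
    if (any(colSums(m == "-") == nrow(m))) {
      rlang::abort("alignment contains an all-gap column",
                   class = "cyclascan_all_gap_column", call = call)
    }
  } else {
    if (any(stringr::str_detect(tbl$seq, "-"))) {
      rlang::abort("gap characters in unaligned records",
                   class = "cyclascan_gap_in_unaligned", call = call)
    }
  }
  invisible(tbl)
}

# character matrix view of an alignment tibble (rows = sequences)
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}

matrix_to_alignment <- function(m) {
  tibble::tibble(id = rownames(m), desc = "",
                 seq = apply(m, 1L, paste, collapse = ""))
}

#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble with one row per record. With
#' `aligned = TRUE` the records are additionally required to form a valid
#' alignment: equal lengths and no column made entirely of gaps. Residues
#' are uppercased and the rare one-letter codes U/O/B/Z/J are folded to
#' `X` (with a warning), so downstream scoring is total.
#'
#' @param path Path to a FASTA file.
#' @param aligned Logical; treat the records as rows of one alignment.
#' @return A tibble with columns `id`, `desc` and `seq`. Order follows the
#'   file. Unaligned records must be gap-free.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 demo", "MKRD"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "cyclascan_missing_file")
  }
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) {
    if (aligned) {
      rlang::abort("empty FASTA where an alignment was expected",
                   class = "cyclascan_empty_alignment")
    }
    return(tibble::tibble(id = character(), desc = character(), seq = character()))
  }
  nm <- names(ss)
  id <- stringr::str_extract(nm, "^\\S+")
  desc <- stringr::str_trim(stringr::str_remove(nm, "^\\S+\\s*"))
  tbl <- tibble::tibble(id = id, desc = desc,
                        seq = normalize_residues(unname(as.character(ss))))
  check_sequence_table(tbl, aligned = aligned)
  tbl
}

#' Write sequences to FASTA
#'
#' Canonical output: `>id desc` headers, residues wrapped at `width`
#' columns. `read_fasta()` followed by `write_fasta()` reproduces a
#' canonical file byte-for-byte.
#'
#' @param tbl Tibble with columns `id`, `seq` and optionally `desc`.
#' @param path Output path.
#' @param width Line-wrap width (columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(tbl, path, width = 60) {
  desc <- if ("desc" %in% names(tbl)) tbl$desc else rep("", nrow(tbl))
  nm <- ifelse(desc == "" | is.na(desc), tbl$id, paste(tbl$id, desc))
  ss <- Biostrings::AAStringSet(tbl$seq)
  names(ss) <- nm
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Read a single-alignment Stockholm 1.0 file
#'
#' Markup lines (`#=GC`, `#=GS`, `#=GF`, `#=GR`) are tolerated and ignored;
#' `.` gaps are normalised to `-`; interleaved blocks are concatenated per
#' sequence name. The file must end with the `//` terminator.
#'
#' @param path Path to a Stockholm file.
#' @return An alignment tibble (`id`, `desc`, `seq`).
#' @export
read_stockholm <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "cyclascan_missing_file")
  }
  lines <- readLines(path, warn = FALSE)
  if (!any(stringr::str_trim(lines) == "//")) {
    rlang::abort("Stockholm file lacks the '//' terminator",
                 class = "cyclascan_stockholm_unterminated")
  }
  lines <- lines[seq_len(which(stringr::str_trim(lines) == "//")[1] - 1L)]
  seqs <- list()
  order <- character()
  for (ln in lines) {
    if (stringr::str_detect(ln, "^#") || stringr::str_trim(ln) == "") next
    parts <- strsplit(stringr::str_trim(ln), "\\s+")[[1]]
    if (length(parts) != 2L) {
      rlang::abort(paste0("malformed Stockholm sequence line: ", ln),
                   class = "cyclascan_stockholm_malformed")
    }
    nm <- parts[1]
    if (!nm %in% order) order <- c(order, nm)
    seqs[[nm]] <- paste0(seqs[[nm]] %||% "", parts[2])
  }
  if (length(seqs) == 0L) {
    rlang::abort("Stockholm file contains no sequence lines",
                 class = "cyclascan_empty_alignment")
  }
  seq <- stringr::str_replace_all(unlist(seqs[order], use.names = FALSE), stringr::fixed("."), "-")
  tbl <- tibble::tibble(id = order, desc = "", seq = normalize_residues(seq))
  check_sequence_table(tbl, aligned = TRUE)
  tbl
}

#' Read a genome gene table (TSV)
#'
#' The table is tab-separated with `#` comment lines and header columns
#' `genome_id, index, locus, strand, protein_id, architecture, orthogroup`.
#' `index` is the 0-based position of the gene in genome order and must be
#' consecutive from 0 within each genome; `architecture` is a `;`-joined
#' list of domain accessions (empty cell = no assigned domains).
#'
#' @param path Path to the TSV file.
#' @return A tibble of gene records; `architecture` is a list-column of
#'   character vectors.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "cyclascan_missing_file")
  }
  tbl <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    genome_id = readr::col_character(), index = readr::col_integer(),
    locus = readr::col_character(), strand = readr::col_character(),
    protein_id = readr::col_character(), architecture = readr::col_character(),
    orthogroup = readr::col_character()
  ), na = character(), progress = FALSE)
  required <- c("genome_id", "index", "locus", "strand", "protein_id",
                "architecture", "orthogroup")
  if (!all(required %in% names(tbl))) {
    rlang::abort("gene table lacks required columns",
                 class = "cyclascan_bad_gene_table")
  }
  tbl$architecture <- purrr::map(tbl$architecture, function(x) {
    if (is.na(x) || x == "") character() else strsplit(x, ";", fixed = TRUE)[[1]]
  })
  validate_gene_table(tbl)
}

validate_gene_table <- function(tbl, call = rlang::caller_env()) {
  if (!all(tbl$strand %in% c("+", "-"))) {
    rlang::abort("unknown strand symbol (must be '+' or '-')",
                 class = "cyclascan_bad_strand", call = call)
  }
  if (anyDuplicated(tbl[, c("genome_id", "locus")]) > 0) {
    rlang::abort("(genome_id, locus) pairs are not unique",
                 class = "cyclascan_duplicate_locus", call = call)
  }
  by_genome <- split(tbl$index, tbl$genome_id)
  for (g in names(by_genome)) {
    idx <- sort(by_genome[[g]])
    if (!identical(idx, seq(0L, length(idx) - 1L))) {
      rlang::abort(paste0("gene indices in genome '", g,
                          "' are not consecutive from 0"),
                   class = "cyclascan_bad_gene_index", call = call)
    }
  }
  tbl
}

#' Write a genome gene table (TSV)
#'
#' Inverse of [read_gene_table()]: list-column architectures are joined
#' with `;`.
#'
#' @param tbl Gene-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(tbl, path) {
  out <- tbl
  out$architecture <- purrr::map_chr(tbl$architecture, paste, collapse = ";")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Build an anchor configuration
#'
#' An anchor configuration names the reference sequence in an alignment and
#' the 1-based ungapped residue numbers of its catalytic positions, drawn
#' from the fixed vocabulary MB1, MB2 (metal-binding aspartates), SS1, SS2
#' (substrate-specifying pair), TS1 and optional TS2 (transition-state /
#' stabilising residues).
#'
#' @param ref_id Id of the reference sequence.
#' @param positions Named list/vector of 1-based residue numbers; names from
#'   `MB1, MB2, SS1, SS2, TS1, TS2` (TS2 optional, others required).
#' @param expected Optional named list mapping position names to accepted
#'   residue sets (characters).
#' @return An object of class `anchor_config`.
#' @examples
#' anchor_config("REF", c(MB1 = 10, MB2 = 54, SS1 = 30, SS2 = 83, TS1 = 70))
#' @export
anchor_config <- function(ref_id, positions, expected = NULL) {
  positions <- unlist(positions)
  nm <- names(positions)
  if (is.null(nm) || any(nm == "")) {
    rlang::abort("anchor positions must be named", class = "cyclascan_bad_anchor")
  }
  unknown <- setdiff(nm, ANCHOR_POSITIONS)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown anchor position name(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "cyclascan_bad_anchor")
  }
  missing <- setdiff(setdiff(ANCHOR_POSITIONS, "TS2"), nm)
  if (length(missing) > 0) {
    rlang::abort(paste0("missing anchor position(s): ",
                        paste(missing, collapse = ", ")),
                 class = "cyclascan_bad_anchor")
  }
  pos <- as.integer(positions)
  if (any(is.na(pos)) || any(pos < 1L)) {
    rlang::abort("anchor positions must be integers >= 1",
                 class = "cyclascan_bad_anchor")
  }
  if (anyDuplicated(pos) > 0) {
    rlang::abort("anchor positions must be distinct",
                 class = "cyclascan_bad_anchor")
  }
  names(pos) <- nm
  structure(list(ref_id = as.character(ref_id),
                 positions = pos[intersect(ANCHOR_POSITIONS, nm)],
                 expected = expected),
            class = "anchor_config")
}

#' Read an anchor configuration from YAML
#'
#' The file holds `ref_id`, a `positions` map (names from the MB/SS/TS
#' vocabulary, values 1-based ungapped residue numbers in the reference)
#' and an optional `expected` map of accepted residues per position.
#'
#' @param path Path to a YAML file.
#' @return An `anchor_config` object.
#' @export
read_anchor_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "cyclascan_missing_file")
  }
  y <- yaml::read_yaml(path)
  if (is.null(y$ref_id) || is.null(y$positions)) {
    rlang::abort("anchor config must provide 'ref_id' and 'positions'",
                 class = "cyclascan_bad_anchor")
  }
  anchor_config(y$ref_id, y$positions, expected = y$expected)
}

#' @export
print.anchor_config <- function(x, ...) {
  cat("<anchor_config> reference:", x$ref_id, "\n")
  cat(paste0("  ", names(x$positions), " = ", x$positions, collapse = "\n"), "\n")
  invisible(x)
}
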