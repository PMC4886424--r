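# End-to-end orchestration and the packaged reference annotation: the
# curated 53-protein key-residue table and the 20-row functional
# association table, with loaders pinned to checksums, a comparison
# report for the classifier, and a config-driven pipeline runner.

FIXTURE_MD5 <- c(
  key_residues_53.tsv = "3b124385c3befb3c9907e500f59c30c9",
  functional_associations_20.tsv = "7b6b92fd01c8c422ec991c41b3cbe077")

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "cyclascan")
  if (path == "") rlang::abort(paste0("fixture not installed: ", file),
                               class = "cyclascan_missing_fixture")
  got <- unname(tools::md5sum(path))
  if (!identical(got, unname(FIXTURE_MD5[[file]]))) {
    rlang::abort(paste0("fixture checksum mismatch for ", file,
                        " (file corrupted or modified)"),
                 class = "cyclascan_fixture_checksum")
  }
  path
}

split_residues <- function(x) strsplit(x, ",", fixed = TRUE)

#' Load the curated key-residue table of 53 cyclase-like proteins
#'
#' The packaged reference annotation: 53 uncharacterised bacterial
#' proteins (22 Actinobacteria, 23 Bacteroidetes, 8 Proteobacteria) with
#' their metal-binding (MB), substrate-specifying (SS) and
#' transition-state (TS) residues and the predicted cyclase class.
#' `single_aspartate` marks the two entries carrying only one conserved
#' metal-binding aspartate. The file checksum is pinned; a modified
#' fixture fails loudly.
#'
#' @return Tibble with columns `uniprot_id`, `length`, `lineage`, `mb`,
#'   `ss`, `ts` (comma-joined residue strings), `predicted` and
#'   `single_aspartate`.
#' @export
load_key_residue_table <- function() {
  tbl <- readr::read_tsv(fixture_path("key_residues_53.tsv"), comment = "#",
                         col_types = readr::cols(
                           uniprot_id = readr::col_character(),
                           length = readr::col_integer(),
                           lineage = readr::col_character(),
                           mb = readr::col_character(),
                           ss = readr::col_character(),
                           ts = readr::col_character(),
                           predicted = readr::col_character(),
                           single_aspartate = readr::col_logical()),
                         progress = FALSE)
  stopifnot(nrow(tbl) == 53L,
            all(tbl$predicted %in% c("GC", "AC/GC")),
            all(tbl$lineage %in% c("Actinobacteria", "Bacteroidetes",
                                   "Proteobacteria")))
  tbl
}

#' Load the curated functional-association table
#'
#' The packaged reference annotation of 20 probable functional
#' associations between predicted nucleotide cyclases and their conserved
#' gene neighbours, each justified by a partner domain known to co-occur
#' with the cyclase domain in multi-domain architectures.
#'
#' @return Tibble with columns `uniprot_id`, `gene_name`,
#'   `partner_locus`, `partner_pfam`, `partner_domain_name` and
#'   `function_category`.
#' @export
load_association_table <- function() {
  tbl <- readr::read_tsv(fixture_path("functional_associations_20.tsv"),
                         comment = "#", col_types = readr::cols(
                           .default = readr::col_character()),
                         progress = FALSE)
  stopifnot(nrow(tbl) == 20L,
            all(grepl("^PF\\d{5}$", tbl$partner_pfam)))
  tbl
}

#' Re-classify the curated key-residue table and compare
#'
#' Applies [classify_profile()] to every row's parsed MB/SS/TS residues
#' and compares the resulting label with the curated `predicted` column.
#' Mismatches are reported, never "corrected".
#'
#' @return Object of class `nc_fixture_report`: list with `comparison`
#'   (per-row tibble including `match`), `crosstab` (lineage x label
#'   counts), `n_mismatch` and `n_mb_ambiguous`. [tidy()] returns the
#'   comparison, [glance()] a one-row summary.
#' @export
classify_reference_table <- function() {
  tbl <- load_key_residue_table()
  mb <- split_residues(tbl$mb)
  ss <- split_residues(tbl$ss)
  ts <- split_residues(tbl$ts)
  cls <- purrr::pmap(list(mb, ss, ts), classify_profile) |> dplyr::bind_rows()
  comparison <- tbl |>
    dplyr::mutate(label = cls$label, mb_ambiguous = cls$mb_ambiguous,
                  match = .data$label == .data$predicted)
  crosstab <- dplyr::count(comparison, .data$lineage, .data$label)
  structure(list(comparison = comparison, crosstab = crosstab,
                 n_mismatch = sum(!comparison$match),
                 n_mb_ambiguous = sum(comparison$mb_ambiguous)),
            class = "nc_fixture_report")
}

#' @export
print.nc_fixture_report <- function(x, ...) {
  cat("<nc_fixture_report>", nrow(x$comparison), "rows,",
      x$n_mismatch, "mismatches\n")
  print(x$crosstab)
  invisible(x)
}

#' Tidiers for the reference-table report
#'
#' @param x An `nc_fixture_report` object.
#' @param ... Unused.
#' @return `tidy()` returns the per-row comparison; `glance()` a one-row
#'   summary.
#' @method tidy nc_fixture_report
#' @export
tidy.nc_fixture_report <- function(x, ...) x$comparison

#' @rdname tidy.nc_fixture_report
#' @method glance nc_fixture_report
#' @export
glance.nc_fixture_report <- function(x, ...) {
  tibble::tibble(n = nrow(x$comparison), n_mismatch = x$n_mismatch,
                 n_mb_ambiguous = x$n_mb_ambiguous)
}

#' Summarise an association table
#'
#' Exact counts over (deduplicated) association rows plus the histogram
#' of function categories.
#'
#' @param records Association tibble, by default the packaged table.
#' @return List: `n_associations`, `n_proteins`, `n_domains`,
#'   `categories` (tibble of category counts), `domains` (sorted distinct
#'   accessions).
#' @export
summarize_associations <- function(records = load_association_table()) {
  records <- dplyr::distinct(records)
  list(n_associations = nrow(records),
       n_proteins = dplyr::n_distinct(records$uniprot_id),
       n_domains = dplyr::n_distinct(records$partner_pfam),
       categories = dplyr::count(records, .data$function_category),
       domains = sort(unique(records$partner_pfam)))
}

#' @rdname autoplot-cyclascan
#' @method autoplot nc_fixture_report
#' @export
autoplot.nc_fixture_report <- function(object, ...) {
  ggplot2::ggplot(object$crosstab,
                  ggplot2::aes(x = .data$lineage, y = .data$n, fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proteins", fill = "predicted class") +
    ggplot2::theme_minimal()
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the configured stages in order - `conserve` (column scores),
#' `classify` (per-sequence predictions), `cluster` (exact dedup),
#' `tree` (NJ with bootstrap support, Newick output) and `neighbors`
#' (Rosetta-stone associations) - writing one TSV/Newick file per stage
#' plus a JSON run log with package version, seed and parameters. The
#' configuration is validated in full before any stage runs; a stage
#' failure aborts with the failing stage named and removes partial
#' outputs.
#'
#' @param config Named list (or path to a YAML file) with elements:
#'   `out_dir`; `stages` (subset of conserve/classify/cluster/tree/
#'   neighbors); `alignment` (path, FASTA) and `anchor` (path, YAML) for
#'   conserve/classify/tree; `fasta` (path) for cluster; `metadata`
#'   (optional TSV seq_id/lineage) for classify; `genomes` (gene-table
#'   TSV), `query_orthogroup`, `architectures` (text file, one
#'   ';'-joined architecture per line), `cyclase_accession` and optional
#'   `function_map` (TSV accession/category) for neighbors; optional
#'   `window`, `min_genomes`, `bootstrap`, `cutoff`, `identity`, `seed`.
#' @return Invisibly, a list of per-stage results plus `files` (paths
#'   written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stages_all <- c("conserve", "classify", "cluster", "tree", "neighbors")
  stages <- config$stages %||% stages_all
  bad <- setdiff(stages, stages_all)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")),
                 class = "cyclascan_bad_config")
  }
  if (is.null(config$out_dir)) {
    rlang::abort("config must name out_dir", class = "cyclascan_bad_config")
  }
  need <- function(field, for_stages) {
    if (any(stages %in% for_stages) && is.null(config[[field]])) {
      rlang::abort(paste0("config field '", field, "' required for stage(s) ",
                          paste(intersect(stages, for_stages), collapse = ", ")),
                   class = "cyclascan_bad_config")
    }
  }
  need("alignment", c("conserve", "classify", "tree"))
  need("anchor", c("conserve", "classify"))
  need("fasta", "cluster")
  need("genomes", "neighbors")
  need("query_orthogroup", "neighbors")
  need("architectures", "neighbors")
  need("cyclase_accession", "neighbors")
  for (f in c("alignment", "anchor", "fasta", "genomes", "architectures",
              "metadata", "function_map")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      rlang::abort(paste0("input file for '", f, "' not found: ", config[[f]]),
                   class = "cyclascan_bad_config")
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  results <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      unlink(written)
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)),
                   class = "cyclascan_stage_failure")
    })
  }
  seed <- config$seed %||% 1L
  if ("conserve" %in% stages) {
    results$conserve <- run_stage("conserve", function() {
      aln <- read_fasta(config$alignment, aligned = TRUE)
      scores <- conservation_scores(aln)
      path <- file.path(config$out_dir, "scores.tsv")
      readr::write_tsv(as_tibble(scores), path, progress = FALSE)
      written <<- c(written, path)
      scores
    })
  }
  if ("classify" %in% stages) {
    results$classify <- run_stage("classify", function() {
      aln <- read_fasta(config$alignment, aligned = TRUE)
      anchor <- read_anchor_config(config$anchor)
      metadata <- if (!is.null(config$metadata)) {
        readr::read_tsv(config$metadata, comment = "#",
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
      }
      cls <- classify_set(aln, anchor, metadata = metadata)
      path <- file.path(config$out_dir, "predictions.tsv")
      readr::write_tsv(cls$predictions, path, progress = FALSE)
      written <<- c(written, path)
      cls
    })
  }
  if ("cluster" %in% stages) {
    results$cluster <- run_stage("cluster", function() {
      recs <- read_fasta(config$fasta)
      identity <- config$identity %||% 100
      clusters <- if (identity >= 100) dedup_exact(recs) else
        greedy_cluster(recs, identity)
      long <- clusters |>
        dplyr::select("representative", "members") |>
        tidyr::unnest_longer("members", values_to = "member")
      path <- file.path(config$out_dir, "clusters.tsv")
      readr::write_tsv(long, path, progress = FALSE)
      written <<- c(written, path)
      clusters
    })
  }
  if ("tree" %in% stages) {
    results$tree <- run_stage("tree", function() {
      aln <- read_fasta(config$alignment, aligned = TRUE)
      boot <- bootstrap_support(aln, n_reps = config$bootstrap %||% 100,
                                seed = seed,
                                correction = config$correction %||% "poisson",
                                cutoff = config$cutoff %||% 50)
      path <- file.path(config$out_dir, "tree.nwk")
      ape::write.tree(boot$tree, file = path)
      written <<- c(written, path)
      boot
    })
  }
  if ("neighbors" %in% stages) {
    results$neighbors <- run_stage("neighbors", function() {
      genes <- read_gene_table(config$genomes)
      arch_lines <- readLines(config$architectures, warn = FALSE)
      arch_lines <- arch_lines[!grepl("^#", arch_lines) & arch_lines != ""]
      architectures <- strsplit(arch_lines, ";", fixed = TRUE)
      fmap <- if (!is.null(config$function_map)) {
        readr::read_tsv(config$function_map, comment = "#",
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
      }
      pairs <- conserved_neighbor_pairs(
        genes, config$query_orthogroup,
        window = config$window %||% 10,
        min_genomes = config$min_genomes %||% 2)
      cooc <- cooccurring_domains(architectures, config$cyclase_accession)
      assoc <- rosetta_associations(pairs, genes, cooc, function_map = fmap)
      path <- file.path(config$out_dir, "associations.tsv")
      readr::write_tsv(assoc, path, progress = FALSE)
      written <<- c(written, path)
      assoc
    })
  }
  log_path <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(list(
    package = "cyclascan",
    version = as.character(utils::packageVersion("cyclascan")),
    seed = seed, stages = stages,
    parameters = config[setdiff(names(config), "stages")]),
    log_path, auto_unbox = TRUE, null = "null")
  written <- c(written, log_path)
  results$files <- written
  invisible(results)
}
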