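# Rosetta-stone functional-association calling: conserved gene
# neighborhoods intersected with the set of domains that co-occur with
# the cyclase domain in known multi-domain architectures.

#' Genes within an index window of a query locus
#'
#' Neighborhood geometry is by gene index (order along the contig), not
#' base-pair distance; contigs are treated as linear, with no circular
#' wraparound.
#'
#' @param genes Gene-record tibble (one genome, or pass `genome_id`).
#' @param locus Query locus tag.
#' @param window Maximum index offset (>= 1).
#' @param genome_id Genome to restrict to when `genes` spans several.
#' @return Neighboring gene records ordered by index, query excluded.
#' @export
neighbors <- function(genes, locus, window = 10, genome_id = NULL) {
  stopifnot(window >= 1)
  if (!is.null(genome_id)) {
    genes <- dplyr::filter(genes, .data$genome_id == !!genome_id)
  }
  if (length(unique(genes$genome_id)) > 1L) {
    rlang::abort("genes span several genomes; supply genome_id",
                 class = "cyclascan_ambiguous_genome")
  }
  qi <- genes$index[genes$locus == locus]
  if (length(qi) != 1L) {
    rlang::abort(paste0("locus '", locus, "' not found"),
                 class = "cyclascan_missing_locus")
  }
  genes |>
    dplyr::filter(abs(.data$index - qi) <= window, .data$locus != !!locus) |>
    dplyr::arrange(.data$index)
}

#' Conserved neighbor pairs of a query orthogroup across genomes
#'
#' For every genome containing the query orthogroup, collects the
#' orthogroups of genes within `window` of the query gene; keeps
#' (query, partner) orthogroup pairs observed in at least `min_genomes`
#' genomes. Strand is ignored; a neighbor gene with an empty orthogroup
#' label contributes nothing.
#'
#' @param genes Gene-record tibble spanning one or more genomes.
#' @param query_orthogroup Orthogroup label of the query family.
#' @param window Index window per side (default 10).
#' @param min_genomes Minimum number of supporting genomes (default 2,
#'   the weakest reading of "conserved across multiple genomes").
#' @return Tibble with one row per conserved pair: `query_orthogroup`,
#'   `partner_orthogroup`, `n_genomes` and `support` (list-column of
#'   per-genome tibbles: `genome_id`, `query_locus`, `partner_locus`,
#'   `offset`).
#' @export
conserved_neighbor_pairs <- function(genes, query_orthogroup, window = 10,
                                     min_genomes = 2) {
  stopifnot(min_genomes >= 1)
  queries <- dplyr::filter(genes, .data$orthogroup == !!query_orthogroup)
  if (nrow(queries) == 0L) {
    rlang::abort(paste0("query orthogroup '", query_orthogroup,
                        "' absent from all genomes"),
                 class = "cyclascan_missing_orthogroup")
  }
  rows <- purrr::map(seq_len(nrow(queries)), function(i) {
    q <- queries[i, ]
    nb <- neighbors(genes, q$locus, window = window, genome_id = q$genome_id)
    nb <- dplyr::filter(nb, .data$orthogroup != "")
    if (nrow(nb) == 0L) return(NULL)
    tibble::tibble(genome_id = q$genome_id, query_locus = q$locus,
                   partner_locus = nb$locus,
                   partner_orthogroup = nb$orthogroup,
                   offset = nb$index - q$index)
  }) |> dplyr::bind_rows()
  if (nrow(rows) == 0L) {
    return(tibble::tibble(query_orthogroup = character(),
                          partner_orthogroup = character(),
                          n_genomes = integer(), support = list()))
  }
  out <- rows |>
    dplyr::group_by(.data$partner_orthogroup) |>
    dplyr::summarise(
      n_genomes = dplyr::n_distinct(.data$genome_id),
      support = list(dplyr::pick("genome_id", "query_locus",
                                 "partner_locus", "offset")),
      .groups = "drop") |>
    dplyr::filter(.data$n_genomes >= min_genomes) |>
    dplyr::mutate(query_orthogroup = !!query_orthogroup, .before = 1) |>
    dplyr::arrange(.data$partner_orthogroup)
  out
}

#' Domains co-occurring with the cyclase domain in known architectures
#'
#' The Rosetta-stone premise: a domain fused with the cyclase domain in
#' some known multi-domain protein has a better-than-random chance of
#' functionally interacting with it when separately encoded. This
#' returns every accession that appears in any architecture containing
#' `cyclase_accession`, minus the cyclase accession itself.
#'
#' @param architectures List of ordered character vectors of domain
#'   accessions (one vector per known architecture).
#' @param cyclase_accession The cyclase family domain accession.
#' @return Sorted character vector of co-occurring accessions.
#' @examples
#' cooccurring_domains(list("CYC", c("CYC", "PF12697"), "PF00027"), "CYC")
#' @export
cooccurring_domains <- function(architectures, cyclase_accession) {
  with_cyc <- purrr::keep(architectures, ~ cyclase_accession %in% .x)
  sort(setdiff(unique(unlist(with_cyc)), cyclase_accession))
}

#' Call Rosetta-stone functional associations
#'
#' For each conserved neighbor pair and each supporting genome, emits one
#' association record per domain of the partner gene's architecture that
#' lies in the co-occurring-domain set. Function categories come from
#' `function_map` (accession -> category); unmapped domains are labelled
#' `"uncategorized"`. Records are deduplicated on all fields and ordered
#' by (query locus, partner locus, accession).
#'
#' @param pairs Output of [conserved_neighbor_pairs()].
#' @param genes Gene-record tibble the pairs were derived from.
#' @param cooccurring Character vector from [cooccurring_domains()].
#' @param function_map Optional tibble with columns `accession` and
#'   `category`.
#' @return Tibble of association records: `query_protein`, `query_locus`,
#'   `partner_locus`, `partner_domain`, `category`.
#' @export
rosetta_associations <- function(pairs, genes, cooccurring,
                                 function_map = NULL) {
  empty <- tibble::tibble(query_protein = character(),
                          query_locus = character(),
                          partner_locus = character(),
                          partner_domain = character(),
                          category = character())
  if (nrow(pairs) == 0L) return(empty)
  gene_key <- paste(genes$genome_id, genes$locus)
  recs <- purrr::map(seq_len(nrow(pairs)), function(i) {
    sup <- pairs$support[[i]]
    purrr::map(seq_len(nrow(sup)), function(k) {
      partner <- genes[match(paste(sup$genome_id[k], sup$partner_locus[k]),
                             gene_key), ]
      query <- genes[match(paste(sup$genome_id[k], sup$query_locus[k]),
                           gene_key), ]
      doms <- intersect(partner$architecture[[1]], cooccurring)
      if (length(doms) == 0L) return(NULL)
      tibble::tibble(query_protein = query$protein_id,
                     query_locus = query$locus,
                     partner_locus = partner$locus,
                     partner_domain = doms)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(recs) == 0L) return(empty)
  if (is.null(function_map)) {
    recs$category <- "uncategorized"
  } else {
    cat <- function_map$category[match(recs$partner_domain,
                                       function_map$accession)]
    recs$category <- ifelse(is.na(cat), "uncategorized", cat)
  }
  recs |>
    dplyr::distinct() |>
    dplyr::arrange(.data$query_locus, .data$partner_locus,
                   .data$partner_domain)
}

#' Summary counts over association records
#'
#' @param records Association-record tibble (see
#'   [rosetta_associations()]); duplicated rows are counted once.
#' @return One-row tibble: `n_associations`, `n_query_proteins`,
#'   `n_partner_domains`.
#' @export
rebuild_association_summary <- function(records) {
  records <- dplyr::distinct(records)
  tibble::tibble(
    n_associations = nrow(records),
    n_query_proteins = dplyr::n_distinct(records$query_protein),
    n_partner_domains = dplyr::n_distinct(records$partner_domain))
}
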