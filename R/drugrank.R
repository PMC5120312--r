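#' Build the full miRNA/mRNA interaction network
#'
#' One node per distinct miRNA and gene appearing in a significant
#' interaction, one edge per significant pair.
#'
#' @param interactions a `mirvalve_interactions` table (or tibble with
#'   mirna_id, gene_id, significant).
#' @return An object of class `mirvalve_network`: list with an igraph
#'   `graph` (node attribute `type` in miRNA/gene) and a `nodes` degree
#'   tibble (node, type, degree).
#' @export
build_full_network <- function(interactions) {
  sig <- interactions[interactions$significant, c("mirna_id", "gene_id")]
  if (nrow(sig) == 0L) abort("no significant interactions to build a network from.")
  verts <- dplyr::bind_rows(
    tibble::tibble(name = unique(sig$mirna_id), type = "miRNA"),
    tibble::tibble(name = unique(sig$gene_id), type = "gene")
  )
  g <- igraph::graph_from_data_frame(sig, directed = FALSE, vertices = verts)
  deg <- igraph::degree(g)
  nodes <- tibble::tibble(
    node = names(deg),
    type = igraph::V(g)$type,
    degree = as.integer(deg)
  ) |>
    dplyr::arrange(dplyr::desc(degree), node)
  structure(list(graph = g, nodes = nodes), class = "mirvalve_network")
}

#' @export
print.mirvalve_network <- function(x, ...) {
  cat(sprintf("<mirvalve_network> %d nodes (%d miRNA, %d gene), %d edges\n",
              nrow(x$nodes), sum(x$nodes$type == "miRNA"),
              sum(x$nodes$type == "gene"), igraph::ecount(x$graph)))
  invisible(x)
}

#' Prioritize druggable up-regulated genes in the interaction network
#'
#' Implements the drug-repurposing triage: keep genes that are (i) nodes of
#' the integrated network, (ii) up-regulated with linear fold change above
#' `min_fold`, and (iii) targeted by at least one drug whose interaction
#' type (case-insensitive) is in the allow-list. The report is split into
#' `"connected"` genes (network degree >= `min_degree`) and `"peripheral"`
#' ones, sorted by degree then fold change. Drug rows for genes absent from
#' the network are counted and reported via a message, not an error.
#'
#' @param mrna_de a `mirvalve_de` table for the mRNAs.
#' @param network a `mirvalve_network` from [build_full_network()].
#' @param drugs tibble (gene_id, drug_name, interaction_type).
#' @param min_fold minimum linear fold change (default 2).
#' @param min_degree degree cut separating connected from peripheral
#'   (default 2, i.e. two or more connections).
#' @param allowed_types drug interaction types that qualify.
#' @return Tibble (gene_id, log2fc, fold_change, p_adj, degree, drugs,
#'   n_drugs, category).
#' @export
rank_drug_targets <- function(mrna_de, network, drugs, min_fold = 2,
                              min_degree = 2L,
                              allowed_types = c("inhibitor", "antagonist", "antibody")) {
  if (!all(c("gene_id", "drug_name", "interaction_type") %in% names(drugs))) {
    abort("`drugs` needs columns gene_id, drug_name, interaction_type.")
  }
  drugs <- dplyr::distinct(drugs)
  net_genes <- network$nodes$node[network$nodes$type == "gene"]
  unknown <- setdiff(unique(drugs$gene_id), network$nodes$node)
  if (length(unknown) > 0L) {
    inform(sprintf("%d drug-table gene(s) not in the network were ignored.",
                   length(unknown)))
  }
  qualifying <- drugs |>
    dplyr::filter(tolower(trimws(interaction_type)) %in% tolower(allowed_types),
                  gene_id %in% net_genes) |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(drugs = paste(sort(unique(drug_name)), collapse = ";"),
                     n_drugs = dplyr::n_distinct(drug_name), .groups = "drop")

  mrna_de |>
    tibble::as_tibble() |>
    dplyr::filter(feature_id %in% net_genes, direction == "up",
                  fold_change > min_fold) |>
    dplyr::inner_join(qualifying, by = c(feature_id = "gene_id")) |>
    dplyr::left_join(network$nodes[, c("node", "degree")],
                     by = c(feature_id = "node")) |>
    dplyr::transmute(
      gene_id = feature_id, log2fc, fold_change, p_adj, degree,
      drugs, n_drugs,
      category = ifelse(degree >= min_degree, "connected", "peripheral")
    ) |>
    dplyr::arrange(dplyr::desc(degree), dplyr::desc(fold_change), gene_id)
}

#' Subnetwork of qualifying drug-target genes and their neighbours
#'
#' @param network a `mirvalve_network`.
#' @param report output of [rank_drug_targets()].
#' @return An igraph object containing the reported genes and their
#'   immediate neighbours.
#' @export
drug_subnetwork <- function(network, report) {
  if (nrow(report) == 0L) abort("empty drug-target report.")
  seeds <- intersect(report$gene_id, names(igraph::V(network$graph)))
  nb <- unique(unlist(igraph::adjacent_vertices(network$graph, seeds)))
  keep <- union(match(seeds, names(igraph::V(network$graph))), nb)
  igraph::induced_subgraph(network$graph, sort(keep))
}
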