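#' Read a GMT gene-set file
#'
#' Standard tab-delimited format: set name, description, then member gene
#' IDs. Members are deduplicated per set.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("GMT file not found: ", path))
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) abort("duplicate set names in GMT file.")
  purrr::map(sets, unique)
}

#' Two-sided hypergeometric test for set overlap
#'
#' The two-sided p-value is the doubled smaller tail (enrichment or
#' depletion), capped at 1 — the conventional construction when a
#' symmetric two-sided hypergeometric probability is required.
#'
#' @param overlap observed overlap between query and set.
#' @param query query size.
#' @param set_size gene-set size.
#' @param universe universe size.
#' @return Two-sided p-value in (0, 1].
#' @export
hypergeometric_test <- function(overlap, query, set_size, universe) {
  overlap <- check_count(overlap, "overlap", 0L)
  query <- check_count(query, "query", 0L)
  set_size <- check_count(set_size, "set_size", 0L)
  universe <- check_count(universe, "universe", 1L)
  if (overlap > min(query, set_size)) abort("overlap exceeds min(query, set_size).")
  if (query > universe || set_size > universe) abort("query and set must fit in universe.")
  if (overlap < max(0L, query + set_size - universe)) {
    abort("overlap below the feasible minimum for these counts.")
  }
  lower <- stats::phyper(overlap, set_size, universe - set_size, query)
  upper <- stats::phyper(overlap - 1L, set_size, universe - set_size, query,
                         lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Gene-set over-representation analysis
#'
#' Tests each gene set for enrichment or depletion of the query genes with
#' the two-sided hypergeometric test, Benjamini-Hochberg adjusted across
#' all tested sets. Sets are trimmed to the universe before testing and
#' empty sets dropped; by default only sets overlapping the query are
#' reported, with `include_depleted = TRUE` adding zero/low-overlap sets.
#'
#' @param query_genes character vector of genes of interest (must lie in
#'   the universe).
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param universe character vector of all assayed genes.
#' @param alpha FDR threshold for the significant flag.
#' @param include_depleted also report sets with no overlap.
#' @return Tibble (set_name, overlap, set_size, query_size, universe_size,
#'   expected, direction, p, p_adj, significant) sorted by adjusted p.
#' @export
enrich_genes <- function(query_genes, collection, universe, alpha = 0.05,
                         include_depleted = FALSE) {
  universe <- unique(universe)
  if (length(universe) == 0L) abort("empty universe.")
  query <- unique(query_genes)
  if (!all(query %in% universe)) {
    abort("query genes outside the universe; trim the query first.")
  }
  if (is.null(names(collection)) || anyDuplicated(names(collection))) {
    abort("`collection` must be a uniquely named list of gene sets.")
  }
  sets <- purrr::map(collection, ~ intersect(unique(.x), universe))
  sets <- sets[purrr::map_int(sets, length) > 0L]
  if (length(sets) == 0L) {
    return(tibble::tibble(
      set_name = character(0), overlap = integer(0), set_size = integer(0),
      query_size = integer(0), universe_size = integer(0),
      expected = numeric(0), direction = character(0), p = numeric(0),
      p_adj = numeric(0), significant = logical(0)
    ))
  }
  nq <- length(query)
  nu <- length(universe)
  res <- purrr::imap_dfr(sets, function(members, nm) {
    k <- length(intersect(query, members))
    tibble::tibble(
      set_name = nm, overlap = k, set_size = length(members),
      query_size = nq, universe_size = nu,
      expected = nq * length(members) / nu
    )
  })
  if (!include_depleted) res <- res[res$overlap >= 1L, ]
  if (nrow(res) == 0L) return(res |> dplyr::mutate(
    direction = character(0), p = numeric(0), p_adj = numeric(0),
    significant = logical(0)
  ))
  res |>
    dplyr::mutate(
      direction = ifelse(overlap >= expected, "enriched", "depleted"),
      p = purrr::pmap_dbl(
        list(overlap, set_size),
        function(k, s) hypergeometric_test(k, nq, s, nu)
      ),
      p_adj = benjamini_hochberg(p),
      significant = p_adj < alpha
    ) |>
    dplyr::arrange(p_adj, p, set_name)
}
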