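# Readers and writers for the pipeline's plain-text formats. All readers
# skip '#' comment lines so stage outputs (which carry a provenance header)
# re-load cleanly.

read_tsv_quiet <- function(path, ...) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Read an expression TSV
#'
#' First column is the feature ID, remaining columns one sample each.
#'
#' @param path file path.
#' @return Expression tibble with first column renamed to `feature_id`.
#' @export
read_expression <- function(path) {
  x <- read_tsv_quiet(path)
  names(x)[1L] <- "feature_id"
  expr_to_matrix(x)  # validation only
  x
}

#' Read a sample-metadata TSV (sample_id, group, ...)
#' @param path file path.
#' @return Tibble.
#' @export
read_metadata <- function(path) {
  x <- read_tsv_quiet(path)
  if (!all(c("sample_id", "group") %in% names(x))) {
    abort("metadata must have columns sample_id and group.")
  }
  x
}

#' Read a target-score TSV (mirna_id, gene_id, score)
#' @param path file path.
#' @return Tibble.
#' @export
read_target_scores <- function(path) {
  x <- read_tsv_quiet(path)
  if (!all(c("mirna_id", "gene_id", "score") %in% names(x))) {
    abort("target table must have columns mirna_id, gene_id, score.")
  }
  check_probability(x$score, "score")
  x
}

#' Read a drug-gene interaction TSV (gene_id, drug_name, interaction_type)
#' @param path file path.
#' @return Tibble with fully duplicated rows removed.
#' @export
read_drug_table <- function(path) {
  x <- read_tsv_quiet(path)
  if (!all(c("gene_id", "drug_name", "interaction_type") %in% names(x))) {
    abort("drug table must have columns gene_id, drug_name, interaction_type.")
  }
  dplyr::distinct(x)
}

#' Read a qPCR Ct TSV (sample_id, group, probe_id, ct)
#' @param path file path.
#' @return Tibble.
#' @export
read_qpcr <- function(path) {
  x <- read_tsv_quiet(path)
  if (!all(c("sample_id", "group", "probe_id", "ct") %in% names(x))) {
    abort("qPCR table must have columns sample_id, group, probe_id, ct.")
  }
  x
}

#' Write a gene-set collection to GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::imap_chr(sets, function(g, nm) {
    paste(c(nm, "synthetic", g), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Serialize simulation ground truth to TSV
#'
#' Long format with columns (record, id1, id2, value); round-trips through
#' [read_ground_truth()] unchanged.
#'
#' @param truth the `truth` element of a [simulate_expression()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  long <- dplyr::bind_rows(
    dplyr::transmute(truth$de_mirna, record = "de_mirna", id1 = feature_id,
                     id2 = NA_character_, value = direction),
    dplyr::transmute(truth$clusters, record = "cluster", id1 = feature_id,
                     id2 = NA_character_, value = as.character(cluster)),
    dplyr::transmute(truth$repressive_pairs, record = "repressive_pair",
                     id1 = mirna_id, id2 = gene_id, value = NA_character_),
    dplyr::transmute(truth$de_mrna, record = "de_mrna", id1 = feature_id,
                     id2 = NA_character_, value = direction)
  )
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}

#' Read simulation ground truth written by [write_ground_truth()]
#' @param path file path.
#' @return The `truth` list (tibbles de_mirna, clusters, repressive_pairs,
#'   de_mrna).
#' @export
read_ground_truth <- function(path) {
  long <- read_tsv_quiet(path, col_types = "cccc")
  list(
    de_mirna = long |> dplyr::filter(record == "de_mirna") |>
      dplyr::transmute(feature_id = id1, direction = value),
    clusters = long |> dplyr::filter(record == "cluster") |>
      dplyr::transmute(feature_id = id1, cluster = as.integer(value)),
    repressive_pairs = long |> dplyr::filter(record == "repressive_pair") |>
      dplyr::transmute(mirna_id = id1, gene_id = id2),
    de_mrna = long |> dplyr::filter(record == "de_mrna") |>
      dplyr::transmute(feature_id = id1, direction = value)
  )
}

#' Write all artifacts of a simulated study to a directory
#'
#' Emits the plain-text inputs every downstream stage reads: miRNA and mRNA
#' expression TSVs, sample metadata, the target-score table, a GMT built
#' around the planted DE genes, a drug-gene table over the mRNA universe, a
#' qPCR Ct table, and the ground-truth TSV.
#'
#' @param sim a [simulate_expression()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "mirvalve_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mirna = file.path(dir, "mirna_expression.tsv"),
    mrna = file.path(dir, "mrna_expression.tsv"),
    meta = file.path(dir, "sample_metadata.tsv"),
    targets = file.path(dir, "target_scores.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    drugs = file.path(dir, "drug_gene.tsv"),
    qpcr = file.path(dir, "qpcr_ct.tsv"),
    truth = file.path(dir, "ground_truth.tsv")
  )
  readr::write_tsv(sim$mirna, paths[["mirna"]], progress = FALSE)
  readr::write_tsv(sim$mrna, paths[["mrna"]], progress = FALSE)
  readr::write_tsv(sim$meta, paths[["meta"]], progress = FALSE)
  readr::write_tsv(sim$target_scores, paths[["targets"]], progress = FALSE)
  seed <- sim$config$seed
  sets <- simulate_gene_sets(unique(sim$truth$de_mrna$feature_id),
                             sim$mrna$feature_id, seed = seed)
  write_gmt(sets, paths[["gmt"]])
  readr::write_tsv(simulate_drug_table(sim$mrna$feature_id, seed = seed),
                   paths[["drugs"]], progress = FALSE)
  readr::write_tsv(simulate_qpcr(seed = seed), paths[["qpcr"]],
                   progress = FALSE)
  write_ground_truth(sim$truth, paths[["truth"]])
  invisible(paths)
}
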