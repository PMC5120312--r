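#' Pipeline configuration
#'
#' Collects and validates all paths and parameters for [run_all()]. Input
#' files use the formats written by [write_simulation()]; `gmt`, `drugs`
#' and `qpcr` are optional — their stages are skipped when NULL.
#'
#' @param mirna,mrna,meta,targets required input paths (expression TSVs,
#'   metadata TSV, target-score TSV).
#' @param gmt,drugs,qpcr optional input paths (GMT gene sets, drug-gene
#'   TSV, qPCR Ct TSV).
#' @param out_dir output directory.
#' @param alpha FDR threshold shared by the DE, integration and enrichment
#'   stages.
#' @param cor_threshold,cor_mode co-expression edge rule (see
#'   [correlation_graph()]).
#' @param inflation,expansion,prune_below,max_iter,tol MCL parameters.
#' @param score_threshold minimum target score for candidate interactions.
#' @param n_permutations permutations for the interaction null.
#' @param integration_samples optional character vector naming the paired
#'   samples used for the integration stage (default: first 10 cases and
#'   first 10 controls, the paired-subset design).
#' @param min_fold,min_degree,allowed_types drug-target filters.
#' @param qpcr_refs reference probe IDs for the qPCR stage.
#' @param censor qPCR censoring threshold in cycles.
#' @param seed integer seed governing the permutation stream.
#' @return A validated list of class `mirvalve_config`.
#' @export
pipeline_config <- function(mirna, mrna, meta, targets,
                            gmt = NULL, drugs = NULL, qpcr = NULL,
                            out_dir = "mirvalve_run",
                            alpha = 0.05,
                            cor_threshold = 0.5,
                            cor_mode = "positive",
                            inflation = 2, expansion = 2L,
                            prune_below = 1e-5, max_iter = 100L, tol = 1e-6,
                            score_threshold = 0.8,
                            n_permutations = 100L,
                            integration_samples = NULL,
                            min_fold = 2, min_degree = 2L,
                            allowed_types = c("inhibitor", "antagonist", "antibody"),
                            qpcr_refs = c("miR-ref-16", "miR-ref-151"),
                            censor = 35,
                            seed = 1L) {
  if (alpha <= 0 || alpha > 1) abort("alpha must be in (0, 1].")
  if (abs(cor_threshold) > 1) abort("cor_threshold must be in [-1, 1].")
  if (!cor_mode %in% c("positive", "absolute")) abort("bad cor_mode.")
  if (inflation <= 1) abort("inflation must be > 1.")
  if (score_threshold < 0 || score_threshold > 1) abort("score_threshold must be in [0, 1].")
  cfg <- list(
    mirna = mirna, mrna = mrna, meta = meta, targets = targets,
    gmt = gmt, drugs = drugs, qpcr = qpcr, out_dir = out_dir,
    alpha = alpha, cor_threshold = cor_threshold, cor_mode = cor_mode,
    inflation = inflation, expansion = check_count(expansion, "expansion", 2L),
    prune_below = prune_below, max_iter = check_count(max_iter, "max_iter"),
    tol = tol, score_threshold = score_threshold,
    n_permutations = check_count(n_permutations, "n_permutations"),
    integration_samples = integration_samples,
    min_fold = min_fold, min_degree = check_count(min_degree, "min_degree", 0L),
    allowed_types = allowed_types, qpcr_refs = qpcr_refs, censor = censor,
    seed = check_count(seed, "seed", 0L)
  )
  structure(cfg, class = "mirvalve_config")
}

# hash of the analysis parameters; the output location is not part of the
# analysis identity, so two runs into different directories hash the same
config_hash <- function(config) {
  flat <- unclass(config)
  flat <- flat[sort(setdiff(names(flat), "out_dir"))]
  rlang::hash(flat)
}

stage_header <- function(config) {
  c(
    sprintf("# mirvalve %s", as.character(utils::packageVersion("mirvalve"))),
    sprintf("# seed=%d config_hash=%s", config$seed, config_hash(config))
  )
}

write_stage_tsv <- function(df, path, config) {
  writeLines(stage_header(config), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Validate pipeline input files
#'
#' Checks every supplied file for structural problems — malformed or short
#' lines (with line numbers for GMT), duplicate sample columns or feature
#' IDs, non-numeric values, out-of-range scores, bad group labels — without
#' running any stage. Nothing is silently dropped: every issue found is a
#' row of the report.
#'
#' @param config a [pipeline_config()] (paths may also be passed as a named
#'   list with the same fields).
#' @return Tibble (file, line, issue); zero rows when everything is well
#'   formed.
#' @export
validate_inputs <- function(config) {
  issues <- list()
  note <- function(file, line, issue) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      file = file, line = line, issue = issue
    )
  }
  check_expr <- function(path) {
    if (is.null(path)) return(invisible())
    if (!file.exists(path)) return(note(path, NA_integer_, "file not found"))
    x <- tryCatch(
      suppressMessages(readr::read_tsv(path, comment = "#",
                                       show_col_types = FALSE, progress = FALSE,
                                       name_repair = "minimal")),
      error = function(e) e
    )
    if (inherits(x, "error")) return(note(path, NA_integer_, conditionMessage(x)))
    if (anyDuplicated(names(x)[-1L])) {
      note(path, 1L, paste0("duplicate sample column(s): ",
                            paste(unique(names(x)[-1L][duplicated(names(x)[-1L])]),
                                  collapse = ", ")))
    }
    if (anyDuplicated(x[[1L]])) note(path, NA_integer_, "duplicate feature IDs")
    numeric_cols <- purrr::map_lgl(x[-1L], is.numeric)
    if (!all(numeric_cols)) {
      note(path, NA_integer_, paste0("non-numeric sample column(s): ",
                                     paste(names(x)[-1L][!numeric_cols], collapse = ", ")))
    }
  }
  check_expr(config$mirna)
  check_expr(config$mrna)

  if (!is.null(config$meta)) {
    if (!file.exists(config$meta)) {
      note(config$meta, NA_integer_, "file not found")
    } else {
      m <- tryCatch(read_tsv_quiet(config$meta), error = function(e) e)
      if (inherits(m, "error")) {
        note(config$meta, NA_integer_, conditionMessage(m))
      } else {
        if (!all(c("sample_id", "group") %in% names(m))) {
          note(config$meta, 1L, "missing sample_id/group columns")
        } else {
          bad <- which(!m$group %in% c("case", "control"))
          for (i in bad) note(config$meta, i + 1L,
                              paste0("bad group label: ", m$group[i]))
        }
      }
    }
  }

  if (!is.null(config$targets)) {
    if (!file.exists(config$targets)) {
      note(config$targets, NA_integer_, "file not found")
    } else {
      tg <- tryCatch(read_tsv_quiet(config$targets), error = function(e) e)
      if (inherits(tg, "error")) {
        note(config$targets, NA_integer_, conditionMessage(tg))
      } else if (!all(c("mirna_id", "gene_id", "score") %in% names(tg))) {
        note(config$targets, 1L, "missing mirna_id/gene_id/score columns")
      } else {
        bad <- which(!is.finite(tg$score) | tg$score < 0 | tg$score > 1)
        for (i in head(bad, 20L)) {
          note(config$targets, i + 1L, "score outside [0, 1]")
        }
      }
    }
  }

  if (!is.null(config$gmt)) {
    if (!file.exists(config$gmt)) {
      note(config$gmt, NA_integer_, "file not found")
    } else {
      lines <- readLines(config$gmt)
      for (i in seq_along(lines)) {
        nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1L]])
        if (nf < 3L) note(config$gmt, i, sprintf("GMT line has %d field(s), needs >= 3", nf))
      }
    }
  }

  for (fld in c("drugs", "qpcr")) {
    path <- config[[fld]]
    if (is.null(path)) next
    if (!file.exists(path)) note(path, NA_integer_, "file not found")
  }

  if (length(issues) == 0L) {
    return(tibble::tibble(file = character(0), line = integer(0),
                          issue = character(0)))
  }
  dplyr::bind_rows(issues)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "mirvalve_stage_error")
  })
}

#' Run the full integrated analysis pipeline
#'
#' Executes the stage sequence — differential expression (miRNA and mRNA),
#' miRNA co-expression network with MCL clustering, paired-sample
#' interaction calling with the permutation null, gene-set
#' over-representation (if a GMT is supplied), drug-target prioritization
#' (if a drug table is supplied) and qPCR statistics (if a Ct table is
#' supplied) — writing each stage's table under `config$out_dir` with a
#' provenance header, plus a `manifest.json` recording version, parameters
#' and per-stage row counts. Reruns with the same config and seed
#' reproduce all outputs byte for byte. A stage failure aborts with the
#' stage name; artifacts already written are retained next to a `FAILED`
#' marker naming the stage.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "mirvalve_config"))
  for (fld in c("mirna", "mrna", "meta", "targets")) {
    if (is.null(config[[fld]]) || !file.exists(config[[fld]])) {
      abort(sprintf("required input '%s' missing or not found: %s",
                    fld, config[[fld]] %||% "<NULL>"))
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fail_marker <- file.path(config$out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  on_fail <- function(stage) writeLines(stage, fail_marker)

  manifest <- list(
    tool = "mirvalve",
    version = as.character(utils::packageVersion("mirvalve")),
    seed = config$seed,
    config_hash = config_hash(config),
    parameters = unclass(config)[setdiff(names(unclass(config)),
                                         c("out_dir"))],
    stages = list()
  )
  counts <- function(...) list(...)

  result <- tryCatch({
    mirna <- read_expression(config$mirna)
    mrna <- read_expression(config$mrna)
    meta <- read_metadata(config$meta)
    targets <- read_target_scores(config$targets)

    ## stage: differential expression
    de_mi <- run_stage("de", differential_expression(mirna, meta, config$alpha))
    de_mr <- run_stage("de", differential_expression(mrna, meta, config$alpha))
    write_stage_tsv(tibble::as_tibble(de_mi),
                    file.path(config$out_dir, "de_mirna.tsv"), config)
    write_stage_tsv(tibble::as_tibble(de_mr),
                    file.path(config$out_dir, "de_mrna.tsv"), config)
    manifest$stages$de <- counts(
      mirna_features = nrow(de_mi), mirna_significant = sum(de_mi$significant),
      mirna_down = sum(de_mi$significant & de_mi$direction == "down"),
      mrna_features = nrow(de_mr), mrna_significant = sum(de_mr$significant)
    )

    ## stage: co-expression network + MCL
    net <- run_stage("network", {
      sig_mi <- de_mi$feature_id[de_mi$significant]
      if (length(sig_mi) < 2L) {
        abort("fewer than 2 significant miRNAs; no network to build.")
      }
      g <- suppressWarnings(correlation_graph(
        mirna, features = sig_mi,
        threshold = config$cor_threshold, mode = config$cor_mode
      ))
      cl <- mcl(g, inflation = config$inflation, expansion = config$expansion,
                prune_below = config$prune_below,
                max_iter = config$max_iter, tol = config$tol)
      list(graph = g, clusters = cl)
    })
    write_stage_tsv(net$graph$edges,
                    file.path(config$out_dir, "coexpression_edges.tsv"), config)
    write_stage_tsv(tibble::as_tibble(net$clusters),
                    file.path(config$out_dir, "mcl_clusters.tsv"), config)
    write_stage_tsv(degree_table(net$graph),
                    file.path(config$out_dir, "mirna_degrees.tsv"), config)
    manifest$stages$network <- counts(
      nodes = length(net$graph$nodes), edges = nrow(net$graph$edges),
      clusters = attr(net$clusters, "n_clusters"),
      mcl_converged = attr(net$clusters, "converged")
    )

    ## stage: paired-sample integration with permutation null
    perm <- run_stage("integrate", {
      samp <- config$integration_samples
      if (is.null(samp)) {
        grp <- meta$group[match(names(mirna)[-1L], meta$sample_id)]
        samp <- c(head(names(mirna)[-1L][grp == "case"], 10L),
                  head(names(mirna)[-1L][grp == "control"], 10L))
      }
      missing <- setdiff(samp, intersect(names(mirna), names(mrna)))
      if (length(missing) > 0L) {
        abort(paste0("integration samples absent from both matrices: ",
                     paste(head(missing, 5L), collapse = ", ")))
      }
      sub_mi <- mirna[, c("feature_id", samp)]
      sub_mr <- mrna[, c("feature_id", samp)]
      permutation_null(
        de_mi, de_mr, sub_mi, sub_mr, targets,
        score_threshold = config$score_threshold, alpha = config$alpha,
        n_permutations = config$n_permutations, seed = config$seed
      )
    })
    write_stage_tsv(tibble::as_tibble(perm$interactions),
                    file.path(config$out_dir, "interactions.tsv"), config)
    write_stage_tsv(tidy(perm),
                    file.path(config$out_dir, "permutation_counts.tsv"), config)
    jsonlite::write_json(
      glance(perm), file.path(config$out_dir, "permutation_summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
    )
    manifest$stages$integrate <- counts(
      candidates = nrow(perm$interactions),
      significant = perm$observed_count,
      exceedances = perm$exceedances,
      p_perm = perm$p_perm, ci_low = perm$ci_low, ci_high = perm$ci_high
    )

    ## stage: enrichment
    if (!is.null(config$gmt)) {
      enr <- run_stage("enrich", {
        sets <- read_gmt(config$gmt)
        sig <- perm$interactions[perm$interactions$significant, ]
        query <- intersect(unique(sig$gene_id), mrna$feature_id)
        if (length(query) == 0L) {
          abort("no significant network genes to enrich.")
        }
        enrich_genes(query, sets, universe = mrna$feature_id,
                     alpha = config$alpha)
      })
      write_stage_tsv(enr, file.path(config$out_dir, "enrichment.tsv"), config)
      manifest$stages$enrich <- counts(
        sets_tested = nrow(enr), significant = sum(enr$significant)
      )
    }

    ## stage: drug-target prioritization
    if (!is.null(config$drugs)) {
      drug_rep <- run_stage("drugs", {
        drugs <- read_drug_table(config$drugs)
        network <- build_full_network(perm$interactions)
        report <- rank_drug_targets(de_mr, network, drugs,
                                    min_fold = config$min_fold,
                                    min_degree = config$min_degree,
                                    allowed_types = config$allowed_types)
        if (nrow(report) > 0L) {
          igraph::write_graph(drug_subnetwork(network, report),
                              file.path(config$out_dir, "drug_subnetwork.graphml"),
                              format = "graphml")
        }
        report
      })
      write_stage_tsv(drug_rep,
                      file.path(config$out_dir, "drug_targets.tsv"), config)
      manifest$stages$drugs <- counts(
        genes = nrow(drug_rep),
        connected = sum(drug_rep$category == "connected")
      )
    }

    ## stage: qPCR validation statistics
    if (!is.null(config$qpcr)) {
      qp <- run_stage("qpcr", {
        tbl <- read_qpcr(config$qpcr)
        dct <- delta_ct(tbl, references = config$qpcr_refs,
                        censor = config$censor)
        list(dct = dct, summary = qpcr_compare(dct))
      })
      write_stage_tsv(tibble::as_tibble(qp$dct),
                      file.path(config$out_dir, "qpcr_delta_ct.tsv"), config)
      write_stage_tsv(qp$summary,
                      file.path(config$out_dir, "qpcr_summary.tsv"), config)
      manifest$stages$qpcr <- counts(
        wells = nrow(qp$dct), probes = nrow(qp$summary),
        censored = attr(qp$dct, "n_censored"),
        samples_dropped = attr(qp$dct, "n_samples_dropped")
      )
    }

    manifest
  }, error = function(e) {
    stage <- if (inherits(e, "mirvalve_stage_error")) {
      sub("^pipeline stage '([^']+)'.*$", "\\1", conditionMessage(e))
    } else "input"
    on_fail(stage)
    abort(conditionMessage(e), parent = e)
  })

  jsonlite::write_json(result, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(result)
}
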