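#' Welch's unequal-variance two-sample t-test
#'
#' Thin, validated wrapper used by [differential_expression()]. The
#' unequal-variance form is the default because the case and control groups
#' in valve-tissue studies differ in size and spread. When both groups are
#' exactly constant the conventional values t = 0, p = 1 (equal means) or
#' |t| = Inf, p = 0 (different means) are returned rather than an error.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return A tibble with columns `t`, `df`, `p` (two-sided).
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("each group needs at least 2 values.")
  }
  if (any(!is.finite(c(group_a, group_b)))) abort("non-finite values in input.")
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  if (va + vb == 0) {
    d <- mean(group_a) - mean(group_b)
    if (d == 0) return(tibble::tibble(t = 0, df = NA_real_, p = 1))
    return(tibble::tibble(t = sign(d) * Inf, df = NA_real_, p = 0))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = FALSE)
  tibble::tibble(t = unname(fit$statistic), df = unname(fit$parameter),
                 p = fit$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values (FDR), same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  check_probability(p_values, "p_values")
  stats::p.adjust(p_values, method = "BH")
}

#' Two-group differential expression with FDR control
#'
#' Runs a Welch t-test per feature of a log2 expression table, reports
#' signed log2 fold change (case minus control) and linear fold change
#' `2^log2fc`, and flags features with Benjamini-Hochberg adjusted p below
#' `alpha`.
#'
#' @param x expression tibble (`feature_id` column plus one numeric column
#'   per sample).
#' @param meta sample metadata with columns `sample_id` and `group`
#'   (`"case"`/`"control"`).
#' @param alpha FDR threshold for the significance flag.
#' @return A tibble of class `mirvalve_de` with one row per feature:
#'   feature_id, mean_case, mean_control, log2fc, fold_change, t, df, p,
#'   p_adj, direction, significant. `glance()` summarises the up/down counts
#'   among significant features; `autoplot()` draws a volcano plot.
#' @export
differential_expression <- function(x, meta, alpha = 0.05) {
  m <- expr_to_matrix(x)
  grp <- check_metadata(meta, colnames(m))
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1].")
  case <- m[, grp == "case", drop = FALSE]
  ctrl <- m[, grp == "control", drop = FALSE]

  tests <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    welch_t_test(case[i, ], ctrl[i, ])
  })
  mc <- unname(rowMeans(case))
  mk <- unname(rowMeans(ctrl))
  out <- tibble::tibble(
    feature_id = rownames(m),
    mean_case = mc,
    mean_control = mk,
    log2fc = mc - mk,
    fold_change = 2^(mc - mk),
    t = tests$t, df = tests$df, p = tests$p,
    p_adj = benjamini_hochberg(tests$p),
    direction = ifelse(mc - mk > 0, "up", "down")
  )
  out$significant <- out$p_adj < alpha
  structure(out,
    class = c("mirvalve_de", class(out)),
    alpha = alpha,
    kind = attr(x, "kind") %||% NA_character_
  )
}

#' @export
glance.mirvalve_de <- function(x, ...) {
  sig <- x[x$significant, ]
  tibble::tibble(
    n_features = nrow(x),
    n_significant = nrow(sig),
    n_up = sum(sig$direction == "up"),
    n_down = sum(sig$direction == "down"),
    alpha = attr(x, "alpha")
  )
}

#' @export
tidy.mirvalve_de <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Volcano plot of a differential-expression table
#'
#' @param object a `mirvalve_de` table.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mirvalve_de <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = log2fc, y = -log10(p),
                                       colour = significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = expression(-log[10] ~ p),
                  colour = sprintf("FDR < %.2g", attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}

#' Principal-component projection of samples
#'
#' Projects samples onto the leading principal components of the centred
#' feature space. Component signs are fixed deterministically (the loading
#' of largest magnitude is made positive) so results are reproducible up to
#' that convention.
#'
#' @param x expression tibble.
#' @param n_components number of components, at most `min(features, samples)`.
#' @return A tibble of class `mirvalve_pca`: sample_id plus PC columns, with
#'   the proportion of variance explained in `attr(, "var_explained")`.
#' @export
pca_projection <- function(x, n_components = 2L) {
  m <- expr_to_matrix(x)
  if (ncol(m) < 2L) abort("need at least 2 samples.")
  n_components <- check_count(n_components, "n_components")
  if (n_components > min(dim(m))) {
    abort("n_components exceeds min(features, samples).")
  }
  fit <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- n_components
  scores <- fit$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    pivot <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[pivot, j] < 0) scores[, j] <- -scores[, j]
  }
  out <- tibble::as_tibble(scores, rownames = "sample_id")
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(out, class = c("mirvalve_pca", class(out)),
            var_explained = ve[seq_len(k)])
}

#' PCA scatter plot coloured by group
#'
#' @param object a `mirvalve_pca` table.
#' @param meta optional sample metadata for group colouring.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mirvalve_pca <- function(object, meta = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(meta)) {
    df <- dplyr::left_join(df, meta[, c("sample_id", "group")], by = "sample_id")
  } else {
    df$group <- "sample"
  }
  ve <- attr(object, "var_explained")
  ggplot2::ggplot(df, ggplot2::aes(PC1, PC2, colour = group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1L]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2L])) +
    ggplot2::theme_minimal()
}

#' Hierarchical clustering orderings for heatmap display
#'
#' Features are clustered with average linkage on the correlation distance
#' `1 - Pearson r`; samples with average linkage on Euclidean distance.
#' Features are sorted by ID before clustering so the result does not depend
#' on input row order. Constant features (zero variance) are dropped with a
#' warning, since their correlation distance is undefined.
#'
#' @param x expression tibble with >= 2 features and >= 2 samples.
#' @return A list with character vectors `feature_order` and `sample_order`
#'   and the two `hclust` objects.
#' @export
hierarchical_order <- function(x) {
  m <- expr_to_matrix(x)
  if (nrow(m) < 2L || ncol(m) < 2L) abort("need >= 2 features and >= 2 samples.")
  m <- m[order(rownames(m)), , drop = FALSE]
  m <- drop_constant_features(m, "hierarchical clustering")
  if (nrow(m) < 2L) abort("fewer than 2 non-constant features.")
  feat_d <- stats::as.dist(1 - stats::cor(t(m)))
  hf <- stats::hclust(feat_d, method = "average")
  hs <- stats::hclust(stats::dist(t(m)), method = "average")
  list(
    feature_order = rownames(m)[hf$order],
    sample_order = colnames(m)[hs$order],
    feature_hclust = hf,
    sample_hclust = hs
  )
}

#' Collapse probe-level rows to unique gene identifiers
#'
#' When several probes map to the same gene, the probe with the highest mean
#' expression is kept (a standard collapse rule for array data).
#'
#' @param x expression tibble keyed by probe `feature_id`.
#' @param probe_map tibble with columns `feature_id`, `gene_id`.
#' @return Expression tibble keyed by `gene_id` (as `feature_id`).
#' @export
collapse_to_genes <- function(x, probe_map) {
  if (!all(c("feature_id", "gene_id") %in% names(probe_map))) {
    abort("`probe_map` needs columns feature_id and gene_id.")
  }
  m <- expr_to_matrix(x)
  mapped <- probe_map[probe_map$feature_id %in% rownames(m), ]
  keep <- mapped |>
    dplyr::mutate(mean_expr = rowMeans(m[feature_id, , drop = FALSE])) |>
    dplyr::group_by(gene_id) |>
    dplyr::slice_max(mean_expr, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  out <- m[keep$feature_id, , drop = FALSE]
  rownames(out) <- keep$gene_id
  matrix_to_expr(out[order(rownames(out)), , drop = FALSE])
}
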