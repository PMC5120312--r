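#' Delta-Ct normalization of a qPCR table
#'
#' Wells with Ct above the censoring threshold (default cycle 35) are
#' marked not detected and excluded. Each sample's target Ct is referenced
#' to the arithmetic mean Ct of the reference probes (equivalent to their
#' geometric mean in linear expression space); samples missing any
#' reference probe are dropped with a reported count. Relative expression
#' is `2^-deltaCt`.
#'
#' @param table tibble (sample_id, group, probe_id, ct).
#' @param references character vector of reference probe IDs (non-empty).
#' @param censor censoring threshold in cycles (default 35).
#' @return A tibble of class `mirvalve_dct` (sample_id, group, probe_id,
#'   ct, delta_ct, rel_expr) for the non-reference probes, with attributes
#'   `references`, `censor`, `n_censored`, `n_samples_dropped`.
#' @export
delta_ct <- function(table, references, censor = 35) {
  if (!all(c("sample_id", "group", "probe_id", "ct") %in% names(table))) {
    abort("`table` needs columns sample_id, group, probe_id, ct.")
  }
  if (length(references) == 0L) abort("`references` must be non-empty.")
  missing_refs <- setdiff(references, unique(table$probe_id))
  if (length(missing_refs) > 0L) {
    abort(paste0("reference probe(s) absent from table: ",
                 paste(missing_refs, collapse = ", ")))
  }
  tbl <- dplyr::mutate(table, detected = ct <= censor)
  n_censored <- sum(!tbl$detected)

  ref_ok <- tbl |>
    dplyr::filter(probe_id %in% references) |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(
      all_detected = sum(detected) == length(references),
      ref_mean = mean(ct[detected]),
      .groups = "drop"
    )
  dropped <- ref_ok$sample_id[!ref_ok$all_detected]
  if (length(dropped) > 0L) {
    inform(sprintf("%d sample(s) dropped: undetected reference probe.",
                   length(dropped)))
  }
  refs <- ref_ok[ref_ok$all_detected, c("sample_id", "ref_mean")]

  out <- tbl |>
    dplyr::filter(!(probe_id %in% references), detected) |>
    dplyr::inner_join(refs, by = "sample_id") |>
    dplyr::transmute(
      sample_id, group, probe_id, ct,
      delta_ct = ct - ref_mean,
      rel_expr = 2^(-(ct - ref_mean))
    )
  structure(out,
    class = unique(c("mirvalve_dct", class(out))),
    references = references, censor = censor,
    n_censored = n_censored, n_samples_dropped = length(dropped)
  )
}

#' Per-target group comparison of delta-Ct values
#'
#' Mann-Whitney comparison of case vs control delta-Ct per target probe.
#' The delta-delta-Ct (mean case minus mean control) converts to a linear
#' fold change as `2^-ddCt`. All retained wells enter the test; any
#' outlier trimming is a display concern only.
#'
#' @param dct a `mirvalve_dct` table from [delta_ct()].
#' @return Tibble (probe_id, n_case, n_control, median_dct_case,
#'   median_dct_control, delta_delta_ct, fold_change, U, p, method).
#' @export
qpcr_compare <- function(dct) {
  stopifnot(inherits(dct, "mirvalve_dct"))
  dct |>
    tibble::as_tibble() |>
    dplyr::group_by(probe_id) |>
    dplyr::group_modify(function(d, key) {
      a <- d$delta_ct[d$group == "case"]
      b <- d$delta_ct[d$group == "control"]
      mw <- mann_whitney_exact(a, b)
      tibble::tibble(
        n_case = length(a), n_control = length(b),
        median_dct_case = stats::median(a),
        median_dct_control = stats::median(b),
        delta_delta_ct = mean(a) - mean(b),
        fold_change = 2^(-(mean(a) - mean(b))),
        U = mw$U, p = mw$p, method = mw$method
      )
    }) |>
    dplyr::ungroup()
}

#' Mann-Whitney U test with exact small-sample p-value
#'
#' Uses the exact null distribution of U when the combined sample size is
#' at most 20 and the pooled data are tie-free; otherwise the normal
#' approximation with tie correction and continuity correction. The method
#' actually used is reported alongside the p-value.
#'
#' @param group_a,group_b numeric vectors, each non-empty.
#' @return A tibble with columns `U` (number of (a, b) pairs with a > b,
#'   plus half-ties), `p` (two-sided) and `method`.
#' @export
mann_whitney_exact <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort("both groups must be non-empty.")
  }
  pooled <- c(group_a, group_b)
  if (any(!is.finite(pooled))) abort("non-finite values in input.")
  has_ties <- anyDuplicated(pooled) > 0L
  use_exact <- (length(pooled) <= 20L) && !has_ties
  fit <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = use_exact, correct = TRUE)
  )
  tibble::tibble(
    U = unname(fit$statistic),
    p = min(1, fit$p.value),
    method = if (use_exact) "exact" else "normal approximation"
  )
}

#' NormFinder-style reference-gene stability
#'
#' Model-based variance decomposition for choosing stable reference genes
#' on log-scale data (log2 expression or Ct values). Each sample is first
#' centred across the candidate genes, removing sample-specific loading.
#' Within each group the per-gene residual (intragroup) variance is
#' estimated with an unbiased correction for the shared centring (this
#' needs at least 3 candidates), and the per-gene intergroup deviation is
#' estimated from the group means of the centred values, shrunk by its
#' sampling error. The stability value combines the magnitude of the
#' shrunken intergroup deviation with the average intragroup sampling
#' noise; lower is more stable.
#'
#' @param x expression tibble (`feature_id` plus sample columns) of
#'   candidate reference genes; at least 3 candidates.
#' @param meta sample metadata with `sample_id` and `group`; each group
#'   needs at least 2 samples.
#' @return Tibble (feature_id, intragroup_var, intergroup_var, stability)
#'   sorted by increasing stability (most stable first), with the
#'   per-group components in `attr(, "per_group")`.
#' @export
normfinder_stability <- function(x, meta) {
  y <- expr_to_matrix(x)
  k <- nrow(y)
  if (k < 3L) abort("need at least 3 candidate genes.")
  grp <- check_metadata(meta, colnames(y))
  groups <- unique(grp)
  n_g <- table(grp)
  if (any(n_g < 2L)) abort("every group needs at least 2 samples.")
  G <- length(groups)

  # remove per-sample loading: centre each sample across candidates
  z <- sweep(y, 2L, colMeans(y))

  d <- matrix(0, k, G, dimnames = list(rownames(y), groups))
  sigma2 <- matrix(0, k, G, dimnames = list(rownames(y), groups))
  for (gi in seq_len(G)) {
    zg <- z[, grp == groups[gi], drop = FALSE]
    d[, gi] <- rowMeans(zg)
    v <- apply(zg, 1L, stats::var)
    # unbiased intragroup variance: centring mixes 1/k of every other
    # gene's noise into each row, so invert that linear map
    s_hat <- (k / (k - 1)) * sum(v)
    sigma2[, gi] <- pmax(0, (v - s_hat / k^2) / (1 - 2 / k))
  }
  dd <- d - rowMeans(d)
  n_per <- as.numeric(n_g[groups])
  se2 <- sweep(sigma2, 2L, n_per, "/")
  gamma2 <- pmax(0, rowSums(dd^2) / (G - 1) - rowMeans(se2))
  shrink <- gamma2 / (gamma2 + se2)
  shrink[!is.finite(shrink)] <- 0
  d_shrunk <- dd * shrink

  stability <- rowMeans(abs(d_shrunk)) + sqrt(rowMeans(se2))
  out <- tibble::tibble(
    feature_id = rownames(y),
    intragroup_var = unname(rowMeans(sigma2)),
    intergroup_var = unname(gamma2),
    stability = unname(stability)
  ) |>
    dplyr::arrange(stability, feature_id)
  per_group <- tibble::as_tibble(sigma2, rownames = "feature_id") |>
    tidyr::pivot_longer(-feature_id, names_to = "group",
                        values_to = "intragroup_var")
  structure(out, per_group = per_group)
}
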