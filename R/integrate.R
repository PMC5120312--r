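#' Spearman rank correlation with t-approximation p-value
#'
#' Midranks are used for ties and the p-value comes from the
#' t-approximation on n - 2 degrees of freedom, the practical choice at the
#' paired-sample sizes (n ~ 20) this pipeline targets, where exact
#' enumeration of rank permutations is infeasible.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param alternative `"two.sided"`, `"less"` (negative association) or
#'   `"greater"`.
#' @return A tibble with columns `rho`, `p`. Constant input yields NA with
#'   a warning (the caller skips such pairs).
#' @export
spearman_rho <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 4L) abort("need at least 4 paired observations.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("constant input: Spearman correlation undefined; returning NA.")
    return(tibble::tibble(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- spearman_p(rho, n, alternative)
  tibble::tibble(rho = rho, p = p)
}

spearman_p <- function(rho, n, alternative) {
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  tt[rho >= 1] <- Inf
  tt[rho <= -1] <- -Inf
  switch(alternative,
    two.sided = 2 * stats::pt(-abs(tt), df = n - 2),
    less = stats::pt(tt, df = n - 2),
    greater = stats::pt(tt, df = n - 2, lower.tail = FALSE)
  )
}

#' Call miRNA-mRNA interactions from paired expression profiles
#'
#' Target-prediction-filtered anti-correlation calling: the candidate
#' universe is all (miRNA, gene) pairs in the target-score table whose
#' aggregated score meets `score_threshold` and whose miRNA and gene are
#' both flagged significant in the supplied differential-expression tables.
#' For each candidate, Spearman correlation is computed across the paired
#' samples (both matrices must carry an identical ordered sample set), the
#' p-values are Benjamini-Hochberg adjusted across all candidates, and
#' pairs with adjusted p below `alpha` are called significant. Scores for
#' duplicated (miRNA, gene) rows (e.g. multiple transcripts) are aggregated
#' by their mean before filtering.
#'
#' @param mirna_de,mrna_de `mirvalve_de` tables (or any tibble with
#'   feature_id and significant columns) defining the DE universe.
#' @param mirna_expr,mrna_expr expression tibbles over the same ordered
#'   samples (typically the paired per-sample subset).
#' @param targets tibble (mirna_id, gene_id, score in \[0, 1\]).
#' @param score_threshold minimum aggregated target score (default 0.8).
#' @param alpha FDR threshold for the significant flag.
#' @param sidedness `"one"` tests for negative correlation only (repression
#'   is the modelled mechanism); `"two"` is two-sided.
#' @return A tibble of class `mirvalve_interactions` (mirna_id, gene_id,
#'   score, rho, p, p_adj, significant) with attributes recording the
#'   settings, the number of DE genes recognized in the target table and
#'   the observed significant count.
#' @export
call_interactions <- function(mirna_de, mrna_de, mirna_expr, mrna_expr,
                              targets, score_threshold = 0.8, alpha = 0.05,
                              sidedness = c("one", "two")) {
  sidedness <- match.arg(sidedness)
  mi <- expr_to_matrix(mirna_expr, "mirna_expr")
  mr <- expr_to_matrix(mrna_expr, "mrna_expr")
  if (!identical(colnames(mi), colnames(mr))) {
    abort("miRNA and mRNA matrices must share an identical ordered sample set.")
  }
  n <- ncol(mi)
  if (n < 4L) abort("need at least 4 paired samples.")
  if (!all(c("mirna_id", "gene_id", "score") %in% names(targets))) {
    abort("`targets` needs columns mirna_id, gene_id, score.")
  }
  check_probability(targets$score, "targets$score")

  de_mi <- mirna_de$feature_id[mirna_de$significant]
  de_mr <- mrna_de$feature_id[mrna_de$significant]

  agg <- targets |>
    dplyr::group_by(mirna_id, gene_id) |>
    dplyr::summarise(score = mean(score), .groups = "drop")

  recognized <- length(intersect(de_mr, unique(agg$gene_id)))

  cand <- agg |>
    dplyr::filter(score >= score_threshold,
                  mirna_id %in% de_mi, gene_id %in% de_mr,
                  mirna_id %in% rownames(mi), gene_id %in% rownames(mr))

  empty <- tibble::tibble(
    mirna_id = character(0), gene_id = character(0), score = numeric(0),
    rho = numeric(0), p = numeric(0), p_adj = numeric(0),
    significant = logical(0)
  )
  if (nrow(cand) == 0L) {
    return(new_interactions(empty, n, alpha, score_threshold, sidedness, recognized))
  }

  # rank-transform each needed row once, then correlate pairwise
  mi_rows <- unique(cand$mirna_id)
  mr_rows <- unique(cand$gene_id)
  rk_mi <- t(apply(mi[mi_rows, , drop = FALSE], 1L, rank))
  rk_mr <- t(apply(mr[mr_rows, , drop = FALSE], 1L, rank))
  sd_mi <- apply(rk_mi, 1L, stats::sd)
  sd_mr <- apply(rk_mr, 1L, stats::sd)
  const <- cand$mirna_id %in% mi_rows[sd_mi == 0] |
    cand$gene_id %in% mr_rows[sd_mr == 0]
  if (any(const)) {
    warn(sprintf("%d candidate pair(s) skipped: constant expression.", sum(const)))
    cand <- cand[!const, ]
    if (nrow(cand) == 0L) {
      return(new_interactions(empty, n, alpha, score_threshold, sidedness, recognized))
    }
  }
  rmat <- stats::cor(t(rk_mi), t(rk_mr))
  rho <- rmat[cbind(match(cand$mirna_id, mi_rows), match(cand$gene_id, mr_rows))]
  p <- spearman_p(rho, n, if (sidedness == "one") "less" else "two.sided")
  out <- cand |>
    dplyr::mutate(rho = rho, p = p, p_adj = benjamini_hochberg(p),
                  significant = p_adj < alpha) |>
    dplyr::arrange(p_adj, p, mirna_id, gene_id)
  new_interactions(out, n, alpha, score_threshold, sidedness, recognized)
}

new_interactions <- function(tbl, n, alpha, score_threshold, sidedness, recognized) {
  structure(tbl,
    class = unique(c("mirvalve_interactions", class(tbl))),
    n_samples = n, alpha = alpha, score_threshold = score_threshold,
    sidedness = sidedness, n_recognized_genes = recognized,
    observed_count = sum(tbl$significant)
  )
}

#' @export
glance.mirvalve_interactions <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x),
    n_significant = attr(x, "observed_count"),
    n_recognized_genes = attr(x, "n_recognized_genes"),
    n_samples = attr(x, "n_samples"),
    score_threshold = attr(x, "score_threshold"),
    alpha = attr(x, "alpha"),
    sidedness = attr(x, "sidedness")
  )
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computed from Beta-distribution quantiles; the lower bound is 0 when
#' there are no successes and the upper bound is 1 when every trial
#' succeeds.
#'
#' @param successes,trials integer counts, 0 <= successes <= trials.
#' @param level confidence level (default 0.95).
#' @return A tibble with columns estimate, low, high.
#' @export
clopper_pearson_ci <- function(successes, trials, level = 0.95) {
  successes <- check_count(successes, "successes", 0L)
  trials <- check_count(trials, "trials", 1L)
  if (successes > trials) abort("`successes` must not exceed `trials`.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  a <- (1 - level) / 2
  low <- if (successes == 0L) 0 else stats::qbeta(a, successes, trials - successes + 1)
  high <- if (successes == trials) 1 else stats::qbeta(1 - a, successes + 1, trials - successes)
  tibble::tibble(estimate = successes / trials, low = low, high = high)
}

#' Permutation null for the significant-interaction count
#'
#' Re-runs [call_interactions()] after each of `n_permutations` random
#' permutations of the miRNA identity labels among the differentially
#' expressed miRNAs' expression rows. Shuffling identities breaks the link
#' between a miRNA and its predicted targets while preserving the
#' expression correlation structure. The permutation p-value uses the
#' add-one estimator `(b + 1) / (N + 1)`, where `b` counts permutations
#' whose significant-interaction count reaches the observed count, so an
#' observed count exceeding all of 100 permutations reports p = 1/101 <
#' 0.01, never 0. An exact Clopper-Pearson 95% interval is attached to the
#' exceedance proportion `b / N`.
#'
#' @inheritParams call_interactions
#' @param n_permutations number of label permutations (default 100).
#' @param seed integer seed for the permutation stream.
#' @param level confidence level for the exceedance interval.
#' @return An object of class `mirvalve_perm`: list with the observed
#'   `interactions` table, `observed_count`, `perm_counts`, `exceedances`,
#'   `p_perm`, `ci_low`, `ci_high`, `n_permutations`, `seed`. `tidy()`
#'   returns the per-permutation counts, `glance()` the one-row summary,
#'   `autoplot()` the null histogram with the observed count marked.
#' @export
permutation_null <- function(mirna_de, mrna_de, mirna_expr, mrna_expr,
                             targets, score_threshold = 0.8, alpha = 0.05,
                             sidedness = c("one", "two"),
                             n_permutations = 100L, seed = 1L, level = 0.95) {
  sidedness <- match.arg(sidedness)
  n_permutations <- check_count(n_permutations, "n_permutations", 1L)
  observed <- call_interactions(mirna_de, mrna_de, mirna_expr, mrna_expr,
                                targets, score_threshold, alpha, sidedness)
  obs_count <- attr(observed, "observed_count")

  de_mi <- mirna_de$feature_id[mirna_de$significant]
  de_mi <- intersect(de_mi, mirna_expr$feature_id)

  # The candidate pair list is fixed under label permutation; only the
  # expression row a DE miRNA identity points to changes. Precomputing the
  # rank-correlation matrix of all DE miRNA rows against all candidate gene
  # rows makes each permutation a pure index lookup, with results identical
  # to re-running call_interactions on a relabelled matrix.
  cand <- observed[, c("mirna_id", "gene_id")]
  n <- attr(observed, "n_samples")
  perm_counts <- if (nrow(cand) == 0L || length(de_mi) < 2L) {
    rep(0L, n_permutations)
  } else {
    mi <- expr_to_matrix(mirna_expr, "mirna_expr")
    mr <- expr_to_matrix(mrna_expr, "mrna_expr")
    genes <- unique(cand$gene_id)
    rk_mi <- t(apply(mi[de_mi, , drop = FALSE], 1L, rank))
    rk_mr <- t(apply(mr[genes, , drop = FALSE], 1L, rank))
    ok_mi <- apply(rk_mi, 1L, stats::sd) > 0
    ok_mr <- apply(rk_mr, 1L, stats::sd) > 0
    rmat <- matrix(NA_real_, length(de_mi), length(genes),
                   dimnames = list(de_mi, genes))
    if (any(ok_mi) && any(ok_mr)) {
      rmat[ok_mi, ok_mr] <- stats::cor(t(rk_mi[ok_mi, , drop = FALSE]),
                                       t(rk_mr[ok_mr, , drop = FALSE]))
    }
    ci <- match(cand$mirna_id, de_mi)
    gi <- match(cand$gene_id, genes)
    alt <- if (sidedness == "one") "less" else "two.sided"
    withr::with_seed(check_count(seed, "seed", 0L), {
      purrr::map_int(seq_len(n_permutations), function(i) {
        # expression row j is relabelled de_mi[perm[j]], so identity m
        # reads its expression from row which(perm == m)
        perm <- sample.int(length(de_mi))
        invperm <- match(seq_along(de_mi), perm)
        rho <- rmat[cbind(invperm[ci], gi)]
        keep <- !is.na(rho)
        if (!any(keep)) return(0L)
        p <- spearman_p(rho[keep], n, alt)
        sum(benjamini_hochberg(p) < alpha)
      })
    })
  }
  b <- sum(perm_counts >= obs_count)
  ci <- clopper_pearson_ci(b, n_permutations, level)
  structure(
    list(
      interactions = observed,
      observed_count = obs_count,
      perm_counts = perm_counts,
      exceedances = b,
      p_perm = (b + 1) / (n_permutations + 1),
      ci_low = ci$low,
      ci_high = ci$high,
      n_permutations = n_permutations,
      level = level,
      seed = seed
    ),
    class = "mirvalve_perm"
  )
}

#' @export
print.mirvalve_perm <- function(x, ...) {
  cat(sprintf(
    "<mirvalve_perm> observed %d significant interactions; %d/%d permutations reached it\n  p_perm = %.4g, %.0f%% CI on exceedance [%.3f, %.3f]\n",
    x$observed_count, x$exceedances, x$n_permutations, x$p_perm,
    100 * x$level, x$ci_low, x$ci_high
  ))
  invisible(x)
}

#' @export
tidy.mirvalve_perm <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$perm_counts), count = x$perm_counts)
}

#' @export
glance.mirvalve_perm <- function(x, ...) {
  tibble::tibble(
    observed_count = x$observed_count,
    n_permutations = x$n_permutations,
    exceedances = x$exceedances,
    p_perm = x$p_perm,
    ci_low = x$ci_low,
    ci_high = x$ci_high
  )
}

#' Histogram of the permutation null with the observed count marked
#'
#' @param object a `mirvalve_perm` result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mirvalve_perm <- function(object, ...) {
  df <- tidy.mirvalve_perm(object)
  ggplot2::ggplot(df, ggplot2::aes(count)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_count,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "significant interactions per permutation",
                  y = "permutations",
                  subtitle = sprintf("observed = %d, p = %.3g",
                                     object$observed_count, object$p_perm)) +
    ggplot2::theme_minimal()
}
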