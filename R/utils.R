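# Internal helpers shared across modules.

# An expression table is a tibble whose first column is `feature_id`
# (character, unique) and whose remaining columns are numeric log2 values,
# one column per sample.
expr_to_matrix <- function(x, arg = "x") {
  if (!is.data.frame(x) || ncol(x) < 2L) {
    abort(sprintf("`%s` must be a data frame with a feature_id column plus sample columns.", arg))
  }
  if (names(x)[1L] != "feature_id") {
    abort(sprintf("first column of `%s` must be named 'feature_id'.", arg))
  }
  ids <- as.character(x[[1L]])
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate feature IDs in `%s`.", arg))
  }
  if (anyDuplicated(names(x)[-1L])) {
    abort(sprintf("duplicate sample IDs in `%s`.", arg))
  }
  m <- as.matrix(x[, -1L, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("sample columns of `%s` must be numeric.", arg))
  if (any(!is.finite(m))) abort(sprintf("non-finite expression values in `%s`.", arg))
  rownames(m) <- ids
  m
}

matrix_to_expr <- function(m) {
  tibble::as_tibble(m, rownames = "feature_id")
}

check_metadata <- function(meta, sample_ids) {
  if (!all(c("sample_id", "group") %in% names(meta))) {
    abort("metadata must contain columns 'sample_id' and 'group'.")
  }
  missing <- setdiff(sample_ids, meta$sample_id)
  if (length(missing) > 0L) {
    abort(paste0("samples without a group label: ", paste(head(missing, 5L), collapse = ", ")))
  }
  grp <- meta$group[match(sample_ids, meta$sample_id)]
  if (!all(grp %in% c("case", "control"))) {
    abort("group labels must be 'case' or 'control'.")
  }
  if (length(unique(grp)) < 2L) abort("both groups must be non-empty.")
  grp
}

check_probability <- function(p, arg = "p") {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort(sprintf("`%s` must contain probabilities in [0, 1].", arg))
  }
  invisible(p)
}

check_count <- function(x, arg, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", arg, min))
  }
  as.integer(x)
}

drop_constant_features <- function(m, context) {
  v <- apply(m, 1L, stats::var)
  keep <- v > 0
  if (!all(keep)) {
    warn(sprintf(
      "%d constant feature(s) dropped before %s: %s",
      sum(!keep), context, paste(head(rownames(m)[!keep], 5L), collapse = ", ")
    ))
  }
  m[keep, , drop = FALSE]
}
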