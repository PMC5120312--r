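test_that("Welch t-test matches the Welch-Satterthwaite closed form", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 3, 4, 5, 6)
  res <- welch_t_test(a, b)
  # closed-form oracle
  se2 <- var(a) / 5 + var(b) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  expect_equal(res$t, t_hand)
  expect_equal(res$df, df_hand)
  expect_equal(res$p, 2 * (1 - pt(abs(t_hand), df_hand)))
  # randomized cases against the same closed form
  withr::with_seed(8, {
    for (i in 1:20) {
      x <- rnorm(sample(3:9, 1))
      y <- rnorm(sample(3:9, 1), sd = runif(1, 0.5, 2))
      r <- welch_t_test(x, y)
      s2 <- var(x) / length(x) + var(y) / length(y)
      th <- (mean(x) - mean(y)) / sqrt(s2)
      dfh <- s2^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
                       (var(y) / length(y))^2 / (length(y) - 1))
      expect_equal(r$t, th)
      expect_equal(r$p, 2 * (1 - pt(abs(th), dfh)))
    }
  })
})

test_that("Welch t-test symmetry and degenerate conventions hold", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  r <- welch_t_test(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  y <- x + 1
  expect_equal(welch_t_test(x, y)$t, -welch_t_test(y, x)$t)
  expect_equal(welch_t_test(x, y)$p, welch_t_test(y, x)$p)
  # separation limit: p -> 0 as jitter -> 0
  p_big <- welch_t_test(c(0, 0, 0, 0) + c(-1, 1, -1, 1) * 0.1, c(1, 1, 1, 1) + c(1, -1, 1, -1) * 0.1)$p
  p_small <- welch_t_test(c(0, 0, 0, 0) + c(-1, 1, -1, 1) * 1e-4, c(1, 1, 1, 1) + c(1, -1, 1, -1) * 1e-4)$p
  expect_lt(p_small, p_big)
  expect_lt(p_small, 1e-6)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  # both groups constant
  expect_equal(welch_t_test(c(2, 2), c(2, 2))$p, 1)
  expect_equal(welch_t_test(c(3, 3), c(2, 2))$p, 0)
})

test_that("Benjamini-Hochberg matches its step-up definition", {
  expect_equal(benjamini_hochberg(c(0.005, 0.02, 0.03, 0.5)),
               c(0.02, 0.04, 0.04, 0.5))
  expect_equal(benjamini_hochberg(rep(0.3, 7)), rep(0.3, 7))
  expect_equal(benjamini_hochberg(0.123), 0.123)
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  withr::with_seed(5, {
    for (i in 1:25) {
      p <- runif(sample(c(1, 5, 50, 500), 1))
      adj <- benjamini_hochberg(p)
      expect_equal(adj, bh_stepup(p))
      expect_true(all(adj >= p - 1e-12))
      expect_true(all(adj >= 0 & adj <= 1))
      # monotone in ranks
      o <- order(p)
      expect_true(all(diff(adj[o]) >= -1e-12))
    }
  })
})

test_that("BH controls the false discovery proportion on null uniforms", {
  withr::with_seed(42, {
    fdp <- replicate(100, mean(benjamini_hochberg(runif(10000)) < 0.05))
  })
  expect_lte(mean(fdp), 0.05)
})

test_that("differential expression flags planted features and reports exact folds", {
  sim <- simulate_expression(synth_config(de_effect = 2, noise_sd = 0.5,
                                          n_case = 16, n_control = 15,
                                          seed = 6))
  de <- differential_expression(sim$mirna, sim$meta)
  planted <- sim$truth$de_mirna$feature_id
  expect_true(all(de$significant[match(planted, de$feature_id)]))
  expect_true(all(de$direction == ifelse(de$log2fc > 0, "up", "down")))
  expect_true(all(de$p_adj >= de$p - 1e-12))
  g <- glance(de)
  expect_equal(g$n_significant, g$n_up + g$n_down)
  # zero-noise shift of 1 log2 unit is a linear fold of exactly 2
  sim0 <- simulate_expression(synth_config(noise_sd = 0, de_effect = 1,
                                           n_de_mirna = 1, fraction_down = 0,
                                           n_repressive_pairs = 0,
                                           n_de_mrna = 0, seed = 2))
  jitter <- sim0$mirna
  # add tiny noise so tests are defined for the flat features
  set.seed(1)
  jitter[, -1] <- jitter[, -1] + matrix(rnorm(prod(dim(jitter[, -1])), 0, 1e-6),
                                        nrow(jitter))
  de0 <- differential_expression(jitter, sim0$meta)
  expect_equal(de0$fold_change[match(sim0$truth$de_mirna$feature_id,
                                     de0$feature_id)], 2, tolerance = 1e-4)
})

test_that("fold change inverts under a group-label swap", {
  sim <- simulate_expression(synth_config(seed = 13))
  meta_sw <- dplyr::mutate(sim$meta,
                           group = ifelse(group == "case", "control", "case"))
  de <- differential_expression(sim$mirna, sim$meta)
  de_sw <- differential_expression(sim$mirna, meta_sw)
  expect_equal(de_sw$fold_change, 1 / de$fold_change)
  expect_equal(de_sw$t, -de$t)
  expect_equal(de_sw$p, de$p)
})

test_that("null data produce almost no differential calls", {
  frac <- purrr::map_dbl(1:5, function(s) {
    sim <- simulate_expression(synth_config(n_de_mirna = 0, n_de_mrna = 0,
                                            n_repressive_pairs = 0,
                                            seed = 100 + s))
    mean(differential_expression(sim$mirna, sim$meta)$significant)
  })
  expect_lte(mean(frac), 0.05)
})

test_that("PCA projection is deterministic and separates planted groups", {
  sim <- simulate_expression(synth_config(seed = 23))
  pc <- pca_projection(sim$mirna, 2)
  expect_identical(tibble::as_tibble(pc), tibble::as_tibble(pca_projection(sim$mirna, 2)))
  grp <- sim$meta$group[match(pc$sample_id, sim$meta$sample_id)]
  # planted two-group structure dominates PC1: linearly separable
  expect_true(max(pc$PC1[grp == "case"]) < min(pc$PC1[grp == "control"]) ||
                min(pc$PC1[grp == "case"]) > max(pc$PC1[grp == "control"]))
  expect_error(pca_projection(sim$mirna, 1000), "n_components")
  # two identical samples get identical coordinates
  dup <- sim$mirna
  dup$case_02 <- dup$case_01
  pd <- pca_projection(dup, 2)
  expect_equal(pd$PC1[pd$sample_id == "case_01"], pd$PC1[pd$sample_id == "case_02"])
  # rank-1 data: first component carries all the variance
  r1 <- tibble::tibble(feature_id = c("f1", "f2"),
                       s1 = c(1, 2), s2 = c(2, 4), s3 = c(3, 6))
  expect_equal(attr(pca_projection(r1, 1), "var_explained")[1], 1)
})

test_that("hierarchical ordering is input-order invariant and groups blocks", {
  sim <- simulate_expression(synth_config(n_case = 20, n_control = 20,
                                          within_cluster_rho = 0.9,
                                          de_effect = 0, n_clusters = 2,
                                          n_de_mirna = 10, n_mirna = 10,
                                          n_repressive_pairs = 0, seed = 3))
  ord <- hierarchical_order(sim$mirna)
  shuffled <- sim$mirna[sample(nrow(sim$mirna)), ]
  expect_identical(hierarchical_order(shuffled)$feature_order, ord$feature_order)
  # two planted blocks are contiguous in the ordering
  cl <- sim$truth$clusters
  pos <- match(cl$feature_id, ord$feature_order)
  block1 <- sort(pos[cl$cluster == 1])
  expect_equal(block1, seq(min(block1), length.out = length(block1)))
  # duplicated feature rows sit adjacent (zero correlation distance)
  dup <- sim$mirna
  dup <- dplyr::bind_rows(dup, dplyr::mutate(dup[1, ], feature_id = "zzz-dup"))
  ord2 <- hierarchical_order(dup)$feature_order
  expect_equal(abs(diff(match(c(dup$feature_id[1], "zzz-dup"), ord2))), 1)
})

test_that("probe collapse keeps the highest-expressed probe per gene", {
  x <- tibble::tibble(
    feature_id = c("p1", "p2", "p3"),
    s1 = c(1, 5, 2), s2 = c(1, 5, 2), s3 = c(1, 5, 2)
  )
  map <- tibble::tibble(feature_id = c("p1", "p2", "p3"),
                        gene_id = c("G1", "G1", "G2"))
  out <- collapse_to_genes(x, map)
  expect_equal(out$feature_id, c("G1", "G2"))
  expect_equal(out$s1, c(5, 2))
})
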