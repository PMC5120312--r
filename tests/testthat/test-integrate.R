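test_that("Spearman correlation matches hand-ranked computation", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(5, 6, 7, 8, 7)
  res <- spearman_rho(x, y)
  expect_equal(res$rho, hand_spearman(x, y))
  # tie-free trivial cases
  expect_equal(spearman_rho(x, x * 3 + 1)$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)
  # invariant under strictly monotone transforms
  expect_equal(spearman_rho(exp(x), y)$rho, res$rho)
  expect_equal(spearman_rho(x, rank(y))$rho, res$rho)
  # p from the t-approximation with n - 2 df
  tt <- res$rho * sqrt((5 - 2) / (1 - res$rho^2))
  expect_equal(res$p, 2 * pt(-abs(tt), 3))
  withr::with_seed(12, {
    for (i in 1:10) {
      a <- rnorm(8)
      b <- sample(c(rnorm(6), a[1:2]))  # some ties after rounding
      a <- round(a, 1); b <- round(b, 1)
      expect_equal(spearman_rho(a, b)$rho, hand_spearman(a, b))
    }
  })
  expect_warning(out <- spearman_rho(rep(1, 5), x), "constant")
  expect_true(is.na(out$rho))
  expect_error(spearman_rho(1:3, 1:3), "at least 4")
})

test_that("interaction calling recovers a noise-free repressive pair exactly", {
  samples <- sprintf("s%02d", 1:10)
  mi <- tibble::tibble(feature_id = "m1", !!!setNames(as.list(1:10), samples))
  mr <- tibble::tibble(feature_id = "g1", !!!setNames(as.list(10:1), samples))
  de_mi <- tibble::tibble(feature_id = "m1", significant = TRUE)
  de_mr <- tibble::tibble(feature_id = "g1", significant = TRUE)
  tg <- tibble::tibble(mirna_id = "m1", gene_id = "g1", score = 0.9)
  it <- call_interactions(de_mi, de_mr, mi, mr, tg)
  expect_equal(it$rho, -1)
  expect_true(it$significant)
  # below-threshold score: empty candidate set
  it0 <- call_interactions(de_mi, de_mr, mi, mr,
                           dplyr::mutate(tg, score = 0.5))
  expect_equal(nrow(it0), 0L)
  expect_equal(attr(it0, "observed_count"), 0L)
  # duplicate rows are mean-aggregated before the score filter
  dup <- tibble::tibble(mirna_id = "m1", gene_id = "g1", score = c(0.9, 0.3))
  expect_equal(nrow(call_interactions(de_mi, de_mr, mi, mr, dup)), 0L)
  # mismatched sample sets are an error
  expect_error(
    call_interactions(de_mi, de_mr, mi, mr[, c(1, 3:11, 2)], tg),
    "identical ordered sample set"
  )
})

test_that("interaction calling is invariant to a shared sample relabeling", {
  sim <- simulate_expression(synth_config(seed = 14))
  de_mi <- differential_expression(sim$mirna, sim$meta)
  de_mr <- differential_expression(sim$mrna, sim$meta)
  smi <- paired_subset(sim$mirna)
  smr <- paired_subset(sim$mrna)
  base <- call_interactions(de_mi, de_mr, smi, smr, sim$target_scores)
  perm <- withr::with_seed(3, sample(2:21))
  reord <- call_interactions(de_mi, de_mr, smi[, c(1, perm)], smr[, c(1, perm)],
                             sim$target_scores)
  expect_equal(tibble::as_tibble(base), tibble::as_tibble(reord))
})

test_that("the permutation kernel agrees with naive relabelled re-calls", {
  sim <- simulate_expression(synth_config(seed = 3))
  de_mi <- differential_expression(sim$mirna, sim$meta)
  de_mr <- differential_expression(sim$mrna, sim$meta)
  smi <- paired_subset(sim$mirna)
  smr <- paired_subset(sim$mrna)
  pm <- permutation_null(de_mi, de_mr, smi, smr, sim$target_scores,
                         n_permutations = 10, seed = 9)
  de_ids <- intersect(de_mi$feature_id[de_mi$significant], smi$feature_id)
  rows_de <- match(de_ids, smi$feature_id)
  naive <- withr::with_seed(9L, purrr::map_int(1:10, function(i) {
    pe <- smi
    pe$feature_id[rows_de] <- de_ids[sample.int(length(de_ids))]
    attr(suppressWarnings(
      call_interactions(de_mi, de_mr, pe, smr, sim$target_scores)
    ), "observed_count")
  }))
  expect_identical(pm$perm_counts, naive)
  # determinism under the seed
  pm2 <- permutation_null(de_mi, de_mr, smi, smr, sim$target_scores,
                          n_permutations = 10, seed = 9)
  expect_identical(pm$perm_counts, pm2$perm_counts)
  expect_equal(pm$p_perm, pm2$p_perm)
})

test_that("permutation p-value uses the add-one estimator and never reports 0", {
  sim <- simulate_expression(synth_config(seed = 7))
  de_mi <- differential_expression(sim$mirna, sim$meta)
  de_mr <- differential_expression(sim$mrna, sim$meta)
  pm <- permutation_null(de_mi, de_mr, paired_subset(sim$mirna),
                         paired_subset(sim$mrna), sim$target_scores,
                         n_permutations = 100, seed = 3)
  expect_equal(pm$p_perm, (pm$exceedances + 1) / 101)
  expect_gte(pm$p_perm, 1 / 101)
  # degenerate: observed count 0 means every permutation ties it, p = 1
  empty_tg <- tibble::tibble(mirna_id = "none", gene_id = "none", score = 0.99)
  pm0 <- permutation_null(de_mi, de_mr, paired_subset(sim$mirna),
                          paired_subset(sim$mrna), empty_tg,
                          n_permutations = 10, seed = 1)
  expect_equal(pm0$observed_count, 0L)
  expect_equal(pm0$p_perm, 1)
  g <- glance(pm)
  expect_equal(g$p_perm, pm$p_perm)
  expect_equal(nrow(tidy(pm)), 100L)
})

test_that("Clopper-Pearson interval matches Beta quantiles and binom.test", {
  ci <- clopper_pearson_ci(0, 100)
  expect_equal(ci$low, 0)
  expect_equal(ci$high, 1 - 0.025^(1 / 100))
  expect_equal(clopper_pearson_ci(100, 100)$high, 1)
  ci50 <- clopper_pearson_ci(50, 100)
  expect_equal(ci50$low, qbeta(0.025, 50, 51))
  expect_equal(ci50$high, qbeta(0.975, 51, 50))
  expect_true(ci50$low < 0.5 && ci50$high > 0.5)
  # independent cross-check: binom.test's interval is Clopper-Pearson
  bt <- binom.test(7, 31)
  ci7 <- clopper_pearson_ci(7, 31)
  expect_equal(c(ci7$low, ci7$high), as.numeric(bt$conf.int))
  expect_error(clopper_pearson_ci(5, 3), "exceed")
  expect_error(clopper_pearson_ci(-1, 3), "successes")
})

test_that("permutation p-values are calibrated on repression-free data", {
  # dense decoy prediction table so the exceedance count has enough spread
  # for its discrete null not to degenerate into ties
  pvals <- purrr::map_dbl(1:50, function(s) {
    sm <- simulate_expression(synth_config(n_repressive_pairs = 0,
                                           n_decoy_pairs = 4000,
                                           seed = 2000 + s))
    pm <- suppressWarnings(permutation_null(
      differential_expression(sm$mirna, sm$meta),
      differential_expression(sm$mrna, sm$meta),
      paired_subset(sm$mirna), paired_subset(sm$mrna),
      sm$target_scores, n_permutations = 100, seed = s
    ))
    pm$p_perm
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
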