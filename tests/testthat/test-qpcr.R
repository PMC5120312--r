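ref_tbl <- function() {
  tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 4),
    group = rep(c("case", "control"), each = 4),
    probe_id = rep(c("r1", "r2", "tgt", "self"), 2),
    ct = c(20, 22, 25, 21, 20, 22, 21, 21)
  )
}

test_that("delta-Ct arithmetic and censoring follow the definitions", {
  d <- delta_ct(ref_tbl(), references = c("r1", "r2"))
  # ct 25 against references 20 and 22: dCt = 4, relative expression 1/16
  expect_equal(d$delta_ct[d$sample_id == "s1" & d$probe_id == "tgt"], 4)
  expect_equal(d$rel_expr[d$sample_id == "s1" & d$probe_id == "tgt"], 0.0625)
  # a target equal to the reference mean has dCt 0, relative expression 1
  expect_equal(d$delta_ct[d$probe_id == "self"], c(0, 0))
  expect_equal(d$rel_expr[d$probe_id == "self"], c(1, 1))
  # a probe referenced only to itself has dCt 0 in every sample
  solo <- delta_ct(dplyr::mutate(ref_tbl(),
                                 probe_id = sub("self", "r1dup", probe_id),
                                 ct = ifelse(probe_id == "r1dup", 20, ct)),
                   references = "r1")
  expect_equal(solo$delta_ct[solo$probe_id == "r1dup"], c(0, 0))
  # censored wells are excluded, samples missing a reference are dropped
  tbl <- ref_tbl()
  tbl$ct[tbl$sample_id == "s2" & tbl$probe_id == "r1"] <- 36
  expect_message(d2 <- delta_ct(tbl, references = c("r1", "r2")), "dropped")
  expect_false("s2" %in% d2$sample_id)
  expect_equal(attr(d2, "n_censored"), 1L)
  expect_error(delta_ct(ref_tbl(), references = character(0)), "non-empty")
  expect_error(delta_ct(ref_tbl(), references = "nope"), "absent")
})

test_that("simulated fold change appears as the expected delta-delta-Ct", {
  q <- simulate_qpcr(de_fold = 2, seed = 5, noise_sd = 0.3)
  s <- qpcr_compare(delta_ct(q, references = c("miR-ref-16", "miR-ref-151")))
  expect_equal(s$delta_delta_ct[s$probe_id == "target-de"], -1, tolerance = 0.25)
  expect_lt(s$p[s$probe_id == "target-de"], 0.001)
  expect_equal(s$delta_delta_ct[s$probe_id == "target-null"], 0,
               tolerance = 0.3)
})

test_that("Mann-Whitney agrees with exhaustive enumeration at small n", {
  r <- mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))$p, 1)
  withr::with_seed(77, {
    for (i in 1:30) {
      m <- sample(2:6, 1)
      n <- sample(2:6, 1)
      pooled <- sample(seq_len(m + n) + runif(m + n, -0.2, 0.2))
      a <- pooled[seq_len(m)]
      b <- pooled[-seq_len(m)]
      expect_equal(mann_whitney_exact(a, b)$p, mw_enumerate_p(a, b))
      # symmetric under group swap
      expect_equal(mann_whitney_exact(a, b)$p, mann_whitney_exact(b, a)$p)
      # invariant under a strictly monotone transform of the pooled data
      expect_equal(mann_whitney_exact(exp(a), exp(b))$p,
                   mann_whitney_exact(a, b)$p)
    }
  })
})

test_that("a large planted shift at the validation group sizes is detected", {
  hits <- withr::with_seed(31, purrr::map_lgl(1:20, function(i) {
    a <- rnorm(16, mean = 3)
    b <- rnorm(36, mean = 0)
    mann_whitney_exact(a, b)$p < 1e-4
  }))
  expect_gte(mean(hits), 0.95)
})

test_that("reference-gene stability ranks candidates by the variance model", {
  samples <- sprintf("s%02d", 1:20)
  meta <- tibble::tibble(sample_id = samples,
                         group = rep(c("case", "control"), each = 10))
  loading <- withr::with_seed(4, rnorm(20))
  e <- withr::with_seed(5, rnorm(20, sd = 0.3))
  s <- c(rep(2, 10), rep(0, 10))
  # deviations cancel pairwise across candidates, so "stable" is exactly
  # constant after the per-sample cross-candidate centring
  x <- tibble::tibble(feature_id = c("stable", "noisyA", "noisyB",
                                     "shiftUp", "shiftDown"))
  vals <- rbind(loading, loading + e, loading - e, loading + s, loading - s)
  x <- dplyr::bind_cols(x, tibble::as_tibble(`colnames<-`(vals, samples)))
  nf <- normfinder_stability(x, meta)
  # constant-after-centering candidate attains the minimum stability
  expect_equal(nf$feature_id[1], "stable")
  expect_equal(nf$stability[1], 0)
  # the pure-group-shift candidates dominate the intergroup component and
  # rank last
  expect_setequal(nf$feature_id[4:5], c("shiftUp", "shiftDown"))
  # adding a per-sample constant to every candidate changes nothing
  shift <- withr::with_seed(6, rnorm(20))
  x2 <- x
  x2[, -1] <- sweep(as.matrix(x[, -1]), 2, shift, "+")
  expect_equal(normfinder_stability(x2, meta), nf)
  expect_error(normfinder_stability(x[1:2, ], meta), "at least 3")
})

test_that("intragroup variance estimates recover the generating model", {
  sigma <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  est <- withr::with_seed(9, purrr::map(1:20, function(i) {
    n <- 100  # 50 per group
    loading <- rnorm(n)
    vals <- t(sapply(sigma, function(s) 5 + loading + rnorm(n, sd = s)))
    samples <- sprintf("s%03d", 1:n)
    x <- dplyr::bind_cols(
      tibble::tibble(feature_id = sprintf("c%d", seq_along(sigma))),
      tibble::as_tibble(`colnames<-`(vals, samples))
    )
    meta <- tibble::tibble(sample_id = samples,
                           group = rep(c("case", "control"), each = n / 2))
    nf <- normfinder_stability(x, meta)
    nf$intragroup_var[match(sprintf("c%d", seq_along(sigma)), nf$feature_id)]
  }))
  mean_est <- Reduce(`+`, est) / length(est)
  expect_true(all(abs(mean_est / sigma^2 - 1) < 0.2))
})
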