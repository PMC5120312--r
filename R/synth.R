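#' Configuration for the paired miRNA/mRNA simulator
#'
#' Builds and validates the parameter set for [simulate_expression()]. The
#' defaults emulate the statistical structure of a two-group (case/control)
#' valve-tissue expression study: array group sizes of 15 cases vs 16
#' controls, a minority of miRNAs differentially expressed with roughly
#' three-quarters of them down-regulated in cases, DE miRNAs organised into
#' five co-expressed clusters, and a set of planted repressive miRNA-target
#' couplings that produce negative Spearman correlation across paired
#' samples.
#'
#' @param n_case,n_control number of case / control samples.
#' @param n_mirna,n_mrna number of miRNA / mRNA features.
#' @param n_de_mirna number of differentially expressed miRNAs.
#' @param fraction_down fraction of DE miRNAs down-regulated in cases.
#' @param n_clusters number of planted co-expression clusters among the DE
#'   miRNAs.
#' @param within_cluster_rho target pairwise Pearson correlation (in (0, 1))
#'   between members of a cluster, achieved through a shared latent factor.
#' @param de_effect mean log2 shift of DE features in cases.
#' @param n_de_mrna number of mRNAs with their own planted group shift
#'   (independent of any miRNA).
#' @param fraction_up_mrna fraction of those mRNAs shifted up in cases.
#' @param n_repressive_pairs number of planted repressive miRNA-target
#'   couplings; each uses a DE miRNA and a dedicated target gene.
#' @param repression_strength target magnitude (in (0, 1]) of the negative
#'   Spearman correlation between a repressive pair across all samples.
#' @param noise_sd residual standard deviation in log2 units.
#' @param n_decoy_pairs number of random non-coupled (miRNA, gene) rows
#'   added to the emitted target-score table.
#' @param true_score_range,decoy_score_range intervals in \[0, 1\] from which
#'   target-prediction scores are drawn for planted and decoy pairs.
#' @param seed integer seed; all randomness in the simulator flows from it.
#'
#' @return A validated list of class `mirvalve_synth_config`.
#' @export
synth_config <- function(n_case = 15L, n_control = 16L,
                         n_mirna = 150L, n_mrna = 300L,
                         n_de_mirna = 30L, fraction_down = 0.75,
                         n_clusters = 5L, within_cluster_rho = 0.7,
                         de_effect = 1.5,
                         n_de_mrna = 60L, fraction_up_mrna = 0.5,
                         n_repressive_pairs = 25L, repression_strength = 0.8,
                         noise_sd = 0.5,
                         n_decoy_pairs = 250L,
                         true_score_range = c(0.85, 1),
                         decoy_score_range = c(0.6, 0.95),
                         seed = 1L) {
  cfg <- list(
    n_case = check_count(n_case, "n_case", 2L),
    n_control = check_count(n_control, "n_control", 2L),
    n_mirna = check_count(n_mirna, "n_mirna"),
    n_mrna = check_count(n_mrna, "n_mrna"),
    n_de_mirna = check_count(n_de_mirna, "n_de_mirna", 0L),
    fraction_down = fraction_down,
    n_clusters = check_count(n_clusters, "n_clusters"),
    within_cluster_rho = within_cluster_rho,
    de_effect = de_effect,
    n_de_mrna = check_count(n_de_mrna, "n_de_mrna", 0L),
    fraction_up_mrna = fraction_up_mrna,
    n_repressive_pairs = check_count(n_repressive_pairs, "n_repressive_pairs", 0L),
    repression_strength = repression_strength,
    noise_sd = noise_sd,
    n_decoy_pairs = check_count(n_decoy_pairs, "n_decoy_pairs", 0L),
    true_score_range = true_score_range,
    decoy_score_range = decoy_score_range,
    seed = check_count(seed, "seed", 0L)
  )
  if (cfg$n_de_mirna > cfg$n_mirna) abort("n_de_mirna must not exceed n_mirna.")
  if (cfg$fraction_down < 0 || cfg$fraction_down > 1) abort("fraction_down must be in [0, 1].")
  if (cfg$fraction_up_mrna < 0 || cfg$fraction_up_mrna > 1) abort("fraction_up_mrna must be in [0, 1].")
  if (cfg$within_cluster_rho <= 0 || cfg$within_cluster_rho >= 1) {
    abort("within_cluster_rho must lie in (0, 1).")
  }
  if (cfg$repression_strength <= 0 || cfg$repression_strength > 1) {
    abort("repression_strength must lie in (0, 1].")
  }
  if (cfg$noise_sd < 0) abort("noise_sd must be non-negative.")
  if (cfg$de_effect < 0) abort("de_effect must be non-negative.")
  if (cfg$n_repressive_pairs > cfg$n_de_mirna * cfg$n_mrna) {
    abort("n_repressive_pairs exceeds n_de_mirna * n_mrna.")
  }
  if (cfg$n_repressive_pairs + cfg$n_de_mrna > cfg$n_mrna) {
    abort("n_repressive_pairs + n_de_mrna must not exceed n_mrna.")
  }
  for (r in list(cfg$true_score_range, cfg$decoy_score_range)) {
    if (length(r) != 2L || any(r < 0) || any(r > 1) || r[1L] > r[2L]) {
      abort("score ranges must be ordered intervals inside [0, 1].")
    }
  }
  structure(cfg, class = "mirvalve_synth_config")
}

# Pearson latent-correlation needed so that a bivariate-normal pair has the
# requested Spearman correlation: rho_s = (6/pi) asin(rho_p / 2).
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Simulate a paired miRNA/mRNA case-control expression study
#'
#' Generates log2-scale miRNA and mRNA expression tables with known ground
#' truth. Cluster co-expression uses a shared latent factor per cluster
#' (`x = sqrt(rho) z_cluster + sqrt(1 - rho) eps`), which makes the expected
#' pairwise within-cluster Pearson correlation exactly `within_cluster_rho`.
#' Each planted repressive pair couples the target gene to the standardized
#' miRNA profile with a negative latent correlation chosen so that the
#' population Spearman correlation across all samples is approximately
#' `-repression_strength`; because the coupling includes the miRNA's group
#' shift, repressed targets are themselves differentially expressed in the
#' opposite direction, as miRNA repression implies.
#'
#' @param config a [synth_config()] object.
#' @return A list of class `mirvalve_sim` with elements `mirna` and `mrna`
#'   (expression tibbles: `feature_id` plus one numeric column per sample),
#'   `meta` (sample_id, group, age, sex), `target_scores` (mirna_id,
#'   gene_id, score) and `truth`, a list of tibbles describing the planted
#'   DE miRNAs/mRNAs with directions, cluster membership, and repressive
#'   pairs.
#' @export
simulate_expression <- function(config = synth_config()) {
  if (!inherits(config, "mirvalve_synth_config")) {
    abort("`config` must be created by synth_config().")
  }
  cfg <- config
  withr::with_seed(cfg$seed, {
    n <- cfg$n_case + cfg$n_control
    samples <- c(sprintf("case_%02d", seq_len(cfg$n_case)),
                 sprintf("ctrl_%02d", seq_len(cfg$n_control)))
    is_case <- rep(c(1, 0), c(cfg$n_case, cfg$n_control))

    meta <- tibble::tibble(
      sample_id = samples,
      group = rep(c("case", "control"), c(cfg$n_case, cfg$n_control)),
      age = round(stats::rnorm(n, mean = ifelse(is_case == 1, 75, 55), sd = 8)),
      sex = sample(c("M", "F"), n, replace = TRUE)
    )

    mirna_ids <- sprintf("miR-%03d", seq_len(cfg$n_mirna))
    gene_ids <- sprintf("GENE%04d", seq_len(cfg$n_mrna))

    ## --- miRNA matrix -----------------------------------------------------
    n_down <- round(cfg$fraction_down * cfg$n_de_mirna)
    de_dir <- rep(c(-1, 1), c(n_down, cfg$n_de_mirna - n_down))
    de_mirna <- mirna_ids[seq_len(cfg$n_de_mirna)]
    cluster_of <- if (cfg$n_de_mirna > 0L) {
      rep_len(seq_len(cfg$n_clusters), cfg$n_de_mirna)
    } else integer(0)

    baseline_mi <- stats::runif(cfg$n_mirna, 6, 12)
    latent <- matrix(stats::rnorm(cfg$n_clusters * n), cfg$n_clusters, n)
    rho <- cfg$within_cluster_rho
    mi <- matrix(0, cfg$n_mirna, n, dimnames = list(mirna_ids, samples))
    for (i in seq_len(cfg$n_mirna)) {
      eps <- stats::rnorm(n)
      if (i <= cfg$n_de_mirna) {
        sig <- sqrt(rho) * latent[cluster_of[i], ] + sqrt(1 - rho) * eps
        mi[i, ] <- baseline_mi[i] + de_dir[i] * cfg$de_effect * is_case +
          cfg$noise_sd * sig
      } else {
        mi[i, ] <- baseline_mi[i] + cfg$noise_sd * eps
      }
    }

    ## --- mRNA matrix ------------------------------------------------------
    baseline_g <- stats::runif(cfg$n_mrna, 5, 13)
    g <- matrix(0, cfg$n_mrna, n, dimnames = list(gene_ids, samples))
    for (j in seq_len(cfg$n_mrna)) {
      g[j, ] <- baseline_g[j] + cfg$noise_sd * stats::rnorm(n)
    }

    # independently DE mRNAs occupy the first n_de_mrna gene slots
    n_up_g <- round(cfg$fraction_up_mrna * cfg$n_de_mrna)
    de_mrna_dir <- rep(c(1, -1), c(n_up_g, cfg$n_de_mrna - n_up_g))
    for (j in seq_len(cfg$n_de_mrna)) {
      g[j, ] <- g[j, ] + de_mrna_dir[j] * cfg$de_effect * is_case
    }

    # repressive pairs: dedicated target genes after the independent DE block
    pairs <- tibble::tibble(mirna_id = character(0), gene_id = character(0))
    rep_dir <- integer(0)
    if (cfg$n_repressive_pairs > 0L) {
      pair_mi_idx <- rep_len(seq_len(cfg$n_de_mirna), cfg$n_repressive_pairs)
      pair_g_idx <- cfg$n_de_mrna + seq_len(cfg$n_repressive_pairs)
      rho_p <- spearman_to_pearson(cfg$repression_strength)
      for (k in seq_len(cfg$n_repressive_pairs)) {
        m <- mi[pair_mi_idx[k], ]
        m_std <- if (stats::sd(m) > 0) (m - mean(m)) / stats::sd(m) else m * 0
        eps <- stats::rnorm(n)
        g[pair_g_idx[k], ] <- baseline_g[pair_g_idx[k]] +
          cfg$noise_sd * (-rho_p * m_std + sqrt(max(0, 1 - rho_p^2)) * eps)
      }
      pairs <- tibble::tibble(
        mirna_id = mirna_ids[pair_mi_idx],
        gene_id = gene_ids[pair_g_idx]
      )
      rep_dir <- -de_dir[pair_mi_idx]
    }

    ## --- target-score table ----------------------------------------------
    true_scores <- stats::runif(nrow(pairs), cfg$true_score_range[1L], cfg$true_score_range[2L])
    target_scores <- dplyr::bind_rows(
      dplyr::mutate(pairs, score = true_scores),
      {
        # decoy predictions scattered over the whole feature space
        di <- sample.int(cfg$n_mirna, cfg$n_decoy_pairs, replace = TRUE)
        dj <- sample.int(cfg$n_mrna, cfg$n_decoy_pairs, replace = TRUE)
        tibble::tibble(
          mirna_id = mirna_ids[di], gene_id = gene_ids[dj],
          score = stats::runif(cfg$n_decoy_pairs, cfg$decoy_score_range[1L],
                               cfg$decoy_score_range[2L])
        )
      }
    )
    # planted rows come first, so a decoy duplicating a planted pair is dropped
    target_scores <- target_scores[!duplicated(target_scores[c("mirna_id", "gene_id")]), ]

    truth <- list(
      de_mirna = tibble::tibble(
        feature_id = de_mirna,
        direction = if (length(de_dir)) ifelse(de_dir > 0, "up", "down") else character(0)
      ),
      clusters = tibble::tibble(feature_id = de_mirna, cluster = cluster_of),
      repressive_pairs = pairs,
      de_mrna = dplyr::bind_rows(
        tibble::tibble(
          feature_id = gene_ids[seq_len(cfg$n_de_mrna)],
          direction = if (length(de_mrna_dir)) ifelse(de_mrna_dir > 0, "up", "down") else character(0)
        ),
        tibble::tibble(
          feature_id = pairs$gene_id,
          direction = if (length(rep_dir)) ifelse(rep_dir > 0, "up", "down") else character(0)
        )
      )
    )

    structure(
      list(
        mirna = matrix_to_expr(mi),
        mrna = matrix_to_expr(g),
        meta = meta,
        target_scores = target_scores,
        truth = truth,
        config = cfg
      ),
      class = "mirvalve_sim"
    )
  })
}

#' Simulate a qPCR Ct table with planted fold change
#'
#' Generates threshold-cycle (Ct) values for target probes and two stable
#' reference probes. A per-sample RNA-loading offset is added to every probe
#' so that delta-Ct normalization is required to recover the planted effect.
#' The probe `"target-de"` carries a group fold change of `de_fold` in cases
#' (delta-delta-Ct of `-log2(de_fold)` in expectation); `"target-null"` has
#' none, and `"target-low"` (optional) sits near the censoring threshold so
#' that some wells read as not detected above cycle 35.
#'
#' @param n_case,n_control samples per group (>= 2 each).
#' @param de_fold planted linear fold change (case vs control) of the
#'   `"target-de"` probe; must be positive.
#' @param seed integer seed.
#' @param noise_sd per-well Ct noise, in cycles.
#' @param include_low_target add the near-censoring probe?
#' @return A tibble with columns sample_id, group, probe_id, ct.
#' @export
simulate_qpcr <- function(n_case = 16L, n_control = 36L, de_fold = 2,
                          seed = 1L, noise_sd = 0.8,
                          include_low_target = TRUE) {
  n_case <- check_count(n_case, "n_case", 2L)
  n_control <- check_count(n_control, "n_control", 2L)
  if (!is.numeric(de_fold) || length(de_fold) != 1L || de_fold <= 0) {
    abort("`de_fold` must be a positive ratio.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  withr::with_seed(check_count(seed, "seed", 0L), {
    n <- n_case + n_control
    samples <- c(sprintf("qcase_%02d", seq_len(n_case)),
                 sprintf("qctrl_%02d", seq_len(n_control)))
    grp <- rep(c("case", "control"), c(n_case, n_control))
    is_case <- as.numeric(grp == "case")
    loading <- stats::rnorm(n, 0, 1)

    probes <- list(
      `miR-ref-16` = 20, `miR-ref-151` = 22,
      `target-de` = 28, `target-null` = 30
    )
    if (include_low_target) probes$`target-low` <- 34.5

    purrr::imap_dfr(probes, function(base, id) {
      shift <- if (id == "target-de") -log2(de_fold) * is_case else 0
      tibble::tibble(
        sample_id = samples, group = grp, probe_id = id,
        ct = base + loading + shift + stats::rnorm(n, 0, noise_sd)
      )
    })
  })
}

#' Build a synthetic gene-set collection around planted DE genes
#'
#' Returns a named list of gene sets (GMT semantics) in which one set,
#' `"planted_de_set"`, is exactly the supplied DE genes and the remaining
#' sets are random draws from the universe. Used to give the
#' over-representation stage a recoverable positive control.
#'
#' @param de_genes character vector of planted genes.
#' @param universe character vector of all gene IDs.
#' @param n_random_sets number of random background sets.
#' @param set_size_range integer range of random set sizes.
#' @param seed integer seed.
#' @return Named list of character vectors.
#' @export
simulate_gene_sets <- function(de_genes, universe, n_random_sets = 19L,
                               set_size_range = c(10L, 40L), seed = 1L) {
  if (!all(de_genes %in% universe)) abort("`de_genes` must be a subset of `universe`.")
  withr::with_seed(check_count(seed, "seed", 0L), {
    sets <- c(
      list(planted_de_set = unique(de_genes)),
      purrr::map(seq_len(n_random_sets), function(i) {
        k <- sample(seq(set_size_range[1L], set_size_range[2L]), 1L)
        sample(universe, min(k, length(universe)))
      }) |> setNames(sprintf("random_set_%02d", seq_len(n_random_sets)))
    )
    sets
  })
}

#' Build a synthetic drug-gene interaction table
#'
#' Emulates a drug-gene interaction database export: each supplied gene gets
#' zero or more drug rows with an interaction-type annotation drawn from a
#' mixture of actionable (inhibitor, antagonist, antibody) and
#' non-actionable (agonist, modulator) types.
#'
#' @param genes character vector of gene IDs to annotate.
#' @param p_druggable probability that a gene has at least one drug row.
#' @param seed integer seed.
#' @return Tibble with columns gene_id, drug_name, interaction_type.
#' @export
simulate_drug_table <- function(genes, p_druggable = 0.4, seed = 1L) {
  types <- c("inhibitor", "antagonist", "antibody", "agonist", "modulator")
  withr::with_seed(check_count(seed, "seed", 0L), {
    purrr::map_dfr(genes, function(gid) {
      if (stats::runif(1) > p_druggable) return(NULL)
      k <- sample(1:3, 1L)
      tibble::tibble(
        gene_id = gid,
        drug_name = sprintf("drug_%s_%d", gid, seq_len(k)),
        interaction_type = sample(types, k, replace = TRUE)
      )
    })
  })
}
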