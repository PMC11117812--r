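#' Configuration for the synthetic paired-cohort generator
#'
#' Defines the study conditions emulated by [simulate_paired_counts()]: two
#' small groups (the paired miRNA/mRNA sequencing design uses 4 + 3 samples),
#' negative-binomial counts with a single dispersion, a subset of features
#' with planted log2 effects, and a set of repressive miRNA-to-gene couplings
#' that induce strong negative cross-sample correlation at the log-mean level.
#'
#' @param n_group_a,n_group_b Samples per group (labelled `"VCM"` / `"ICM"`).
#' @param n_genes,n_mirnas Feature counts for the mRNA and miRNA matrices.
#' @param n_de_genes,n_de_mirnas Number of features with planted group
#'   effects.
#' @param lfc_range Magnitude interval (log2 units) for planted effects; both
#'   signs are used.
#' @param dispersion NB dispersion `alpha` in the mean-dispersion
#'   parameterization `Var = mu + alpha * mu^2`; a scalar, or a vector of
#'   per-feature values recycled per matrix.
#' @param lib_size_range Expected library sizes; drawn log-uniformly.
#' @param n_repressive_pairs Planted miRNA-to-target couplings (each pairs a
#'   planted DE miRNA with a dedicated target gene).
#' @param coupling_strength Target log2-mean decrement per unit miRNA
#'   log2-deviation; must be negative for repression.
#' @param seed Integer RNG seed; equal seeds give byte-identical output.
#' @return A list of class `mirlink_sim_config`.
#' @export
sim_config <- function(n_group_a = 4, n_group_b = 3,
                       n_genes = 1000, n_mirnas = 100,
                       n_de_genes = 50, n_de_mirnas = 5,
                       lfc_range = c(1, 2.5),
                       dispersion = 0.05,
                       lib_size_range = c(5e5, 1.5e6),
                       n_repressive_pairs = 4,
                       coupling_strength = -1.5,
                       seed = 1L) {
  cfg <- list(
    n_group_a = n_group_a, n_group_b = n_group_b,
    n_genes = n_genes, n_mirnas = n_mirnas,
    n_de_genes = n_de_genes, n_de_mirnas = n_de_mirnas,
    lfc_range = lfc_range, dispersion = dispersion,
    lib_size_range = lib_size_range,
    n_repressive_pairs = n_repressive_pairs,
    coupling_strength = coupling_strength,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "mirlink_sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("n_group_a", "n_group_b", "n_genes", "n_mirnas")
  for (f in pos) {
    if (cfg[[f]] < 1) abort(sprintf("`%s` must be >= 1.", f))
  }
  if (cfg$n_de_genes < 0 || cfg$n_de_genes > cfg$n_genes) {
    abort("`n_de_genes` must lie in [0, n_genes].")
  }
  if (cfg$n_de_mirnas < 0 || cfg$n_de_mirnas > cfg$n_mirnas) {
    abort("`n_de_mirnas` must lie in [0, n_mirnas].")
  }
  if (cfg$n_repressive_pairs > 0) {
    if (cfg$n_de_mirnas < 1) abort("repressive pairs require at least one planted DE miRNA.")
    if (cfg$coupling_strength >= 0) abort("`coupling_strength` must be negative for repressive pairs.")
    if (cfg$n_repressive_pairs > cfg$n_de_mirnas * cfg$n_genes) {
      abort("`n_repressive_pairs` exceeds the available miRNA x gene combinations.")
    }
  }
  if (any(cfg$lib_size_range <= 0) || diff(cfg$lib_size_range) < 0) {
    abort("`lib_size_range` must be positive and nondecreasing.")
  }
  if (any(cfg$lfc_range < 0) || diff(cfg$lfc_range) < 0) {
    abort("`lfc_range` must be nonnegative and nondecreasing.")
  }
  if (any(cfg$dispersion < 0)) abort("`dispersion` must be >= 0.")
  invisible(cfg)
}

rnbinom_mu <- function(n, mu, alpha) {
  if (all(alpha <= 1e-12)) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / pmax(alpha, 1e-12), mu = mu)
}

#' Simulate paired miRNA/mRNA count matrices with planted ground truth
#'
#' Draws two negative-binomial count matrices over a shared set of samples.
#' Planted differentially expressed features have group mean ratio
#' `2^effect`. Each repressive pair couples a planted DE miRNA to a dedicated
#' target gene: the gene's log2 mean is shifted by `coupling_strength` times
#' the miRNA's realized log2 deviation from its overall mean, so both the
#' target's differential expression and the negative cross-sample correlation
#' arise from one mechanism.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `mrna` and `mirna` (count tibbles), `meta`
#'   (sample metadata tibble) and `truth` (a `mirlink_truth` list with
#'   `de_genes`, `de_mirnas` — tibbles of feature IDs and signed planted
#'   log2 effects — and `repressive_pairs`).
#' @export
#' @examples
#' sim <- simulate_paired_counts(sim_config(n_genes = 50, n_mirnas = 10, seed = 7))
#' dim(sim$mrna)
simulate_paired_counts <- function(config) {
  stopifnot(inherits(config, "mirlink_sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  nA <- config$n_group_a; nB <- config$n_group_b
  ns <- nA + nB
  samples <- sprintf("S%02d", seq_len(ns))
  group <- c(rep("VCM", nA), rep("ICM", nB))
  x <- ifelse(group == "VCM", 0.5, -0.5)

  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))
  mirna_ids <- sprintf("hsa-miR-sim-%03d", seq_len(config$n_mirnas))

  draw_effects <- function(n) {
    if (n == 0) return(numeric(0))
    mag <- runif(n, config$lfc_range[1], config$lfc_range[2])
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    mag * sgn
  }

  # planted DE miRNAs and their repressive targets (targets are dedicated
  # genes outside the explicitly planted DE gene set)
  de_mirna_idx <- if (config$n_de_mirnas > 0) sample(config$n_mirnas, config$n_de_mirnas) else integer(0)
  mirna_effects <- draw_effects(config$n_de_mirnas)
  de_gene_idx <- if (config$n_de_genes > 0) sample(config$n_genes, config$n_de_genes) else integer(0)
  gene_effects <- draw_effects(config$n_de_genes)

  n_pairs <- config$n_repressive_pairs
  if (n_pairs > 0) {
    pool <- setdiff(seq_len(config$n_genes), de_gene_idx)
    if (length(pool) < n_pairs) abort("not enough uncoupled genes to host repressive pairs.")
    target_idx <- sample(pool, n_pairs)
    pair_mirna <- de_mirna_idx[((seq_len(n_pairs) - 1) %% config$n_de_mirnas) + 1]
  } else {
    target_idx <- integer(0)
    pair_mirna <- integer(0)
  }

  simulate_matrix <- function(n_feat, ids, de_idx, effects) {
    lib <- exp(runif(ns, log(config$lib_size_range[1]), log(config$lib_size_range[2])))
    base <- rnorm(n_feat, mean = 0, sd = 2)            # log2 relative abundance
    prop <- 2^base / sum(2^base)
    eff <- numeric(n_feat)
    eff[de_idx] <- effects
    log2mu <- outer(log2(prop), rep(1, ns)) + outer(eff, x) +
      outer(rep(1, n_feat), log2(lib))
    list(log2mu = log2mu, lib = lib, ids = ids)
  }

  mir <- simulate_matrix(config$n_mirnas, mirna_ids, de_mirna_idx, mirna_effects)
  mir_counts <- matrix(
    rnbinom_mu(length(mir$log2mu), mu = 2^mir$log2mu, alpha = config$dispersion),
    nrow = config$n_mirnas, dimnames = list(mirna_ids, samples)
  )

  gen <- simulate_matrix(config$n_genes, gene_ids, de_gene_idx, gene_effects)
  if (n_pairs > 0) {
    # realized miRNA log2 deviation from its overall lib-size-corrected mean
    libm <- mir$lib / exp(mean(log(mir$lib)))
    for (k in seq_len(n_pairs)) {
      z <- log2(mir_counts[pair_mirna[k], ] / libm + 0.5)
      dev <- z - mean(z)
      gen$log2mu[target_idx[k], ] <- gen$log2mu[target_idx[k], ] +
        config$coupling_strength * dev
    }
  }
  gene_counts <- matrix(
    rnbinom_mu(length(gen$log2mu), mu = 2^gen$log2mu, alpha = config$dispersion),
    nrow = config$n_genes, dimnames = list(gene_ids, samples)
  )

  truth <- structure(list(
    de_genes = tibble::tibble(feature_id = gene_ids[de_gene_idx], log2fc = gene_effects),
    de_mirnas = tibble::tibble(feature_id = mirna_ids[de_mirna_idx], log2fc = mirna_effects),
    repressive_pairs = tibble::tibble(
      mirna_id = mirna_ids[pair_mirna],
      gene_id = gene_ids[target_idx],
      coupling = rep(config$coupling_strength, n_pairs)
    )
  ), class = "mirlink_truth")

  list(
    mrna = matrix_to_counts(gene_counts),
    mirna = matrix_to_counts(mir_counts),
    meta = tibble::tibble(sample_id = samples, group = group),
    truth = truth
  )
}
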