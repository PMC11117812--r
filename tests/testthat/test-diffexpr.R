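test_that("size factors reproduce hand-computed worked examples", {
  # identical columns: symmetry forces all factors to 1
  m <- tibble::tibble(feature_id = c("a", "b"), s1 = c(5, 9), s2 = c(5, 9))
  expect_equal(unname(size_factors(m)), c(1, 1))
  # column2 = 2 x column1: geometric mean splits the ratio symmetrically
  m <- tibble::tibble(feature_id = c("a", "b", "c"),
                      s1 = c(10, 20, 40), s2 = c(20, 40, 80))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-10)
})

test_that("all-zero features are excluded from the size-factor reference", {
  m1 <- tibble::tibble(feature_id = c("a", "b"), s1 = c(10, 30), s2 = c(25, 30))
  m2 <- dplyr::bind_rows(m1, tibble::tibble(feature_id = "z", s1 = 0, s2 = 0))
  expect_equal(size_factors(m1), size_factors(m2))
  mz <- tibble::tibble(feature_id = c("a", "b"), s1 = c(0, 3), s2 = c(2, 0))
  expect_error(size_factors(mz), "positive")
})

test_that("size factors agree with the established median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  sim <- small_sim(seed = 31)
  m <- as.matrix(sim$mrna[, -1])
  rownames(m) <- sim$mrna$feature_id
  expect_equal(unname(size_factors(sim$mrna)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("a feature with identical counts everywhere gets log2fc 0 and p 1", {
  sim <- small_sim(seed = 5)
  counts <- sim$mrna
  flat <- counts[1, ]
  flat[1, -1] <- as.list(rep(50, ncol(counts) - 1))
  flat$feature_id <- "FLATGENE"
  counts <- dplyr::bind_rows(counts, flat)
  # equalize size factors by construction: use two identical sample columns
  m <- tibble::tibble(feature_id = paste0("g", 1:20),
                      a1 = 10 * (1:20), a2 = 10 * (1:20),
                      b1 = 10 * (1:20), b2 = 10 * (1:20))
  m[5, -1] <- as.list(c(7, 7, 7, 7))
  meta <- tibble::tibble(sample_id = c("a1", "a2", "b1", "b2"),
                         group = c("A", "A", "B", "B"))
  de <- de_test(m, meta)
  expect_equal(de$log2fc[5], 0)
  expect_equal(de$stat[5], 0)
  expect_equal(de$pvalue[5], 1)
})

test_that("planted four-fold features are estimated within half a log2 unit", {
  hits <- vapply(1:100, function(s) {
    sim <- simulate_paired_counts(sim_config(
      n_genes = 40, n_mirnas = 5, n_de_genes = 1, n_de_mirnas = 0,
      n_repressive_pairs = 0, lfc_range = c(2, 2), dispersion = 0.05,
      n_group_a = 4, n_group_b = 4, seed = s
    ))
    de <- de_test(sim$mrna, sim$meta, contrast = c("VCM", "ICM"))
    est <- de$log2fc[de$feature_id == sim$truth$de_genes$feature_id]
    abs(est - sim$truth$de_genes$log2fc) < 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("scaling a sample scales its relative size factor and leaves log2fc invariant", {
  sim <- small_sim(seed = 13)
  de1 <- de_test(sim$mrna, sim$meta)
  scaled <- sim$mrna
  scaled[[2]] <- scaled[[2]] * 3
  sf1 <- size_factors(sim$mrna)
  sf2 <- size_factors(scaled)
  # the estimator is unnormalized, so the exact invariant is on factor ratios
  expect_equal(unname((sf2[1] / sf2[2]) / (sf1[1] / sf1[2])), 3, tolerance = 1e-10)
  # log2fc is invariant up to the data-driven dispersion re-estimate
  de2 <- de_test(scaled, sim$meta)
  expect_equal(de2$log2fc, de1$log2fc, tolerance = 0.02)
  expect_gt(cor(de2$log2fc, de1$log2fc), 0.999)
})

test_that("relabelling the groups negates log2fc and preserves p-values", {
  sim <- small_sim(seed = 17)
  de_ab <- de_test(sim$mrna, sim$meta, contrast = c("VCM", "ICM"))
  de_ba <- de_test(sim$mrna, sim$meta, contrast = c("ICM", "VCM"))
  expect_equal(de_ab$log2fc, -de_ba$log2fc, tolerance = 1e-8)
  expect_equal(de_ab$pvalue, de_ba$pvalue, tolerance = 1e-8)
})

test_that("padj equals the brute-force BH step-up", {
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  sim <- small_sim(seed = 29)
  de <- de_test(sim$mrna, sim$meta)
  keep <- !is.na(de$padj)
  expect_equal(de$padj[keep], bh_oracle(de$pvalue[keep]), tolerance = 1e-12)
  # monotone nondecreasing in p-value rank
  ord <- order(de$pvalue[keep])
  expect_true(all(diff(de$padj[keep][ord]) >= -1e-12))
})

test_that("filter_de applies strict thresholds and splits by sign", {
  de <- new_de <- tibble::tibble(
    feature_id = c("at_threshold", "up", "down", "ns"),
    base_mean = 100, log2fc = c(0.5, 2, -2, 1), se = 0.1,
    stat = c(5, 8, -8, 1), pvalue = c(0.001, 0.001, 0.001, 0.5),
    padj = c(0.004, 0.004, 0.004, 0.6), filtered = FALSE
  )
  class(de) <- c("mirlink_de", class(de))
  out <- filter_de(de, lfc_min = 0.5, alpha = 0.05)
  expect_setequal(out$feature_id, c("up", "down"))
  expect_equal(out$direction[out$feature_id == "up"], "up")
  expect_equal(out$direction[out$feature_id == "down"], "down")
  expect_equal(nrow(filter_de(de[0, ], 0.5, 0.05)), 0)
  expect_error(filter_de(de, lfc_min = -1), ">= 0")
})

test_that("the up/down split recovers every planted sign", {
  sim <- simulate_paired_counts(sim_config(
    n_genes = 200, n_mirnas = 5, n_de_genes = 15, n_de_mirnas = 0,
    n_repressive_pairs = 0, lfc_range = c(2, 2), seed = 41
  ))
  de <- de_test(sim$mrna, sim$meta, contrast = c("VCM", "ICM"))
  sig <- filter_de(de)
  joined <- merge(sig, sim$truth$de_genes, by = "feature_id")
  expect_gt(nrow(joined), 0)
  expect_true(all(sign(joined$log2fc.x) == sign(joined$log2fc.y)))
})

test_that("group sizes below two are rejected", {
  sim <- small_sim()
  meta_bad <- sim$meta
  meta_bad$group <- c("A", rep("B", nrow(meta_bad) - 1))
  expect_error(de_test(sim$mrna, meta_bad), ">= 2 samples")
})
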