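test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 80, n_mirnas = 10, seed = 11)
  a <- simulate_paired_counts(cfg)
  b <- simulate_paired_counts(cfg)
  expect_identical(a, b)

  ev1 <- simulate_evidence(a$truth, n_decoys = 10, seed = 3,
                           universe = list(mirna_ids = a$mirna$feature_id,
                                           gene_ids = a$mrna$feature_id))
  ev2 <- simulate_evidence(a$truth, n_decoys = 10, seed = 3,
                           universe = list(mirna_ids = a$mirna$feature_id,
                                           gene_ids = a$mrna$feature_id))
  expect_identical(ev1, ev2)

  expect_identical(simulate_clinical(seed = 5), simulate_clinical(seed = 5))
  expect_identical(simulate_ct(seed = 5), simulate_ct(seed = 5))
  expect_identical(simulate_luciferase(seed = 5), simulate_luciferase(seed = 5))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(n_de_genes = 100, n_genes = 50), "n_de_genes")
  expect_error(sim_config(coupling_strength = 0.5), "negative")
  expect_error(sim_config(n_repressive_pairs = 2, n_de_mirnas = 0), "DE miRNA")
  expect_error(sim_config(lib_size_range = c(-1, 10)), "lib_size_range")
})

test_that("truth references features present in the emitted matrices", {
  sim <- small_sim()
  expect_true(all(sim$truth$de_genes$feature_id %in% sim$mrna$feature_id))
  expect_true(all(sim$truth$de_mirnas$feature_id %in% sim$mirna$feature_id))
  expect_true(all(sim$truth$repressive_pairs$gene_id %in% sim$mrna$feature_id))
  expect_true(all(sim$truth$repressive_pairs$mirna_id %in% sim$mirna$feature_id))
  # planted DE features realize roughly their planted group ratio
  de <- de_test(sim$mrna, sim$meta, contrast = c("VCM", "ICM"))
  joined <- merge(de, sim$truth$de_genes, by = "feature_id")
  expect_gt(cor(joined$log2fc.x, joined$log2fc.y), 0.9)
})

test_that("without planted structure pairwise correlations match the null tail", {
  sim <- simulate_paired_counts(sim_config(
    n_genes = 100, n_mirnas = 20, n_de_genes = 0, n_de_mirnas = 0,
    n_repressive_pairs = 0, seed = 19
  ))
  rec <- correlate_pairs(sim$mirna, sim$mrna)
  # null tail P(|r| >= 0.7) at n = 7 from the t transform
  tcrit <- 0.7 * sqrt((7 - 2) / (1 - 0.49))
  expected <- 2 * pt(-tcrit, df = 5)
  observed <- mean(abs(rec$r) >= 0.7, na.rm = TRUE)
  expect_lt(abs(observed - expected), 0.04)
  expect_lt(abs(mean(rec$r, na.rm = TRUE)), 0.1)
})

test_that("a strongly coupled pair yields r < -0.7 in at least 90% of replicates", {
  hits <- vapply(1:200, function(s) {
    sim <- simulate_paired_counts(sim_config(
      n_genes = 30, n_mirnas = 5, n_de_genes = 3, n_de_mirnas = 1,
      n_repressive_pairs = 1, coupling_strength = -1.5, dispersion = 0.05,
      seed = s
    ))
    pr <- sim$truth$repressive_pairs
    rec <- correlate_pairs(sim$mirna, sim$mrna,
                           mirna_features = pr$mirna_id,
                           gene_features = pr$gene_id)
    rec$r[1] < -0.7
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("expected planted-pair correlation strengthens with coupling magnitude", {
  mean_r <- vapply(c(-0.25, -1, -2.5), function(cs) {
    mean(vapply(101:130, function(s) {
      sim <- simulate_paired_counts(sim_config(
        n_genes = 30, n_mirnas = 5, n_de_genes = 3, n_de_mirnas = 1,
        n_repressive_pairs = 1, coupling_strength = cs, dispersion = 0.05,
        seed = s
      ))
      pr <- sim$truth$repressive_pairs
      correlate_pairs(sim$mirna, sim$mrna, mirna_features = pr$mirna_id,
                      gene_features = pr$gene_id)$r[1]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r) < 0))
})

test_that("evidence fixtures contain every planted pair plus disjoint decoys", {
  sim <- small_sim()
  ev <- simulate_evidence(sim$truth, n_decoys = 25, seed = 2,
                          universe = list(mirna_ids = sim$mirna$feature_id,
                                          gene_ids = sim$mrna$feature_id))
  expect_s3_class(validate_evidence(ev), "tbl_df")
  pairs <- sim$truth$repressive_pairs
  present <- merge(pairs, ev, by.x = c("mirna_id", "gene_id"),
                   by.y = c("mirna_id", "target_symbol"))
  expect_setequal(paste(present$mirna_id, present$gene_id),
                  paste(pairs$mirna_id, pairs$gene_id))
  decoys <- attr(ev, "decoy_pairs")
  expect_equal(nrow(decoys), 25)
  expect_equal(nrow(merge(decoys, pairs, by = c("mirna_id", "gene_id"))), 0)
  expect_true(all(ev$type %in% c("validated", "predicted")))
  expect_error(simulate_evidence(sim$truth, n_decoys = -1), ">= 0")
})

test_that("null clinical simulation has nominal type-I error", {
  vars <- tibble::tibble(variable = "x", kind = "continuous",
                         mean_a = 10, sd_a = 2, pct_a = NA,
                         mean_b = 10, sd_b = 2, pct_b = NA,
                         n_a = 6, n_b = 9)
  rejections <- vapply(1:500, function(s) {
    cl <- simulate_clinical(vars, seed = s)
    res <- compare_continuous(cl$value[cl$group == "ICM"],
                              cl$value[cl$group == "VCM"],
                              force_test = "student_t")
    res$pvalue < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.03)
})

test_that("degenerate clinical variance is rejected", {
  vars <- tibble::tibble(variable = "x", kind = "continuous",
                         mean_a = 1, sd_a = 0, pct_a = NA,
                         mean_b = 1, sd_b = 1, pct_b = NA, n_a = 6, n_b = 9)
  expect_error(simulate_clinical(vars), "positive SD")
})

test_that("DE p-values are uniform when nothing is planted", {
  sim <- simulate_paired_counts(sim_config(
    n_genes = 2000, n_mirnas = 10, n_de_genes = 0, n_de_mirnas = 0,
    n_repressive_pairs = 0, seed = 23
  ))
  de <- de_test(sim$mrna, sim$meta)
  ks <- suppressWarnings(stats::ks.test(de$pvalue[!is.na(de$pvalue)], "punif"))
  expect_gt(ks$p.value, 0.01)
})
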