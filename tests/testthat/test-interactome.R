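test_that("correlation records reproduce hand-computed product-moment values", {
  mk <- function(ids, ...) {
    vals <- list(...)
    tibble::as_tibble(c(list(feature_id = ids), vals))
  }
  # exact reversal: r = -1
  x <- mk("m1", s1 = 1, s2 = 2, s3 = 3, s4 = 4, s5 = 5, s6 = 6, s7 = 7)
  y <- mk("g1", s1 = 7, s2 = 6, s3 = 5, s4 = 4, s5 = 3, s6 = 2, s7 = 1)
  rec <- correlate_pairs(x, y, normalization = "none", transform = "none")
  expect_equal(rec$r, -1)
  # under the default log2(count+1) transform the reversal stays strongly
  # negative but is no longer exactly -1 (the transform is nonlinear)
  rec_t <- correlate_pairs(x, y, normalization = "none")
  expect_lt(rec_t$r, -0.9)
  # r = 0.5 by hand from the product-moment formula
  x2 <- mk("m1", s1 = 1, s2 = 2, s3 = 3)
  y2 <- mk("g1", s1 = 1, s2 = 3, s3 = 2)
  rec2 <- correlate_pairs(x2, y2, normalization = "none", transform = "none")
  expect_equal(rec2$n, 3)
  expect_equal(rec2$r, 0.5, tolerance = 1e-12)
})

test_that("correlation p-values follow the t transform and flag zero variance", {
  sim <- small_sim(seed = 3)
  rec <- correlate_pairs(sim$mirna, sim$mrna,
                         mirna_features = sim$mirna$feature_id[1:4])
  n <- rec$n[1]
  tval <- rec$r * sqrt((n - 2) / (1 - rec$r^2))
  expect_equal(rec$pvalue, pmax(2 * pt(-abs(tval), n - 2), .Machine$double.xmin),
               tolerance = 1e-12)
  expect_true(all(rec$pvalue > 0 & rec$pvalue <= 1))
  # zero-variance feature: r undefined, flagged as NA
  flat <- sim$mrna
  flat[1, -1] <- as.list(rep(100, 7))
  recz <- correlate_pairs(sim$mirna, flat,
                          mirna_features = sim$mirna$feature_id[1],
                          gene_features = flat$feature_id[1],
                          normalization = "none")
  expect_true(is.na(recz$r))
  expect_equal(nrow(filter_negative(recz)), 0)
})

test_that("the screen equals a brute-force all-pairs oracle on small matrices", {
  sim <- simulate_paired_counts(sim_config(n_genes = 5, n_mirnas = 4,
                                           n_de_genes = 0, n_de_mirnas = 0,
                                           n_repressive_pairs = 0, seed = 47))
  rec <- correlate_pairs(sim$mirna, sim$mrna)
  A <- log2(sweep(as.matrix(sim$mirna[, -1]), 2, size_factors(sim$mirna), "/") + 1)
  B <- log2(sweep(as.matrix(sim$mrna[, -1]), 2, size_factors(sim$mrna), "/") + 1)
  for (i in seq_len(nrow(rec))) {
    mi <- match(rec$mirna_id[i], sim$mirna$feature_id)
    gi <- match(rec$gene_id[i], sim$mrna$feature_id)
    ct <- cor.test(A[mi, ], B[gi, ])
    expect_equal(rec$r[i], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(rec$pvalue[i], ct$p.value, tolerance = 1e-9)
  }
})

test_that("filter_negative applies strict thresholds and is idempotent", {
  rec <- tibble::tibble(
    mirna_id = paste0("m", 1:4), gene_id = paste0("g", 1:4), n = 7,
    r = c(-0.69, -0.9, -0.9, -0.7), pvalue = c(0.01, 0.2, 0.01, 0.01),
    scope = "pooled"
  )
  out <- filter_negative(rec)
  expect_equal(out$mirna_id, "m3")     # -0.69 fails r, -0.9/0.2 fails p, -0.70 exact fails strict r
  expect_equal(filter_negative(out), out)
  expect_warning(filter_negative(rec, r_max = 0.7), "positive")
})

test_that("evidence merging honours validated bypass and the database threshold", {
  ev <- table3()
  rec <- records_for_pairs(ev)
  edges1 <- merge_evidence(rec, ev, min_predicted_dbs = 1)
  # DDX6 retained through its validated miRTarBase row
  ddx6 <- edges1[edges1$gene_id == "DDX6" & edges1$mirna_id == "hsa-miR-218-5p", ]
  expect_equal(nrow(ddx6), 1)
  expect_true(ddx6$validated)
  # TTC39C (ElMMo-only) switches with min_predicted_dbs
  expect_true("TTC39C" %in% edges1$gene_id)
  edges3 <- merge_evidence(rec, ev, min_predicted_dbs = 3)
  expect_false("TTC39C" %in% edges3$gene_id)
  expect_true("DDX6" %in% edges3$gene_id)  # validated bypass survives
  # a pair with no evidence yields no edge
  rec_alien <- tibble::tibble(mirna_id = "hsa-miR-218-5p", gene_id = "NOSUCHGENE",
                              n = 7, r = -0.9, pvalue = 0.01, scope = "pooled")
  expect_equal(nrow(merge_evidence(rec_alien, ev)), 0)
})

test_that("evidence merging is independent of row order and matches accessions", {
  ev <- table3()
  rec <- records_for_pairs(ev)
  e1 <- merge_evidence(rec, ev)
  e2 <- merge_evidence(rec, ev[sample.int(nrow(ev)), ])
  expect_equal(e1, e2)
  # matching works on the mature accession too
  rec_acc <- dplyr::mutate(rec, mirna_id = ev$mirna_acc[match(mirna_id, ev$mirna_id)])
  e3 <- merge_evidence(rec_acc, ev)
  expect_equal(nrow(e3), nrow(e1))
})

test_that("the printed evidence table collapses to 5 miRNAs, 18 genes, 21 edges", {
  ev <- table3()
  rec <- records_for_pairs(ev)
  edges <- merge_evidence(rec, ev, min_predicted_dbs = 1)
  net <- build_network(edges)
  expect_equal(net$summary$n_mirnas, 5L)
  expect_equal(net$summary$n_genes, 18L)
  expect_equal(net$summary$n_edges, 21L)
  # the duplicated pair carries two distinct prediction databases
  gatad2b <- net$edges[net$edges$gene_id == "GATAD2B", ]
  expect_equal(gatad2b$n_predicted_dbs, 2L)
})

test_that("empty edge lists build an empty network", {
  net <- build_network(merge_evidence(
    tibble::tibble(mirna_id = character(0), gene_id = character(0),
                   n = integer(0), r = numeric(0), pvalue = numeric(0)),
    table3()
  ))
  expect_equal(net$summary, tibble::tibble(n_mirnas = 0L, n_genes = 0L, n_edges = 0L))
})

test_that("node directions come from DE sign with unknowns flagged", {
  ev <- table3()
  rec <- records_for_pairs(ev)[1:3, ]
  edges <- merge_evidence(rec, ev)
  de_mirna <- tibble::tibble(feature_id = unique(edges$mirna_id), log2fc = 1.2)
  de_mrna <- tibble::tibble(feature_id = edges$gene_id[1], log2fc = -2)
  expect_warning(net <- build_network(edges, de_mrna = de_mrna, de_mirna = de_mirna),
                 "unknown")
  nd <- net$nodes
  expect_equal(nd$direction[nd$name == edges$gene_id[1]], "down")
  expect_true(all(nd$direction[nd$kind == "mirna"] == "up"))
})

test_that("planted-pair recovery rises with coupling strength", {
  recovery <- vapply(c(-0.25, -2), function(cs) {
    mean(vapply(301:320, function(s) {
      sim <- simulate_paired_counts(sim_config(
        n_genes = 60, n_mirnas = 10, n_de_genes = 5, n_de_mirnas = 2,
        n_repressive_pairs = 2, coupling_strength = cs, seed = s
      ))
      pr <- sim$truth$repressive_pairs
      rec <- correlate_pairs(sim$mirna, sim$mrna, mirna_features = unique(pr$mirna_id))
      neg <- filter_negative(rec)
      found <- merge(neg, pr, by = c("mirna_id", "gene_id"))
      nrow(found) / nrow(pr)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(recovery[2], recovery[1])
  expect_gte(recovery[2], 0.8)
})
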