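# Shared fixtures built in code. Seeds used here are fixed once; simulation
# conditions follow the generator defaults (4 + 3 samples, NB counts,
# coupling -1.5) unless a test explicitly probes another regime.

small_sim <- function(seed = 7, ...) {
  simulate_paired_counts(sim_config(
    n_genes = 300, n_mirnas = 30, n_de_genes = 20, n_de_mirnas = 3,
    n_repressive_pairs = 4, seed = seed, ...
  ))
}

tiny_ranking <- function() {
  rk <- tibble::tibble(feature_id = paste0("g", 1:5), score = c(3, 2, 1, -1, -2))
  class(rk) <- c("mirlink_ranking", class(rk))
  rk
}

table3 <- function() read_evidence(mirlink_example("table3_evidence.tsv"))
table2 <- function() read_clinical(mirlink_example("table2_clinical.tsv"))

# correlation records covering every unique pair of an evidence table, all
# passing the negative screen, for evidence-merging tests
records_for_pairs <- function(evidence, r = -0.9, pvalue = 0.01, n = 7) {
  dplyr::distinct(evidence, mirna_id, gene_id = target_symbol) |>
    dplyr::mutate(n = n, r = r, pvalue = pvalue, scope = "pooled")
}
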