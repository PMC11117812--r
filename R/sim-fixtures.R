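#' Simulate a miRNA-target evidence table around planted ground truth
#'
#' Emits an evidence table in the standard schema (database, mature miRNA
#' accession/ID, target symbol/Entrez/Ensembl, type, PubMed ID, score) in
#' which every planted repressive pair appears in at least one database row,
#' plus `n_decoys` decoy rows referencing null pairs: combinations that were
#' never coupled and whose gene carries no planted group effect (a pair of
#' two independently DE features is not null under pooled correlation).
#' Decoys make downstream evidence-intersection tests non-circular: a screen
#' that simply returned every evidenced pair would keep them.
#'
#' @param truth A `mirlink_truth` object from [simulate_paired_counts()].
#' @param n_decoys Number of decoy pairs (>= 0).
#' @param seed Integer RNG seed.
#' @param universe Optional list with `mirna_ids` and `gene_ids` giving the
#'   feature universe decoys are drawn from; defaults to the IDs present in
#'   `truth` plus synthetic fill-ins.
#' @return An evidence tibble; the decoy pairs are attached as the
#'   `decoy_pairs` attribute (tibble of `mirna_id`, `gene_id`).
#' @export
simulate_evidence <- function(truth, n_decoys = 40, seed = 1L, universe = NULL) {
  stopifnot(inherits(truth, "mirlink_truth"))
  if (n_decoys < 0) abort("`n_decoys` must be >= 0.")
  pairs <- truth$repressive_pairs
  if (nrow(pairs) == 0 && n_decoys == 0) abort("`truth` holds no pairs and no decoys were requested.")
  set.seed(as.integer(seed))

  mirna_univ <- unique(c(truth$de_mirnas$feature_id, universe$mirna_ids))
  # decoys must be null pairs: exclude coupled target genes AND the
  # independently DE genes, whose group effect induces a genuine (if
  # indirect) cross-sample correlation with any DE miRNA
  gene_univ <- unique(c(truth$de_genes$feature_id, universe$gene_ids))
  gene_univ <- setdiff(gene_univ, c(pairs$gene_id, truth$de_genes$feature_id))
  if (n_decoys > 0 && (length(mirna_univ) == 0 || length(gene_univ) == 0)) {
    abort("decoys requested but the feature universe is empty.")
  }

  all_mirnas <- sort(unique(c(mirna_univ, pairs$mirna_id)))
  all_genes <- sort(unique(c(gene_univ, pairs$gene_id)))
  acc_of <- function(id) sprintf("MIMATS%06d", match(id, all_mirnas))

  row_for <- function(mirna, gene, validated) {
    db <- if (validated) sample(VALIDATED_DBS, 1) else sample(PREDICTED_DBS, 1)
    tibble::tibble(
      database = db,
      mirna_acc = acc_of(mirna),
      mirna_id = mirna,
      target_symbol = gene,
      target_entrez = as.character(1e5 + match(gene, all_genes)),
      target_ensembl = sprintf("ENSGSIM%08d", match(gene, all_genes)),
      type = if (validated) "validated" else "predicted",
      pubmed = if (validated) sprintf("%08d", sample.int(1e7, 1) + 1e7) else NA_character_,
      score = if (validated) NA_real_ else round(runif(1, 0.5, 1), 3)
    )
  }

  planted_rows <- purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    validated_first <- runif(1) < 0.5
    out <- row_for(pairs$mirna_id[k], pairs$gene_id[k], validated_first)
    if (runif(1) < 0.5) {    # some pairs carry a second, independent row
      out <- dplyr::bind_rows(out, row_for(pairs$mirna_id[k], pairs$gene_id[k], !validated_first))
    }
    out
  })

  decoy_pairs <- tibble::tibble(mirna_id = character(0), gene_id = character(0))
  decoy_rows <- NULL
  if (n_decoys > 0) {
    grid <- expand.grid(mirna_id = mirna_univ, gene_id = gene_univ,
                        stringsAsFactors = FALSE)
    grid <- dplyr::anti_join(grid, pairs, by = c("mirna_id", "gene_id"))
    if (nrow(grid) < n_decoys) abort("not enough distinct uncoupled pairs for the requested decoys.")
    decoy_pairs <- tibble::as_tibble(grid[sample.int(nrow(grid), n_decoys), ])
    decoy_rows <- purrr::map_dfr(seq_len(n_decoys), function(k) {
      row_for(decoy_pairs$mirna_id[k], decoy_pairs$gene_id[k], validated = runif(1) < 0.3)
    })
  }

  ev <- dplyr::bind_rows(planted_rows, decoy_rows)
  ev <- validate_evidence(ev)
  attr(ev, "decoy_pairs") <- decoy_pairs
  ev
}

#' Default clinical-variable template for the cohort simulator
#'
#' A per-variable specification in the layout of a baseline-characteristics
#' table: continuous variables with group means/SDs, categorical variables
#' with group percentages.
#'
#' @param n_a,n_b Group sizes.
#' @return A tibble usable as the `variables` argument of
#'   [simulate_clinical()].
#' @export
clinical_template <- function(n_a = 6, n_b = 9) {
  tibble::tribble(
    ~variable,          ~kind,         ~mean_a, ~sd_a, ~pct_a, ~mean_b, ~sd_b, ~pct_b,
    "Age (years)",      "continuous",  66,      8,     NA,     64,      12,    NA,
    "LVEF (%)",         "continuous",  38,      16,    NA,     48,      11,    NA,
    "LVEDD (mm)",       "continuous",  60,      2,     NA,     60,      5,     NA,
    "Diabetes",         "categorical", NA,      NA,    50,     NA,      NA,    67,
    "Aspirin",          "categorical", NA,      NA,    100,    NA,      NA,    22
  ) |>
    dplyr::mutate(n_a = n_a, n_b = n_b)
}

#' Simulate raw clinical data for a two-group cohort
#'
#' Continuous variables are drawn from the stated group Gaussians and
#' categorical variables from the stated group proportions.
#'
#' @param variables A tibble in the layout of [clinical_template()].
#' @param seed Integer RNG seed.
#' @return A long tibble with columns `variable`, `kind`, `sample_id`,
#'   `group`, `value` (numeric; 0/1 for categorical).
#' @export
simulate_clinical <- function(variables = clinical_template(), seed = 1L) {
  if (any(variables$n_a < 2) || any(variables$n_b < 2)) abort("group sizes must be >= 2.")
  bad <- variables$kind == "continuous" & (is.na(variables$sd_a) | is.na(variables$sd_b) |
                                             variables$sd_a <= 0 | variables$sd_b <= 0)
  if (any(bad)) abort(sprintf("continuous variable '%s' needs positive SDs in both groups.",
                              variables$variable[which(bad)[1]]))
  set.seed(as.integer(seed))
  purrr::map_dfr(seq_len(nrow(variables)), function(i) {
    v <- variables[i, ]
    draw <- function(n, grp, mean, sd, pct) {
      val <- if (v$kind == "continuous") rnorm(n, mean, sd) else rbinom(n, 1, pct / 100)
      tibble::tibble(
        variable = v$variable, kind = v$kind,
        sample_id = sprintf("%s%02d", grp, seq_len(n)), group = grp, value = val
      )
    }
    dplyr::bind_rows(
      draw(v$n_a, "ICM", v$mean_a, v$sd_a, v$pct_a),
      draw(v$n_b, "VCM", v$mean_b, v$sd_b, v$pct_b)
    )
  })
}

#' Simulate a qPCR Ct table
#'
#' Generates cycle-threshold readings for target and reference assays over a
#' two-group cohort. Reference assays are flat across groups (up to noise);
#' each target assay shifts its Ct in the test group by `delta_ct` cycles
#' (negative values mean higher expression, i.e. fold change `2^-delta_ct`).
#'
#' @param n_a,n_b Samples per group (groups `"VCM"`, `"ICM"`; `"VCM"` is the
#'   conventional calibrator).
#' @param targets Character vector of target assay names.
#' @param references Character vector of reference assay names (>= 2 mirrors
#'   the usual dual-reference normalization).
#' @param delta_ct Per-target Ct shift in group `"ICM"` relative to `"VCM"`,
#'   recycled over `targets`.
#' @param noise_sd Technical noise SD in cycles.
#' @param seed Integer RNG seed.
#' @return A Ct tibble with columns `sample_id, group, assay_id, ct, role`.
#' @export
simulate_ct <- function(n_a = 9, n_b = 6, targets = c("DDX6", "SGMS2"),
                        references = c("GAPDH", "ACTB"),
                        delta_ct = -2, noise_sd = 0.15, seed = 1L) {
  if (n_a < 2 || n_b < 2) abort("group sizes must be >= 2.")
  if (length(references) < 1) abort("at least one reference assay is required.")
  set.seed(as.integer(seed))
  samples <- tibble::tibble(
    sample_id = c(sprintf("V%02d", seq_len(n_a)), sprintf("I%02d", seq_len(n_b))),
    group = c(rep("VCM", n_a), rep("ICM", n_b))
  )
  # per-sample loading offset, removed by reference normalization
  samples$offset <- rnorm(nrow(samples), 0, 0.5)
  delta_ct <- rep_len(delta_ct, length(targets))
  assays <- dplyr::bind_rows(
    tibble::tibble(assay_id = references, role = "reference", base = runif(length(references), 18, 22), shift = 0),
    tibble::tibble(assay_id = targets, role = "target", base = runif(length(targets), 24, 30), shift = delta_ct)
  )
  tidyr::crossing(samples, assays) |>
    dplyr::mutate(ct = .data$base + .data$offset +
                    ifelse(.data$group == "ICM", .data$shift, 0) +
                    rnorm(dplyr::n(), 0, noise_sd)) |>
    dplyr::select("sample_id", "group", "assay_id", "ct", "role")
}

#' Simulate a dual-luciferase experiment
#'
#' Draws paired experimental/control luminescence readings in triplicate for
#' a baseline condition and a set of treatment conditions with specified
#' knockdown fractions (0 = no repression, 0.4 = 40% signal loss).
#'
#' @param conditions Named numeric vector: condition name -> knockdown
#'   fraction in \[0, 1). The baseline is added automatically.
#' @param baseline Name of the baseline condition.
#' @param n_rep Replicates per condition (>= 3).
#' @param cv Coefficient of variation of the readings.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `condition, replicate, signal, control`.
#' @export
simulate_luciferase <- function(conditions = c(wt_mimic = 0.4, mut_mimic = 0),
                                baseline = "control", n_rep = 3, cv = 0.05,
                                seed = 1L) {
  if (n_rep < 3) abort("`n_rep` must be >= 3.")
  if (any(conditions < 0 | conditions >= 1)) abort("knockdown fractions must lie in [0, 1).")
  set.seed(as.integer(seed))
  all_cond <- c(setNames(0, baseline), conditions)
  purrr::imap_dfr(all_cond, function(kd, cond) {
    control <- rnorm(n_rep, 1e5, cv * 1e5)
    signal <- rnorm(n_rep, 5e4 * (1 - kd), cv * 5e4)
    tibble::tibble(condition = cond, replicate = seq_len(n_rep),
                   signal = signal, control = pmax(control, 1))
  })
}
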