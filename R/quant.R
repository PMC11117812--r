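#' Relative quantification by the 2^-ddCt method
#'
#' For each sample, `dCt = Ct_target - mean(Ct_references)` (the arithmetic
#' mean of reference Cts is the geometric mean of reference expression in
#' linear space — the standard multi-reference normalization), `ddCt = dCt -
#' mean(dCt over the calibrator group)` and `fold = 2^-ddCt`. Any additive Ct
#' offset applied to all assays of one sample cancels. The group comparison
#' is performed on the dCt values via [compare_continuous()] (auto mode).
#'
#' @param ct Ct tibble with columns `sample_id, group, assay_id, ct` (a
#'   `role` column, if present, is ignored in favour of the explicit
#'   target/reference arguments).
#' @param target Target assay name.
#' @param references Character vector of reference assay names (>= 1).
#' @param calibrator_group Group whose mean dCt anchors fold = 1.
#' @return A tibble of class `mirlink_ddct` with per-sample columns
#'   `sample_id, group, dct, ddct, fold`; the group summary and the dCt group
#'   test are attached as attributes `group_summary` and `test`.
#' @export
ddct <- function(ct, target, references, calibrator_group) {
  need <- c("sample_id", "group", "assay_id", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss) > 0) abort(sprintf("Ct table lacks columns: %s", paste(miss, collapse = ", ")))
  if (!calibrator_group %in% ct$group) abort(sprintf("calibrator group '%s' absent.", calibrator_group))
  samples <- unique(ct$sample_id)
  per_sample <- purrr::map_dfr(samples, function(s) {
    rows <- ct[ct$sample_id == s, ]
    tgt <- rows$ct[rows$assay_id == target]
    refs <- rows$ct[rows$assay_id %in% references]
    if (length(tgt) != 1) abort(sprintf("sample '%s': target assay '%s' measured %d times (need exactly 1).",
                                        s, target, length(tgt)))
    if (length(refs) != length(references)) {
      abort(sprintf("sample '%s': missing reference assay(s) %s.", s,
                    paste(setdiff(references, rows$assay_id), collapse = ", ")))
    }
    tibble::tibble(sample_id = s, group = rows$group[1], dct = tgt - mean(refs))
  })
  cal_mean <- mean(per_sample$dct[per_sample$group == calibrator_group])
  per_sample <- dplyr::mutate(per_sample, ddct = .data$dct - cal_mean,
                              fold = 2^(-.data$ddct))
  summary <- per_sample |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean_fold = mean(.data$fold),
                     sem_fold = sd(.data$fold) / sqrt(dplyr::n()), .groups = "drop")
  groups <- unique(per_sample$group)
  test <- if (length(groups) == 2) {
    compare_continuous(per_sample$dct[per_sample$group == groups[1]],
                       per_sample$dct[per_sample$group == groups[2]])
  } else {
    NULL
  }
  class(per_sample) <- c("mirlink_ddct", class(per_sample))
  attr(per_sample, "group_summary") <- summary
  attr(per_sample, "test") <- test
  attr(per_sample, "target") <- target
  per_sample
}

#' Dual-luciferase activity analysis
#'
#' Computes per-well activity as experimental signal divided by the
#' co-transfected control reading, rescales all conditions so the baseline
#' condition has mean activity 1, and tests each non-baseline condition
#' against the baseline with a two-sided pooled-variance Student t-test.
#'
#' @param wells Tibble with columns `condition, signal, control` (and
#'   optionally `replicate`).
#' @param baseline_condition Name of the normalizing condition.
#' @return A tibble of class `mirlink_luciferase` with one row per condition:
#'   `condition, n, activity` (mean, baseline = 1), `sem`, `pvalue` (NA for
#'   the baseline itself); per-well activities are attached as attribute
#'   `wells`.
#' @export
luciferase_activity <- function(wells, baseline_condition) {
  need <- c("condition", "signal", "control")
  miss <- setdiff(need, names(wells))
  if (length(miss) > 0) abort(sprintf("luciferase table lacks columns: %s",
                                      paste(miss, collapse = ", ")))
  if (any(wells$control <= 0)) abort("control readings must be positive.")
  if (!baseline_condition %in% wells$condition) {
    abort(sprintf("baseline condition '%s' absent.", baseline_condition))
  }
  wells <- dplyr::mutate(wells, activity = .data$signal / .data$control)
  base_mean <- mean(wells$activity[wells$condition == baseline_condition])
  wells <- dplyr::mutate(wells, activity = .data$activity / base_mean)
  base_act <- wells$activity[wells$condition == baseline_condition]
  out <- wells |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = dplyr::n(), activity = mean(.data$activity),
                     sem = sd(.data$activity) / sqrt(dplyr::n()), .groups = "drop") |>
    dplyr::mutate(pvalue = purrr::map_dbl(.data$condition, function(cond) {
      if (cond == baseline_condition) return(NA_real_)
      compare_continuous(wells$activity[wells$condition == cond], base_act,
                         force_test = "student_t")$pvalue
    }))
  class(out) <- c("mirlink_luciferase", class(out))
  attr(out, "wells") <- wells
  attr(out, "baseline") <- baseline_condition
  out
}
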