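#' ROUT outlier detection for a single sample of values
#'
#' Robust outlier removal specialized to the constant model: the center is
#' the median, the robust standard deviation of the residuals (RSDR) is the
#' 68.27th percentile of the absolute residuals with the small-n correction
#' `n/(n-1)`, and outliers are flagged by a step-up FDR test at rate `Q` on
#' the two-sided t-tail probabilities of `residual / RSDR` (`n - 1` degrees
#' of freedom).
#'
#' @param values Numeric vector (n >= 3; smaller samples return no flags,
#'   with a warning, because outlier status is indeterminate).
#' @param Q Target false-discovery rate (GraphPad-style, default 1%).
#' @return Integer indices of flagged outliers (possibly empty), sorted.
#' @export
#' @examples
#' rout_outliers(c(1:10, 100))
rout_outliers <- function(values, Q = 0.01) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) {
    warn("fewer than 3 values: outlier detection not performed.")
    return(integer(0))
  }
  resid <- values - median(values)
  rsdr <- quantile(abs(resid), 0.6827, names = FALSE) * n / (n - 1)
  if (rsdr < .Machine$double.eps) return(integer(0))
  p <- 2 * pt(-abs(resid) / rsdr, df = n - 1)
  ord <- order(p)
  thresh <- Q * seq_len(n) / n
  below <- p[ord] <= thresh
  if (!any(below)) return(integer(0))
  sort(ord[seq_len(max(which(below)))])
}

new_stat_test <- function(test, statistic, df, pvalue, note = NA_character_) {
  tibble::tibble(test = test, statistic = statistic, df = df,
                 pvalue = pvalue, note = note)
}

#' Compare a continuous variable between two groups
#'
#' With raw data and `force_test = "auto"`, each group is screened with the
#' Shapiro-Wilk test at the 5% level; if both pass, a two-tailed pooled-
#' variance Student t-test is used, otherwise a Mann-Whitney test (exact for
#' small untied samples, normal approximation with tie correction
#' otherwise). With summary input (means, SDs, group sizes) only the pooled
#' Student t is available — baseline tables typically print only summaries.
#'
#' @param a,b Raw numeric vectors (omit when using summaries).
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @param force_test `"auto"`, `"student_t"` or `"mann_whitney"`.
#' @return A one-row tibble: `test, statistic, df, pvalue, note`.
#' @export
#' @examples
#' compare_continuous(mean_a = 66.33, sd_a = 7.84, n_a = 6,
#'                    mean_b = 63.67, sd_b = 11.78, n_b = 9)
compare_continuous <- function(a = NULL, b = NULL,
                               mean_a = NULL, sd_a = NULL, n_a = NULL,
                               mean_b = NULL, sd_b = NULL, n_b = NULL,
                               force_test = c("auto", "student_t", "mann_whitney")) {
  force_test <- match.arg(force_test)
  raw <- !is.null(a) && !is.null(b)
  if (raw) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) abort("each group needs >= 2 observations.")
    use_t <- switch(force_test,
      student_t = TRUE,
      mann_whitney = FALSE,
      auto = {
        gaussian <- function(x) {
          if (length(x) < 3 || sd(x) == 0) TRUE else shapiro.test(x)$p.value >= 0.05
        }
        gaussian(a) && gaussian(b)
      }
    )
    if (use_t) {
      if (sd(a) == 0 && sd(b) == 0) {
        return(new_stat_test("student_t", 0, length(a) + length(b) - 2,
                             if (mean(a) == mean(b)) 1 else 0,
                             "degenerate variance"))
      }
      ht <- t.test(a, b, var.equal = TRUE)
      new_stat_test("student_t", unname(ht$statistic), unname(ht$parameter), ht$p.value)
    } else {
      ht <- suppressWarnings(wilcox.test(a, b, exact = length(a) <= 8 && length(b) <= 8,
                                         correct = TRUE))
      new_stat_test("mann_whitney", unname(ht$statistic), NA_real_, ht$p.value)
    }
  } else {
    if (force_test == "mann_whitney") {
      abort("Mann-Whitney requires raw data; summaries only support the Student t.")
    }
    need <- list(mean_a, sd_a, n_a, mean_b, sd_b, n_b)
    if (any(vapply(need, is.null, TRUE))) {
      abort("supply either raw vectors `a`,`b` or all six summary values.")
    }
    if (n_a < 2 || n_b < 2) abort("each group needs n >= 2.")
    if (sd_a < 0 || sd_b < 0) abort("SDs must be >= 0.")
    df <- n_a + n_b - 2
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
    if (sp2 == 0) {
      return(new_stat_test("student_t", 0, df, if (mean_a == mean_b) 1 else 0,
                           "degenerate variance; computed from summaries"))
    }
    tval <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
    new_stat_test("student_t", tval, df, 2 * pt(-abs(tval), df),
                  "computed from summaries")
  }
}

#' Compare a categorical variable between two groups
#'
#' Uncorrected Pearson chi-square on the 2x2 table of successes/failures
#' (df = 1, two-sided). Jointly degenerate tables (both groups at 0% or both
#' at 100%) return p = 1 with a note; equal proportions give a statistic of
#' exactly zero.
#'
#' @param k1,n1 Successes and size of group 1.
#' @param k2,n2 Successes and size of group 2.
#' @return A one-row tibble: `test, statistic, df, pvalue, note`.
#' @export
#' @examples
#' compare_categorical(6, 6, 2, 9)  # chi-square 8.75
compare_categorical <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) abort("group sizes must be >= 1.")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) abort("counts must satisfy 0 <= k <= n.")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2)
  if (any(rowSums(tab) == 0)) {
    return(new_stat_test("chi_square", NA_real_, 1, 1, "degenerate margin"))
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  new_stat_test("chi_square", unname(ht$statistic), unname(ht$parameter), ht$p.value)
}

#' Assemble a baseline-characteristics comparison table
#'
#' Runs the appropriate two-group test per variable of a clinical summary
#' table: continuous rows (group means/SDs) through the pooled Student t,
#' categorical rows (group percentages) through the uncorrected chi-square on
#' counts reconstructed as `round(percent/100 * n)`. A warning is raised when
#' a percentage does not correspond to an integer count within 0.51
#' percentage points (irrecoverable print rounding).
#'
#' @param clinical A tibble with columns `variable, kind, mean_a, sd_a,
#'   pct_a, n_a, mean_b, sd_b, pct_b, n_b` (see
#'   `mirlink_example("table2_clinical.tsv")`).
#' @return A tibble with one row per variable: `variable, kind, test,
#'   statistic, pvalue`.
#' @export
#' @examples
#' tab <- read_clinical(mirlink_example("table2_clinical.tsv"))
#' baseline_table(tab)
baseline_table <- function(clinical) {
  need <- c("variable", "kind", "n_a", "n_b")
  miss <- setdiff(need, names(clinical))
  if (length(miss) > 0) abort(sprintf("clinical table lacks columns: %s",
                                      paste(miss, collapse = ", ")))
  purrr::map_dfr(seq_len(nrow(clinical)), function(i) {
    v <- clinical[i, ]
    res <- if (v$kind == "continuous") {
      compare_continuous(mean_a = v$mean_a, sd_a = v$sd_a, n_a = v$n_a,
                         mean_b = v$mean_b, sd_b = v$sd_b, n_b = v$n_b)
    } else if (v$kind == "categorical") {
      reconstruct <- function(pct, n) {
        k <- round(pct / 100 * n)
        # a genuine printed percentage must equal 100*k/n up to print rounding
        if (abs(pct - 100 * k / n) > 0.51) {
          warn(sprintf("variable '%s': %.2f%% of n=%d is not within 0.51%% of any integer count; using k=%d.",
                       v$variable, pct, n, k))
        }
        k
      }
      compare_categorical(reconstruct(v$pct_a, v$n_a), v$n_a,
                          reconstruct(v$pct_b, v$n_b), v$n_b)
    } else {
      abort(sprintf("unknown variable kind '%s' for '%s'.", v$kind, v$variable))
    }
    tibble::tibble(variable = v$variable, kind = v$kind, test = res$test,
                   statistic = res$statistic, pvalue = res$pvalue)
  })
}

#' Read a clinical summary table from TSV
#'
#' @param path Path to a TSV in the [baseline_table()] layout.
#' @return A tibble.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_tsv(path, col_types = readr::cols(
    variable = readr::col_character(), kind = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}
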