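#' Median-of-ratios size factors
#'
#' Estimates one positive scale factor per sample by the median-of-ratios
#' method: each sample's counts are divided by the per-feature geometric mean
#' across samples (computed over features positive in every sample), and the
#' factor is the median of those ratios. The factors are returned exactly as
#' the estimator produces them — their geometric mean is close to, but not
#' renormalized to, one.
#'
#' @param counts A count tibble (`feature_id` + one column per sample).
#' @return A named numeric vector of per-sample size factors.
#' @export
#' @examples
#' m <- tibble::tibble(feature_id = c("a", "b"), s1 = c(1, 4), s2 = c(2, 8))
#' size_factors(m)  # ratio 2 between the samples
size_factors <- function(counts) {
  m <- counts_to_matrix(counts)
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    abort("no feature has positive counts in every sample; size factors are undefined.")
  }
  logm <- log(m[all_pos, , drop = FALSE])
  loggeo <- rowMeans(logm)
  sf <- apply(logm, 2, function(col) exp(median(col - loggeo)))
  setNames(sf, colnames(m))
}

new_de_result <- function(tab, contrast = NULL) {
  out <- tibble::as_tibble(tab)
  class(out) <- c("mirlink_de", class(out))
  attr(out, "contrast") <- contrast
  out
}

# Method-of-moments dispersion, used only to initialize the likelihood fit.
mom_dispersions <- function(norm, group, sf = NULL) {
  mu <- rowMeans(norm)
  groups <- split(seq_along(group), group)
  ss <- 0
  df <- 0
  for (idx in groups) {
    if (length(idx) >= 2) {
      gm <- rowMeans(norm[, idx, drop = FALSE])
      ss <- ss + rowSums((norm[, idx, drop = FALSE] - gm)^2)
      df <- df + length(idx) - 1
    }
  }
  v <- ss / max(df, 1)
  # Var(y/sf) = mu/sf + alpha mu^2, so subtract the Poisson part scaled by E[1/sf]
  shot <- if (is.null(sf)) 1 else mean(1 / sf)
  mom <- (v - mu * shot) / mu^2
  mom[!is.finite(mom) | mom <= 0] <- NA_real_
  mom
}

# Binned trend of dispersion against the mean, linearly interpolated on the
# log-log scale. Bin centers use the trimmed MEAN of the (linear-scale)
# estimates: the Cox-Reid ML estimator is approximately unbiased on that
# scale, while a median of logs would sit systematically below the true
# dispersion for a right-skewed sampling distribution. Robust against the
# small feature counts of miRNA matrices.
dispersion_trend <- function(log_alpha, mu, n_bins = 20, trim = 0.05) {
  usable <- which(!is.na(log_alpha) & mu > 1)
  center <- function(la) log(max(mean(exp(la), trim = trim), 1e-8))
  if (length(usable) < 10) {
    fill <- if (length(usable) > 0) center(log_alpha[usable]) else log(0.1)
    return(rep(fill, length(mu)))
  }
  lm_ <- log(mu[usable])
  br <- unique(quantile(lm_, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(lm_, breaks = br, include.lowest = TRUE)
  med <- tapply(log_alpha[usable], bins, center)
  ctr <- tapply(lm_, bins, median)
  ok <- !is.na(med)
  if (sum(ok) < 2) return(rep(center(log_alpha[usable]), length(mu)))
  approx(ctr[ok], med[ok], xout = log(pmax(mu, 1e-8)), rule = 2)$y
}

# Cox-Reid adjusted NB profile log-likelihood of a dispersion grid, given the
# fitted means: the adjustment -0.5 log det(X'WX) corrects the bias from
# estimating the two mean parameters, exactly as in the DESeq2/edgeR lineage.
# Returns a features x grid matrix; optionally adds a log-normal prior.
cr_loglik_grid <- function(m, mu, x, log_alpha_grid, prior_mean = NULL,
                           prior_var = NULL) {
  nf <- nrow(m)
  out <- matrix(NA_real_, nf, length(log_alpha_grid))
  for (j in seq_along(log_alpha_grid)) {
    a <- exp(log_alpha_grid[j])
    size <- 1 / a
    ll <- rowSums(stats::dnbinom(m, size = size, mu = mu, log = TRUE))
    w <- mu / (1 + a * mu)
    I00 <- rowSums(w)
    I01 <- rowSums(sweep(w, 2, x, "*"))
    I11 <- rowSums(sweep(w, 2, x^2, "*"))
    det <- pmax(I00 * I11 - I01^2, 1e-300)
    adj <- -0.5 * log(det)
    pen <- if (is.null(prior_mean)) 0 else
      -(log_alpha_grid[j] - prior_mean)^2 / (2 * prior_var)
    out[, j] <- ll + adj + pen
  }
  out
}

grid_argmax <- function(ll, log_alpha_grid) {
  idx <- max.col(ll, ties.method = "first")
  log_alpha_grid[idx]
}

# Moderated per-feature NB dispersion in the DESeq2 style: Cox-Reid adjusted
# ML per feature, a binned-median trend over the mean, and MAP shrinkage
# toward the trend with a prior width estimated from the spread of the ML
# estimates in excess of their expected sampling variance. Features far above
# the trend (dispersion outliers) keep their own ML estimate.
estimate_dispersions <- function(m, norm, group, sf, x,
                                 alpha_min = 1e-8, alpha_max = 20,
                                 min_prior_var = 0.25, outlier_sd = 2) {
  mu_bar <- rowMeans(norm)
  mom <- mom_dispersions(norm, group, sf)
  init <- exp(dispersion_trend(log(mom), mu_bar))
  fit0 <- fit_nb_two_group(m, sf, x, init)
  eta <- outer(fit0$b0, rep(1, length(x))) + outer(fit0$b1, x)
  mu <- exp(sweep(eta, 2, log(sf), "+"))

  grid <- seq(log(1e-6), log(alpha_max), length.out = 60)
  ll <- cr_loglik_grid(m, mu, x, grid)
  log_mle <- grid_argmax(ll, grid)

  log_trend <- dispersion_trend(log_mle, mu_bar)
  resid <- log_mle - log_trend
  # spread of the ML estimates in excess of their sampling variance; the
  # trigamma term is the asymptotic variance of a log-dispersion estimate
  # with (n - 2) residual degrees of freedom
  samp_var <- trigamma((length(x) - 2) / 2)
  prior_var <- max(stats::mad(resid, na.rm = TRUE)^2 - samp_var, min_prior_var)

  ll_map <- ll - outer(-log_trend, grid, "+")^2 / (2 * prior_var)
  log_map <- grid_argmax(ll_map, grid)
  # dispersion outliers stay at their own estimate rather than being shrunk
  outlier <- !is.na(resid) & resid > outlier_sd * sqrt(samp_var + prior_var)
  log_map[outlier] <- log_mle[outlier]

  pmin(pmax(exp(log_map), alpha_min), alpha_max)
}

# Vectorized penalized Newton fit of the two-group NB GLM
#   mu_fs = sf_s * exp(b0_f + x_s * b1_f),  x_s in {+1/2, -1/2}
# with known per-feature dispersion alpha. A weak ridge on b1 (prior sd
# `prior_sd` natural-log units) keeps the coefficient finite when one group is
# all zeros; it is negligible otherwise.
fit_nb_two_group <- function(m, sf, x, alpha, prior_sd = 10, max_iter = 50, tol = 1e-10) {
  nf <- nrow(m)
  tau <- 1 / prior_sd^2
  mu0 <- rowMeans(sweep(m, 2, sf, "/"))
  b0 <- log(pmax(mu0, 1e-8))
  b1 <- numeric(nf)
  lsf <- log(sf)
  for (iter in seq_len(max_iter)) {
    eta <- outer(b0, rep(1, length(x))) + outer(b1, x)
    mu <- exp(sweep(eta, 2, lsf, "+"))
    denom <- 1 + alpha * mu
    r <- (m - mu) / denom          # d loglik / d eta
    wgt <- mu / denom              # Fisher weights
    U0 <- rowSums(r)
    U1 <- rowSums(sweep(r, 2, x, "*")) - tau * b1
    I00 <- rowSums(wgt) + 1e-10
    I01 <- rowSums(sweep(wgt, 2, x, "*"))
    I11 <- rowSums(sweep(wgt, 2, x^2, "*")) + tau
    det <- I00 * I11 - I01^2
    det[det < 1e-12] <- 1e-12
    d0 <- (I11 * U0 - I01 * U1) / det
    d1 <- (I00 * U1 - I01 * U0) / det
    # damp large steps for stability on extreme features
    step <- pmax(abs(d0), abs(d1))
    damp <- ifelse(step > 4, 4 / step, 1)
    b0 <- b0 + damp * d0
    b1 <- b1 + damp * d1
    if (max(abs(d0), abs(d1)) < tol) break
  }
  eta <- outer(b0, rep(1, length(x))) + outer(b1, x)
  mu <- exp(sweep(eta, 2, lsf, "+"))
  denom <- 1 + alpha * mu
  wgt <- mu / denom
  I00 <- rowSums(wgt) + 1e-10
  I01 <- rowSums(sweep(wgt, 2, x, "*"))
  I11 <- rowSums(sweep(wgt, 2, x^2, "*")) + tau
  det <- pmax(I00 * I11 - I01^2, 1e-12)
  se_b1 <- sqrt(I00 / det)
  list(b0 = b0, b1 = b1, se_b1 = se_b1)
}

#' Two-group negative-binomial Wald test per feature
#'
#' Fits, per feature, an NB generalized linear model with a log link, sample
#' size-factor offsets and a single two-group coefficient. Dispersions are
#' moderated in the DESeq2 style: Cox-Reid adjusted maximum likelihood per
#' feature, a binned-median trend over the mean, and MAP shrinkage toward
#' the trend with a data-estimated prior width (dispersion outliers keep
#' their own estimate) — the moderation that makes 3-4 samples per group
#' workable. The reported `log2fc` is the fitted group coefficient for
#' `contrast[1]` versus `contrast[2]`; the two-sided Wald p-value uses the
#' standard normal reference. Features whose mean normalized count falls
#' below `min_count` are excluded from multiple-testing adjustment
#' (`padj = NA`, `filtered = TRUE`); BH adjustment is applied across the
#' remaining features.
#'
#' @param counts Count tibble (`feature_id` + sample columns).
#' @param meta Metadata tibble with `sample_id` and `group` (exactly two
#'   groups, each with at least two samples).
#' @param contrast Character vector of two group labels; `log2fc` is
#'   log2(first / second). Defaults to the two groups in the order they first
#'   appear in `meta`.
#' @param min_count Mean-normalized-count threshold of the independent
#'   low-count filter.
#' @return A tibble of class `mirlink_de` with columns `feature_id,
#'   base_mean, log2fc, se, stat, pvalue, padj, filtered`.
#' @export
de_test <- function(counts, meta, contrast = NULL, min_count = 0.5) {
  validate_counts(counts)
  m <- counts_to_matrix(counts)
  validate_meta(meta, colnames(m))
  meta <- meta[match(colnames(m), meta$sample_id), ]
  grp <- as.character(meta$group)
  lv <- unique(grp)
  if (length(lv) != 2) abort(sprintf("`meta` must define exactly 2 groups, found %d.", length(lv)))
  if (is.null(contrast)) contrast <- lv
  if (!setequal(contrast, lv)) abort("`contrast` must name the two groups in `meta`.")
  nA <- sum(grp == contrast[1]); nB <- sum(grp == contrast[2])
  if (nA < 2 || nB < 2) abort("each group needs >= 2 samples.")

  sf <- size_factors(counts)
  norm <- sweep(m, 2, sf, "/")
  base_mean <- unname(rowMeans(norm))
  x <- ifelse(grp == contrast[1], 0.5, -0.5)

  alpha <- estimate_dispersions(m, norm, grp, sf, x)
  fit <- fit_nb_two_group(m, sf, x, alpha)

  log2fc <- unname(fit$b1) / log(2)
  se <- unname(fit$se_b1) / log(2)
  stat <- unname(fit$b1 / fit$se_b1)
  # degenerate features: constant normalized counts carry no group signal
  constant <- unname(apply(norm, 1, function(z) max(z) - min(z) < 1e-12))
  log2fc[constant] <- 0; stat[constant] <- 0
  pvalue <- 2 * pnorm(-abs(stat))
  pvalue[constant] <- 1
  zero <- base_mean == 0
  log2fc[zero] <- 0; stat[zero] <- NA_real_; pvalue[zero] <- NA_real_; se[zero] <- NA_real_

  filtered <- base_mean < min_count
  padj <- rep(NA_real_, length(pvalue))
  keep <- !filtered & !is.na(pvalue)
  padj[keep] <- p.adjust(pvalue[keep], method = "BH")

  new_de_result(tibble::tibble(
    feature_id = rownames(m),
    base_mean = base_mean,
    log2fc = log2fc,
    se = se,
    stat = stat,
    pvalue = pvalue,
    padj = padj,
    filtered = filtered
  ), contrast = contrast)
}

#' Filter a DE table by effect size and significance
#'
#' Retains features with `|log2fc| > lfc_min` (strict) and adjusted (or raw)
#' p-value `< alpha` (strict), and annotates the direction of change. The
#' strict inequalities mean a feature sitting exactly at the fold-change
#' threshold is excluded.
#'
#' @param de A `mirlink_de` tibble.
#' @param lfc_min Minimum absolute log2 fold change (exclusive).
#' @param alpha Significance threshold (exclusive).
#' @param use_adjusted Gate on `padj` (default) or on raw `pvalue`.
#' @return The retained subset with an added `direction` column (`"up"` /
#'   `"down"` for positive / negative `log2fc`).
#' @export
filter_de <- function(de, lfc_min = 0.5, alpha = 0.05, use_adjusted = TRUE) {
  if (lfc_min < 0) abort("`lfc_min` must be >= 0.")
  if (nrow(de) == 0) {
    return(dplyr::mutate(de, direction = character(0)))
  }
  p <- if (use_adjusted) de$padj else de$pvalue
  keep <- !is.na(p) & p < alpha & abs(de$log2fc) > lfc_min
  out <- de[keep, , drop = FALSE]
  dplyr::mutate(out, direction = ifelse(.data$log2fc > 0, "up", "down"))
}
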