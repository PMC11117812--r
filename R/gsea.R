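#' Build a ranked gene list from a DE result
#'
#' Orders features by the chosen metric, descending, with ties broken by
#' lexicographic feature ID so the ranking is deterministic and independent
#' of input row order. The default metric is the signed log2 fold change, so
#' sets concentrated among downregulated genes obtain negative enrichment
#' scores; `"abs_lfc"` ranks by effect magnitude and `"stat"` by the Wald
#' statistic.
#'
#' @param de A `mirlink_de` tibble (or any data frame with `feature_id` and
#'   the metric column).
#' @param metric One of `"signed_lfc"`, `"abs_lfc"`, `"stat"`.
#' @return A tibble of class `mirlink_ranking` with columns `feature_id`,
#'   `score`, in ranking order.
#' @export
rank_genes <- function(de, metric = c("signed_lfc", "abs_lfc", "stat")) {
  metric <- match.arg(metric)
  if (nrow(de) == 0) abort("`de` is empty.")
  if (anyDuplicated(de$feature_id)) abort("duplicate feature IDs in `de`.")
  score <- switch(metric,
    signed_lfc = de$log2fc,
    abs_lfc = abs(de$log2fc),
    stat = de$stat
  )
  if (anyNA(score) || any(!is.finite(score))) {
    abort(sprintf("ranking metric '%s' has missing or non-finite values.", metric))
  }
  ord <- order(-score, de$feature_id, method = "radix")
  out <- tibble::tibble(feature_id = de$feature_id[ord], score = score[ord])
  class(out) <- c("mirlink_ranking", class(out))
  attr(out, "metric") <- metric
  out
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranking from top to bottom: members of the set ("hits")
#' increment the running sum by `|score|^p` normalized over all hits, and
#' non-members decrement it by `1 / (N - N_hits)`. The enrichment score (ES)
#' is the signed maximum deviation of the running sum from zero, so ES always
#' lies in \[-1, 1\].
#'
#' @param ranked A `mirlink_ranking` tibble (or data frame with `feature_id`
#'   and `score` in ranking order).
#' @param set Character vector of feature IDs.
#' @param p Weighting exponent on the hit scores (1 is the classic default).
#' @return A list with elements `es` (scalar), `profile` (tibble with
#'   `position`, `feature_id`, `running`, `hit`) and `leading_edge`
#'   (character vector of hits up to the running-sum extremum).
#' @export
enrichment_score <- function(ranked, set, p = 1) {
  n <- nrow(ranked)
  hit <- ranked$feature_id %in% set
  nh <- sum(hit)
  if (nh == 0) abort("`set` is disjoint from the ranking.")
  if (nh == n) abort("`set` covers the entire ranking; misses are undefined.")
  w <- abs(ranked$score)^p
  wh <- w * hit
  tot <- sum(wh)
  inc <- if (tot > 0) wh / tot else hit / nh   # all-zero hit scores: uniform weights
  dec <- (!hit) / (n - nh)
  running <- cumsum(inc - dec)
  imax <- which.max(running); imin <- which.min(running)
  # an exact |max| == |min| tie carries no direction: ES = 0 (the fgsea
  # convention, which keeps ES antisymmetric under score negation)
  tie <- abs(running[imax] + running[imin]) <= 1e-9
  es <- if (tie) 0 else if (running[imax] > -running[imin]) running[imax] else running[imin]
  leading <- if (tie) {
    character(0)
  } else if (es >= 0) {
    ranked$feature_id[seq_len(imax)][hit[seq_len(imax)]]
  } else {
    ranked$feature_id[imin:n][hit[imin:n]]
  }
  list(
    es = es,
    profile = tibble::tibble(position = seq_len(n), feature_id = ranked$feature_id,
                             running = running, hit = hit),
    leading_edge = leading
  )
}

# O(k log k) enrichment score from hit positions only, for the permutation
# null: the running-sum maximum occurs at a hit and the minimum just before a
# hit, so only those 2k candidate values need evaluating.
es_from_positions <- function(pos, w, n) {
  k <- length(pos)
  o <- order(pos)
  pos <- pos[o]; w <- w[o]
  tot <- sum(w)
  cw <- if (tot > 0) cumsum(w) / tot else seq_len(k) / k
  miss <- 1 / (n - k)
  at_hit <- cw - (pos - seq_len(k)) * miss
  # running sum just before hit j: cw_{j-1} - (pos_j - j) * miss
  before_hit <- c(0, cw[-k]) - (pos - seq_len(k)) * miss
  hi <- max(at_hit, 0)       # the path ends at exactly 0
  lo <- min(before_hit, 0)
  if (abs(hi + lo) <= 1e-9) 0 else if (hi > -lo) hi else lo
}

#' Pre-ranked gene-set enrichment with a gene-permutation null
#'
#' Computes the weighted running-sum ES for each gene set, then builds a null
#' distribution by drawing `n_perm` random same-size gene sets from the
#' ranked universe. NES divides ES by the mean |null ES| of matching sign and
#' the permutation p-value is the same-sign tail frequency with +1
#' smoothing, so p is never exactly zero. Gene permutation (rather than
#' sample permutation) is the appropriate null at 3-4 samples per group.
#'
#' @param ranked A `mirlink_ranking` tibble.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer RNG seed.
#' @param min_size,max_size Size bounds applied to each set after
#'   intersection with the ranking.
#' @param p Hit-weighting exponent.
#' @return A tibble of class `mirlink_gsea` with per-set columns `set, size,
#'   es, nes, pvalue, padj, leading_edge` (list column); running profiles are
#'   attached as the `profiles` attribute.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 10000, seed = 1L,
                           min_size = 5, max_size = 500, p = 1) {
  if (n_perm < 100) abort("`n_perm` must be >= 100.")
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("`sets` must be a uniquely named list.")
  }
  n <- nrow(ranked)
  inter <- lapply(sets, function(s) unique(s[s %in% ranked$feature_id]))
  sizes <- lengths(inter)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) abort("all gene sets fall outside the size bounds after intersection.")
  inter <- inter[keep]
  sizes <- sizes[keep]

  w_all <- abs(ranked$score)^p
  set.seed(as.integer(seed))

  null_for_size <- function(k) {
    vapply(seq_len(n_perm), function(i) {
      pos <- sample.int(n, k)
      es_from_positions(pos, w_all[pos], n)
    }, 0)
  }
  null_cache <- new.env(parent = emptyenv())

  res <- purrr::imap_dfr(inter, function(members, nm) {
    sc <- enrichment_score(ranked, members, p = p)
    key <- as.character(length(members))
    if (is.null(null_cache[[key]])) null_cache[[key]] <- null_for_size(length(members))
    null <- null_cache[[key]]
    es <- sc$es
    if (es > 0) {
      pos_null <- null[null > 0]
      pv <- (1 + sum(pos_null >= es - 1e-9)) / (1 + length(pos_null))
      nes <- if (length(pos_null) > 0) es / mean(pos_null) else NA_real_
    } else if (es < 0) {
      neg_null <- null[null < 0]
      pv <- (1 + sum(neg_null <= es + 1e-9)) / (1 + length(neg_null))
      nes <- if (length(neg_null) > 0) -es / mean(neg_null) else NA_real_
    } else {
      pv <- 1; nes <- 0
    }
    tibble::tibble(set = nm, size = length(members), es = es, nes = nes,
                   pvalue = pv, leading_edge = list(sc$leading_edge),
                   profile = list(sc$profile))
  })
  res$padj <- p.adjust(res$pvalue, method = "BH")
  profiles <- setNames(res$profile, res$set)
  res <- dplyr::select(res, "set", "size", "es", "nes", "pvalue", "padj", "leading_edge")
  class(res) <- c("mirlink_gsea", class(res))
  attr(res, "profiles") <- profiles
  attr(res, "n_perm") <- n_perm
  res
}
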