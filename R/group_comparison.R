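#' Two-sample t-test for phenotypes
#'
#' Thin, contract-checked wrapper around [stats::t.test()]. Welch's unequal
#' variance form is the default; the pooled-variance form is available by
#' flag. When both groups have zero variance the test statistic is taken by
#' convention: p = 1 for equal means, p = 0 otherwise.
#'
#' @param x,y Numeric vectors, each of length >= 2, finite.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return A tibble with columns `statistic` (t), `df`, `p_value`,
#'   `mean_x`, `mean_y`.
#' @export
t_test_independent <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in input", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble::tibble(
      statistic = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
      df = length(x) + length(y) - 2,
      p_value = if (same) 1 else 0,
      mean_x = mean(x), mean_y = mean(y)))
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_x = mean(x), mean_y = mean(y)
  )
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie-corrected
#' variance and continuity correction. Both routes are two-sided and
#' delegate to [stats::wilcox.test()].
#'
#' @param x,y Numeric vectors, non-empty.
#' @param mode `"auto"` (the rule above), `"exact"`, or `"normal"`.
#' @return A tibble with columns `statistic` (the Mann-Whitney U of `x`)
#'   and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) {
    stop("empty input vector", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
    auto = (length(x) + length(y) <= 20) && !ties,
    exact = TRUE,
    normal = FALSE
  )
  if (exact && ties) {
    stop("exact mode is unavailable with tied values", call. = FALSE)
  }
  r <- rank(c(x, y))
  if (stats::var(r) == 0) {
    # every value tied: no evidence of a shift
    return(tibble::tibble(statistic = length(x) * length(y) / 2, p_value = 1))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment via [stats::p.adjust()], with domain checks: sort the
#' p-values ascending, take \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}
#' capped at 1, and return in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential-abundance table between two enterotypes
#'
#' For a rank-aggregated relative-abundance table and a two-cluster
#' assignment, selects features by mean relative abundance (either the top N
#' or all features above a percentage threshold), tests each with the
#' Wilcoxon rank-sum test, adjusts with Benjamini-Hochberg, and reports
#' per-cluster means and standard errors on the percentage scale — the
#' familiar "mean ± SE, P, q" table of two-group microbiome comparisons.
#'
#' @param table A [feature_table()] of kind `"relative"`.
#' @param clusters A clustering object or named label vector with exactly
#'   two clusters, each of size >= 2.
#' @param selector `list(top_n = 15)` or `list(min_mean_pct = 1)`. The
#'   selection mean is over all samples by default; set
#'   `scope = "per_cluster"` inside the selector list to require the
#'   threshold in either cluster instead.
#' @param alpha FDR level for the `enriched_in` call (default 0.05).
#' @return A tibble (one row per selected feature, ordered by overall mean,
#'   descending) with columns `feature_id`, `mean_1`, `se_1`, `mean_2`,
#'   `se_2` (percent), `p_raw`, `q_fdr`, `enriched_in`
#'   (`"cluster1"`/`"cluster2"`/`"ns"`).
#' @export
differential_table <- function(table, clusters,
                               selector = list(top_n = 15), alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  lab <- cluster_labels(clusters)
  lab <- lab[colnames(table)]
  if (anyNA(lab)) stop("cluster labels missing for some samples", call. = FALSE)
  lev <- sort(unique(lab))
  if (length(lev) != 2) stop("differential_table requires exactly 2 clusters",
                             call. = FALSE)
  if (any(table(lab) < 2)) stop("each cluster needs at least 2 samples",
                                call. = FALSE)
  m <- unclass(table)
  m1 <- m[, lab == lev[1], drop = FALSE]
  m2 <- m[, lab == lev[2], drop = FALSE]

  scope <- selector$scope %||% "overall"
  keep <- if (!is.null(selector$top_n)) {
    mu <- rowMeans(m)
    ord <- order(-mu, rownames(m))
    ord[seq_len(min(selector$top_n, nrow(m)))]
  } else if (!is.null(selector$min_mean_pct)) {
    thr <- selector$min_mean_pct / 100
    if (scope == "per_cluster") {
      which(rowMeans(m1) > thr | rowMeans(m2) > thr)
    } else {
      which(rowMeans(m) > thr)
    }
  } else {
    stop("selector must contain top_n or min_mean_pct", call. = FALSE)
  }
  if (length(keep) == 0) stop("no feature passes the selector", call. = FALSE)

  se <- function(v) stats::sd(v) / sqrt(length(v))
  res <- purrr::map_dfr(keep, function(i) {
    w <- wilcoxon_rank_sum(m1[i, ], m2[i, ], mode = "auto")
    tibble::tibble(
      feature_id = rownames(m)[i],
      mean_1 = 100 * mean(m1[i, ]), se_1 = 100 * se(m1[i, ]),
      mean_2 = 100 * mean(m2[i, ]), se_2 = 100 * se(m2[i, ]),
      p_raw = w$p_value
    )
  })
  res$q_fdr <- bh_adjust(res$p_raw)
  res$enriched_in <- dplyr::case_when(
    res$q_fdr >= alpha ~ "ns",
    res$mean_1 > res$mean_2 ~ "cluster1",
    TRUE ~ "cluster2"
  )
  dplyr::arrange(res, dplyr::desc((mean_1 + mean_2) / 2), feature_id)
}

#' Phenotype comparison table between two enterotypes
#'
#' Runs [t_test_independent()] on every numeric metadata column, cluster 1
#' versus cluster 2, reporting mean ± SE per cluster in the trait's own
#' units.
#'
#' @param meta Metadata tibble with a `sample_id` column.
#' @param clusters Clustering object or named label vector (two clusters).
#' @param variant Passed to [t_test_independent()].
#' @return A tibble with one row per numeric trait.
#' @export
phenotype_table <- function(meta, clusters, variant = "welch") {
  lab <- cluster_labels(clusters)
  lab <- lab[meta$sample_id]
  if (anyNA(lab)) stop("cluster labels missing for some samples", call. = FALSE)
  lev <- sort(unique(lab))
  traits <- names(meta)[vapply(meta, is.numeric, logical(1))]
  se <- function(v) stats::sd(v) / sqrt(length(v))
  purrr::map_dfr(traits, function(tr) {
    x <- meta[[tr]][lab == lev[1]]
    y <- meta[[tr]][lab == lev[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    ht <- t_test_independent(x, y, variant = variant)
    tibble::tibble(
      trait = tr,
      mean_1 = mean(x), se_1 = se(x),
      mean_2 = mean(y), se_2 = se(y),
      statistic = ht$statistic, p_value = ht$p_value
    )
  })
}
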