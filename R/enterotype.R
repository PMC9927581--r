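#' Partitioning around medoids on a precomputed distance matrix
#'
#' Deterministic k-medoids. When the number of candidate medoid sets
#' \eqn{\binom{n}{k}} is small (at most `exact_limit`), the globally optimal
#' medoid set is found by exhaustive enumeration. Otherwise a greedy BUILD
#' phase picks medoids one at a time, each minimizing the total distance of
#' all samples to their nearest medoid, and a steepest-descent SWAP phase
#' accepts, at each step, the (medoid, non-medoid) exchange with the largest
#' strict decrease in the objective until no exchange improves it. All ties
#' break toward the lowest sample index, so the result depends only on the
#' input order; there is no randomness.
#'
#' @param dist A [dist_matrix()].
#' @param k Number of clusters, `2 <= k < n`.
#' @param exact_limit Enumerate all medoid sets exactly when
#'   `choose(n, k)` does not exceed this (default 20000; covers k = 2 up to
#'   n = 200 and every instance with a handful of samples).
#' @return An object of class `pam_clustering`: list with `assignment`
#'   (tibble `sample_id`, `cluster`), `medoid_ids`, `k`, and `objective`
#'   (total distance of samples to their cluster medoid).
#' @export
pam_cluster <- function(dist, k, exact_limit = 20000) {
  stopifnot(inherits(dist, "dist_matrix"))
  d <- unclass(dist)
  n <- nrow(d)
  if (k < 2 || k >= n) {
    stop(sprintf("k must satisfy 2 <= k < n (k = %d, n = %d)", k, n),
         call. = FALSE)
  }

  if (choose(n, k) <= exact_limit) {
    medoids <- pam_exact(d, k)
    return(pam_finish(d, medoids, k))
  }

  # BUILD: first medoid minimizes total distance; each later medoid is the
  # point whose addition most reduces sum(min distance to medoid set).
  totals <- colSums(d)
  medoids <- which.min(totals)            # which.min takes lowest index on ties
  nearest <- d[, medoids]
  while (length(medoids) < k) {
    cand <- setdiff(seq_len(n), medoids)
    gains <- vapply(cand, function(h) sum(pmin(nearest, d[, h])), numeric(1))
    best <- cand[which.min(gains)]
    medoids <- c(medoids, best)
    nearest <- pmin(nearest, d[, best])
  }

  objective_of <- function(med) sum(apply(d[, med, drop = FALSE], 1, min))

  # SWAP: steepest feasible exchange, ties toward lowest medoid index then
  # lowest candidate index.
  obj <- objective_of(medoids)
  repeat {
    dm <- d[, medoids, drop = FALSE]
    ord <- apply(dm, 1, order)            # columns: per-sample medoid order
    near_i <- ord[1, ]
    near <- dm[cbind(seq_len(n), near_i)]
    second <- dm[cbind(seq_len(n), ord[2, ])]
    non <- setdiff(seq_len(n), medoids)
    best_delta <- 0; best_swap <- NULL
    for (mi in seq_along(medoids)) {
      # distance to nearest surviving medoid once medoid mi is removed
      base <- ifelse(near_i == mi, second, near)
      for (h in non) {
        new_obj <- sum(pmin(base, d[, h]))
        delta <- new_obj - obj
        if (delta < best_delta - 1e-15) {
          best_delta <- delta
          best_swap <- c(mi, h)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1]] <- best_swap[2]
    obj <- objective_of(medoids)
  }

  pam_finish(d, medoids, k)
}

# Exhaustive search over all k-subsets of medoids; lowest subset in
# lexicographic order wins ties, so the result is deterministic.
pam_exact <- function(d, k) {
  n <- nrow(d)
  if (k == 2) {
    best <- NULL; best_obj <- Inf
    for (a in seq_len(n - 1)) {
      objs <- colSums(pmin(d[, (a + 1):n, drop = FALSE], d[, a]))
      j <- which.min(objs)
      if (objs[j] < best_obj - 1e-15) {
        best_obj <- objs[j]
        best <- c(a, a + j)
      }
    }
    return(best)
  }
  sets <- utils::combn(n, k)
  objs <- vapply(seq_len(ncol(sets)), function(s) {
    sum(Reduce(pmin, asplit(d[, sets[, s], drop = FALSE], 2)))
  }, numeric(1))
  sets[, which.min(objs)]
}

# Nearest-medoid assignment (ties to the lowest medoid index) and final
# objective, shared by the exact and heuristic paths.
pam_finish <- function(d, medoids, k) {
  n <- nrow(d)
  medoids <- sort(medoids)
  dm <- d[, medoids, drop = FALSE]
  lab <- apply(dm, 1, which.min)
  obj <- sum(dm[cbind(seq_len(n), lab)])
  structure(
    list(
      assignment = tibble::tibble(sample_id = rownames(d),
                                  cluster = as.integer(lab)),
      medoid_ids = rownames(d)[medoids],
      k = as.integer(k),
      objective = obj
    ),
    class = "pam_clustering"
  )
}

#' @export
print.pam_clustering <- function(x, ...) {
  cat(sprintf("<pam_clustering> k = %d, objective = %.4f\n", x$k, x$objective))
  cat("medoids:", paste(x$medoid_ids, collapse = ", "), "\n")
  print(table(cluster = x$assignment$cluster))
  invisible(x)
}

#' Calinski-Harabasz index of a clustering
#'
#' \eqn{CH = [B/(k-1)] / [W/(n-k)]} with B and W the between- and
#' within-cluster sums of squared deviations from centroids. Because the
#' index is defined for Euclidean geometry, samples are first embedded by
#' principal-coordinate analysis of the distance matrix and the sums of
#' squares taken over all positive-eigenvalue axes.
#'
#' @param dist A [dist_matrix()].
#' @param clusters Integer cluster labels (vector named by sample or in the
#'   matrix order), or a `pam_clustering` object.
#' @return The CH index; `Inf` (with a warning) when all within-cluster
#'   scatter is zero.
#' @export
calinski_harabasz <- function(dist, clusters) {
  stopifnot(inherits(dist, "dist_matrix"))
  if (inherits(clusters, "pam_clustering")) {
    clusters <- stats::setNames(clusters$assignment$cluster,
                                clusters$assignment$sample_id)
  }
  if (!is.null(names(clusters))) {
    clusters <- clusters[rownames(dist)]
  }
  clusters <- as.integer(as.factor(clusters))
  n <- nrow(dist)
  k <- length(unique(clusters))
  if (k < 2) stop("Calinski-Harabasz is undefined for k = 1", call. = FALSE)
  coords <- pcoa(dist)$coordinates
  grand <- colMeans(coords)
  w <- 0; b <- 0
  for (g in unique(clusters)) {
    sub <- coords[clusters == g, , drop = FALSE]
    cen <- colMeans(sub)
    w <- w + sum(sweep(sub, 2, cen)^2)
    b <- b + nrow(sub) * sum((cen - grand)^2)
  }
  if (w <= .Machine$double.eps * max(b, 1)) {
    warning("zero within-cluster scatter; CH index is infinite")
    return(Inf)
  }
  (b / (k - 1)) / (w / (n - k))
}

#' Discover enterotypes: scan k, cluster, and keep the best-supported model
#'
#' Runs [pam_cluster()] for every k in `k_range`, scores each clustering with
#' [calinski_harabasz()], and keeps the assignment at the k with the maximum
#' CH index (ties go to the smallest k).
#'
#' @param dist A [dist_matrix()] (typically from [jsd_distance()]).
#' @param k_range Integer vector of cluster numbers to scan (default `2:10`,
#'   truncated to `n - 1`).
#' @return An object of class `enterotype_fit`: list with `trace` (tibble
#'   `k`, `ch`), `optimal_k`, `assignment`, `medoid_ids`, `objective`, and
#'   the input distance matrix.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(simulation_config(), seed = 1)
#' rel <- to_relative(cohort$counts)
#' genus <- aggregate_by_rank(rel, cohort$taxonomy, "genus")
#' fit <- enterotype(jsd_distance(genus))
#' glance(fit)
#' }
#' @export
enterotype <- function(dist, k_range = 2:10) {
  stopifnot(inherits(dist, "dist_matrix"))
  n <- nrow(dist)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) stop("empty k_range", call. = FALSE)
  fits <- lapply(k_range, function(k) pam_cluster(dist, k))
  ch <- vapply(fits, function(f) calinski_harabasz(dist, f), numeric(1))
  best <- which.max(ch)                   # lowest k on ties
  fit <- fits[[best]]
  structure(
    list(
      trace = tibble::tibble(k = k_range, ch = ch),
      optimal_k = k_range[best],
      assignment = fit$assignment,
      medoid_ids = fit$medoid_ids,
      objective = fit$objective,
      dist = dist
    ),
    class = "enterotype_fit"
  )
}

#' @export
print.enterotype_fit <- function(x, ...) {
  cat(sprintf("<enterotype_fit> optimal k = %d (CH = %.2f)\n",
              x$optimal_k, max(x$trace$ch)))
  print(table(cluster = x$assignment$cluster))
  invisible(x)
}

#' Identify the driver taxon of each enterotype
#'
#' The driver of a cluster is the feature with the highest mean relative
#' abundance among that cluster's samples (ties broken by lexicographically
#' smallest feature ID). The full ranked contribution list per cluster is
#' returned; the driver is the `rank == 1` row.
#'
#' @param table A [feature_table()] of kind `"relative"`.
#' @param clusters A `pam_clustering`/`enterotype_fit` object or a named
#'   vector of cluster labels.
#' @return A tibble with columns `cluster`, `feature_id`, `mean_abundance`,
#'   `rank`, `driver`.
#' @export
identify_drivers <- function(table, clusters) {
  stopifnot(inherits(table, "feature_table"))
  lab <- cluster_labels(clusters)
  missing <- setdiff(colnames(table), names(lab))
  if (length(missing) > 0) {
    stop(sprintf("no cluster label for sample '%s'", missing[1]), call. = FALSE)
  }
  lab <- lab[colnames(table)]
  purrr::map_dfr(sort(unique(lab)), function(g) {
    sub <- unclass(table)[, lab == g, drop = FALSE]
    if (ncol(sub) == 0) stop(sprintf("cluster %s is empty", g), call. = FALSE)
    mu <- rowMeans(sub)
    ord <- order(-mu, rownames(table))
    tibble::tibble(
      cluster = g,
      feature_id = rownames(table)[ord],
      mean_abundance = mu[ord],
      rank = seq_along(ord),
      driver = seq_along(ord) == 1L
    )
  })
}

# Coerce the various clustering carriers to a named integer label vector.
cluster_labels <- function(clusters) {
  if (inherits(clusters, "enterotype_fit") ||
      inherits(clusters, "pam_clustering")) {
    stats::setNames(clusters$assignment$cluster, clusters$assignment$sample_id)
  } else if (!is.null(names(clusters))) {
    clusters
  } else {
    stop("clusters must be a fit object or a named label vector",
         call. = FALSE)
  }
}

#' Principal-coordinate analysis of a distance matrix
#'
#' Classical scaling (Gower): double-center \eqn{-D^2/2}, eigendecompose,
#' and scale eigenvectors by the square root of positive eigenvalues.
#' Negative eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are reported but excluded from the coordinates and from
#' `proportion_explained`.
#'
#' @param dist A [dist_matrix()].
#' @return An object of class `pcoa_result`: list with `coordinates`
#'   (samples x positive axes, columns `PCo1`, `PCo2`, ...), `eigenvalues`
#'   (all, descending), and `proportion_explained` (over positive
#'   eigenvalues; sums to at most 1).
#' @export
pcoa <- function(dist) {
  stopifnot(inherits(dist, "dist_matrix"))
  n <- nrow(dist)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(unclass(dist)), k = n - 1, eig = TRUE)
  )
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- sum(eig > max(abs(eig[1]), 1) * 1e-12 & eig > 0)
  pos <- min(pos, ncol(fit$points))
  coords <- fit$points[, seq_len(pos), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(pos))
  rownames(coords) <- rownames(dist)
  structure(
    list(
      coordinates = coords,
      eigenvalues = eig,
      proportion_explained = eig[seq_len(pos)] / sum(eig[eig > 0])
    ),
    class = "pcoa_result"
  )
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d samples, %d positive axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  pe <- round(100 * x$proportion_explained[seq_len(min(3, ncol(x$coordinates)))], 1)
  cat("variation explained:", paste0(pe, "%", collapse = ", "), "\n")
  invisible(x)
}

#' ANOSIM: analysis of similarities
#'
#' Ranks all pairwise distances and contrasts mean between-group with mean
#' within-group ranks: \eqn{R = (\bar r_B - \bar r_W) / (n(n-1)/4)}. The
#' permutation p-value is \eqn{(1 + \#\{R^* \ge R\}) / (1 + n_{perm})} over
#' random relabelings, so it can never fall below the permutation floor.
#'
#' @param dist A [dist_matrix()].
#' @param groups Group labels, named by sample or in matrix order; at least
#'   two groups of two.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutations (required for
#'   reproducibility).
#' @return A tibble with columns `statistic` (R), `p_value`, `n_perm`.
#' @export
anosim_test <- function(dist, groups, n_perm = 999, seed = NULL) {
  stopifnot(inherits(dist, "dist_matrix"))
  if (!is.null(names(groups))) groups <- groups[rownames(dist)]
  groups <- as.factor(groups)
  n <- nrow(dist)
  if (length(groups) != n) stop("groups do not match samples", call. = FALSE)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop(sprintf("group '%s' has fewer than 2 members",
                 names(sizes)[sizes < 2][1]), call. = FALSE)
  }
  up <- which(upper.tri(unclass(dist)))
  rk <- rank(unclass(dist)[up])           # mid-ranks on ties
  ij <- which(upper.tri(unclass(dist)), arr.ind = TRUE)
  denom <- n * (n - 1) / 4
  r_stat <- function(g) {
    within <- g[ij[, 1]] == g[ij[, 2]]
    (mean(rk[!within]) - mean(rk[within])) / denom
  }
  r_obs <- r_stat(groups)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  perm <- vapply(seq_len(n_perm), function(i) r_stat(sample(groups)), numeric(1))
  tibble::tibble(
    statistic = r_obs,
    p_value = (1 + sum(perm >= r_obs)) / (1 + n_perm),
    n_perm = as.integer(n_perm)
  )
}
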