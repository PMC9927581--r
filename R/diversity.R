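#' Construct a sample-by-sample distance matrix
#'
#' @param values Square numeric matrix with identical row/column sample
#'   names, symmetric to 1e-12, zero diagonal, non-negative.
#' @param metric Short metric name (e.g. `"jsd"`, `"bray"`).
#' @return A classed matrix of class `dist_matrix`.
#' @export
dist_matrix <- function(values, metric = "unknown") {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(values))) stop("distance matrix needs sample IDs",
                                      call. = FALSE)
  if (!identical(rownames(values), colnames(values))) {
    stop("row and column sample IDs differ", call. = FALSE)
  }
  if (max(abs(values - t(values))) > 1e-12) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(values)) > 1e-12)) {
    stop("distance matrix diagonal is not zero", call. = FALSE)
  }
  if (any(values < -1e-15)) stop("negative distances", call. = FALSE)
  values[values < 0] <- 0
  diag(values) <- 0
  values <- (values + t(values)) / 2
  structure(values, class = c("dist_matrix", "matrix", "array"),
            metric = metric)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d samples, metric = %s\n",
              nrow(x), attr(x, "metric")))
  k <- min(5L, nrow(x))
  print(round(unclass(x)[seq_len(k), seq_len(k), drop = FALSE], 4))
  if (nrow(x) > k) cat("...\n")
  invisible(x)
}

#' Tidy a distance matrix to long pair form
#' @param x A [dist_matrix()].
#' @param ... Unused.
#' @return Tibble with one row per unordered sample pair.
#' @exportS3Method tibble::as_tibble
as_tibble.dist_matrix <- function(x, ...) {
  n <- nrow(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    sample_1 = rownames(x)[idx[, 1]],
    sample_2 = colnames(x)[idx[, 2]],
    distance = unclass(x)[idx]
  )
}

#' Write / read a distance matrix as square TSV
#' @param dist A [dist_matrix()].
#' @param path File path.
#' @param metric Metric label used on read.
#' @return `path` / a [dist_matrix()].
#' @export
write_dist_matrix <- function(dist, path) {
  df <- data.frame(sample_id = rownames(dist), unclass(dist),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path, metric = "unknown") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  dist_matrix(m, metric = metric)
}

#' Alpha-diversity indices per sample
#'
#' Computes, from integer counts: observed richness (Sobs), the classic
#' Chao1 estimator \eqn{S + F_1^2 / (2 F_2)} (with the fallback
#' \eqn{S + F_1 (F_1 - 1) / 2} when no doubletons exist), the
#' abundance-based coverage estimator ACE with rare cutoff 10, Shannon
#' entropy in nats, and both Simpson forms: dominance \eqn{\sum p_i^2} and
#' diversity \eqn{1 - \sum p_i^2}.
#'
#' Richness estimators are undefined on relative abundances, so the input
#' must be a counts table.
#'
#' @param table A [feature_table()] of kind `"counts"`.
#' @return A tibble with columns `sample_id`, `sobs`, `chao1`, `ace`,
#'   `shannon`, `simpson_dominance`, `simpson_diversity`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table_kind(table) != "counts") {
    stop("alpha_diversity requires integer counts (richness estimators are undefined on relative abundances)",
         call. = FALSE)
  }
  m <- unclass(table)
  if (any(colSums(m) == 0)) {
    stop("sample with zero total count", call. = FALSE)
  }
  per_sample <- function(x) {
    x <- x[x > 0]
    s <- length(x)
    p <- x / sum(x)
    shannon <- -sum(p * log(p))
    simpson <- sum(p^2)
    f1 <- sum(x == 1); f2 <- sum(x == 2)
    chao1 <- if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / 2
    c(sobs = s, chao1 = chao1, ace = ace_estimate(x, chao1),
      shannon = shannon, simpson_dominance = simpson,
      simpson_diversity = 1 - simpson)
  }
  res <- t(apply(m, 2, per_sample))
  dplyr::bind_cols(tibble::tibble(sample_id = colnames(m)),
                   tibble::as_tibble(res))
}

# ACE with rare cutoff 10; falls back to Chao1 when sample coverage of the
# rare group cannot be estimated (C_ace = 0).
ace_estimate <- function(x, chao1_fallback) {
  x <- x[x > 0]
  rare <- x[x <= 10]
  s_abund <- sum(x > 10)
  s_rare <- length(rare)
  if (s_rare == 0) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) return(chao1_fallback)
  fk <- tabulate(rare, nbins = 10)
  k <- seq_len(10)
  gamma2 <- max(0, (s_rare / c_ace) * sum(k * (k - 1) * fk) /
                  (n_rare * (n_rare - 1)) - 1)
  s_abund + s_rare / c_ace + (f1 / c_ace) * gamma2
}

#' Jensen-Shannon distance matrix
#'
#' The enterotyping distance: for each sample pair the Jensen-Shannon
#' divergence \eqn{JSD(P, Q) = H(M) - (H(P) + H(Q))/2} with
#' \eqn{M = (P + Q)/2} and Shannon entropy \eqn{H} in nats, and the reported
#' distance its square root (a metric bounded by \eqn{\sqrt{\ln 2}}).
#' Zero abundances are replaced by a small pseudocount and each profile
#' renormalized before the divergence, so no Kullback-Leibler term is
#' infinite.
#'
#' @param table A [feature_table()] of kind `"relative"`.
#' @param pseudocount Positive replacement for zero abundances
#'   (default `1e-6`).
#' @return A [dist_matrix()] with metric `"jsd"`.
#' @export
jsd_distance <- function(table, pseudocount = 1e-6) {
  stopifnot(inherits(table, "feature_table"))
  if (table_kind(table) != "relative") {
    stop("jsd_distance requires a relative-abundance table", call. = FALSE)
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be > 0", call. = FALSE)
  }
  x <- unclass(table)
  x[x == 0] <- pseudocount
  x <- sweep(x, 2, colSums(x), "/")
  n <- ncol(x)
  h <- function(p) -sum(p * log(p))
  hx <- apply(x, 2, h)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m <- (x[, i] + x[, j]) / 2
      jsd <- h(m) - (hx[i] + hx[j]) / 2
      d[i, j] <- d[j, i] <- sqrt(max(jsd, 0))
    }
  }
  dist_matrix(d, metric = "jsd")
}

#' Bray-Curtis distance matrix
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, computed with
#' \code{vegan::vegdist}.
#'
#' @param table A [feature_table()] (counts or relative).
#' @return A [dist_matrix()] with metric `"bray"`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  zero <- colnames(table)[colSums(table) == 0]
  if (length(zero) >= 2) {
    stop(sprintf("Bray-Curtis undefined for all-zero sample pair: '%s', '%s'",
                 zero[1], zero[2]), call. = FALSE)
  }
  d <- as.matrix(vegan::vegdist(t(unclass(table)), method = "bray"))
  dist_matrix(d, metric = "bray")
}
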