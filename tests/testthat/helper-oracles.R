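# Independent oracles and small fixture builders shared across the suite.

# Adjusted Rand index between two label vectors.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  (si - expected) / ((sa + sb) / 2 - expected)
}

# Exhaustive k-medoids optimum: minimum over all medoid subsets of the sum
# of each point's distance to its nearest medoid.
oracle_pam_optimum <- function(d, k) {
  best <- Inf
  for (m in utils::combn(nrow(d), k, simplify = FALSE)) {
    obj <- sum(apply(d[, m, drop = FALSE], 1, min))
    if (obj < best) best <- obj
  }
  best
}

# Calinski-Harabasz from coordinates, straight from the definition.
oracle_ch <- function(coords, labels) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k <- length(unique(labels))
  grand <- colMeans(coords)
  w <- 0; b <- 0
  for (g in unique(labels)) {
    sub <- coords[labels == g, , drop = FALSE]
    cen <- colMeans(sub)
    w <- w + sum(sweep(sub, 2, cen)^2)
    b <- b + nrow(sub) * sum((cen - grand)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

# BH q-values by enumerating every rejection threshold: q_i is the smallest
# level alpha at which p_i would be rejected by the step-up rule.
oracle_bh <- function(p) {
  m <- length(p)
  sp <- sort(p)
  vapply(p, function(pi) {
    js <- which(sp >= pi - 1e-15)
    min(1, min(sp[js] * m / js))
  }, numeric(1))
}

# Spearman rho/p by explicit mid-rank Pearson + t approximation.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p)
}

# Random symmetric distance-like matrix (zero diagonal, non-negative).
random_dist <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  dist_matrix(m)
}

# dist_matrix from a coordinate matrix (Euclidean).
dist_from_coords <- function(coords) {
  coords <- as.matrix(coords)
  if (is.null(rownames(coords))) {
    rownames(coords) <- paste0("s", seq_len(nrow(coords)))
  }
  dist_matrix(as.matrix(stats::dist(coords)))
}

# Small counts fixture: 4 features x 3 samples.
toy_counts <- function() {
  m <- matrix(c(5, 5, 5, 5,
                10, 0, 0, 0,
                1, 2, 3, 4), nrow = 4,
              dimnames = list(paste0("f", 1:4), c("a", "b", "c")))
  feature_table(m, kind = "counts")
}

# Fast simulator settings for property tests: fewer reads, same structure.
quick_config <- function(...) {
  simulation_config(depth = 2000L, ...)
}
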