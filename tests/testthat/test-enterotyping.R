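test_that("pam recovers the planted two-pair structure", {
  m <- matrix(1, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.1
  m[3, 4] <- m[4, 3] <- 0.1
  diag(m) <- 0
  dimnames(m) <- list(LETTERS[1:4], LETTERS[1:4])
  fit <- pam_cluster(dist_matrix(m), 2)
  expect_equal(fit$objective, 0.2)
  lab <- stats::setNames(fit$assignment$cluster, fit$assignment$sample_id)
  expect_equal(lab[["A"]], lab[["B"]])
  expect_equal(lab[["C"]], lab[["D"]])
  expect_false(lab[["A"]] == lab[["C"]])
})

test_that("pam objective equals the exhaustive optimum on random instances", {
  set.seed(7)
  for (r in 1:40) {
    n <- sample(6:10, 1)
    k <- sample(2:3, 1)
    d <- random_dist(n)
    fit <- pam_cluster(d, k)
    expect_equal(fit$objective, oracle_pam_optimum(unclass(d), k),
                 tolerance = 1e-12)
    # invariant: objective = sum of distances to own-cluster medoid
    lab <- fit$assignment$cluster
    med <- match(fit$medoid_ids, rownames(d))
    expect_equal(fit$objective,
                 sum(unclass(d)[cbind(seq_len(n), med[lab])]))
    # each medoid belongs to its own cluster
    expect_equal(lab[med], seq_len(k))
  }
})

test_that("pam heuristic path (large instances) never increases the objective and stays deterministic", {
  set.seed(8)
  d <- random_dist(40)
  # force the BUILD+SWAP path by disabling exact enumeration
  h1 <- pam_cluster(d, 3, exact_limit = 1)
  h2 <- pam_cluster(d, 3, exact_limit = 1)
  expect_identical(h1, h2)
  ex <- pam_cluster(d, 3)              # exact path, choose(40,3) < 20000
  expect_gte(h1$objective, ex$objective - 1e-12)
  # heuristic should still be close to optimal on easy instances
  expect_lt((h1$objective - ex$objective) / ex$objective, 0.2)
})

test_that("pam handles edge cases: k bounds, duplicates, k = n - 1", {
  d <- random_dist(6, seed = 9)
  expect_error(pam_cluster(d, 1), "k must")
  expect_error(pam_cluster(d, 6), "k must")

  # duplicate samples (zero distance) are co-assigned
  m <- unclass(d)
  m[1, 2] <- m[2, 1] <- 0
  d2 <- dist_matrix(m)
  fit <- pam_cluster(d2, 2)
  lab <- fit$assignment$cluster
  expect_equal(lab[1], lab[2])

  # k = n - 1 on distinct points: objective is the smallest pairwise distance
  fit <- pam_cluster(d, 5)
  off <- unclass(d)[upper.tri(unclass(d))]
  expect_equal(fit$objective, min(off))
})

test_that("calinski_harabasz matches direct formula evaluation", {
  coords <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- dist_from_coords(matrix(coords))
  good <- stats::setNames(rep(1:2, each = 3), rownames(d))
  ch <- calinski_harabasz(d, good)
  expect_equal(ch, 15000, tolerance = 1e-9)
  expect_equal(ch, oracle_ch(matrix(coords), good), tolerance = 1e-9)

  wrong <- stats::setNames(c(1, 1, 2, 2, 2, 2), rownames(d))
  expect_lt(calinski_harabasz(d, wrong), 15000)
  expect_equal(calinski_harabasz(d, wrong), oracle_ch(matrix(coords), wrong),
               tolerance = 1e-9)

  set.seed(10)
  pts <- matrix(rnorm(40), 20, 2)
  lab <- stats::setNames(sample(1:3, 20, TRUE), paste0("s", 1:20))
  expect_equal(calinski_harabasz(dist_from_coords(pts), lab),
               oracle_ch(pts, lab[paste0("s", 1:20)]), tolerance = 1e-9)
})

test_that("calinski_harabasz degenerate cases: W = 0 sentinel, k = 1 error", {
  pts <- matrix(rep(c(0, 5), each = 3))
  d <- dist_from_coords(pts)
  lab <- stats::setNames(rep(1:2, each = 3), rownames(d))
  expect_warning(ch <- calinski_harabasz(d, lab), "infinite")
  expect_identical(ch, Inf)
  expect_error(calinski_harabasz(d, stats::setNames(rep(1, 6), rownames(d))),
               "k = 1")
})

test_that("enterotype() finds three well-separated point clouds", {
  set.seed(12)
  pts <- rbind(cbind(rnorm(10, 0, 0.1), rnorm(10, 0, 0.1)),
               cbind(rnorm(10, 5, 0.1), rnorm(10, 5, 0.1)),
               cbind(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1)))
  fit <- enterotype(dist_from_coords(pts), k_range = 2:6)
  expect_equal(fit$optimal_k, 3)
  truth <- rep(1:3, each = 10)
  expect_gte(ari(fit$assignment$cluster, truth), 0.99)
  expect_equal(fit$trace$k, 2:6)
  expect_equal(max(fit$trace$ch), fit$trace$ch[fit$trace$k == 3])
  expect_error(enterotype(dist_from_coords(pts), k_range = integer(0)),
               "empty")
})

test_that("identify_drivers ranks by within-cluster mean with lexicographic ties", {
  m <- matrix(c(0.35, 0.35, 0.30,
                0.35, 0.35, 0.30,
                0.10, 0.60, 0.30,
                0.10, 0.62, 0.28), 3, 4,
              dimnames = list(c("zeta", "alpha", "mid"),
                              c("s1", "s2", "s3", "s4")))
  ft <- feature_table(m, kind = "relative")
  lab <- stats::setNames(c(1, 1, 2, 2), colnames(m))
  dr <- identify_drivers(ft, lab)
  d1 <- dr[dr$cluster == 1 & dr$driver, ]
  # cluster 1: zeta and alpha tie at 0.35 -> lexicographically smallest wins
  expect_equal(d1$feature_id, "alpha")
  d2 <- dr[dr$cluster == 2 & dr$driver, ]
  expect_equal(d2$feature_id, "alpha")   # mean 0.61 tops cluster 2
  expect_equal(dr$rank[dr$cluster == 1], 1:3)
  expect_error(identify_drivers(ft, stats::setNames(c(1, 1), c("s1", "s2"))),
               "no cluster label")
})

test_that("pcoa reconstructs Euclidean geometry and reports eigenvalues", {
  # collinear points at mutual distances 1, 1, 2
  m <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  ord <- pcoa(dist_matrix(m))
  expect_equal(ncol(ord$coordinates), 1)
  rec <- as.matrix(stats::dist(ord$coordinates))
  expect_equal(rec[lower.tri(rec)], m[lower.tri(m)], tolerance = 1e-9)
  expect_equal(sum(ord$proportion_explained), 1, tolerance = 1e-9)

  # random 3-D configuration: full positive eigenspace reproduces distances
  set.seed(13)
  pts <- matrix(rnorm(36), 12, 3)
  d <- dist_from_coords(pts)
  ord <- pcoa(d)
  rec <- as.matrix(stats::dist(ord$coordinates))
  expect_equal(max(abs(rec - unclass(d))), 0, tolerance = 1e-9)
  expect_equal(ord$eigenvalues, sort(ord$eigenvalues, decreasing = TRUE))
  expect_lte(sum(ord$proportion_explained), 1 + 1e-12)

  # duplicated sample lands on coincident coordinates
  d2 <- dist_from_coords(rbind(pts, pts[1, ]))
  ord2 <- pcoa(d2)
  expect_equal(ord2$coordinates[1, ], ord2$coordinates[13, ],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("anosim separates structure, respects the permutation floor, matches vegan", {
  set.seed(14)
  pts <- rbind(matrix(rnorm(16, 0, 0.05), 8, 2),
               matrix(rnorm(16, 3, 0.05), 8, 2))
  d <- dist_from_coords(pts)
  g <- stats::setNames(rep(c("a", "b"), each = 8), rownames(d))
  res <- anosim_test(d, g, n_perm = 199, seed = 3)
  expect_equal(res$statistic, 1)       # all within < all between
  expect_equal(res$p_value, 1 / 200)   # permutation floor
  expect_gte(res$p_value, 1 / (1 + 199))

  # statistic agrees with the independent vegan implementation
  set.seed(15)
  pts <- matrix(rnorm(40), 20, 2)
  d <- dist_from_coords(pts)
  g <- stats::setNames(rep(c("a", "b"), 10), rownames(d))
  ours <- anosim_test(d, g, n_perm = 99, seed = 4)
  veg <- vegan::anosim(stats::as.dist(unclass(d)), g, permutations = 99)
  expect_equal(ours$statistic, unname(veg$statistic), tolerance = 1e-12)

  expect_error(anosim_test(d, stats::setNames(c("a", rep("b", 19)),
                                              rownames(d))),
               "fewer than 2")

  # reproducible under the same seed
  expect_identical(anosim_test(d, g, n_perm = 99, seed = 4),
                   anosim_test(d, g, n_perm = 99, seed = 4))
})
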