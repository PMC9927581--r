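test_that("spearman handles monotone, antitone and tied data against the oracle", {
  expect_equal(spearman_cor(c(1, 2, 3), c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 2, 1))$rho, -1)

  x <- c(1, 1, 2, 3); y <- c(2, 3, 1, 4)
  s <- spearman_cor(x, y)
  o <- oracle_spearman(x, y)
  expect_equal(s$rho, o$rho, tolerance = 1e-12)
  expect_equal(s$p_value, o$p, tolerance = 1e-12)

  set.seed(8)
  for (r in 1:30) {
    x <- sample(1:6, 12, TRUE)          # heavy ties
    y <- rnorm(12)
    s <- spearman_cor(x, y)
    o <- oracle_spearman(x, y)
    expect_equal(s$rho, o$rho, tolerance = 1e-12)
    expect_equal(s$p_value, o$p, tolerance = 1e-12)
  }
  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)), "rank variance")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("trait_correlations recovers planted coupling and skips bad traits", {
  hits <- 0
  for (r in 1:20) {
    co <- simulate_cohort(quick_config(), seed = 200 + r)
    genus <- aggregate_by_rank(to_relative(co$counts), co$taxonomy, "genus")
    corr <- trait_correlations(genus, co$metadata,
                               genera = "Prevotellaceae_NK3B31_group",
                               traits = "adg")
    if (corr$rho > 0 && corr$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)                 # planted rank coupling is recovered

  co <- simulate_cohort(quick_config(), seed = 300)
  genus <- aggregate_by_rank(to_relative(co$counts), co$taxonomy, "genus")
  meta <- co$metadata
  meta$constant <- 1
  expect_warning(
    corr <- trait_correlations(genus, meta, traits = c("adg", "constant")),
    "constant")
  expect_false("constant" %in% corr$trait)
  expect_true(all(abs(corr$rho) <= 1, na.rm = TRUE))
  expect_identical(corr$sig_05, !is.na(corr$p_value) & corr$p_value < 0.05)
})

test_that("null traits flag about 5% of cells at p < 0.05", {
  set.seed(9)
  rates <- vapply(1:10, function(r) {
    co <- simulate_cohort(quick_config(), seed = 400 + r)
    genus <- aggregate_by_rank(to_relative(co$counts), co$taxonomy, "genus")
    meta <- tibble::tibble(sample_id = colnames(genus),
                           noise = rnorm(ncol(genus)))
    corr <- trait_correlations(genus, meta, traits = "noise")
    mean(corr$sig_05, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(rates), 0.12)
  expect_gt(mean(rates), 0.005)
})

test_that("network node filters apply the documented abundance and prevalence rules", {
  # 10 samples; A,B,C abundant & prevalent; D nonzero in only 4/10;
  # E mean abundance 0.0005 (below 0.1%)
  set.seed(10)
  n <- 10
  latent <- sort(runif(n))
  A <- 0.02 + 0.1 * latent
  B <- 0.01 + 0.05 * latent^2          # strictly increasing in latent
  C <- 0.15 - 0.1 * latent             # strictly decreasing
  D <- c(0.01, 0.01, 0.01, 0.01, rep(0, 6))
  E <- rep(0.0005, n)
  filler <- 1 - (A + B + C + D + E)
  m <- rbind(A = A, B = B, C = C, D = D, E = E, filler = filler)
  colnames(m) <- paste0("s", 1:n)
  ft <- feature_table(m, kind = "relative")

  net <- build_network(ft)
  expect_setequal(net$nodes$genus, c("A", "B", "C", "filler"))
  expect_false("D" %in% net$nodes$genus)   # prevalence 0.4 <= 0.5
  expect_false("E" %in% net$nodes$genus)   # mean 0.0005 <= 0.001

  # edge set equals the brute-force threshold set over surviving nodes
  surv <- net$nodes$genus
  expected <- list()
  for (i in seq_along(surv)) for (j in seq_along(surv)) {
    if (i < j) {
      o <- oracle_spearman(m[surv[i], ], m[surv[j], ])
      if (abs(o$rho) > 0.2 && o$p < 0.05) {
        expected[[length(expected) + 1]] <-
          paste(sort(c(surv[i], surv[j])), collapse = "|")
      }
    }
  }
  got <- paste(net$edges$from, net$edges$to, sep = "|")
  expect_setequal(got, unlist(expected))

  # the two co-monotone genera are positively linked, the antitone pair negative
  expect_true(any(net$edges$from == "A" & net$edges$to == "B" &
                    net$edges$sign == "pos"))
  ac <- net$edges[(net$edges$from == "A" & net$edges$to == "C"), ]
  expect_equal(ac$sign, "neg")
})

test_that("network edges are invariant to strictly monotone transformations", {
  set.seed(11)
  co <- simulate_cohort(quick_config(), seed = 500)
  genus <- aggregate_by_rank(to_relative(co$counts), co$taxonomy, "genus")
  sub <- co$truth$sample_id[co$truth$component == 1]
  net1 <- build_network(genus, samples = sub)
  # strictly monotone per-genus transform: sqrt then a fine integer grid.
  # Abundances live on the k/depth grid, so rounding at 1e7 resolution is
  # injective and preserves all ranks exactly.
  tr <- round(1e7 * sqrt(unclass(genus)))
  net2 <- build_network(feature_table(tr, kind = "counts"), samples = sub,
                        min_mean_abundance = 0, min_prevalence = 0)
  e1 <- paste(net1$edges$from, net1$edges$to, net1$edges$sign)
  e2 <- paste(net2$edges$from, net2$edges$to, net2$edges$sign)
  expect_true(all(e1 %in% e2))
})

test_that("filters are order-independent and extreme thresholds empty the edge set", {
  co <- simulate_cohort(quick_config(), seed = 600)
  genus <- aggregate_by_rank(to_relative(co$counts), co$taxonomy, "genus")
  sub <- co$truth$sample_id[co$truth$component == 2]
  net <- build_network(genus, samples = sub)
  # restricting the input to the filtered nodes reproduces the same edges
  net_restricted <- build_network(genus, samples = sub,
                                  nodes = net$nodes$genus)
  expect_equal(net$edges, net_restricted$edges)

  hard <- build_network(genus, samples = sub, rho_threshold = 1.0)
  expect_equal(nrow(hard$edges), 0)

  expect_warning(
    empty <- build_network(genus, samples = sub, min_mean_abundance = 0.9),
    "fewer than 2")
  expect_equal(nrow(empty$nodes), 0)
  expect_error(build_network(genus, samples = sub[1:3]), "at least 4")
})

test_that("network export: SIF lines, edge TSV, GraphML attribute round-trip", {
  m <- rbind(A = c(0.02, 0.04, 0.06, 0.08, 0.10),
             B = c(0.010, 0.015, 0.020, 0.025, 0.030),
             C = c(0.10, 0.08, 0.06, 0.04, 0.02))   # antitone with A
  m <- rbind(m, filler = 1 - colSums(m))
  colnames(m) <- paste0("s", 1:5)
  net <- build_network(feature_table(m, kind = "relative"),
                       min_prevalence = 0, alpha = 0.2)
  expect_gte(nrow(net$edges), 2)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  lines <- readLines(sif)
  edge_lines <- grep("\t(pos|neg)\t", lines, value = TRUE)
  expect_length(edge_lines, nrow(net$edges))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(sort(back$rho), sort(net$edges$rho), tolerance = 1e-12)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_equal(sort(igraph::E(g)$rho), sort(net$edges$rho),
               tolerance = 1e-9)
  expect_true("mean_abundance" %in%
                igraph::vertex_attr_names(g))

  # empty network still writes its node list
  expect_warning(empty <- build_network(feature_table(m, kind = "relative"),
                                        min_mean_abundance = 0.9,
                                        min_prevalence = 0))
  export_network(empty, sif, "sif")
  expect_length(readLines(sif), 0)
  expect_error(export_network(net, sif, "dot"), "arg")
})
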