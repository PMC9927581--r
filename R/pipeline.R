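#' Run the full enterotyping analysis
#'
#' Orchestrates the whole chain on one cohort: (simulate or load inputs) ->
#' genus/family aggregation -> Jensen-Shannon distance -> PAM + CH
#' enterotype discovery -> alpha diversity -> Bray-Curtis PCoA + ANOSIM ->
#' phenotype t-tests -> family/genus differential tables -> microbe-trait
#' correlations -> per-enterotype co-occurrence networks -> plain-text
#' report. Every artifact is written in a format the package's own readers
#' re-read, a JSON run manifest is written before any output, and rerunning
#' with the same config and seed reproduces all numeric outputs.
#'
#' @param config A named list, or path to a YAML file with the same
#'   structure. Recognized entries: `simulate` (logical; default TRUE when
#'   no input paths are given), `feature_table`/`taxonomy`/`metadata`
#'   (input TSV paths for a real cohort), `orientation`, and the parameters
#'   `k_range` (default `2:10`), `pseudocount` (1e-6), `n_perm` (999),
#'   `alpha` (0.05), `rho_threshold` (0.2), `min_mean_abundance` (0.001),
#'   `min_prevalence` (0.5), `top_n_families` (15), `min_genus_pct` (1).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed governing simulation and permutation tests.
#' @return Invisibly, a list with the main in-memory results (`fit`,
#'   `alpha`, `anosim`, `diff_genus`, `diff_family`, `phenotypes`,
#'   `correlations`, `networks`, `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  p <- function(name, default) config[[name]] %||% default
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)

  params <- list(
    k_range = p("k_range", 2:10),
    pseudocount = p("pseudocount", 1e-6),
    n_perm = p("n_perm", 999L),
    alpha = p("alpha", 0.05),
    rho_threshold = p("rho_threshold", 0.2),
    min_mean_abundance = p("min_mean_abundance", 0.001),
    min_prevalence = p("min_prevalence", 0.5),
    top_n_families = p("top_n_families", 15L),
    min_genus_pct = p("min_genus_pct", 1),
    seed = seed
  )
  simulate <- p("simulate", is.null(config$feature_table))

  manifest <- c(list(
    tool = "enterotyper",
    version = as.character(utils::packageVersion("enterotyper")),
    simulate = simulate,
    inputs = config[intersect(names(config),
                              c("feature_table", "taxonomy", "metadata"))]
  ), params)
  manifest$k_range <- range(params$k_range)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  if (simulate) {
    cohort <- simulate_cohort(simulation_config(), seed = seed)
    counts <- cohort$counts
    tax <- cohort$taxonomy
    meta <- cohort$metadata
    write_feature_table(counts, path("counts.tsv"))
    write_taxonomy(tax, path("taxonomy.tsv"))
    utils::write.table(meta, path("metadata.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(cohort$truth, path("truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    for (nm in c("feature_table", "taxonomy", "metadata")) {
      if (is.null(config[[nm]])) {
        stop(sprintf("config entry '%s' is required when not simulating", nm),
             call. = FALSE)
      }
      if (!file.exists(config[[nm]])) {
        stop(sprintf("input file not found: %s", config[[nm]]), call. = FALSE)
      }
    }
    counts <- read_feature_table(config$feature_table,
                                 orientation = p("orientation", "features"))
    tax <- read_taxonomy(config$taxonomy)
    meta <- read_metadata(config$metadata)
  }
  extra <- union(setdiff(colnames(counts), meta$sample_id),
                 setdiff(meta$sample_id, colnames(counts)))
  if (length(extra) > 0) {
    stop(sprintf("samples not shared by table and metadata: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }

  rel <- if (table_kind(counts) == "counts") to_relative(counts) else counts
  genus <- aggregate_by_rank(rel, tax, "genus")
  family <- aggregate_by_rank(rel, tax, "family")

  # enterotype discovery on the JSD matrix
  jsd <- jsd_distance(rel, pseudocount = params$pseudocount)
  write_dist_matrix(jsd, path("jsd_distance.tsv"))
  fit <- enterotype(jsd, k_range = params$k_range)
  utils::write.table(tidy(fit), path("enterotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fit$trace, path("ch_trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  drivers <- identify_drivers(rel, fit)
  utils::write.table(drivers, path("drivers.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # diversity
  alpha_tbl <- if (table_kind(counts) == "counts") {
    a <- alpha_diversity(counts)
    utils::write.table(a, path("alpha_diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    a
  } else NULL

  bray <- bray_curtis(rel)
  write_dist_matrix(bray, path("bray_curtis.tsv"))
  ord <- pcoa(bray)
  utils::write.table(tidy(ord), path("pcoa_coordinates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(axis = seq_along(ord$eigenvalues),
               eigenvalue = ord$eigenvalues,
               proportion_explained = c(ord$proportion_explained,
                                        rep(NA, length(ord$eigenvalues) -
                                              length(ord$proportion_explained)))),
    path("pcoa_eigenvalues.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  grp <- stats::setNames(fit$assignment$cluster, fit$assignment$sample_id)
  ano <- anosim_test(bray, grp, n_perm = params$n_perm, seed = seed + 1L)

  # two-group statistics
  pheno <- phenotype_table(meta, fit)
  utils::write.table(pheno, path("phenotype_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  diff_family <- differential_table(
    family, fit, selector = list(top_n = params$top_n_families),
    alpha = params$alpha)
  utils::write.table(diff_family, path("differential_family.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  diff_genus <- differential_table(
    genus, fit, selector = list(min_mean_pct = params$min_genus_pct),
    alpha = params$alpha)
  utils::write.table(diff_genus, path("differential_genus.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # microbe-trait correlations over the differential genera
  diff_ids <- setdiff(diff_genus$feature_id[diff_genus$enriched_in != "ns"],
                      "unassigned")
  corr <- if (length(diff_ids) >= 1) {
    co <- trait_correlations(genus, meta, genera = diff_ids)
    utils::write.table(tibble::as_tibble(co), path("trait_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    co
  } else NULL

  # per-enterotype co-occurrence networks
  networks <- lapply(sort(unique(fit$assignment$cluster)), function(g) {
    net <- build_network(
      genus, samples = fit$assignment$sample_id[fit$assignment$cluster == g],
      min_mean_abundance = params$min_mean_abundance,
      min_prevalence = params$min_prevalence,
      rho_threshold = params$rho_threshold, alpha = params$alpha)
    export_network(net, path(sprintf("network_cluster%d.sif", g)), "sif")
    export_network(net, path(sprintf("network_cluster%d_edges.tsv", g)), "tsv")
    export_network(net, path(sprintf("network_cluster%d.graphml", g)),
                   "graphml")
    net
  })

  report <- c(
    "# Enterotyping pipeline report", "",
    sprintf("Samples: %d; features: %d; genera: %d; families: %d",
            ncol(counts), nrow(counts), nrow(genus), nrow(family)),
    sprintf("Optimal number of enterotypes (max Calinski-Harabasz): %d (CH = %.2f)",
            fit$optimal_k, max(fit$trace$ch)),
    sprintf("Cluster sizes: %s",
            paste(table(fit$assignment$cluster), collapse = " / ")),
    sprintf("Driver taxa: %s",
            paste(sprintf("cluster %d -> %s", drivers$cluster[drivers$driver],
                          drivers$feature_id[drivers$driver]),
                  collapse = "; ")),
    sprintf("ANOSIM on Bray-Curtis: R = %.3f, p = %.4g (%d permutations)",
            ano$statistic, ano$p_value, ano$n_perm),
    sprintf("Differential genera (q < %.2f): %d of %d tested",
            params$alpha, sum(diff_genus$enriched_in != "ns"),
            nrow(diff_genus)),
    sprintf("Differential families (q < %.2f): %d of %d tested",
            params$alpha, sum(diff_family$enriched_in != "ns"),
            nrow(diff_family)),
    sprintf("Co-occurrence networks: %s",
            paste(vapply(seq_along(networks), function(i)
              sprintf("cluster %d: %d nodes / %d edges", i,
                      nrow(networks[[i]]$nodes), nrow(networks[[i]]$edges)),
              character(1)), collapse = "; "))
  )
  writeLines(report, path("report.md"))

  invisible(list(fit = fit, drivers = drivers, alpha = alpha_tbl,
                 anosim = ano, phenotypes = pheno,
                 diff_genus = diff_genus, diff_family = diff_family,
                 correlations = corr, networks = networks,
                 manifest = manifest))
}
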