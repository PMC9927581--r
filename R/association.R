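#' Spearman rank correlation with t-approximation p-value
#'
#' Mid-ranks (average ranks on ties) are taken on both vectors, rho is their
#' Pearson correlation, and the two-sided p-value comes from
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A tibble with columns `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("zero rank variance: Spearman correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  tibble::tibble(rho = rho, p_value = p, n = n)
}

#' Microbe-trait Spearman correlation matrix
#'
#' Correlates each selected genus with each numeric trait over the pooled
#' samples (missing trait values dropped pairwise), flagging significance at
#' 0.05 and 0.01 — the machinery behind genus-by-phenotype association
#' heatmaps.
#'
#' @param genus_table A [feature_table()] of kind `"relative"`.
#' @param meta Metadata tibble with `sample_id` and numeric traits.
#' @param genera Character vector of genus IDs to test (default: all rows).
#' @param traits Character vector of trait columns (default: all numeric).
#' @return An object of class `correlation_matrix`: a tibble with columns
#'   `genus`, `trait`, `rho`, `p_value`, `n`, `sig_05`, `sig_01`.
#' @export
trait_correlations <- function(genus_table, meta, genera = NULL,
                               traits = NULL) {
  stopifnot(inherits(genus_table, "feature_table"))
  genera <- genera %||% rownames(genus_table)
  missing <- setdiff(genera, rownames(genus_table))
  if (length(missing) > 0) {
    stop(sprintf("genus '%s' not in table", missing[1]), call. = FALSE)
  }
  traits <- traits %||%
    names(meta)[vapply(meta, is.numeric, logical(1))]
  idx <- match(colnames(genus_table), meta$sample_id)
  if (anyNA(idx)) stop("metadata missing some table samples", call. = FALSE)
  meta <- meta[idx, ]

  res <- purrr::map_dfr(traits, function(tr) {
    v <- meta[[tr]]
    ok <- !is.na(v)
    if (sum(ok) < 3 || length(unique(v[ok])) < 2) {
      warning(sprintf("trait '%s' skipped (fewer than 3 values or constant)",
                      tr))
      return(NULL)
    }
    purrr::map_dfr(genera, function(g) {
      ab <- unclass(genus_table)[g, ok]
      if (length(unique(ab)) < 2) {
        return(tibble::tibble(genus = g, trait = tr, rho = NA_real_,
                              p_value = NA_real_, n = sum(ok)))
      }
      s <- spearman_cor(ab, v[ok])
      tibble::tibble(genus = g, trait = tr, rho = s$rho,
                     p_value = s$p_value, n = s$n)
    })
  })
  res$sig_05 <- !is.na(res$p_value) & res$p_value < 0.05
  res$sig_01 <- !is.na(res$p_value) & res$p_value < 0.01
  structure(res, class = c("correlation_matrix", class(res)))
}

#' Per-enterotype co-occurrence network
#'
#' Builds a signed, weighted genus-genus graph within a sample subgroup
#' (typically one enterotype). Node filter: mean relative abundance above
#' `min_mean_abundance` AND nonzero in more than `min_prevalence` of the
#' subgroup samples. Edge criterion: pairwise Spearman with
#' `|rho| > rho_threshold` and unadjusted `p < alpha`, both strict. The
#' signed rho is the edge weight.
#'
#' @param genus_table A [feature_table()] of kind `"relative"`.
#' @param samples Sample IDs of the subgroup (default: all samples);
#'   must number at least 4.
#' @param min_mean_abundance Node mean-abundance threshold (proportion;
#'   default 0.001, i.e. 0.1%).
#' @param min_prevalence Node prevalence threshold (fraction of subgroup
#'   samples with nonzero abundance; default 0.5).
#' @param rho_threshold Absolute-correlation edge threshold (default 0.2).
#' @param alpha Edge p-value threshold (default 0.05).
#' @param nodes Optional whitelist of genus IDs applied before the abundance
#'   and prevalence filters (e.g. to restrict to differential genera).
#' @return An object of class `cooccurrence_network`: list with `nodes`
#'   (tibble `genus`, `mean_abundance`, `prevalence`) and `edges` (tibble
#'   `from`, `to`, `rho`, `p_value`, `sign`), plus the filter parameters.
#' @export
build_network <- function(genus_table, samples = NULL,
                          min_mean_abundance = 0.001, min_prevalence = 0.5,
                          rho_threshold = 0.2, alpha = 0.05, nodes = NULL) {
  stopifnot(inherits(genus_table, "feature_table"))
  samples <- samples %||% colnames(genus_table)
  if (length(samples) < 4) stop("subgroup needs at least 4 samples",
                                call. = FALSE)
  m <- unclass(genus_table)[, samples, drop = FALSE]
  if (!is.null(nodes)) m <- m[intersect(rownames(m), nodes), , drop = FALSE]
  mu <- rowMeans(m)
  prev <- rowMeans(m > 0)
  keep <- mu > min_mean_abundance & prev > min_prevalence
  node_tbl <- tibble::tibble(
    genus = rownames(m)[keep],
    mean_abundance = mu[keep],
    prevalence = prev[keep]
  )
  node_tbl <- dplyr::arrange(node_tbl, genus)
  empty_edges <- tibble::tibble(
    from = character(), to = character(), rho = numeric(),
    p_value = numeric(), sign = character())
  if (nrow(node_tbl) < 2) {
    warning("fewer than 2 genera survive the node filters; empty network")
    edges <- empty_edges
  } else {
    g <- node_tbl$genus
    pairs <- utils::combn(g, 2)
    edges <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      if (length(unique(m[a, ])) < 2 || length(unique(m[b, ])) < 2) {
        return(NULL)
      }
      s <- spearman_cor(m[a, ], m[b, ])
      if (abs(s$rho) > rho_threshold && s$p_value < alpha) {
        tibble::tibble(from = a, to = b, rho = s$rho, p_value = s$p_value,
                       sign = if (s$rho > 0) "pos" else "neg")
      } else NULL
    })
    if (nrow(edges) == 0) edges <- empty_edges
  }
  structure(
    list(nodes = node_tbl, edges = edges,
         params = list(min_mean_abundance = min_mean_abundance,
                       min_prevalence = min_prevalence,
                       rho_threshold = rho_threshold, alpha = alpha,
                       n_samples = length(samples))),
    class = "cooccurrence_network"
  )
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("<cooccurrence_network> %d nodes, %d edges (%d pos, %d neg)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "pos"), sum(x$edges$sign == "neg")))
  invisible(x)
}

#' Export a co-occurrence network
#'
#' Writes the graph in SIF (`A pos B` / `A neg B` interaction lines),
#' GraphML (via igraph, with `rho`/`p_value` edge attributes and
#' `mean_abundance`/`prevalence` node attributes), or a plain edge TSV.
#' Nodes and edges are emitted in lexicographic order so exports are
#' deterministic. An empty network still writes its node list (SIF lists
#' isolated nodes on their own lines).
#'
#' @param net A [build_network()] result.
#' @param path Output file path.
#' @param format `"sif"`, `"graphml"`, or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "cooccurrence_network"))
  edges <- dplyr::arrange(net$edges, from, to)
  nodes <- dplyr::arrange(net$nodes, genus)
  if (format == "sif") {
    lines <- if (nrow(edges) > 0) {
      sprintf("%s\t%s\t%s", edges$from, edges$sign, edges$to)
    } else character()
    linked <- unique(c(edges$from, edges$to))
    isolated <- setdiff(nodes$genus, linked)
    writeLines(c(lines, isolated), path)
  } else if (format == "tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("from", "to", "rho", "p_value", "sign")],
      directed = FALSE,
      vertices = as.data.frame(nodes)
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
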