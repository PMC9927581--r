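#' @importFrom rlang %||%
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an enterotype fit into per-sample assignments
#' @param x An [enterotype()] fit.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `cluster`, `is_medoid`.
#' @exportS3Method generics::tidy
tidy.enterotype_fit <- function(x, ...) {
  dplyr::mutate(x$assignment,
                is_medoid = .data$sample_id %in% x$medoid_ids)
}

#' One-row summary of an enterotype fit
#' @param x An [enterotype()] fit.
#' @param ... Unused.
#' @return Tibble with `optimal_k`, `ch_max`, `objective`, `n_samples`.
#' @exportS3Method generics::glance
glance.enterotype_fit <- function(x, ...) {
  tibble::tibble(
    optimal_k = x$optimal_k,
    ch_max = max(x$trace$ch),
    objective = x$objective,
    n_samples = nrow(x$assignment)
  )
}

#' Tidy a PAM clustering
#' @param x A [pam_cluster()] result.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pam_clustering <- function(x, ...) {
  dplyr::mutate(x$assignment,
                is_medoid = .data$sample_id %in% x$medoid_ids)
}

#' Tidy a PCoA into sample coordinates
#' @param x A [pcoa()] result.
#' @param ... Unused.
#' @return Tibble with `sample_id` and one column per retained axis.
#' @exportS3Method generics::tidy
tidy.pcoa_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(x$coordinates)),
    tibble::as_tibble(x$coordinates)
  )
}

#' One-row summary of a PCoA
#' @param x A [pcoa()] result.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.pcoa_result <- function(x, ...) {
  tibble::tibble(
    n_axes = ncol(x$coordinates),
    n_negative_eigenvalues = sum(x$eigenvalues < 0),
    prop_axis1 = x$proportion_explained[1],
    prop_axis2 = if (ncol(x$coordinates) >= 2) x$proportion_explained[2]
                 else NA_real_
  )
}

#' Tidy a co-occurrence network into its edge list
#' @param x A [build_network()] result.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cooccurrence_network <- function(x, ...) x$edges

#' One-row summary of a co-occurrence network
#' @param x A [build_network()] result.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.cooccurrence_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_positive = sum(x$edges$sign == "pos"),
    n_negative = sum(x$edges$sign == "neg")
  )
}
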