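#' Construct a feature abundance table
#'
#' A `feature_table` is the package's central container: a non-negative
#' numeric matrix of features (ASVs, genera, families, pathways...) by
#' samples, tagged as raw `counts` or `relative` abundances. Relative tables
#' must have sample columns summing to 1.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   unique row and column names.
#' @param kind `"counts"` or `"relative"`. If `NULL`, auto-detected:
#'   `"counts"` when every entry is a whole number, `"relative"` otherwise.
#' @return An object of class `feature_table` (a classed matrix with a
#'   `kind` attribute).
#' @examples
#' m <- matrix(c(5, 5, 2, 8), 2, 2,
#'             dimnames = list(c("ASV1", "ASV2"), c("s1", "s2")))
#' feature_table(m)
#' @export
feature_table <- function(values, kind = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature row names and sample column names",
         call. = FALSE)
  }
  if (anyNA(values)) stop("feature table contains missing values", call. = FALSE)
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative abundance at feature '%s', sample '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]),
         call. = FALSE)
  }
  dup_f <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_f) > 0) {
    stop(sprintf("duplicate feature ID: '%s'", dup_f[1]), call. = FALSE)
  }
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s) > 0) {
    stop(sprintf("duplicate sample ID: '%s'", dup_s[1]), call. = FALSE)
  }
  if (is.null(kind)) {
    kind <- if (all(abs(values - round(values)) < 1e-9)) "counts" else "relative"
  }
  kind <- match.arg(kind, c("counts", "relative"))
  if (kind == "relative") {
    cs <- colSums(values)
    bad <- which(abs(cs - 1) > 1e-6)
    if (length(bad) > 0) {
      stop(sprintf("relative table: sample '%s' sums to %.8f, not 1",
                   colnames(values)[bad[1]], cs[bad[1]]), call. = FALSE)
    }
  }
  structure(values, class = c("feature_table", "matrix", "array"), kind = kind)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (%s)\n",
              nrow(x), ncol(x), table_kind(x)))
  k <- min(6L, nrow(x)); j <- min(6L, ncol(x))
  print(unclass(x)[seq_len(k), seq_len(j), drop = FALSE])
  if (nrow(x) > k || ncol(x) > j) cat("...\n")
  invisible(x)
}

#' Kind of a feature table
#' @param table A [feature_table()].
#' @return `"counts"` or `"relative"`.
#' @export
table_kind <- function(table) attr(table, "kind")

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a feature table to long form
#' @param x A [feature_table()].
#' @param ... Unused.
#' @return A tibble with columns `feature_id`, `sample_id`, `abundance`.
#' @exportS3Method tibble::as_tibble
as_tibble.feature_table <- function(x, ...) {
  tibble::tibble(
    feature_id = rep(rownames(x), times = ncol(x)),
    sample_id  = rep(colnames(x), each = nrow(x)),
    abundance  = as.vector(unclass(x))
  )
}

#' Read a feature table from TSV
#'
#' Expects a tab-delimited file with a header row; the first column holds
#' feature IDs (or sample IDs with `orientation = "samples"`, in which case
#' the table is transposed on read so that the canonical features-by-samples
#' orientation always comes back).
#'
#' @param path Path to a TSV file.
#' @param orientation `"features"` (rows are features; default) or
#'   `"samples"` (rows are samples).
#' @param kind Passed to [feature_table()]; `NULL` auto-detects counts.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, orientation = c("features", "samples"),
                               kind = NULL) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  if (length(lines) < 2) stop("feature table file has no data rows", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  ragged <- which(vapply(fields, length, integer(1)) != width)
  if (length(ragged) > 0) {
    stop(sprintf("ragged row in '%s' at line %d (expected %d fields)",
                 path, ragged[1], width), call. = FALSE)
  }
  header <- fields[[1]][-1]
  ids <- vapply(fields[-1], `[[`, character(1), 1)
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(fields[-1], `[`, -1))),
           nrow = length(ids), byrow = TRUE,
           dimnames = list(ids, header))
  )
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    stop(sprintf("non-numeric value at row '%s', column '%s'",
                 rownames(vals)[bad[1, 1]], colnames(vals)[bad[1, 2]]),
         call. = FALSE)
  }
  if (orientation == "samples") vals <- t(vals)
  feature_table(vals, kind = kind)
}

#' Write a feature table to TSV
#' @param table A [feature_table()].
#' @param path Output path.
#' @param id_column Name for the leading ID column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, id_column = "feature_id") {
  df <- data.frame(rownames(table), unclass(table), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides every sample column by its total so that columns sum to 1.
#'
#' @param table A [feature_table()] of kind `"counts"`.
#' @return A [feature_table()] of kind `"relative"`.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table_kind(table) == "relative") return(table)
  cs <- colSums(table)
  if (any(cs == 0)) {
    stop(sprintf("sample '%s' has zero total count",
                 colnames(table)[which(cs == 0)[1]]), call. = FALSE)
  }
  feature_table(sweep(unclass(table), 2, cs, "/"), kind = "relative")
}

#' Read a taxonomy map
#'
#' Two-column TSV (`feature_id`, semicolon-delimited lineage from phylum to
#' genus). Missing trailing ranks are permitted; empty labels become `NA`.
#'
#' @param path Path to the taxonomy TSV.
#' @return A tibble with columns `feature_id`, `phylum`, `class`, `order`,
#'   `family`, `genus`.
#' @export
read_taxonomy <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) < 2) stop("taxonomy file needs feature_id + lineage columns",
                          call. = FALSE)
  if (anyDuplicated(raw[[1]])) {
    stop(sprintf("duplicate feature ID in taxonomy: '%s'",
                 raw[[1]][duplicated(raw[[1]])][1]), call. = FALSE)
  }
  ranks <- c("phylum", "class", "order", "family", "genus")
  parts <- strsplit(raw[[2]], ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p[p == ""] <- NA_character_
    length(p) <- length(ranks)
    p
  }, character(length(ranks))))
  colnames(mat) <- ranks
  out <- tibble::as_tibble(mat)
  out$feature_id <- raw[[1]]
  dplyr::relocate(out, "feature_id")
}

#' Write a taxonomy map
#' @param tax Tibble as returned by [read_taxonomy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  ranks <- c("phylum", "class", "order", "family", "genus")
  lineage <- apply(as.matrix(tax[, ranks]), 1, function(p) {
    p[is.na(p)] <- ""
    paste(p, collapse = ";")
  })
  utils::write.table(
    data.frame(feature_id = tax$feature_id, lineage = lineage),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#' @param path TSV with a `sample_id` column; remaining columns are parsed as
#'   numeric phenotypes where possible, else kept as character.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(raw)) {
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  }
  raw$sample_id <- as.character(raw$sample_id)
  if (anyDuplicated(raw$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  tibble::as_tibble(raw)
}

#' Aggregate a feature table at a taxonomic rank
#'
#' Sums feature rows that share the same label at the requested rank.
#' Features with no label at that rank are pooled into a single
#' `"unassigned"` row, so per-sample totals are conserved exactly.
#'
#' @param table A [feature_table()].
#' @param tax Taxonomy tibble (see [read_taxonomy()]).
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`.
#' @return A [feature_table()] of the same kind with rank labels as features.
#' @export
aggregate_by_rank <- function(table, tax,
                              rank = c("genus", "family", "order", "class",
                                       "phylum")) {
  rank <- match.arg(rank)
  stopifnot(inherits(table, "feature_table"))
  hit <- match(rownames(table), tax$feature_id)
  if (all(is.na(hit))) {
    stop("no feature of the table appears in the taxonomy map", call. = FALSE)
  }
  labels <- tax[[rank]][hit]
  labels[is.na(labels)] <- "unassigned"
  agg <- rowsum(unclass(table), group = labels, reorder = TRUE)
  feature_table(agg, kind = table_kind(table))
}
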