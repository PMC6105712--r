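#' Order a category's genes for heatmap export
#'
#' Agglomerative hierarchical clustering of the log2 fold-change rows
#' (Euclidean distance, average linkage by default; both configurable) with
#' the dendrogram's default left-to-right leaf traversal. \code{hclust} is
#' deterministic for a fixed input ordering; ties therefore break by input
#' index, which is the documented tie-break.
#'
#' @param log2fc Numeric matrix, genes x contrasts, finite values.
#' @param distance "euclidean" or "correlation" (1 - Pearson between rows).
#' @param linkage "average" or "complete".
#' @return A \code{kdtc_clustered}: list with \code{gene_order} (leaf
#'   order), the reordered \code{log2fc}, and the \code{hclust} object
#'   (NULL for a singleton passthrough).
#' @export
cluster_order <- function(log2fc, distance = c("euclidean", "correlation"),
                          linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (!is.matrix(log2fc) || !all(is.finite(log2fc))) {
    kdtc_stop("kdtc_non_finite", "clustering input must be a finite numeric matrix")
  }
  if (nrow(log2fc) < 2L) {
    kdtc_warn("kdtc_singleton", "fewer than 2 genes: passthrough order")
    return(structure(list(gene_order = rownames(log2fc),
                          log2fc = log2fc, hclust = NULL),
                     class = "kdtc_clustered"))
  }
  d <- if (distance == "euclidean") {
    stats::dist(log2fc)
  } else {
    stats::as.dist(1 - stats::cor(t(log2fc)))
  }
  h <- stats::hclust(d, method = linkage)
  ord <- h$order
  structure(list(gene_order = rownames(log2fc)[ord],
                 log2fc = log2fc[ord, , drop = FALSE],
                 hclust = h),
            class = "kdtc_clustered")
}

#' Rank network hubs by degree
#'
#' Degree of every node of an undirected interaction network; self-loops are
#' dropped and parallel edges collapsed before counting. Larger degree means
#' a more connected hub; ranking is stable (ties broken by node identifier).
#'
#' @param edges Two-column data frame or matrix of node pairs.
#' @return Data frame (node, degree, rank) sorted by rank.
#' @export
rank_hubs <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L || ncol(edges) < 2L) {
    kdtc_stop("kdtc_empty_edges", "edge list empty or not two columns")
  }
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  if (!length(a)) kdtc_stop("kdtc_empty_edges", "no edges remain after dropping self-loops")
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  uniq <- !duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[uniq]; hi <- hi[uniq]
  deg <- table(c(lo, hi))
  nodes <- names(deg)
  out <- data.frame(node = nodes, degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node, method = "radix"), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Read an interaction edge list (two-column TSV or SIF)
#'
#' SIF records are \code{source<TAB>relation<TAB>target1 [target2 ...]};
#' plain edge lists are \code{source<TAB>target} with no relation column.
#' Format is chosen by extension (".sif") unless forced.
#'
#' @param path Path to the edge file.
#' @param format "auto", "tsv" or "sif".
#' @return Two-column data frame (from, to).
#' @export
read_edge_list <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) kdtc_stop("kdtc_missing_file", "edge file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) kdtc_stop("kdtc_empty_edges", "edge file is empty")
  if (format == "tsv") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2L)) kdtc_stop("kdtc_malformed_edges", "TSV edge rows need 2 columns")
    return(data.frame(from = vapply(parts, `[`, "", 1L),
                      to = vapply(parts, `[`, "", 2L),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) kdtc_stop("kdtc_malformed_edges", "SIF record needs >= 3 fields")
    data.frame(from = f[1L], to = f[-(1:2)], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a heatmap-ready ordered matrix
#' @param clustered A \code{kdtc_clustered}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_clustered_matrix <- function(clustered, path) {
  df <- data.frame(gene_id = clustered$gene_order,
                   clustered$log2fc,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
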