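#' Hierarchical clustering of miRNA tissue-expression profiles
#'
#' Rows (miRNAs) are z-scored (mean 0, sd 1 per row) and clustered
#' hierarchically; columns (tissues) are clustered on the transposed
#' z-scored matrix with the same distance and linkage. Cutting the row
#' dendrogram at `k_rows` gives the cluster labels. Constant rows (zero
#' variance, undefined z-score) are excluded from the dendrogram and
#' assigned afterwards to the cluster with the nearest centroid; they are
#' reported in `flagged`.
#'
#' @param mat numeric matrix (miRNAs x tissues), >= 2 rows and columns,
#'   finite values.
#' @param k_rows number of row clusters to cut (default 2, the expected
#'   number of tissue-expression programs).
#' @param distance `"correlation"` (1 - Pearson, default) or
#'   `"euclidean"`, both computed on z-scored rows.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return An object of class `pg_cluster`: list with `row_order`,
#'   `col_order` (id permutations), `row_labels` (named cluster
#'   assignment), `linkage_record` (merge pairs and heights for rows and
#'   columns), `flagged` (constant rows), and the hclust objects.
#' @export
cluster_expression <- function(mat, k_rows = 2L,
                               distance = c("correlation", "euclidean"),
                               linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (!is.matrix(mat) || nrow(mat) < 2L || ncol(mat) < 2L)
    stop("need a matrix with >= 2 rows and >= 2 columns")
  if (any(!is.finite(mat))) stop("expression values must be finite")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("row", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("col", seq_len(ncol(mat)))
  if (k_rows < 1L || k_rows > nrow(mat)) stop("k_rows out of range")

  sds <- apply(mat, 1, stats::sd)
  flagged <- rownames(mat)[sds == 0]
  z <- t(scale(t(mat)))
  zc <- z[sds > 0, , drop = FALSE]
  if (nrow(zc) < 2L) stop("fewer than 2 non-constant rows")

  hc_rows <- stats::hclust(row_dist(zc, distance), method = linkage)
  hc_cols <- stats::hclust(row_dist(t(z[sds > 0, , drop = FALSE]), distance),
                           method = linkage)

  k_eff <- min(k_rows, nrow(zc))
  labels <- stats::cutree(hc_rows, k = k_eff)
  if (length(flagged)) {
    cent <- vapply(sort(unique(labels)), function(cl)
      colMeans(zc[labels == cl, , drop = FALSE]), numeric(ncol(zc)))
    for (r in flagged) {
      d <- colSums((cent - 0)^2)  # constant row z-scores treated as all-zero
      labels[r] <- sort(unique(labels))[which.min(d)]
    }
  }
  if (k_rows > nrow(zc)) {
    # more clusters requested than clusterable rows: each row on its own
    labels <- stats::setNames(seq_len(nrow(mat)), rownames(mat))
  }
  structure(list(
    row_order = rownames(zc)[hc_rows$order],
    col_order = colnames(mat)[hc_cols$order],
    row_labels = labels[rownames(mat)[rownames(mat) %in% names(labels)]],
    linkage_record = list(
      rows = data.frame(hc_rows$merge, height = hc_rows$height),
      cols = data.frame(hc_cols$merge, height = hc_cols$height)),
    flagged = flagged,
    hclust_rows = hc_rows, hclust_cols = hc_cols,
    distance = distance, linkage = linkage, k_rows = k_rows),
    class = "pg_cluster")
}

row_dist <- function(m, distance) {
  if (distance == "correlation") stats::as.dist(1 - stats::cor(t(m)))
  else stats::dist(m)
}

#' @export
print.pg_cluster <- function(x, ...) {
  cat("Expression clustering:", length(x$row_labels), "rows into",
      length(unique(x$row_labels)), "clusters (", x$distance, "distance,",
      x$linkage, "linkage )\n")
  invisible(x)
}

#' Write a clustered expression matrix as TSV
#'
#' Emits the matrix reordered by the row/column dendrograms with a
#' `cluster` column — a text heatmap export for external plotting.
#'
#' @param mat the expression matrix passed to [cluster_expression()].
#' @param clust the resulting `pg_cluster`.
#' @param path output TSV path.
#' @export
write_cluster_tsv <- function(mat, clust, path) {
  stopifnot(inherits(clust, "pg_cluster"))
  rows <- c(clust$row_order, clust$flagged)
  out <- data.frame(mirna_id = rows,
                    cluster = unname(clust$row_labels[rows]),
                    mat[rows, clust$col_order, drop = FALSE],
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
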