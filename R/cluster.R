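#' Row-wise z-scoring
#'
#' Standardizes each feature (row) to mean 0 and sample (n-1) standard
#' deviation 1, the transform behind the clustered heat-map display.
#' Constant rows cannot be standardized: they are dropped from the output
#' and their identifiers recorded in `attr(, "constant")`, with a warning.
#'
#' @param m Numeric matrix (features x subjects) or counts-style tibble.
#' @return Matrix of z-scores, possibly with fewer rows.
#' @export
#' @examples
#' zscore_rows(matrix(1:3, 1))  # -1 0 1
zscore_rows <- function(m) {
  m <- counts_to_matrix(m)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  const <- s == 0
  if (any(const)) {
    warn(sprintf("Dropping %d constant row(s) that cannot be z-scored.",
                 sum(const)))
  }
  out <- (m[!const, , drop = FALSE] - mu[!const]) / s[!const]
  attr(out, "constant") <- rownames(m)[const]
  out
}

#' Hierarchical clustering of features (UPGMA on Euclidean distances)
#'
#' Agglomerates feature rows by average linkage on the Euclidean distance
#' matrix, the combination used for the published heat map. Thin wrapper
#' over [stats::hclust()]; the result gains a tidy merge table via
#' [merge_table()] and a Newick serialization via [dendro_newick()].
#'
#' @param m Numeric matrix (features x subjects), typically z-scored rows.
#' @param method Linkage (default `"average"`).
#' @return An `hclust` object (also class `mir_dendro`).
#' @export
#' @examples
#' hc <- cluster_features(matrix(c(0, 1, 5), 3, 2))
#' hc$height  # 1, then mean(5, 4) = 4.5
cluster_features <- function(m, method = "average") {
  m <- counts_to_matrix(m)
  if (nrow(m) < 2) abort("Need at least 2 rows to cluster.")
  if (anyNA(m)) abort("NA/NaN cells are not allowed in clustering input.")
  hc <- hclust(dist(m, method = "euclidean"), method = method)
  class(hc) <- c("mir_dendro", "hclust")
  hc
}

#' @rdname cluster_features
#' @param hc An `hclust` object.
#' @return `merge_table()`: tibble with one row per agglomeration step
#'   (`step`, `left`, `right`, `height`, `size`); negative entries index
#'   leaves, positive entries earlier steps.
#' @export
merge_table <- function(hc) {
  sizes <- integer(nrow(hc$merge))
  node_size <- function(v) if (v < 0) 1L else sizes[v]
  for (i in seq_len(nrow(hc$merge))) {
    sizes[i] <- node_size(hc$merge[i, 1]) + node_size(hc$merge[i, 2])
  }
  tibble::tibble(step = seq_len(nrow(hc$merge)),
                 left = hc$merge[, 1], right = hc$merge[, 2],
                 height = hc$height, size = sizes)
}

#' @rdname cluster_features
#' @return `dendro_newick()`: a single Newick string with branch lengths
#'   derived from merge heights.
#' @export
dendro_newick <- function(hc) {
  labs <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1L))
  node <- function(v, parent_h) {
    if (v < 0) {
      sprintf("%s:%g", labs[-v], parent_h)
    } else {
      h <- hc$height[v]
      sprintf("(%s,%s):%g",
              node(hc$merge[v, 1], h), node(hc$merge[v, 2], h),
              parent_h - h)
    }
  }
  root <- nrow(hc$merge)
  paste0("(", node(hc$merge[root, 1], hc$height[root]), ",",
         node(hc$merge[root, 2], hc$height[root]), ");")
}
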