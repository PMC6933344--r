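#' Cosine distance between sample profiles
#'
#' \eqn{d(u, v) = 1 - \frac{u \cdot v}{\lVert u \rVert \lVert v \rVert}}
#' between sample rows. On nonnegative profiles the range is [0, 1]; on
#' log-ratio profiles (which may be negative) it is [0, 2].
#'
#' @param profiles numeric samples x features matrix with sample row
#'   names.
#' @return symmetric distance matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
cosine_distance <- function(profiles) {
  profiles <- unclass(profiles)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("sample", seq_len(nrow(profiles)))
  norms <- sqrt(rowSums(profiles^2))
  if (any(norms == 0))
    stop("zero-norm sample vector(s): ",
         paste(rownames(profiles)[norms == 0], collapse = ", "))
  sim <- tcrossprod(profiles / norms)
  d <- 1 - sim
  d <- (d + t(d)) / 2
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Ward agglomeration of a distance matrix
#'
#' Hierarchical clustering with the Ward.D2 convention (merges minimize
#' the increase in within-cluster sum of squared distances).
#'
#' @param d symmetric distance matrix (see [cosine_distance()]).
#' @return an object of class \code{hclust}.
#' @export
ward_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2) stop("need at least 2 samples to build a tree")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  stats::hclust(stats::as.dist(d), method = "ward.D2")
}

# mean silhouette width of a flat clustering against a distance matrix;
# returns NA when only one cluster is present
mean_silhouette <- function(clustering, d) {
  if (length(unique(clustering)) < 2) return(NA_real_)
  sil <- cluster::silhouette(clustering, dmatrix = as.matrix(d))
  mean(sil[, "sil_width"])
}

#' Choose the number of clusters by maximal average silhouette width
#'
#' Cuts the tree into k = 2, ..., k_max groups, scores each cut by the
#' mean silhouette width over all samples computed from \code{d}, and
#' returns the k with the maximal mean (ties broken toward smaller k).
#'
#' @param d distance matrix used for the silhouette widths.
#' @param tree an \code{hclust} tree over the same samples.
#' @param k_max largest k considered (>= 2, <= n - 1).
#' @return a list: \code{k} (chosen), and \code{widths} (named numeric of
#'   mean silhouette width per candidate k).
#' @export
find_k <- function(d, tree, k_max = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(k_max)) k_max <- min(20L, n - 1L)
  if (k_max < 2 || k_max > n - 1)
    stop("k_max must lie in [2, n - 1]")
  if (all(d == 0))
    stop("all samples identical: silhouette undefined")
  ks <- 2:k_max
  widths <- vapply(ks, function(k)
    mean_silhouette(stats::cutree(tree, k = k), d), numeric(1))
  names(widths) <- ks
  best <- ks[which.max(widths)]  # which.max takes the first (smallest k) tie
  list(k = best, widths = widths)
}

#' Cut a dendrogram into k clusters
#'
#' The partition induced by removing the k - 1 highest merges. Cluster
#' indices are renumbered by the first-appearing sample so the labelling
#' is deterministic and independent of the tree's internal ordering.
#'
#' @param tree an \code{hclust} tree.
#' @param k number of clusters, 1 <= k <= n.
#' @return a \code{cluster_assignment}: named integer vector sample ->
#'   cluster in 1..k, with attribute \code{k}.
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k out of range [1, n]")
  raw <- stats::cutree(tree, k = k)
  first <- vapply(unique(raw), function(cl) which(raw == cl)[1L], integer(1))
  relabel <- stats::setNames(rank(first), unique(raw))
  out <- as.integer(relabel[as.character(raw)])
  names(out) <- names(raw)
  structure(out, k = as.integer(k), class = "cluster_assignment")
}

#' Export a dendrogram as Newick text
#'
#' Plain-text serialization of the merge history for inspection; branch
#' lengths are the differences in merge heights.
#'
#' @param tree an \code{hclust} tree.
#' @return a single Newick string.
#' @export
tree_newick <- function(tree) {
  build <- function(i, parent_h) {
    if (i < 0) {
      lab <- tree$labels[-i]
      sprintf("%s:%.6g", lab, parent_h)
    } else {
      h <- tree$height[i]
      sprintf("(%s,%s):%.6g",
              build(tree$merge[i, 1], h), build(tree$merge[i, 2], h),
              parent_h - h)
    }
  }
  m <- nrow(tree$merge)
  paste0("(", build(tree$merge[m, 1], tree$height[m]), ",",
         build(tree$merge[m, 2], tree$height[m]), ");")
}
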