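#' Assign pixels to their nearest centroid
#'
#' Labels every feature row with the index of the closest centroid under
#' Euclidean distance. Ties are broken toward the lowest cluster index.
#'
#' @param features a [extract_features()] result or an N x d matrix.
#' @param centroids K x d matrix of cluster centroids.
#' @return Integer vector of labels in 1..K.
#' @export
assign_pixels <- function(features, centroids) {
  Z <- as_feature_matrix(features)
  centroids <- as.matrix(centroids)
  if (ncol(Z) != ncol(centroids))
    stop("feature and centroid dimensions differ", call. = FALSE)
  nearest_centroid(Z, centroids)$labels
}

# Shared kernel: squared distances, strict-< updates so ties keep the lowest
# cluster index. Returns labels and the squared distance to the assigned
# centroid.
nearest_centroid <- function(Z, centroids) {
  tZ <- t(Z)
  k <- nrow(centroids)
  d2min <- colSums((tZ - centroids[1, ])^2)
  labels <- rep.int(1L, nrow(Z))
  if (k > 1) {
    for (j in 2:k) {
      d2 <- colSums((tZ - centroids[j, ])^2)
      upd <- d2 < d2min
      d2min[upd] <- d2[upd]
      labels[upd] <- j
    }
  }
  list(labels = labels, d2 = d2min)
}

#' Recompute centroids as cluster means
#'
#' Row i of the result is the arithmetic mean of the feature rows labelled i.
#' A cluster with no members keeps its previous centroid, which must then be
#' supplied via `previous`.
#'
#' @param features feature set or N x d matrix.
#' @param labels integer labels in 1..k.
#' @param k number of clusters.
#' @param previous optional K x d matrix of current centroids, required when
#'   some cluster is empty.
#' @return K x d matrix of updated centroids.
#' @export
update_centroids <- function(features, labels, k, previous = NULL) {
  Z <- as_feature_matrix(features)
  if (any(labels < 1 | labels > k))
    stop("labels must lie in 1..k", call. = FALSE)
  agg <- rowsum(Z, labels)  # drops empty clusters; re-indexed below
  sums <- matrix(0, k, ncol(Z))
  sums[as.integer(rownames(agg)), ] <- agg
  counts <- tabulate(labels, nbins = k)
  out <- sums / pmax(counts, 1)
  if (any(counts == 0)) {
    if (is.null(previous))
      stop("empty cluster but no previous centroids supplied", call. = FALSE)
    out[counts == 0, ] <- previous[counts == 0, , drop = FALSE]
  }
  unname(out)
}

#' K-means clustering with a fixed iteration budget
#'
#' Lloyd's algorithm: seeded random centroid initialisation uniform within
#' the per-dimension bounding box of the features, then alternating
#' nearest-centroid assignment and mean update for at most `t_max`
#' iterations, stopping early when the labelling no longer changes.
#'
#' @param features feature set or N x d matrix.
#' @param k number of clusters (>= 2, <= N).
#' @param t_max maximum number of Lloyd iterations (>= 1).
#' @param seed optional integer seed for the initialisation.
#' @return Object of class `kmeans_fit`: list with `centroids`, `labels`,
#'   `sizes`, `k`, `iterations` (iterations actually run), `converged`
#'   (labels stabilised before the budget) and `sse`.
#' @export
lloyd_kmeans <- function(features, k, t_max = 100, seed = NULL) {
  Z <- as_feature_matrix(features)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > nrow(Z)) stop("k exceeds the number of pixels", call. = FALSE)
  if (t_max < 1) stop("t_max must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lo <- apply(Z, 2, min)
  hi <- apply(Z, 2, max)
  centroids <- sapply(seq_along(lo), function(j) stats::runif(k, lo[j], hi[j]))
  centroids <- matrix(centroids, nrow = k)
  labels <- integer(nrow(Z))
  converged <- FALSE
  iter <- 0L
  for (t in seq_len(t_max)) {
    iter <- t
    new_labels <- nearest_centroid(Z, centroids)$labels
    centroids <- update_centroids(Z, new_labels, k, previous = centroids)
    if (identical(new_labels, labels)) {
      labels <- new_labels
      converged <- TRUE
      break
    }
    labels <- new_labels
  }
  sizes <- tabulate(labels, nbins = k)
  fit <- structure(list(centroids = centroids, labels = labels, sizes = sizes,
                        k = k, iterations = iter, converged = converged),
                   class = "kmeans_fit")
  fit$sse <- cluster_sse(Z, fit)
  fit
}

#' Within-cluster sum of squared errors
#'
#' Sum over pixels of the squared Euclidean distance to the assigned
#' centroid.
#'
#' @param features feature set or N x d matrix.
#' @param model a `kmeans_fit`, or any list with `centroids` and `labels`.
#' @return Scalar SSE.
#' @export
cluster_sse <- function(features, model) {
  Z <- as_feature_matrix(features)
  diffs <- Z - model$centroids[model$labels, , drop = FALSE]
  sum(diffs^2)
}

#' @export
print.kmeans_fit <- function(x, ...) {
  cat(sprintf("k-means fit: k = %d, N = %d, %d iteration(s)%s, SSE = %.4g\n",
              x$k, length(x$labels), x$iterations,
              if (x$converged) " (converged)" else "", x$sse))
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}
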