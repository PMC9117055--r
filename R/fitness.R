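#' Decode a candidate position into a centroid matrix
#'
#' A candidate solution for K clusters in d dimensions is a length K*d
#' vector: the K centroids concatenated in order. Row k of the result is the
#' k-th centroid.
#'
#' @param position numeric vector of length `k * d`.
#' @param k number of clusters.
#' @param d feature dimension.
#' @return K x d matrix.
#' @export
decode_centroids <- function(position, k, d) {
  if (length(position) != k * d)
    stop("position length must equal k * d", call. = FALSE)
  matrix(position, nrow = k, ncol = d, byrow = TRUE)
}

#' Worst-case average intracluster distance
#'
#' Each pixel is assigned to its nearest decoded centroid; the value returned
#' is the largest, over clusters, of the mean Euclidean distance between a
#' cluster's pixels and its centroid. This is the compactness term of the
#' clustering objective: small values mean every cluster is tight around its
#' centroid. A cluster that attracts no pixels contributes 0 to the maximum,
#' keeping the function defined everywhere a search algorithm roams (but see
#' [segment_tumor()] for why the optimiser must not be allowed to exploit
#' empty clusters).
#'
#' @param position candidate centroid vector (length `k * d`).
#' @param features feature set or N x d matrix.
#' @param k number of clusters.
#' @return Scalar >= 0.
#' @export
max_intracluster_distance <- function(position, features, k) {
  Z <- as_feature_matrix(features)
  centroids <- decode_centroids(position, k, ncol(Z))
  nc <- nearest_centroid(Z, centroids)
  per_cluster_mean_distance(nc, k, default = 0)$dmax
}

# mean distance to assigned centroid per cluster; empty clusters get
# `default`. Shared by the objective and its cached-evaluation path.
# (rowsum drops empty groups, so sums are re-indexed by group name.)
per_cluster_mean_distance <- function(nc, k, default) {
  agg <- rowsum(sqrt(nc$d2), nc$labels)
  sums <- numeric(k)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  counts <- tabulate(nc$labels, nbins = k)
  means <- ifelse(counts > 0, sums / pmax(counts, 1), default)
  list(dmax = max(means), counts = counts)
}

#' Minimum intercluster separation
#'
#' The smallest Euclidean distance over all unordered pairs of decoded
#' centroids. Large values mean well-separated clusters; the clustering
#' objective rewards separation through the term `z_max - separation`.
#'
#' @param position candidate centroid vector.
#' @param k number of clusters (>= 2).
#' @param d feature dimension.
#' @return Scalar >= 0.
#' @export
min_intercluster_distance <- function(position, k, d) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  centroids <- decode_centroids(position, k, d)
  min(stats::dist(centroids))
}

#' Clustering objective for centroid search
#'
#' The scalarised objective minimised by the ABC search:
#' \deqn{f = y_1 \bar{d}_{max} + y_2 (Z_{max} - d_{min})}
#' where \eqn{\bar{d}_{max}} is [max_intracluster_distance()],
#' \eqn{d_{min}} is [min_intercluster_distance()] and \eqn{Z_{max}} is the
#' maximum feature value of the image. The first term drives compact
#' clusters, the second drives centroids apart (it can go negative once the
#' separation exceeds \eqn{Z_{max}}). With `objective = "single"` only the
#' compactness term is used (weights 1, 0).
#'
#' @param position candidate centroid vector.
#' @param features feature set (needed for `z_max`; a plain matrix also
#'   works, with `z_max` taken as its maximum entry).
#' @param k number of clusters.
#' @param objective `"multi"` (both terms) or `"single"` (compactness only).
#' @param weights nonnegative weights `c(y1, y2)`, not both zero; used when
#'   `objective = "multi"`.
#' @return Scalar objective value, to be minimised.
#' @export
#' @examples
#' feats <- extract_features(matrix(c(0, 2), 1))
#' clustering_objective(c(1, 100), feats, k = 2)  # 0.5*1 + 0.5*(2 - 99)
clustering_objective <- function(position, features, k,
                                 objective = c("multi", "single"),
                                 weights = c(0.5, 0.5)) {
  objective <- match.arg(objective)
  if (objective == "single") weights <- c(1, 0)
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be nonnegative and not both zero", call. = FALSE)
  Z <- as_feature_matrix(features)
  z_max <- if (inherits(features, "pixel_features")) features$z_max else max(Z)
  val <- weights[1] * max_intracluster_distance(position, Z, k)
  if (weights[2] > 0)
    val <- val + weights[2] *
      (z_max - min_intercluster_distance(position, k, ncol(Z)))
  val
}

#' Search objective used by the segmentation pipeline
#'
#' [clustering_objective()] with two safeguards that make minimisation well
#' posed when the features live in a d-dimensional bounded box rather than
#' on the 1-D gray-level axis the objective was conceived for:
#'
#' * the separation reward is clamped at zero,
#'   `y2 * max(0, z_max - separation)`. On 1-D gray levels the separation
#'   between centroids in \[0, 255\] can never exceed `z_max = 255`, so the
#'   clamp changes nothing there; in an RGB box the centroid separation can
#'   reach `255 * sqrt(3) ~ 441 > z_max`, and without the clamp the reward
#'   for pushing centroids into opposite corners grows without limit and
#'   dominates the compactness term for any weights `y1 = y2`.
#' * candidate centroid sets under which some cluster attracts no pixels
#'   are infeasible and score a finite penalty strictly above every
#'   feasible value (an empty cluster would otherwise contribute nothing to
#'   compactness while still collecting the separation reward).
#'
#' @param position candidate centroid vector (length `k * d`).
#' @param features a [extract_features()] result.
#' @param k number of clusters.
#' @param objective `"multi"` or `"single"` (compactness only).
#' @param weights nonnegative weights `c(y1, y2)` for `"multi"`.
#' @return Scalar objective value, to be minimised.
#' @export
segmentation_objective <- function(position, features, k,
                                   objective = c("multi", "single"),
                                   weights = c(0.5, 0.5)) {
  objective <- match.arg(objective)
  if (objective == "single") weights <- c(1, 0)
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be nonnegative and not both zero", call. = FALSE)
  Z <- as_feature_matrix(features)
  z_max <- if (inherits(features, "pixel_features")) features$z_max else max(Z)
  segmentation_objective_core(decode_centroids(position, k, ncol(Z)),
                              t(Z), z_max, weights)
}

# shared by segmentation_objective and the pipeline's hot loop
segmentation_objective_core <- function(centroids, tZ, z_max, w) {
  k <- nrow(centroids)
  nc <- nearest_centroid_t(tZ, centroids)
  pc <- per_cluster_mean_distance(nc, k, default = 0)
  if (any(pc$counts == 0)) {
    diag_len <- sqrt(nrow(tZ)) * 255
    return(w[1] * diag_len + w[2] * z_max + 1)
  }
  val <- w[1] * pc$dmax
  if (w[2] > 0)
    val <- val + w[2] * max(0, z_max - min(stats::dist(centroids)))
  val
}
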