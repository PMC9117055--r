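# Independent brute-force oracles used across the suite. These deliberately
# use plain double loops / naive accumulation so they share no code path with
# the package implementations they check.

# nearest-centroid labels by exhaustive pairwise distance scan
oracle_assign <- function(Z, centroids) {
  labels <- integer(nrow(Z))
  for (i in seq_len(nrow(Z))) {
    best <- Inf
    for (k in seq_len(nrow(centroids))) {
      d <- sqrt(sum((Z[i, ] - centroids[k, ])^2))
      if (d < best) {  # strict: ties keep the earlier (lower) index
        best <- d
        labels[i] <- k
      }
    }
  }
  labels
}

# cluster means by independent accumulation loop
oracle_centroids <- function(Z, labels, k) {
  out <- matrix(NA_real_, k, ncol(Z))
  for (j in seq_len(k)) {
    rows <- which(labels == j)
    if (length(rows) > 0)
      out[j, ] <- colSums(Z[rows, , drop = FALSE]) / length(rows)
  }
  out
}

# worst-case average intracluster distance, naive per-cluster loop
oracle_dmax <- function(position, Z, k) {
  centroids <- matrix(position, nrow = k, byrow = TRUE)
  labels <- oracle_assign(Z, centroids)
  worst <- 0
  for (j in seq_len(k)) {
    rows <- which(labels == j)
    if (length(rows) == 0) next
    tot <- 0
    for (i in rows) tot <- tot + sqrt(sum((Z[i, ] - centroids[j, ])^2))
    worst <- max(worst, tot / length(rows))
  }
  worst
}

# minimum pairwise centroid distance over all unordered pairs
oracle_dmin <- function(position, k, d) {
  centroids <- matrix(position, nrow = k, byrow = TRUE)
  best <- Inf
  for (a in seq_len(k - 1))
    for (b in (a + 1):k)
      best <- min(best, sqrt(sum((centroids[a, ] - centroids[b, ])^2)))
  best
}

# SSE by exhaustive double loop
oracle_sse <- function(Z, centroids, labels) {
  tot <- 0
  for (i in seq_len(nrow(Z)))
    tot <- tot + sum((Z[i, ] - centroids[labels[i], ])^2)
  tot
}

# confusion counts by per-pixel tally loop
oracle_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] && truth[i]) tp <- tp + 1L
    else if (!pred[i] && !truth[i]) tn <- tn + 1L
    else if (pred[i]) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# point-in-ellipse test over every pixel, scalar loop
oracle_ellipse_count <- function(h, w, center, axes) {
  n <- 0L
  for (r in seq_len(h))
    for (c in seq_len(w))
      if (((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2 <= 1)
        n <- n + 1L
  n
}

# small random feature matrix for parameterised oracle checks
random_features <- function(n, d, lo = 0, hi = 255) {
  matrix(runif(n * d, lo, hi), n, d)
}
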