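test_that("centroid decoding reshapes position vectors row-wise", {
  C <- decode_centroids(c(1, 2, 3, 4, 5, 6), k = 2, d = 3)
  expect_equal(C, rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_error(decode_centroids(1:5, 2, 3), "k \\* d")
})

test_that("worst-case intracluster distance matches hand and oracle values", {
  # all pixels at their centroids
  Z <- rbind(c(0, 0), c(10, 10))
  expect_equal(max_intracluster_distance(c(0, 0, 10, 10), Z, 2), 0)
  # 1-D pixels {0,2}, centroids {1,100}: both join cluster 1, mean distance 1
  expect_equal(max_intracluster_distance(c(1, 100), matrix(c(0, 2)), 2), 1)
  set.seed(71)
  for (rep in 1:30) {
    k <- sample(2:4, 1); d <- sample(1:3, 1)
    Z <- random_features(25, d)
    pos <- runif(k * d, 0, 255)
    expect_equal(max_intracluster_distance(pos, Z, k), oracle_dmax(pos, Z, k))
  }
})

test_that("intercluster separation is the minimum over all centroid pairs", {
  expect_equal(min_intercluster_distance(c(5, 5), 2, 1), 0)  # coincident
  expect_equal(min_intercluster_distance(c(0, 0, 3, 4), 2, 2), 5)
  set.seed(81)
  for (rep in 1:30) {
    pos <- runif(8, 0, 255)  # 4 centroids in 2-D: 6 pairs
    expect_equal(min_intercluster_distance(pos, 4, 2), oracle_dmin(pos, 4, 2))
  }
  expect_error(min_intercluster_distance(c(1, 2), 1, 2), "k must be")
})

test_that("clustering objective combines the two terms as specified", {
  Z <- matrix(c(0, 2))
  feats <- structure(list(features = Z, z_max = 2, origin_shape = c(1, 2),
                          d = 1), class = "pixel_features")
  pos <- c(1, 100)
  # y2 = 0 reduces to the compactness term alone
  expect_equal(clustering_objective(pos, feats, 2, weights = c(1, 0)), 1)
  expect_equal(clustering_objective(pos, feats, 2, objective = "single"), 1)
  # y1 = 0, coincident centroids: y2 * z_max
  expect_equal(clustering_objective(c(5, 5), feats, 2, weights = c(0, 1)), 2)
  # hand evaluation: 0.5*1 + 0.5*(2 - 99); second term goes negative
  expect_equal(clustering_objective(pos, feats, 2, weights = c(0.5, 0.5)),
               0.5 * 1 + 0.5 * (2 - 99))
  expect_error(clustering_objective(pos, feats, 2, weights = c(0, 0)),
               "weights")
})

test_that("clustering objective is linear in the weights", {
  set.seed(91)
  Z <- random_features(30, 3)
  feats <- structure(list(features = Z, z_max = max(Z),
                          origin_shape = c(5, 6), d = 3),
                     class = "pixel_features")
  pos <- runif(6, 0, 255)
  f10 <- clustering_objective(pos, feats, 2, weights = c(1, 0))
  f01 <- clustering_objective(pos, feats, 2, weights = c(0, 1))
  for (w in list(c(0.3, 0.7), c(2, 1), c(0.5, 0.5)))
    expect_equal(clustering_objective(pos, feats, 2, weights = w),
                 w[1] * f10 + w[2] * f01)
})

test_that("separation term behaves monotonically on constructed instances", {
  # moving one centroid toward the other strictly decreases separation
  seps <- sapply(c(100, 60, 30, 10), function(g)
    min_intercluster_distance(c(0, g), 2, 1))
  expect_true(all(diff(seps) < 0))
  # for fixed intracluster structure, more separation lowers the objective:
  # two tight 1-D blobs; slide the second blob and its centroid outward
  base <- c(0, 1, 2)
  for (i in 1:3) {
    gap_small <- c(base, base + 50)
    gap_large <- c(base, base + 150)
    f <- function(pix, cent) {
      feats <- structure(list(features = matrix(pix), z_max = 255,
                              origin_shape = c(1, length(pix)), d = 1),
                         class = "pixel_features")
      clustering_objective(cent, feats, 2, weights = c(0.5, 0.5))
    }
    expect_lt(f(gap_large, c(1, 151)), f(gap_small, c(1, 51)))
  }
})

test_that("pipeline search objective clamps separation and rejects empty clusters", {
  Z <- matrix(c(0, 2))
  feats <- structure(list(features = Z, z_max = 2, origin_shape = c(1, 2),
                          d = 1), class = "pixel_features")
  # both pixels join cluster 1 -> cluster 2 empty -> finite penalty above
  # any feasible value
  pen <- segmentation_objective(c(1, 100), feats, 2)
  expect_true(is.finite(pen))
  expect_gt(pen, 0.5 * 255 + 0.5 * 2)
  # feasible position: centroids at the pixels; separation 2 >= z_max = 2
  # so the clamped term is exactly 0
  expect_equal(segmentation_objective(c(0, 2), feats, 2), 0)
  # clamp inactive when separation < z_max: agrees with the textbook form
  Zb <- matrix(c(0, 200))
  fb <- structure(list(features = Zb, z_max = 200, origin_shape = c(1, 2),
                       d = 1), class = "pixel_features")
  expect_equal(segmentation_objective(c(0, 200), fb, 2),
               clustering_objective(c(0, 200), fb, 2))
})
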