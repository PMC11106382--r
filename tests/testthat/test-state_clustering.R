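test_that("manhattan distance is the L1 metric", {
  expect_equal(manhattan_distance(c(0, 0), c(3, 4)), 7)
  expect_equal(manhattan_distance(1:5, 1:5), 0)
  expect_error(manhattan_distance(1:3, 1:4), "length")
  set.seed(1)
  for (i in 1:1000) {
    u <- rnorm(4); v <- rnorm(4); w <- rnorm(4)
    expect_lte(manhattan_distance(u, w),
               manhattan_distance(u, v) + manhattan_distance(v, w) + 1e-12)
  }
})

test_that("k = 1 clustering returns the global mean", {
  set.seed(2)
  p <- matrix(rnorm(50 * 4), 50, 4)
  m <- kmeans_l1(p, 1, seed = 1, n_restarts = 2)
  expect_equal(as.numeric(m$centroids), colMeans(p), tolerance = 1e-12)
  expect_true(all(m$assignments == 1))
})

test_that("well-separated blobs are recovered exactly", {
  set.seed(3)
  p <- rbind(matrix(rnorm(60 * 3, 0, 1), 60, 3),
             matrix(rnorm(60 * 3, 10, 1), 60, 3))
  truth <- rep(1:2, each = 60)
  m <- kmeans_l1(p, 2, seed = 5, n_restarts = 10)
  expect_equal(adjusted_rand_index(m$assignments, truth), 1)
})

test_that("duplicating every point leaves centroids unchanged", {
  set.seed(4)
  p <- rbind(matrix(rnorm(40 * 3), 40, 3),
             matrix(rnorm(40 * 3, 6), 40, 3))
  m1 <- kmeans_l1(p, 2, seed = 7, n_restarts = 10)
  m2 <- kmeans_l1(rbind(p, p), 2, seed = 7, n_restarts = 10)
  o1 <- m1$centroids[order(m1$centroids[, 1]), ]
  o2 <- m2$centroids[order(m2$centroids[, 1]), ]
  expect_equal(o1, o2, tolerance = 1e-8)
})

test_that("clustering is deterministic given the seed", {
  set.seed(5)
  p <- matrix(rnorm(100 * 5), 100, 5)
  m1 <- kmeans_l1(p, 3, seed = 9, n_restarts = 5)
  m2 <- kmeans_l1(p, 3, seed = 9, n_restarts = 5)
  expect_identical(m1$assignments, m2$assignments)
  expect_identical(m1$centroids, m2$centroids)
})

test_that("the squared-error objective decreases over iterations", {
  set.seed(6)
  for (i in 1:5) {
    p <- rbind(matrix(rnorm(50 * 4), 50, 4),
               matrix(rnorm(50 * 4, 3), 50, 4))
    m <- kmeans_l1(p, 2, seed = i, n_restarts = 1)
    expect_true(all(diff(m$objective_trace) <= 1e-8))
  }
})

test_that("median update gives the k-medians alternative", {
  set.seed(7)
  p <- rbind(matrix(rnorm(30 * 2), 30, 2),
             matrix(rnorm(30 * 2, 8), 30, 2))
  m <- kmeans_l1(p, 2, seed = 3, n_restarts = 5, update = "median")
  expect_equal(adjusted_rand_index(m$assignments, rep(1:2, each = 30)), 1)
})

test_that("silhouette-based selection finds planted blob counts", {
  set.seed(8)
  blobs <- rbind(matrix(rnorm(40 * 3, 0, 0.5), 40, 3),
                 matrix(rnorm(40 * 3, 8, 0.5), 40, 3),
                 matrix(rnorm(40 * 3, -8, 0.5), 40, 3))
  sel <- select_k(blobs, 2:6, seed = 2, n_restarts = 10)
  expect_equal(sel$k_best, 3)
  expect_gt(max(sel$curves$silhouette), 0.9)
  expect_equal(sel$curves$k, 2:6)
  expect_error(select_k(matrix(1, 30, 2), 2:3, seed = 1), "identical")
  expect_error(select_k(blobs, 1:3, seed = 1), "k_range")
})

test_that("state labels permuting leaves occupancy multiset unchanged", {
  set.seed(9)
  p <- rbind(matrix(rnorm(30 * 2), 30, 2),
             matrix(rnorm(60 * 2, 9), 60, 2))
  m <- kmeans_l1(p, 2, seed = 4, n_restarts = 5)
  wi <- tibble::tibble(subject_id = rep(c("a", "b"), 45),
                       window = rep(1:45, each = 2))
  occ <- state_occupancy(m, wi)
  expect_setequal(round(occ$fraction[occ$scope == "overall"], 6),
                  round(c(30, 60) / 90, 6))
})

test_that("occupancy fractions follow the window counts", {
  m <- structure(list(k = 2, assignments = c(rep(1L, 3), rep(2L, 8))),
                 class = "state_model")
  wi <- tibble::tibble(subject_id = rep("s1", 11), window = 1:11)
  occ <- state_occupancy(m, wi)
  ov <- occ[occ$scope == "overall", ]
  expect_equal(ov$n_windows, c(3L, 8L))
  expect_equal(sprintf("%.2f%%", 100 * ov$fraction[1]), "27.27%")
  expect_equal(sum(ov$fraction), 1, tolerance = 1e-12)

  # per-group fractions also sum to one
  man <- tibble::tibble(subject_id = "s1", group = "patient",
                        age = 20, sex = "F")
  occ2 <- state_occupancy(m, wi, man)
  expect_equal(sum(occ2$fraction[occ2$scope == "patient"]), 1,
               tolerance = 1e-12)
})

test_that("centroid matrices invert the vectorization", {
  set.seed(10)
  mats <- lapply(1:6, function(i) {
    m <- matrix(rnorm(16), 4, 4); diag(m) <- 0; m
  })
  pts <- t(vapply(mats, braindec:::vectorize_ec, numeric(12)))
  m <- kmeans_l1(pts, 1, seed = 1, n_restarts = 1)
  cent <- state_centroid_matrices(m, 4)[[1]]
  expect_equal(cent, Reduce(`+`, mats) / 6, tolerance = 1e-10)
  expect_equal(diag(cent), rep(0, 4))
  # centroid of identical matrices is that matrix
  pts2 <- pts[c(1, 1, 1), ]
  m2 <- kmeans_l1(pts2, 1, seed = 1, n_restarts = 1)
  expect_equal(state_centroid_matrices(m2, 4)[[1]], mats[[1]],
               tolerance = 1e-10)
  expect_error(state_centroid_matrices(m, 5), "n_rois")
})

test_that("silhouette agrees with the cluster-package oracle", {
  skip_if_not_installed("cluster")
  set.seed(11)
  p <- rbind(matrix(rnorm(25 * 3), 25, 3), matrix(rnorm(25 * 3, 4), 25, 3))
  a <- rep(1:2, each = 25)
  ours <- braindec:::silhouette_l1(p, a, max_points = 50)
  ref <- mean(cluster::silhouette(a, stats::dist(p, method = "manhattan"))[, 3])
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("pooled window bookkeeping aligns subjects and windows", {
  co <- small_cohort()
  dec <- lapply(co$subjects[1:3], function(s) dec_series(s, c(2, 7, 12)))
  pooled <- pool_ec_windows(dec)
  expect_equal(nrow(pooled$points), 3 * 79)
  expect_equal(ncol(pooled$points), 6)
  expect_equal(unique(pooled$window_info$subject_id),
               co$manifest$subject_id[1:3])
})
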