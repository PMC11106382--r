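triangle <- adjacency_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3)))
star4 <- adjacency_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4)))
path3 <- adjacency_from_edges(3, list(c(1, 2), c(2, 3)))
k5 <- matrix(1L, 5, 5) - diag(1L, 5)

test_that("clustering coefficient matches triangle enumeration", {
  expect_equal(clustering_coefficient(triangle)$mean, 1)
  expect_equal(clustering_coefficient(star4)$node, rep(0, 4))
  # 4-cycle with chord 1-3: the chord closes two triangles (1,2,3) and
  # (1,3,4), so nodes 1 and 3 (k = 3) score 2/3 and nodes 2 and 4 (k = 2)
  # score 1; cross-checked against the brute-force enumerator
  chord <- adjacency_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4),
                                        c(4, 1), c(1, 3)))
  cc <- clustering_coefficient(chord)
  expect_equal(cc$node, c(2 / 3, 1, 2 / 3, 1))
  expect_equal(cc$mean, 5 / 6)
  expect_equal(cc$node, bf_clustering(chord)$node)
})

test_that("path length uses finite pairs only", {
  expect_equal(as.numeric(characteristic_path_length(k5)), 1)
  expect_equal(as.numeric(characteristic_path_length(path3)), 4 / 3)
  two_edges <- adjacency_from_edges(4, list(c(1, 2), c(3, 4)))
  lp <- characteristic_path_length(two_edges)
  expect_equal(as.numeric(lp), 1)
  expect_gt(attr(lp, "frac_infinite"), 0)
  expect_error(characteristic_path_length(matrix(0L, 3, 3)), "disconnected")
})

test_that("efficiencies follow the inverse-distance convention", {
  expect_equal(global_efficiency(k5), 1)
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_equal(local_efficiency(star4), 0)
  expect_equal(local_efficiency(triangle), 1)
})

test_that("nodal metrics match hand-derived values", {
  nm <- nodal_metrics(path3)
  expect_equal(nm$betweenness, c(0, 1, 0))
  expect_equal(nm$degree, c(1, 2, 1))
  hub <- nodal_metrics(star4)
  expect_equal(hub$betweenness[1], 3)
  full <- nodal_metrics(k5)
  expect_equal(full$efficiency, rep(1, 5))
  expect_equal(full$betweenness, rep(0, 5))
})

test_that("metrics agree with brute-force enumeration on random graphs", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    adj <- random_adjacency(n, runif(1, 0.25, 0.7))
    if (sum(adj) == 0) next
    cc <- clustering_coefficient(adj)
    bf <- bf_clustering(adj)
    expect_equal(cc$node, bf$node, tolerance = 1e-9)
    nm <- nodal_metrics(adj)
    expect_equal(nm$betweenness, bf_betweenness(adj), tolerance = 1e-9)
    expect_equal(nm$efficiency, bf_nodal_efficiency(adj), tolerance = 1e-9)
    expect_equal(global_efficiency(adj), bf_eglob(adj), tolerance = 1e-9)
    expect_equal(local_efficiency(adj), bf_eloc(adj), tolerance = 1e-9)
    if (any(is.finite(bf_distances(adj)[upper.tri(adj)]))) {
      expect_equal(as.numeric(characteristic_path_length(adj)), bf_lp(adj),
                   tolerance = 1e-9)
    }
  }
})

test_that("null networks preserve every degree exactly and are seeded", {
  set.seed(5)
  adj <- random_adjacency(15, 0.3)
  nulls <- random_null_networks(adj, n_null = 8, seed = 2)
  for (m in nulls) {
    expect_equal(rowSums(m), rowSums(adj))
    expect_true(all(diag(m) == 0))
  }
  nulls2 <- random_null_networks(adj, n_null = 8, seed = 2)
  expect_identical(nulls, nulls2)
  # the triangle admits no rewiring: nulls equal the input
  expect_equal(random_null_networks(triangle, 3, seed = 1)[[1]],
               unclass(triangle), ignore_attr = TRUE)
})

test_that("small-world normalization is self-consistent", {
  set.seed(6)
  adj <- random_adjacency(20, 0.3)
  sw <- small_world_normalize(adj, list(adj))
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
  # sigma == gamma / lambda on arbitrary records
  nulls <- random_null_networks(adj, 10, seed = 3)
  sw2 <- small_world_normalize(adj, nulls)
  expect_identical(sw2$sigma, sw2$gamma / sw2$lambda)
  expect_error(small_world_normalize(adj, list()), "empty")
})

test_that("a random graph self-normalizes to gamma near 1", {
  set.seed(77)
  z <- matrix(rnorm(90 * 90), 90, 90)
  z <- (z + t(z)) / 2
  net <- threshold_by_sparsity(z, 0.2)
  nulls <- random_null_networks(net, 20, seed = 4)
  sw <- small_world_normalize(net, nulls)
  expect_gt(sw$gamma, 0.9)
  expect_lt(sw$gamma, 1.1)
})

test_that("AUC is the trapezoidal integral with linearity", {
  grid <- seq(0.10, 0.34, by = 0.01)
  expect_equal(auc_over_grid(rep(2, length(grid)), grid), 0.48)
  expect_equal(auc_over_grid(c(1, 3), c(0.1, 0.2)), 0.2)
  expect_error(auc_over_grid(1, 0.1), "two points")
  expect_error(auc_over_grid(c(1, 2), c(0.1, 0.2, 0.3)), "mismatch")
  set.seed(21)
  x <- rnorm(length(grid))
  y <- rnorm(length(grid))
  expect_equal(auc_over_grid(2 * x + 3 * y, grid),
               2 * auc_over_grid(x, grid) + 3 * auc_over_grid(y, grid),
               tolerance = 1e-12)
})

test_that("global_metrics records keep the sigma identity and ranges", {
  set.seed(30)
  z <- matrix(rnorm(30 * 30), 30, 30)
  z <- (z + t(z)) / 2
  net <- threshold_by_sparsity(z, 0.25)
  gm <- global_metrics(net, random_null_networks(net, 10, seed = 1))
  expect_gte(gm$Cp, 0); expect_lte(gm$Cp, 1)
  expect_gte(gm$Eglob, 0); expect_lte(gm$Eglob, 1)
  expect_gte(gm$Eloc, 0); expect_lte(gm$Eloc, 1)
  expect_gte(gm$Lp, 1)
  expect_equal(gm$sigma, gm$gamma / gm$lambda)
})

test_that("nodal AUC table summarizes metrics across the grid", {
  co <- small_cohort()
  z <- lapply(co$subjects[1:2], function(s) fisher_z(pearson_fc(s)))
  names(z) <- co$manifest$subject_id[1:2]
  grid <- c(0.2, 0.25, 0.3)
  tab <- nodal_auc_table(z, grid)
  expect_equal(nrow(tab), 2 * 24 * 3)
  expect_setequal(unique(tab$metric), c("degree", "betweenness", "efficiency"))
  # cross-check one cell against a direct computation
  vals <- sapply(grid, function(s)
    nodal_metrics(threshold_by_sparsity(z[[1]], s))$degree[5])
  expect_equal(tab$auc[tab$subject_id == names(z)[1] & tab$node == 5 &
                         tab$metric == "degree"],
               auc_over_grid(vals, grid))
})
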