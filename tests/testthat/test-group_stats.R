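make_manifest <- function(n_per_group, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(2 * n_per_group)),
    group = rep(c("patient", "control"), each = n_per_group),
    age = round(runif(2 * n_per_group, 15, 30), 1),
    sex = sample(c("M", "F"), 2 * n_per_group, TRUE))
}

test_that("causal flow is the row/column sums of the state-mean EC", {
  ec <- matrix(c(0, 1, 2, 0), 2, 2) # (1,2)=2: 1->2; (2,1)=1: 2->1
  d <- structure(list(ec = list(ec),
                      windows = tibble::tibble(window = 1L, start = 1L,
                                               end = 22L),
                      roi_subset = c(1, 2), subject_id = "s1"),
                 class = "dec_series")
  model <- structure(list(k = 1, assignments = 1L), class = "state_model")
  wi <- tibble::tibble(subject_id = "s1", window = 1L)
  fl <- causal_flow(list(d), model, wi)
  expect_equal(fl$out_weighted, c(2, 1))
  expect_equal(fl$in_weighted, c(1, 2))

  # zero matrix gives zero flows; transposition swaps in and out
  d0 <- d; d0$ec <- list(matrix(0, 2, 2))
  expect_true(all(causal_flow(list(d0), model, wi)$in_weighted == 0))
  dt <- d; dt$ec <- list(t(ec))
  flt <- causal_flow(list(dt), model, wi)
  expect_equal(flt$in_weighted, fl$out_weighted)
  expect_equal(flt$out_weighted, fl$in_weighted)
})

test_that("total in-flow equals total out-flow per subject and state", {
  co <- small_cohort()
  dec <- lapply(co$subjects[1:4], function(s) dec_series(s, c(2, 7, 12, 17)))
  pooled <- pool_ec_windows(dec)
  model <- kmeans_l1(pooled$points, 2, seed = 1, n_restarts = 5)
  fl <- causal_flow(dec, model, pooled$window_info)
  sums <- dplyr::summarise(
    dplyr::group_by(fl, .data$subject_id, .data$state),
    gap = abs(sum(.data$in_weighted) - sum(.data$out_weighted)),
    .groups = "drop")
  expect_lt(max(sums$gap, na.rm = TRUE), 1e-9)
})

test_that("identical group values give t = 0 and p = 1", {
  man <- tibble::tibble(
    subject_id = sprintf("s%d", 1:6),
    group = rep(c("patient", "control"), each = 3),
    age = rep(20, 6), sex = rep(c("M", "F", "M"), 2))
  res <- adjusted_group_test(rep(c(1, 2, 3), 2), man)
  expect_equal(res$t, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
})

test_that("with constant covariates the test reduces to the pooled t-test", {
  set.seed(20)
  man <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:20),
    group = rep(c("patient", "control"), each = 10),
    age = rep(25, 20), sex = rep("F", 20))
  v <- rnorm(20) + rep(c(0.8, 0), each = 10)
  res <- adjusted_group_test(v, man)
  ref <- t.test(v[1:10], v[11:20], var.equal = TRUE)
  expect_equal(abs(res$t), abs(unname(ref$statistic)), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_equal(res$direction, "increased")
})

test_that("planted group shifts are detected with high power", {
  set.seed(21)
  man <- make_manifest(20)
  hits <- vapply(1:100, function(i) {
    v <- rnorm(40, sd = 0.1) + rep(c(1, 0), each = 20)
    adjusted_group_test(v, man)$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("a group-collinear design raises a singularity error", {
  man <- tibble::tibble(
    subject_id = sprintf("s%d", 1:8),
    group = rep(c("patient", "control"), each = 4),
    age = c(20, 21, 22, 23, 20, 21, 22, 23),
    sex = rep(c("M", "M", "M", "M"), 2))
  man$sex <- rep(c("M", "F"), c(4, 4)) # sex == group -> collinear
  expect_error(adjusted_group_test(rnorm(8), man), "collinear|singular")
})

test_that("missing values are excluded and small groups rejected", {
  man <- make_manifest(4)
  v <- rnorm(8)
  v[1:2] <- NA
  expect_error(adjusted_group_test(v, man), ">= 3")
})

test_that("BH adjustment matches the worked example and brute force", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
  set.seed(22)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_equal(fdr_bh(p), bf_bh(p), tolerance = 1e-12)
  }
})

test_that("adjusted p-values dominate raw p-values", {
  set.seed(23)
  p <- runif(50)
  adj <- fdr_bh(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
})

test_that("spearman association matches the rank-difference formula", {
  expect_equal(spearman_assoc(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_assoc(1:8, -(1:8))$rho, -1)
  # sum d^2 = 4 -> rho = 1 - 6*4/(5*24) = 0.8
  res <- spearman_assoc(1:5, c(2, 1, 4, 3, 5))
  expect_equal(res$rho, 0.8)
  tref <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(res$p, 2 * pt(-tref, df = 3), tolerance = 1e-12)
  expect_error(spearman_assoc(rep(1, 5), 1:5), "constant")
  expect_error(spearman_assoc(1:3, 1:3), "at least 4")
})

test_that("group test tables apply FDR within the stated family", {
  set.seed(24)
  man <- make_manifest(8)
  df <- tidyr::expand_grid(subject_id = man$subject_id, node = 1:4,
                           metric = c("degree", "efficiency"))
  df$value <- rnorm(nrow(df))
  res <- group_test_table(df, man, unit_cols = c("node", "metric"),
                          family_cols = "metric")
  expect_equal(nrow(res), 8)
  fam <- res[res$metric == "degree", ]
  expect_equal(fam$p_fdr, fdr_bh(fam$p))
})

test_that("abnormal-node report flags directions and handles emptiness", {
  tests <- tibble::tibble(
    node = c(1, 2, 3), metric = "degree",
    t = c(3, -3, 0.1), p = c(0.001, 0.002, 0.9),
    mean_patient = c(2, 1, 0), mean_control = c(1, 2, 0),
    direction = c("increased", "decreased", "increased"),
    n_patient = 10, n_control = 10,
    p_fdr = c(0.003, 0.003, 0.9))
  rep <- abnormal_node_report(tests, alpha = 0.05)
  expect_equal(rep$node, c(1, 2))
  expect_equal(rep$direction, c("increased", "decreased"))
  expect_equal(rep$direction,
               ifelse(rep$mean_patient >= rep$mean_control,
                      "increased", "decreased"))
  empty <- tests
  empty$p_fdr <- 0.9
  expect_message(res <- abnormal_node_report(empty, 0.05), "no node")
  expect_equal(nrow(res), 0)
})
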