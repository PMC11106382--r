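#' Manhattan (L1) distance
#'
#' Sum of elementwise absolute differences between two equal-length vectors.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
#' @examples
#' manhattan_distance(c(0, 0), c(3, 4)) # 7
manhattan_distance <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch")
  sum(abs(u - v))
}

# m x k matrix of L1 distances from each row of `points` to each centroid row.
l1_cross_dist <- function(points, centroids) {
  .l1_cross_dist_cpp(points, centroids)
}

#' K-means clustering with Manhattan-distance assignment
#'
#' The hybrid rule used in dynamic-connectivity state analyses: samples are
#' assigned to the nearest centroid under the L1 (Manhattan) distance, and
#' centroids are updated as cluster means. Iteration stops at an assignment
#' fix-point or after `max_iter` sweeps; the best of `n_restarts` runs by
#' the within-cluster squared error E is kept. Note the mean is not the
#' L1-optimal centre (the componentwise median is); `update = "median"`
#' gives the strict k-medians alternative.
#'
#' @param points Numeric matrix, one sample per row (>= k rows).
#' @param k Number of clusters.
#' @param seed Seed for centroid initialisation (caller RNG restored).
#' @param n_restarts Random restarts (default 50).
#' @param update `"mean"` (default) or `"median"`.
#' @param max_iter Iteration cap per restart (default 300).
#' @return Object of class `state_model`: `k`, `centroids` (k x d),
#'   `assignments`, `objective` (final E, squared-error), `objective_trace`,
#'   `sizes`, `iterations`, `converged`.
#' @export
kmeans_l1 <- function(points, k, seed = 1, n_restarts = 50,
                      update = c("mean", "median"), max_iter = 300) {
  update <- match.arg(update)
  points <- as.matrix(points)
  m <- nrow(points)
  if (m < k) stop("fewer points than clusters")
  update_fn <- if (update == "mean") colMeans else
    function(x) apply(x, 2, stats::median)

  run_once <- function() {
    init <- points[sample.int(m, k), , drop = FALSE]
    if (update == "mean") {
      res <- .kmeans_l1_run_cpp(points, init, max_iter)
      return(list(centroids = res$centroids, assignments = res$assignments,
                  objective = res$trace[length(res$trace)],
                  trace = res$trace, iterations = length(res$trace),
                  converged = res$converged))
    }
    centroids <- init
    assign_prev <- rep(0L, m)
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      d <- l1_cross_dist(points, centroids)
      assign_cur <- max.col(-d, ties.method = "first")
      # re-seed empty clusters at the point farthest (L1) from its centroid
      for (j in which(tabulate(assign_cur, k) == 0)) {
        far <- which.max(d[cbind(seq_len(m), assign_cur)])
        assign_cur[far] <- j
        d[far, ] <- -Inf # exclude from further re-seeding
      }
      for (j in seq_len(k)) {
        centroids[j, ] <- update_fn(points[assign_cur == j, , drop = FALSE])
      }
      sq <- points - centroids[assign_cur, , drop = FALSE]
      trace <- c(trace, sum(sq * sq))
      if (all(assign_cur == assign_prev)) { converged <- TRUE; break }
      assign_prev <- assign_cur
    }
    list(centroids = centroids, assignments = assign_cur,
         objective = trace[length(trace)], trace = trace,
         iterations = length(trace), converged = converged)
  }

  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      res <- run_once()
      if (is.null(best) || res$objective < best$objective) best <- res
    }
    structure(
      list(k = k, centroids = best$centroids,
           assignments = best$assignments, objective = best$objective,
           objective_trace = best$trace,
           sizes = tabulate(best$assignments, k),
           iterations = best$iterations, converged = best$converged,
           update = update),
      class = "state_model")
  })
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> k = %d, %d samples, E = %.4g, sizes: %s\n",
              x$k, length(x$assignments), x$objective,
              paste(x$sizes, collapse = "/")))
  invisible(x)
}

# Mean silhouette width under L1 distance. For large inputs the silhouette
# is evaluated on a seeded subsample (distances still to all cluster
# co-members within the subsample).
silhouette_l1 <- function(points, assignments, max_points = 2000,
                          seed = 1) {
  m <- nrow(points)
  idx <- if (m > max_points)
    with_seed(seed, sort(sample.int(m, max_points))) else seq_len(m)
  p <- points[idx, , drop = FALSE]
  a <- assignments[idx]
  ks <- sort(unique(a))
  if (length(ks) < 2) return(NA_real_)
  d <- as.matrix(stats::dist(p, method = "manhattan"))
  s <- numeric(length(idx))
  for (i in seq_along(idx)) {
    own <- a == a[i]
    n_own <- sum(own) - 1
    if (n_own == 0) { s[i] <- 0; next }
    a_i <- sum(d[i, own]) / n_own
    b_i <- min(vapply(ks[ks != a[i]], function(kk)
      mean(d[i, a == kk]), numeric(1)))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

# Calinski-Harabasz index (squared-Euclidean between/within dispersion).
calinski_harabasz <- function(points, assignments) {
  m <- nrow(points)
  ks <- sort(unique(assignments))
  k <- length(ks)
  if (k < 2) return(NA_real_)
  overall <- colMeans(points)
  b <- w <- 0
  for (kk in ks) {
    sub <- points[assignments == kk, , drop = FALSE]
    mu <- colMeans(sub)
    b <- b + nrow(sub) * sum((mu - overall)^2)
    sq <- sweep(sub, 2, mu, "-")
    w <- w + sum(sq * sq)
  }
  (b / (k - 1)) / (w / (m - k))
}

#' Select the number of connectivity states
#'
#' Fits [kmeans_l1()] for each candidate k and scores the partition with the
#' L1 silhouette coefficient and the Calinski-Harabasz index. The selected k
#' maximises the silhouette; ties break by Calinski-Harabasz, then by
#' smaller k.
#'
#' @param points Sample matrix (vectorized EC matrices, one window per row).
#' @param k_range Integer candidates, each in `[2, nrow(points) - 1]`.
#' @param seed Seed (restart initialisation and silhouette subsampling).
#' @param n_restarts Restarts per candidate k.
#' @param silhouette_max_points Subsample cap for the silhouette.
#' @return List with `k_best`, `curves` (tibble: k, silhouette,
#'   calinski_harabasz, objective) and `models` (fitted `state_model` per k).
#' @export
select_k <- function(points, k_range = 2:10, seed = 1, n_restarts = 50,
                     silhouette_max_points = 2000) {
  points <- as.matrix(points)
  if (any(k_range < 2) || any(k_range > nrow(points) - 1)) {
    stop("k_range must lie within [2, nrow(points) - 1]")
  }
  if (all(stats::dist(points[seq_len(min(50, nrow(points))), ]) == 0)) {
    stop("all points identical: state count is undefined")
  }
  models <- list()
  rows <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- kmeans_l1(points, k, seed = seed + k, n_restarts = n_restarts)
    models[[as.character(k)]] <- fit
    rows[[i]] <- tibble::tibble(
      k = k,
      silhouette = silhouette_l1(points, fit$assignments,
                                 max_points = silhouette_max_points,
                                 seed = seed),
      calinski_harabasz = calinski_harabasz(points, fit$assignments),
      objective = fit$objective
    )
  }
  curves <- dplyr::bind_rows(rows)
  ord <- order(-curves$silhouette, -curves$calinski_harabasz, curves$k)
  list(k_best = curves$k[ord[1]], curves = curves, models = models)
}

#' State occupancy fractions
#'
#' Fraction of windows assigned to each state, overall and per group.
#'
#' @param model A `state_model`.
#' @param window_info Tibble aligning samples with subjects: one row per
#'   sample (in `model$assignments` order) with a `subject_id` column.
#' @param manifest Cohort manifest (for the group of each subject); optional.
#' @return Tibble `scope` ("overall" or group name), `state`, `n_windows`,
#'   `fraction`; fractions sum to 1 within each scope.
#' @export
state_occupancy <- function(model, window_info, manifest = NULL) {
  df <- tibble::tibble(state = model$assignments,
                       subject_id = window_info$subject_id)
  count_scope <- function(d, scope) {
    tab <- tabulate(d$state, model$k)
    tibble::tibble(scope = scope, state = seq_len(model$k),
                   n_windows = tab, fraction = tab / sum(tab))
  }
  out <- count_scope(df, "overall")
  if (!is.null(manifest)) {
    df <- dplyr::left_join(df, manifest[, c("subject_id", "group")],
                           by = "subject_id")
    for (g in unique(df$group)) {
      out <- dplyr::bind_rows(out, count_scope(df[df$group == g, ], g))
    }
  }
  out
}

#' Reshape state centroids to directed matrices
#'
#' Inverts the row-major off-diagonal vectorization used on EC matrices;
#' diagonals are zero.
#'
#' @param model A `state_model` fitted on vectorized n x n EC matrices.
#' @param n_rois Matrix dimension n.
#' @return List of `model$k` matrices.
#' @export
state_centroid_matrices <- function(model, n_rois) {
  if (ncol(model$centroids) != n_rois * (n_rois - 1)) {
    stop("centroid length does not match n_rois * (n_rois - 1)")
  }
  lapply(seq_len(model$k), function(i)
    devectorize_ec(model$centroids[i, ], n_rois))
}

#' Pool windowed EC matrices across subjects
#'
#' Stacks every subject's vectorized EC windows into one sample matrix and
#' the aligned bookkeeping table used by [state_occupancy()] and
#' [causal_flow()].
#'
#' @param dec_list List of [dec_series()] objects.
#' @return List with `points` (windows x n(n-1) matrix) and `window_info`
#'   (tibble: subject_id, window).
#' @export
pool_ec_windows <- function(dec_list) {
  pts <- list(); info <- list()
  for (d in dec_list) {
    pts[[length(pts) + 1]] <- t(vapply(d$ec, vectorize_ec,
                                       numeric(length(d$roi_subset) *
                                                 (length(d$roi_subset) - 1))))
    info[[length(info) + 1]] <- tibble::tibble(
      subject_id = d$subject_id, window = d$windows$window)
  }
  list(points = do.call(rbind, pts), window_info = dplyr::bind_rows(info))
}
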