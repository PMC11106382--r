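as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(unclass(net) != 0, mode = "undirected",
                                      diag = FALSE)
}

#' Clustering coefficient
#'
#' Per-node transitivity `2 * triangles / (k (k - 1))` (zero for degree < 2)
#' and its mean over all nodes.
#'
#' @param net 0/1 symmetric adjacency matrix ([threshold_by_sparsity()]).
#' @return List with `node` (per-node values) and `mean` (Cp).
#' @export
clustering_coefficient <- function(net) {
  g <- as_igraph(net)
  node <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  list(node = node, mean = mean(node))
}

# All-pairs shortest-path matrix (hops), Inf off the connected component.
distance_matrix <- function(net) {
  igraph::distances(as_igraph(net))
}

#' Characteristic path length
#'
#' Mean shortest-path length over node pairs. Infinite (disconnected) pairs
#' are excluded from the average; their fraction is available as attribute
#' `frac_infinite`.
#'
#' @param net 0/1 symmetric adjacency matrix.
#' @return Scalar Lp with attribute `frac_infinite`.
#' @export
characteristic_path_length <- function(net) {
  d <- distance_matrix(net)
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  if (!any(finite)) stop("fully disconnected network: no finite pairs")
  structure(mean(off[finite]), frac_infinite = mean(!finite))
}

#' Global efficiency
#'
#' Mean over node pairs of the inverse shortest-path length, with
#' disconnected pairs contributing zero.
#'
#' @param net 0/1 symmetric adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  d <- distance_matrix(net)
  off <- d[row(d) != col(d)]
  mean(1 / off) # 1/Inf = 0
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbours; nodes with fewer than two neighbours contribute zero.
#'
#' @param net 0/1 symmetric adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
local_efficiency <- function(net) {
  a <- unclass(net) != 0
  n <- nrow(a)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ])
    if (length(nb) < 2) return(0)
    global_efficiency(a[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

#' Nodal topology metrics
#'
#' Degree centrality (edge count), unnormalized betweenness centrality
#' (undirected pairs counted once), and nodal efficiency (mean inverse
#' distance to all other nodes).
#'
#' @param net 0/1 symmetric adjacency matrix.
#' @return Tibble with columns `node`, `degree`, `betweenness`, `efficiency`.
#' @export
nodal_metrics <- function(net) {
  g <- as_igraph(net)
  d <- igraph::distances(g)
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  tibble::tibble(
    node = seq_len(n),
    degree = as.numeric(rowSums(unclass(net) != 0)),
    betweenness = igraph::betweenness(g, directed = FALSE),
    efficiency = rowSums(inv) / (n - 1)
  )
}

#' Degree-preserving null networks
#'
#' Maslov-Sneppen double-edge-swap rewiring: every null preserves each
#' node's degree exactly. Connectedness is not enforced.
#'
#' @param net 0/1 symmetric adjacency matrix with at least 2 edges.
#' @param n_null Number of nulls.
#' @param rewires_per_edge Swap attempts per edge.
#' @param seed Seed for reproducibility (caller RNG state restored).
#' @return List of adjacency matrices.
#' @export
random_null_networks <- function(net, n_null = 100, rewires_per_edge = 10,
                                 seed = NULL) {
  g <- as_igraph(net)
  n_edges <- igraph::ecount(g)
  if (n_edges < 2) stop("need at least 2 edges to rewire")
  with_seed(seed, {
    lapply(seq_len(n_null), function(i) {
      gr <- igraph::rewire(
        g, igraph::keeping_degseq(niter = rewires_per_edge * n_edges))
      adj <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
      storage.mode(adj) <- "integer"
      adj
    })
  })
}

#' Small-world normalization against null networks
#'
#' gamma = Cp(net) / mean Cp(nulls), lambda = Lp(net) / mean Lp(nulls),
#' sigma = gamma / lambda. sigma > 1 (conventionally > 1.1) indicates
#' small-world organisation.
#'
#' @param net 0/1 symmetric adjacency matrix.
#' @param nulls Non-empty list of null adjacencies
#'   ([random_null_networks()]).
#' @return List with `gamma`, `lambda`, `sigma`.
#' @export
small_world_normalize <- function(net, nulls) {
  if (!length(nulls)) stop("null list is empty")
  cp <- clustering_coefficient(net)$mean
  lp <- as.numeric(characteristic_path_length(net))
  cp0 <- mean(vapply(nulls, function(m) clustering_coefficient(m)$mean,
                     numeric(1)))
  lp0 <- mean(vapply(nulls, function(m)
    as.numeric(characteristic_path_length(m)), numeric(1)))
  if (cp0 <= 0 || lp0 <= 0) stop("null mean Cp/Lp is zero; cannot normalize")
  gamma <- cp / cp0
  lambda <- lp / lp0
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' All global metrics of one network
#'
#' @param net 0/1 symmetric adjacency matrix.
#' @param nulls Null networks for the small-world ratios (optional; without
#'   them gamma/lambda/sigma are `NA`).
#' @return One-row tibble: `sparsity`, `Cp`, `Lp`, `Eglob`, `Eloc`, `gamma`,
#'   `lambda`, `sigma`.
#' @export
global_metrics <- function(net, nulls = NULL) {
  sw <- if (is.null(nulls)) list(gamma = NA_real_, lambda = NA_real_,
                                 sigma = NA_real_)
        else small_world_normalize(net, nulls)
  tibble::tibble(
    sparsity = attr(net, "sparsity") %||% NA_real_,
    Cp = clustering_coefficient(net)$mean,
    Lp = as.numeric(characteristic_path_length(net)),
    Eglob = global_efficiency(net),
    Eloc = local_efficiency(net),
    gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma
  )
}

#' Trapezoidal area under a metric-vs-sparsity curve
#'
#' @param values Metric values, one per grid point.
#' @param grid Strictly increasing sparsity grid of the same length (>= 2).
#' @return Scalar trapezoidal integral.
#' @export
#' @examples
#' auc_over_grid(rep(2, 25), seq(0.10, 0.34, by = 0.01)) # 0.48
auc_over_grid <- function(values, grid) {
  if (length(values) != length(grid)) stop("values/grid length mismatch")
  if (length(grid) < 2) stop("grid needs at least two points")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  sum(diff(grid) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Per-subject nodal metrics across a sparsity grid, summarized by AUC
#'
#' Thresholds each subject's connectivity matrix at every grid sparsity,
#' computes the nodal metrics, and integrates each metric over the grid.
#'
#' @param z_list Named list of subjects' symmetric connectivity matrices.
#' @param grid Sparsity grid (length >= 2).
#' @param rank_by Passed to [threshold_by_sparsity()].
#' @return Tibble `subject_id`, `node`, `metric`, `auc` in long format.
#' @export
nodal_auc_table <- function(z_list, grid, rank_by = "signed") {
  ids <- names(z_list) %||% as.character(seq_along(z_list))
  rows <- purrr::map2(z_list, ids, function(z, id) {
    per_s <- purrr::map(grid, function(s) {
      nm <- nodal_metrics(threshold_by_sparsity(z, s, rank_by = rank_by))
      nm$sparsity <- s
      nm
    })
    long <- tidyr::pivot_longer(dplyr::bind_rows(per_s),
                                c("degree", "betweenness", "efficiency"),
                                names_to = "metric", values_to = "value")
    out <- dplyr::summarise(
      dplyr::group_by(long, .data$node, .data$metric),
      auc = auc_over_grid(.data$value[order(.data$sparsity)], sort(grid)),
      .groups = "drop")
    out$subject_id <- id
    out
  })
  dplyr::bind_rows(rows)[, c("subject_id", "node", "metric", "auc")]
}
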