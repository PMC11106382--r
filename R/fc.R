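#' Pearson functional connectivity matrix
#'
#' Correlates every pair of ROI time courses, giving a symmetric N x N
#' matrix with unit diagonal.
#'
#' @param ts A [subject_ts()] (or plain T x N matrix), T >= 3.
#' @return Symmetric numeric matrix of class `fc_matrix` with attribute
#'   `subject_id`.
#' @export
pearson_fc <- function(ts) {
  m <- if (inherits(ts, "subject_ts")) ts$data else as.matrix(ts)
  if (nrow(m) < 3) stop("need at least 3 time points for correlation")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0] %||% which(sds == 0)
    stop("constant time series for ROI(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(m)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(r, class = c("fc_matrix", "matrix"),
            subject_id = if (inherits(ts, "subject_ts")) ts$subject_id else NA)
}

#' Fisher r-to-z transformation
#'
#' Applies `atanh` elementwise to the off-diagonal of a correlation matrix.
#' The map is strictly increasing, so edge rankings are unchanged. Values at
#' exactly +/-1 are clipped to +/-(1 - 1e-7) first.
#'
#' @param fc Symmetric correlation matrix (e.g. from [pearson_fc()]).
#' @return Matrix of class `z_matrix`; diagonal set to 0 (excluded from all
#'   downstream edge selection).
#' @export
fisher_z <- function(fc) {
  r <- unclass(fc)
  clip <- 1 - 1e-7
  off <- row(r) != col(r)
  clipped <- sum(abs(r[off]) >= 1)
  if (clipped > 0) {
    message("fisher_z: clipped ", clipped, " correlation(s) at |r| = 1")
  }
  r[off] <- pmin(pmax(r[off], -clip), clip)
  z <- r
  z[off] <- atanh(r[off])
  diag(z) <- 0
  structure(z, class = c("z_matrix", "matrix"),
            subject_id = attr(fc, "subject_id"))
}

# Number of retained edges at a sparsity: round-half-up of s * N(N-1)/2.
edge_count_at <- function(sparsity, n) {
  floor(sparsity * n * (n - 1) / 2 + 0.5)
}

#' Binarize a connectivity matrix at a target sparsity
#'
#' Retains the strongest `round(sparsity * N(N-1)/2)` off-diagonal entries as
#' edges. Ranking is by signed value by default (most positive first), so at
#' the usual sparsities negative correlations are effectively excluded;
#' `rank_by = "abs"` ranks by magnitude. Ties at the cut break
#' deterministically by larger value, then smaller row index, then smaller
#' column index.
#'
#' @param z Symmetric matrix (correlation or Fisher z; rankings agree).
#' @param sparsity Fraction of possible edges to retain, in (0, 1).
#' @param rank_by `"signed"` (default) or `"abs"`.
#' @return 0/1 adjacency matrix of class `binary_network` with attributes
#'   `sparsity` and `subject_id`.
#' @export
threshold_by_sparsity <- function(z, sparsity, rank_by = c("signed", "abs")) {
  rank_by <- match.arg(rank_by)
  if (sparsity <= 0 || sparsity >= 1) stop("sparsity must be in (0, 1)")
  m <- unclass(z)
  n <- nrow(m)
  k <- edge_count_at(sparsity, n)
  if (k < 1) stop("sparsity ", sparsity, " retains zero edges for N = ", n)
  ut <- which(upper.tri(m))
  w <- m[ut]
  if (rank_by == "abs") w <- abs(w)
  ri <- ((ut - 1) %% n) + 1
  ci <- ((ut - 1) %/% n) + 1
  ord <- order(-w, ri, ci)
  keep <- ut[ord[seq_len(k)]]
  adj <- matrix(0L, n, n)
  adj[keep] <- 1L
  adj <- adj + t(adj)
  dimnames(adj) <- dimnames(m)
  structure(adj, class = c("binary_network", "matrix"),
            sparsity = sparsity, subject_id = attr(z, "subject_id"))
}

#' Admissible sparsity range across a cohort
#'
#' Restricts a candidate sparsity grid to the points where, for every
#' subject, (i) the network's mean degree exceeds `2 * log(N)` and (ii) its
#' small-world scalar sigma exceeds 1.1. Returns the admissible sub-grid and
#' a per-point diagnostic table.
#'
#' @param z_list List of subjects' symmetric connectivity matrices.
#' @param grid Candidate sparsity values (e.g. [sparsity_grid()]).
#' @param sigma_fn Function `(binary_network) -> sigma`; defaults to
#'   normalization against `n_null` degree-preserving nulls.
#' @param log_base Base of the log in the degree criterion (natural log by
#'   default).
#' @param n_null,rewires_per_edge,seed Null-model settings used by the
#'   default `sigma_fn`.
#' @param sigma_threshold Small-world criterion (default 1.1).
#' @param rank_by Passed to [threshold_by_sparsity()].
#' @return List with `s_min`, `s_max`, `admissible` (the sub-grid) and
#'   `diagnostics` (tibble of per-sparsity criterion values).
#' @export
admissible_sparsity_range <- function(z_list, grid, sigma_fn = NULL,
                                      log_base = exp(1),
                                      n_null = 20, rewires_per_edge = 10,
                                      seed = 1, sigma_threshold = 1.1,
                                      rank_by = "signed") {
  if (!length(grid)) stop("candidate sparsity grid is empty")
  n <- nrow(z_list[[1]])
  degree_bound <- 2 * log(n, base = log_base)
  if (is.null(sigma_fn)) {
    sigma_fn <- function(net, seed_i) {
      nulls <- random_null_networks(net, n_null, rewires_per_edge,
                                    seed = seed_i)
      small_world_normalize(net, nulls)$sigma
    }
  } else {
    user_fn <- sigma_fn
    sigma_fn <- function(net, seed_i) user_fn(net)
  }
  diag_rows <- vector("list", length(grid))
  ok <- logical(length(grid))
  for (gi in seq_along(grid)) {
    s <- grid[gi]
    degs <- sigmas <- numeric(length(z_list))
    for (si in seq_along(z_list)) {
      net <- threshold_by_sparsity(z_list[[si]], s, rank_by = rank_by)
      degs[si] <- mean(rowSums(net))
      sigmas[si] <- sigma_fn(net, seed + 1000L * gi + si)
    }
    ok[gi] <- all(degs > degree_bound) && all(sigmas > sigma_threshold)
    diag_rows[[gi]] <- tibble::tibble(
      sparsity = s, min_mean_degree = min(degs), degree_bound = degree_bound,
      min_sigma = min(sigmas),
      degree_ok = all(degs > degree_bound),
      sigma_ok = all(sigmas > sigma_threshold)
    )
  }
  diagnostics <- dplyr::bind_rows(diag_rows)
  if (!any(ok)) {
    stop("no admissible sparsity in the candidate grid; widen or shift it ",
         "(see diagnostics: smallest mean degree ",
         round(min(diagnostics$min_mean_degree), 2), " vs bound ",
         round(degree_bound, 2), ")")
  }
  admissible <- grid[ok]
  list(s_min = min(admissible), s_max = max(admissible),
       admissible = admissible, diagnostics = diagnostics)
}
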