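# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Zero-phase band-pass filtering of column signals
#'
#' Applies a finite-impulse-response band-pass (Hamming-window design,
#' forward-backward so the net phase is zero) to each column. Power outside
#' the passband is attenuated by at least 20 dB relative to the passband.
#'
#' @param x Numeric T x N matrix (or vector), one signal per column.
#' @param low_hz,high_hz Passband edges in Hz; `0 <= low < high < ` Nyquist.
#' @param tr_seconds Sampling interval in seconds.
#' @return Filtered matrix of the same dimensions.
#' @export
#' @examples
#' t <- seq(0, by = 2, length.out = 190)
#' noisy <- sin(2 * pi * 0.2 * t) # outside the 0.01-0.08 Hz band
#' var(bandlimit(noisy, 0.01, 0.08, 2)) / var(noisy) # ~0
bandlimit <- function(x, low_hz, high_hz, tr_seconds) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  nyq <- 1 / (2 * tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("band must satisfy 0 <= low < high < Nyquist (", nyq, " Hz)")
  }
  T_len <- nrow(x)
  # filtfilt needs the signal to be comfortably longer than the filter
  ord <- min(48L, 2L * ((T_len - 4L) %/% 6L))
  if (ord < 8) stop("time series too short to band-pass filter")
  b <- signal::fir1(ord, c(low_hz, high_hz) / nyq, type = "pass")
  y <- apply(x, 2, function(col) signal::filtfilt(b, col))
  if (vec) as.numeric(y) else y
}

#' Sample a Markov regime sequence
#'
#' First-order Markov chain over `k_true` regimes with switch probability
#' `1/dwell_mean_tr` per step (geometric dwell times with the stated mean);
#' on a switch the chain moves to one of the other regimes uniformly.
#'
#' @param n_timepoints Sequence length T.
#' @param k_true Number of regimes (>= 1).
#' @param dwell_mean_tr Mean dwell time in samples (>= 1).
#' @param seed Optional seed for reproducibility (caller RNG restored).
#' @return Integer vector of length T with values in `1..k_true`.
#' @export
sample_state_sequence <- function(n_timepoints, k_true, dwell_mean_tr,
                                  seed = NULL) {
  if (k_true < 1) stop("k_true must be >= 1")
  if (dwell_mean_tr < 1) stop("dwell_mean_tr must be >= 1")
  if (k_true == 1) return(rep(1L, n_timepoints))
  with_seed(seed, {
    s <- integer(n_timepoints)
    s[1] <- sample.int(k_true, 1)
    p_switch <- 1 / dwell_mean_tr
    flips <- stats::runif(n_timepoints - 1) < p_switch
    for (t in seq_len(n_timepoints - 1)) {
      if (flips[t]) {
        others <- setdiff(seq_len(k_true), s[t])
        s[t + 1] <- others[sample.int(length(others), 1)]
      } else {
        s[t + 1] <- s[t]
      }
    }
    s
  })
}

#' Default regime coupling matrices for the synthetic cohort
#'
#' Regime 1 is a densely coupled directed configuration (a skew-symmetric
#' matrix of equal-magnitude rotation planes, so the implied VAR is stable
#' by construction) and regime 2 a weakly coupled one, mimicking the
#' strong-versus-weak state structure dynamic effective-connectivity studies
#' report. Entry (i, j) is the lag-1 influence of ROI i on ROI j; diagonals
#' are zero (the autoregressive self-term is carried separately).
#'
#' @param n_coupled Number of coupled ROIs (even sizes use all rotation
#'   planes; with an odd size one direction stays uncoupled).
#' @param k_true Number of regimes (1 or 2 supported by the default).
#' @param strength Spectral magnitude of the strong regime's coupling.
#' @return List of `k_true` zero-diagonal matrices.
#' @export
default_coupling <- function(n_coupled = 6, k_true = 2, strength = 0.85) {
  # dense skew-symmetric coupling built from equal-magnitude rotation
  # planes: all eigenvalues sit at +/- strength i, so the VAR is stable by
  # construction while the regime contrast (Frobenius mass) is maximal for
  # that spectral radius; a fixed internal seed makes the matrix a constant
  strong <- with_seed(613, {
    q <- qr.Q(qr(matrix(stats::rnorm(n_coupled^2), n_coupled, n_coupled)))
    j <- matrix(0, n_coupled, n_coupled)
    for (b in seq(1, n_coupled - 1, by = 2)) {
      j[b, b + 1] <- 1
      j[b + 1, b] <- -1
    }
    strength * q %*% j %*% t(q)
  })
  diag(strong) <- 0
  weak <- matrix(0, n_coupled, n_coupled)
  if (n_coupled >= 2) weak[1, 2] <- 0.10
  if (n_coupled >= 5) weak[4, 5] <- 0.10
  if (k_true == 1) list(strong) else
    c(list(strong, weak), rep(list(weak), max(0, k_true - 2)))
}

# Spectral radius of the VAR(1) companion matrix t(M) + ar_self * I.
companion_radius <- function(m, ar_self) {
  max(Mod(eigen(t(m) + diag(ar_self, nrow(m)), only.values = TRUE)$values))
}

# Community-structured correlation target with graded edge strengths (a
# smooth spectrum rather than two levels, so sparsity thresholds cut
# through every node's edge-weight distribution) and sparse stronger
# long-range links providing small-world shortcuts. Planted nodes get
# defined baselines: deficit nodes high (their down-weighted edges cross
# the sparsity cutoffs from above) and enhanced nodes at their *enhanced*
# level (the control group is later derived by down-scaling them, so the
# positive-definiteness projection is only ever asked to shrink entries,
# which it does nearly losslessly). Drawn from the caller RNG; PD by
# eigenvalue clipping.
build_correlation_target <- function(n_rois, module_size = 15,
                                     within_range = c(0.25, 0.60),
                                     between_range = c(0, 0.15),
                                     longrange_frac = 0.06,
                                     longrange_range = c(0.25, 0.45),
                                     deficit_nodes = integer(0),
                                     enhanced_nodes = integer(0)) {
  module <- ceiling(seq_len(n_rois) / module_size)
  r <- matrix(0, n_rois, n_rois)
  same <- outer(module, module, "==")
  ut <- upper.tri(r)
  r[ut & same] <- stats::runif(sum(ut & same), within_range[1],
                               within_range[2])
  r[ut & !same] <- stats::runif(sum(ut & !same), between_range[1],
                                between_range[2])
  set_planted <- function(r, nodes, lo, hi) {
    if (!length(nodes)) return(r)
    planted <- (row(r) %in% nodes) | (col(r) %in% nodes)
    sel <- ut & same & planted
    r[sel] <- stats::runif(sum(sel), lo, hi)
    r
  }
  r <- set_planted(r, deficit_nodes, 0.40, 0.60)
  r <- set_planted(r, enhanced_nodes, 0.27, 0.48)
  # enhanced nodes are modelled as diffusely connected association hubs:
  # their between-module edges sit just under the threshold band, so the
  # up-weighting moves many of them across the sparsity cutoffs
  if (length(enhanced_nodes)) {
    enh <- (row(r) %in% enhanced_nodes) | (col(r) %in% enhanced_nodes)
    sel <- ut & !same & enh
    r[sel] <- stats::runif(sum(sel), 0.10, 0.20)
  }
  between_pairs <- which(ut & !same)
  pick <- sample(between_pairs, round(longrange_frac * length(between_pairs)))
  r[pick] <- stats::runif(length(pick), longrange_range[1],
                          longrange_range[2])
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  diag(r) <- 1
  nearest_correlation(r)
}

# Eigenvalue-clipped projection to a valid correlation matrix.
nearest_correlation <- function(r, eps = 1e-6) {
  e <- eigen((r + t(r)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  m <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(m))
  m <- m / tcrossprod(d)
  diag(m) <- 1
  (m + t(m)) / 2
}

# Down-scale off-diagonal entries incident to the given nodes and
# re-project. Shrinking keeps the matrix close to positive definite, so
# the projection is nearly lossless; this is why both group targets are
# derived from a common "high" target by down-scalings only.
scale_nodes_down <- function(r, nodes, factor) {
  if (!length(nodes) || factor == 1) return(r)
  scale <- rep(1, nrow(r))
  scale[nodes] <- factor
  s <- tcrossprod(scale)
  diag(s) <- 1
  r2 <- r * s
  diag(r2) <- 1
  nearest_correlation(r2)
}

#' Simulate a two-group cohort with planted network effects
#'
#' Generates per-subject ROI time series as band-limited correlated Gaussian
#' background whose target correlation has community structure (so
#' binarized graphs are small-world). In the patient group, edges incident to
#' `deficit_nodes` are down-weighted and edges incident to `enhanced_nodes`
#' up-weighted by `effect_size` before projection back to a valid correlation
#' matrix. On top, the `coupled_rois` subset follows a regime-switching
#' VAR(1) whose active coupling matrix is selected by a hidden Markov dwell
#' process; its innovations mix the (group-adjusted, band-limited)
#' background of those columns with a temporally white component that keeps
#' the lagged design identifiable at window scale. The planted-node and
#' coupled ROI sets are disjoint by default so each mechanism is tested on
#' clean ground.
#'
#' @param config A [default_config()] list (band, TR, etc.).
#' @param n_patients,n_controls Group sizes.
#' @param n_timepoints Time points per subject (T).
#' @param n_rois Number of atlas nodes (N).
#' @param coupled_rois Atlas indices carrying the regime-switching coupling.
#' @param deficit_nodes,enhanced_nodes Atlas indices with planted
#'   connectivity decrease / increase in patients.
#' @param k_true Number of hidden coupling regimes.
#' @param dwell_mean_tr Mean regime dwell time in TR.
#' @param effect_size Fractional edge-weight change for planted nodes
#'   (in `[0, 1)`).
#' @param coupling Optional list of `k_true` zero-diagonal coupling matrices
#'   over `coupled_rois` (defaults to [default_coupling()]).
#' @param ar_self Autoregressive self-coefficient of the coupled VAR.
#' @param innovation_band_weight Variance share of the band-limited
#'   background in the coupled columns' innovations (the rest is white).
#' @param seed Integer seed; identical inputs give bit-identical cohorts.
#' @return A list with elements `subjects` (list of [subject_ts()]),
#'   `manifest` (tibble), `clinical` (tibble, patients only), and `truth`
#'   (regime sequences, coupling matrices, planted nodes, correlation
#'   targets).
#' @export
simulate_cohort <- function(config = default_config(),
                            n_patients = 20, n_controls = 20,
                            n_timepoints = 190, n_rois = 90,
                            coupled_rois = c(31, 36, 38, 50, 60, 81),
                            deficit_nodes = c(33, 75),
                            enhanced_nodes = 66,
                            k_true = 2, dwell_mean_tr = 100,
                            effect_size = 0.5,
                            coupling = NULL, ar_self = 0.10,
                            innovation_band_weight = 0.15,
                            seed = 1) {
  if (length(coupled_rois) && max(coupled_rois) > n_rois) {
    stop("coupled_rois outside 1..n_rois")
  }
  if (effect_size < 0 || effect_size >= 1) {
    stop("effect_size must be in [0, 1): larger values do not yield a valid ",
         "correlation target")
  }
  if (dwell_mean_tr < 2) stop("dwell_mean_tr must be >= 2")
  if (n_timepoints < config$window_length_tr) {
    stop("n_timepoints below window length")
  }
  n_c <- length(coupled_rois)
  if (is.null(coupling)) {
    coupling <- if (n_c >= 2) default_coupling(n_c, k_true) else
      rep(list(matrix(0, n_c, n_c)), k_true)
  }
  stopifnot(length(coupling) == k_true)
  for (m in coupling) {
    stopifnot(nrow(m) == n_c, ncol(m) == n_c)
    if (any(diag(m) != 0)) stop("coupling matrices must have zero diagonal")
    if (n_c && companion_radius(m, ar_self) >= 1) {
      stop("non-stationary coupling matrix (companion spectral radius >= 1)")
    }
  }

  with_seed(seed, {
    r_high <- build_correlation_target(
      n_rois, deficit_nodes = deficit_nodes,
      enhanced_nodes = enhanced_nodes)
    # both group targets descend from the shared high target by shrinking:
    # patients lose the deficit nodes' edges, controls sit below the
    # enhanced nodes' (patient-level) edges
    r_patient <- scale_nodes_down(r_high, deficit_nodes, 1 - effect_size)
    r_control <- scale_nodes_down(r_high, enhanced_nodes, 1 / (1 + effect_size))
    half <- list(
      control = correlation_sqrt(r_control),
      patient = correlation_sqrt(r_patient)
    )

    n_total <- n_patients + n_controls
    groups <- rep(c("patient", "control"), c(n_patients, n_controls))
    ids <- sprintf("sub-%03d", seq_len(n_total))
    ages <- round(pmin(pmax(stats::rnorm(n_total, 20, 6), 12), 40), 1)
    sexes <- ifelse(stats::runif(n_total) < 0.5, "M", "F")

    subjects <- vector("list", n_total)
    state_sequences <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      z <- matrix(stats::rnorm(n_timepoints * n_rois), n_timepoints, n_rois)
      bg <- z %*% half[[groups[i]]]
      bg <- bandlimit(bg, config$bandpass_low_hz, config$bandpass_high_hz,
                      config$tr_seconds)
      bg <- scale(bg)[, , drop = FALSE] # unit-variance columns
      s_seq <- sample_state_sequence(n_timepoints, k_true, dwell_mean_tr)
      if (n_c > 0) {
        # innovations: mostly temporally white (a heavily autocorrelated
        # in-band innovation makes the lagged design of any causal model
        # nearly singular at window scale) with a band-limited background
        # component retaining some module correlation
        u <- sqrt(innovation_band_weight) * bg[, coupled_rois, drop = FALSE] +
          sqrt(1 - innovation_band_weight) *
            matrix(stats::rnorm(n_timepoints * n_c), n_timepoints, n_c)
        e_innov <- u
        for (t in 2:n_timepoints) {
          m <- coupling[[s_seq[t]]]
          u[t, ] <- e_innov[t, ] + as.numeric(t(m) %*% u[t - 1, ]) +
            ar_self * u[t - 1, ]
        }
        # standardize within each regime so the feedback-driven variance
        # inflation of strongly coupled regimes does not make a subject's
        # static FC depend on its regime occupancy
        for (s in unique(s_seq)) {
          rows <- s_seq == s
          if (sum(rows) >= 2) {
            u[rows, ] <- sweep(u[rows, , drop = FALSE], 2,
                               apply(u[rows, , drop = FALSE], 2,
                                     stats::sd), "/")
          }
        }
        bg[, coupled_rois] <- scale(u)
      }
      colnames(bg) <- NULL
      subjects[[i]] <- subject_ts(bg, ids[i], group = groups[i],
                                  age = ages[i], sex = sexes[i],
                                  tr_seconds = config$tr_seconds)
      state_sequences[[i]] <- s_seq
    }
    names(state_sequences) <- ids

    manifest <- tibble::tibble(subject_id = ids, group = groups,
                               age = ages, sex = sexes)
    pat <- manifest$subject_id[manifest$group == "patient"]
    clinical <- tibble::tibble(
      subject_id = pat,
      duration_months = round(abs(stats::rnorm(length(pat), 49, 47)), 1),
      nhs3 = round(stats::runif(length(pat), 0, 15), 1)
    )
    truth <- list(
      state_sequences = state_sequences,
      coupling_matrices = coupling,
      coupled_rois = coupled_rois,
      deficit_nodes = deficit_nodes,
      enhanced_nodes = enhanced_nodes,
      effect_size = effect_size,
      ar_self = ar_self,
      correlation_targets = list(control = r_control, patient = r_patient)
    )
    list(subjects = subjects, manifest = manifest, clinical = clinical,
         truth = truth)
  })
}

# Symmetric square root of a correlation matrix.
correlation_sqrt <- function(r) {
  e <- eigen(r, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Write a simulated cohort to a directory
#'
#' One TSV per subject (header row of ROI abbreviations), a manifest TSV, a
#' clinical TSV, and a ground-truth JSON.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param atlas Atlas supplying the column header; must match `n_rois`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, atlas = read_atlas()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_rois <- ncol(cohort$subjects[[1]]$data)
  if (nrow(atlas) != n_rois) stop("atlas size does not match cohort ROIs")
  for (s in cohort$subjects) {
    m <- s$data
    colnames(m) <- atlas$abbreviation
    utils::write.table(format(m, digits = 15, trim = TRUE, scientific = FALSE),
                       file.path(dir, paste0(s$subject_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  readr::write_tsv(cohort$manifest, file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"),
                   progress = FALSE)
  truth <- cohort$truth
  truth$coupling_matrices <- lapply(truth$coupling_matrices, function(m)
    apply(m, 1, identity, simplify = FALSE))
  truth$correlation_targets <- NULL # large; regenerable from the seed
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
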