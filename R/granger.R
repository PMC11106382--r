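#' Sliding-window bookkeeping
#'
#' Windows of `length_tr` samples advancing by `step_tr`; the window count is
#' `floor((T - length) / step) + 1`, so the last window ends at or before T.
#' The study default (T = 190, length 22, step 1) gives 169 windows.
#'
#' @param n_timepoints Series length T.
#' @param length_tr Window length in samples (default 22).
#' @param step_tr Step in samples (default 1).
#' @return Tibble with `window`, `start`, `end` (1-based, inclusive).
#' @export
make_windows <- function(n_timepoints, length_tr = 22, step_tr = 1) {
  if (n_timepoints < length_tr) {
    stop("series too short: T = ", n_timepoints, " < window length ",
         length_tr)
  }
  count <- (n_timepoints - length_tr) %/% step_tr + 1
  start <- 1 + (seq_len(count) - 1) * step_tr
  tibble::tibble(window = seq_len(count), start = start,
                 end = start + length_tr - 1)
}

#' Pairwise Granger-causal fit of one window
#'
#' Fits the joint autoregressive pair of equations by ordinary least squares
#' with intercept: y regressed on p lags of x and of y (plus optional
#' covariates), and symmetrically for x. The lagged-x coefficients in the y
#' equation are the signed path coefficients x -> y.
#'
#' @param x,y Numeric series of equal length.
#' @param p VAR order (default 1).
#' @param covariates Optional matrix of per-timepoint covariates (aligned
#'   with the response rows, i.e. times `p+1 .. T`).
#' @return List with `a` (x -> y path coefficients, length p), `a_rev`
#'   (y -> x), `b`, `b_rev` (autoregressive coefficients), `resid`,
#'   `resid_rev`, `p`, and `flagged` (TRUE if either design was
#'   rank-deficient).
#' @export
fit_pair_gc <- function(x, y, p = 1, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  n_cov <- if (is.null(covariates)) 0 else ncol(covariates)
  if (n < 2 * p + n_cov + 3) stop("window too short for VAR order ", p)
  resp_rows <- (p + 1):n
  lagmat <- function(v) {
    sapply(seq_len(p), function(k) v[resp_rows - k])
  }
  design <- cbind(1, lagmat(x), lagmat(y))
  if (n_cov > 0) design <- cbind(design, covariates)
  fit_one <- function(yy) {
    f <- stats::lm.fit(design, yy)
    flagged <- f$rank < ncol(design)
    list(coef = f$coefficients, resid = f$residuals, flagged = flagged)
  }
  fy <- fit_one(y[resp_rows]) # y eq: lags of x are the causal path
  fx <- fit_one(x[resp_rows])
  idx_x <- 1 + seq_len(p)       # columns holding lags of x
  idx_y <- 1 + p + seq_len(p)   # columns holding lags of y
  co_y <- fy$coef; co_x <- fx$coef
  co_y[is.na(co_y)] <- 0; co_x[is.na(co_x)] <- 0
  list(a = unname(co_y[idx_x]),      # x -> y
       a_rev = unname(co_x[idx_y]),  # y -> x
       b = unname(co_y[idx_y]),
       b_rev = unname(co_x[idx_x]),
       resid = fy$resid, resid_rev = fx$resid,
       p = p, flagged = fy$flagged || fx$flagged)
}

#' Directed effective-connectivity matrix of one window
#'
#' Entry (i, j) is the signed influence of ROI i on ROI j: the sum over lags
#' of the path coefficients from the pairwise fit with x = i, y = j (at
#' p = 1 this is the single lag-1 coefficient). Rank-deficient pair fits are
#' recorded and their entries set to 0.
#'
#' @param w Window matrix, time points x ROIs (the ROI subset).
#' @param p VAR order.
#' @return Matrix with zero diagonal, attribute `flagged_pairs` (two-column
#'   matrix of flagged (i, j) pairs, possibly empty).
#' @export
window_ec_matrix <- function(w, p = 1) {
  n <- ncol(w)
  ec <- matrix(0, n, n)
  flagged <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      f <- fit_pair_gc(w[, i], w[, j], p = p)
      if (f$flagged) {
        flagged <- rbind(flagged, c(i, j), c(j, i))
        next
      }
      ec[i, j] <- sum(f$a)      # i -> j
      ec[j, i] <- sum(f$a_rev)  # j -> i
    }
  }
  dimnames(ec) <- list(colnames(w), colnames(w))
  structure(ec, flagged_pairs = flagged)
}

#' Windowed dynamic effective connectivity of one subject
#'
#' Slides a window over the ROI-subset time series and fits the pairwise
#' Granger model in each, yielding one directed EC matrix per window.
#'
#' @param ts A [subject_ts()] or T x N matrix.
#' @param roi_subset Atlas column indices to analyse (>= 2).
#' @param length_tr,step_tr Window shape (defaults 22 / 1).
#' @param p VAR order (default 1).
#' @return List of class `dec_series`: `ec` (list of matrices), `windows`
#'   (the [make_windows()] table), `roi_subset`, `subject_id`.
#' @export
dec_series <- function(ts, roi_subset, length_tr = 22, step_tr = 1, p = 1) {
  m <- if (inherits(ts, "subject_ts")) ts$data else as.matrix(ts)
  if (length(roi_subset) < 2) stop("roi_subset needs at least 2 ROIs")
  if (max(roi_subset) > ncol(m)) stop("roi_subset outside matrix columns")
  sub <- m[, roi_subset, drop = FALSE]
  win <- make_windows(nrow(m), length_tr, step_tr)
  ec <- purrr::map(seq_len(nrow(win)), function(i) {
    window_ec_matrix(sub[win$start[i]:win$end[i], , drop = FALSE], p = p)
  })
  structure(list(ec = ec, windows = win, roi_subset = roi_subset,
                 subject_id = if (inherits(ts, "subject_ts"))
                   ts$subject_id else NA_character_),
            class = "dec_series")
}

#' @export
print.dec_series <- function(x, ...) {
  cat(sprintf("<dec_series> %s: %d windows x %d ROIs\n",
              x$subject_id, length(x$ec), length(x$roi_subset)))
  invisible(x)
}

# Vectorize an EC matrix: all off-diagonal entries in row-major ordered-pair
# order (fixed convention shared with state_centroid_matrices).
vectorize_ec <- function(ec) {
  n <- nrow(ec)
  t(ec)[t(row(ec) != col(ec))]
}

devectorize_ec <- function(v, n) {
  ec <- matrix(0, n, n)
  idx <- which(t(row(ec) != col(ec)))
  m <- t(ec)
  m[idx] <- v
  t(m)
}
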