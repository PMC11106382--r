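#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to label permutation), ~0 for independent
#' ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Majority regime label per sliding window
#'
#' Reduces a per-timepoint regime sequence to one label per window (the most
#' frequent regime inside the window, earliest regime on ties), for
#' comparison with window-level state assignments.
#'
#' @param state_sequence Integer regime labels, length T.
#' @param windows Window table from [make_windows()].
#' @return Integer vector, one label per window.
#' @export
window_majority_labels <- function(state_sequence, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    seg <- state_sequence[windows$start[i]:windows$end[i]]
    as.integer(names(which.max(table(seg))))
  }, integer(1))
}
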