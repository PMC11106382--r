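#' Per-state causal-flow measures
#'
#' For each subject and state, averages the subject's EC matrices over the
#' windows assigned to that state; the row sums of the mean matrix are the
#' out-weighted degrees (summed influence from each node to all others) and
#' the column sums the in-weighted degrees. Subjects with no windows in a
#' state yield missing values.
#'
#' @param dec_list List of [dec_series()] objects.
#' @param model Fitted `state_model` over the pooled windows.
#' @param window_info Bookkeeping tibble from [pool_ec_windows()] aligned
#'   with `model$assignments`.
#' @return Tibble `subject_id`, `state`, `node` (position within the ROI
#'   subset), `in_weighted`, `out_weighted`, `n_windows`.
#' @export
causal_flow <- function(dec_list, model, window_info) {
  stopifnot(nrow(window_info) == length(model$assignments))
  rows <- list()
  for (d in dec_list) {
    sel <- window_info$subject_id == d$subject_id
    assign_sub <- model$assignments[sel]
    n <- length(d$roi_subset)
    for (s in seq_len(model$k)) {
      wins <- which(assign_sub == s)
      if (!length(wins)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = d$subject_id, state = s, node = seq_len(n),
          in_weighted = NA_real_, out_weighted = NA_real_, n_windows = 0L)
        next
      }
      mean_ec <- Reduce(`+`, d$ec[wins]) / length(wins)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = d$subject_id, state = s, node = seq_len(n),
        in_weighted = colSums(mean_ec), out_weighted = rowSums(mean_ec),
        n_windows = length(wins))
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-state mean EC edge table
#'
#' Each subject's mean EC matrix per state, unrolled to directed edges; the
#' unit later tested between groups.
#'
#' @inheritParams causal_flow
#' @return Tibble `subject_id`, `state`, `from`, `to`, `ec`.
#' @export
state_edge_table <- function(dec_list, model, window_info) {
  rows <- list()
  for (d in dec_list) {
    sel <- window_info$subject_id == d$subject_id
    assign_sub <- model$assignments[sel]
    n <- length(d$roi_subset)
    pairs <- which(row(diag(n)) != col(diag(n)))
    for (s in seq_len(model$k)) {
      wins <- which(assign_sub == s)
      if (!length(wins)) next
      mean_ec <- Reduce(`+`, d$ec[wins]) / length(wins)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = d$subject_id, state = s,
        from = row(mean_ec)[pairs], to = col(mean_ec)[pairs],
        ec = mean_ec[pairs])
    }
  }
  dplyr::bind_rows(rows)
}

#' Covariate-adjusted two-group comparison
#'
#' Fits `value ~ group + age + sex` by least squares and reports the t
#' statistic and two-sided p of the group term (patient vs control).
#' Constant covariates are dropped, so with no usable covariates the test
#' reduces to the classical pooled-variance two-sample t-test. The reported
#' direction is the sign of (patient mean - control mean) of the raw values.
#'
#' @param values Per-subject scalars, aligned with `manifest` rows (or named
#'   by subject id).
#' @param manifest Cohort manifest tibble (`subject_id`, `group`, `age`,
#'   `sex`).
#' @return One-row tibble: `t`, `p`, `mean_patient`, `mean_control`,
#'   `direction`, `n_patient`, `n_control`.
#' @export
adjusted_group_test <- function(values, manifest) {
  if (!is.null(names(values))) {
    values <- values[manifest$subject_id]
  }
  df <- tibble::tibble(value = as.numeric(values),
                       group = factor(manifest$group,
                                      levels = c("control", "patient")),
                       age = manifest$age, sex = manifest$sex)
  df <- df[stats::complete.cases(df), ]
  if (min(table(df$group)) < 3) {
    stop("need >= 3 non-missing subjects per group")
  }
  keep_cov <- function(v) length(unique(v)) > 1
  form <- stats::reformulate(
    c("group", if (keep_cov(df$age)) "age", if (keep_cov(df$sex)) "sex"),
    response = "value")
  fit <- stats::lm(form, data = df)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased)) {
    stop("singular design: collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  co <- summary(fit)$coefficients
  mp <- mean(df$value[df$group == "patient"])
  mc <- mean(df$value[df$group == "control"])
  tibble::tibble(
    t = co["grouppatient", "t value"],
    p = co["grouppatient", "Pr(>|t|)"],
    mean_patient = mp, mean_control = mc,
    direction = ifelse(mp >= mc, "increased", "decreased"),
    n_patient = sum(df$group == "patient"),
    n_control = sum(df$group == "control"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1, returned in the
#' input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
fdr_bh <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation using average ranks for ties; the two-sided p-value uses
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Paired numeric vectors (>= 4 complete pairs).
#' @return One-row tibble `rho`, `p`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired non-missing observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("rho undefined for a constant vector")
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(rho = rho, p = p, n = n)
}

#' Group tests over a long table of per-subject measurements
#'
#' Runs [adjusted_group_test()] for every measurement unit and applies BH-FDR
#' within the stated family columns.
#'
#' @param df Long tibble with a `subject_id`, a `value` column, and unit
#'   columns (e.g. `node`, `metric`, `state`).
#' @param manifest Cohort manifest.
#' @param unit_cols Character vector of columns identifying one test unit.
#' @param family_cols Columns defining an FDR family (adjustment is applied
#'   within each combination); default: all tests form one family.
#' @return Tibble of one [adjusted_group_test()] row per unit plus `p_fdr`.
#' @export
group_test_table <- function(df, manifest, unit_cols,
                             family_cols = character(0)) {
  nested <- dplyr::group_by(df, dplyr::across(dplyr::all_of(unit_cols)))
  res <- dplyr::reframe(nested, {
    v <- stats::setNames(.data$value, .data$subject_id)
    # units that cannot be tested (e.g. too few non-missing subjects in a
    # state) are skipped, per the listwise-exclusion rule
    tryCatch(adjusted_group_test(v, manifest),
             error = function(e) tibble::tibble())
  })
  if (length(family_cols)) {
    res <- dplyr::mutate(
      dplyr::group_by(res, dplyr::across(dplyr::all_of(family_cols))),
      p_fdr = fdr_bh(.data$p))
    res <- dplyr::ungroup(res)
  } else {
    res$p_fdr <- fdr_bh(res$p)
  }
  res
}

#' Report nodes with abnormal nodal topology
#'
#' From the nodal AUC group tests (FDR within each metric family), lists the
#' nodes significant on any of the three nodal metrics, labelled
#' increased/decreased by the sign of the patient-minus-control mean. This
#' list is the default ROI subset handed to the dynamic
#' effective-connectivity stage.
#'
#' @param auc_tests Result of [group_test_table()] on a [nodal_auc_table()]
#'   (unit columns `node`, `metric`; family column `metric`).
#' @param alpha Significance level on the FDR-adjusted p (default 0.05).
#' @param atlas Optional atlas to attach ROI abbreviations.
#' @return Tibble `node`, `metric`, `t`, `p`, `p_fdr`, `direction` (one row
#'   per significant node x metric), ordered by node. Empty (with a message)
#'   if nothing is significant.
#' @export
abnormal_node_report <- function(auc_tests, alpha = 0.05, atlas = NULL) {
  sig <- dplyr::filter(auc_tests, .data$p_fdr < alpha)
  sig <- dplyr::arrange(sig, .data$node, .data$metric)
  if (!nrow(sig)) {
    message("no node survives FDR at alpha = ", alpha)
  }
  if (!is.null(atlas) && nrow(sig)) {
    sig$abbreviation <- atlas$abbreviation[sig$node]
  }
  sig
}
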