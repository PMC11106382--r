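#' Run the whole analysis pipeline
#'
#' Orchestrates the six analysis stages end to end: cohort input (simulated
#' or read from disk), functional connectivity with Fisher z, sparsity-grid
#' graph construction with admissibility screening and metric AUCs,
#' nodal-metric group statistics selecting abnormal ROIs, sliding-window
#' Granger causality over those ROIs, L1 k-means state decomposition, and
#' per-state causal-flow / edge / clinical statistics. Each stage draws its
#' seed deterministically from the master seed, so identical inputs
#' reproduce identical outputs.
#'
#' @param config A [default_config()] list.
#' @param out_dir Output directory; created if needed. `NULL` keeps results
#'   in memory only.
#' @param simulate If `TRUE` (default) generate the cohort with
#'   [simulate_cohort()]; otherwise read it from `data_dir`.
#' @param data_dir Directory holding `manifest.tsv`, optional `clinical.tsv`
#'   and one `<subject_id>.tsv` per subject (used when `simulate = FALSE`).
#' @param atlas Atlas for file input; defaults to the packaged AAL-90.
#' @param seed Master seed (default `config$rng_seed`).
#' @param sim_args Named arguments forwarded to [simulate_cohort()].
#' @param rois Optional atlas indices forced as the ROI subset of the
#'   dynamic stage, overriding the abnormal-node report.
#' @param n_null Null networks per (subject, sparsity) for the small-world
#'   normalisation inside the pipeline (default 10; see the methods
#'   vignette on this choice).
#' @param admissibility Apply the mean-degree / sigma grid screening
#'   (default TRUE).
#' @param verbose Emit per-stage progress messages.
#' @return A list of class `run_record`: per-stage results plus `config`,
#'   `seeds`, `timestamps` and (when `out_dir` is set) `digests` of every
#'   file written.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         simulate = TRUE, data_dir = NULL,
                         atlas = NULL, seed = config$rng_seed,
                         sim_args = list(), rois = NULL,
                         n_null = 10, admissibility = TRUE,
                         verbose = FALSE) {
  t0 <- Sys.time()
  say <- function(stage, ...) if (verbose)
    message(sprintf("[%s] %s", stage, paste0(...)))
  seeds <- list(
    simulate = stage_seed(seed, "simulate"),
    graph = stage_seed(seed, "graph"),
    states = stage_seed(seed, "states")
  )

  ## stage 1: cohort input ---------------------------------------------------
  if (simulate) {
    say("simulate", "generating synthetic cohort")
    cohort <- do.call(simulate_cohort,
                      c(list(config = config, seed = seeds$simulate),
                        sim_args))
  } else {
    if (is.null(data_dir)) stop("simulate = FALSE requires data_dir")
    man_path <- file.path(data_dir, "manifest.tsv")
    if (!file.exists(man_path)) stop("missing manifest: ", man_path)
    manifest <- read_manifest(man_path)
    if (is.null(atlas)) atlas <- read_atlas()
    clin_path <- file.path(data_dir, "clinical.tsv")
    clinical <- if (file.exists(clin_path))
      read_clinical(clin_path, manifest) else NULL
    subjects <- purrr::pmap(manifest, function(subject_id, group, age, sex) {
      read_timeseries(file.path(data_dir, paste0(subject_id, ".tsv")),
                      atlas = atlas, subject_id = subject_id, group = group,
                      age = age, sex = sex, tr_seconds = config$tr_seconds)
    })
    cohort <- list(subjects = subjects, manifest = manifest,
                   clinical = clinical, truth = NULL)
  }
  manifest <- cohort$manifest

  ## stage 2: functional connectivity ---------------------------------------
  say("fc", "Pearson correlation + Fisher z for ",
      length(cohort$subjects), " subjects")
  z_list <- purrr::map(cohort$subjects, function(s) fisher_z(pearson_fc(s)))
  names(z_list) <- manifest$subject_id

  ## stage 3: graph metrics over the sparsity grid ---------------------------
  grid <- sparsity_grid(config)
  n <- nrow(z_list[[1]])
  degree_bound <- 2 * log(n, base = config$log_base)
  say("graph", "thresholding at ", length(grid), " sparsities, ",
      n_null, " nulls each")
  global_rows <- vector("list", length(grid) * length(z_list))
  ri <- 0
  for (gi in seq_along(grid)) {
    for (si in seq_along(z_list)) {
      net <- threshold_by_sparsity(z_list[[si]], grid[gi],
                                   rank_by = config$rank_by)
      nulls <- random_null_networks(net, n_null, config$rewires_per_edge,
                                    seed = seeds$graph + 1000L * gi + si)
      gm <- global_metrics(net, nulls)
      gm$mean_degree <- mean(rowSums(net))
      gm$subject_id <- manifest$subject_id[si]
      gm$group <- manifest$group[si]
      ri <- ri + 1
      global_rows[[ri]] <- gm
    }
  }
  global_records <- dplyr::bind_rows(global_rows)
  if (admissibility) {
    per_s <- dplyr::summarise(
      dplyr::group_by(global_records, .data$sparsity),
      ok = all(.data$mean_degree > degree_bound) & all(.data$sigma > 1.1),
      .groups = "drop")
    admissible <- per_s$sparsity[per_s$ok]
    if (length(admissible) < 2) {
      stop("graph: fewer than 2 admissible sparsities ",
           "(mean degree > ", round(degree_bound, 2),
           " and sigma > 1.1); adjust the grid")
    }
  } else {
    admissible <- grid
  }
  say("graph", "admissible sparsity range ", min(admissible), "-",
      max(admissible))
  nodal_auc <- nodal_auc_table(z_list, admissible, rank_by = config$rank_by)

  ## stage 4: nodal group statistics -> abnormal ROI set ---------------------
  say("stats", "nodal AUC group tests")
  nodal_tests <- group_test_table(
    dplyr::rename(nodal_auc, value = "auc"), manifest,
    unit_cols = c("node", "metric"), family_cols = "metric")
  report <- abnormal_node_report(nodal_tests, alpha = config$alpha,
                                 atlas = atlas)
  roi_subset <- rois %||% sort(unique(report$node))
  if (length(roi_subset) < 2) {
    stop("stats: fewer than 2 abnormal ROIs found and no rois= override; ",
         "dynamic stage needs at least 2")
  }

  ## stage 5: sliding-window Granger causality -------------------------------
  say("dec", "windowed Granger causality on ", length(roi_subset), " ROIs")
  dec_list <- purrr::map(cohort$subjects, function(s)
    dec_series(s, roi_subset, length_tr = config$window_length_tr,
               step_tr = config$window_step_tr, p = config$var_order))

  ## stage 6: state decomposition -------------------------------------------
  pooled <- pool_ec_windows(dec_list)
  say("states", "clustering ", nrow(pooled$points), " windows, k in ",
      config$k_min, "..", config$k_max)
  sel <- select_k(pooled$points, k_range = config$k_min:config$k_max,
                  seed = seeds$states, n_restarts = config$n_restarts)
  model <- sel$models[[as.character(sel$k_best)]]
  occupancy <- state_occupancy(model, pooled$window_info, manifest)

  ## stage 7: per-state statistics -------------------------------------------
  say("stats", "causal flow and edge tests in ", model$k, " states")
  flows <- causal_flow(dec_list, model, pooled$window_info)
  flow_long <- tidyr::pivot_longer(flows, c("in_weighted", "out_weighted"),
                                   names_to = "measure", values_to = "value")
  flow_tests <- group_test_table(flow_long, manifest,
                                 unit_cols = c("state", "node", "measure"),
                                 family_cols = c("state", "measure"))
  edges <- state_edge_table(dec_list, model, pooled$window_info)
  edge_tests <- group_test_table(
    dplyr::rename(edges, value = "ec"), manifest,
    unit_cols = c("state", "from", "to"), family_cols = "state")

  clinical_tests <- NULL
  if (!is.null(cohort$clinical) && nrow(cohort$clinical) >= 4 &&
      nrow(report) > 0) {
    clinical_tests <- clinical_correlations(cohort$clinical, nodal_auc,
                                            report, flow_long, manifest)
  }

  record <- structure(list(
    config = config, seeds = seeds, manifest = manifest,
    z_list = z_list, global_records = global_records,
    admissible_sparsity = admissible, nodal_auc = nodal_auc,
    nodal_tests = nodal_tests, abnormal_nodes = report,
    roi_subset = roi_subset, dec_list = dec_list,
    selection = sel[c("k_best", "curves")], state_model = model,
    occupancy = occupancy, flows = flows, flow_tests = flow_tests,
    edge_tests = edge_tests, clinical_tests = clinical_tests,
    truth = cohort$truth, window_info = pooled$window_info,
    timestamps = list(start = t0, end = Sys.time())), class = "run_record")

  if (!is.null(out_dir)) {
    record$digests <- write_run_outputs(record, out_dir)
  }
  record
}

# Spearman tests of clinical variables against abnormal-node AUCs and flow
# measures (patients only), BH-FDR within each clinical variable.
clinical_correlations <- function(clinical, nodal_auc, report, flow_long,
                                  manifest) {
  pats <- manifest$subject_id[manifest$group == "patient"]
  clin <- clinical[match(pats, clinical$subject_id), ]
  units <- list()
  auc_units <- dplyr::distinct(report[, c("node", "metric")])
  for (i in seq_len(nrow(auc_units))) {
    sub <- dplyr::filter(nodal_auc, .data$node == auc_units$node[i],
                         .data$metric == auc_units$metric[i])
    v <- sub$auc[match(pats, sub$subject_id)]
    units[[paste0("auc.", auc_units$metric[i], ".node",
                  auc_units$node[i])]] <- v
  }
  flow_units <- dplyr::distinct(flow_long[, c("state", "node", "measure")])
  for (i in seq_len(nrow(flow_units))) {
    sub <- dplyr::filter(flow_long, .data$state == flow_units$state[i],
                         .data$node == flow_units$node[i],
                         .data$measure == flow_units$measure[i])
    v <- sub$value[match(pats, sub$subject_id)]
    units[[paste0("flow.", flow_units$measure[i], ".state",
                  flow_units$state[i], ".node", flow_units$node[i])]] <- v
  }
  rows <- list()
  for (var in c("nhs3", "duration_months")) {
    for (u in names(units)) {
      ok <- stats::complete.cases(clin[[var]], units[[u]])
      if (sum(ok) < 4) next
      if (length(unique(clin[[var]][ok])) < 2 ||
          length(unique(units[[u]][ok])) < 2) next
      r <- spearman_assoc(clin[[var]], units[[u]])
      r$clinical <- var
      r$unit <- u
      rows[[length(rows) + 1]] <- r
    }
  }
  if (!length(rows)) return(NULL)
  res <- dplyr::bind_rows(rows)
  res <- dplyr::mutate(dplyr::group_by(res, .data$clinical),
                       p_fdr = fdr_bh(.data$p))
  dplyr::ungroup(res)
}

# Write the run's tabular outputs and return their md5 digests.
write_run_outputs <- function(record, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (is.null(df)) return(NULL)
    readr::write_tsv(df, file.path(out_dir, name), progress = FALSE)
    name
  }
  files <- c(
    wr(record$manifest, "manifest.tsv"),
    wr(record$global_records, "global_metrics.tsv"),
    wr(record$nodal_auc, "nodal_auc.tsv"),
    wr(record$nodal_tests, "nodal_tests.tsv"),
    wr(record$abnormal_nodes, "abnormal_nodes.tsv"),
    wr(record$selection$curves, "selection_curves.tsv"),
    wr(record$occupancy, "occupancy.tsv"),
    wr(record$flows, "causal_flow.tsv"),
    wr(record$flow_tests, "flow_tests.tsv"),
    wr(record$edge_tests, "edge_tests.tsv"),
    wr(record$clinical_tests, "clinical_tests.tsv")
  )
  n_roi <- length(record$roi_subset)
  cents <- state_centroid_matrices(record$state_model, n_roi)
  for (i in seq_along(cents)) {
    f <- sprintf("state_%d_centroid.tsv", i)
    write_matrix(cents[[i]], file.path(out_dir, f),
                 labels = as.character(record$roi_subset),
                 kind = "ec_state_centroid")
    files <- c(files, f, paste0(f, ".json"))
  }
  jsonlite::write_json(
    list(seeds = record$seeds,
         config = record$config[setdiff(names(record$config), "log_base")],
         roi_subset = record$roi_subset,
         k_best = record$selection$k_best),
    file.path(out_dir, "run_config.json"), auto_unbox = TRUE)
  files <- c(files, "run_config.json")
  digests <- tools::md5sum(file.path(out_dir, files))
  names(digests) <- files
  digests
}

#' @export
print.run_record <- function(x, ...) {
  cat("<run_record>\n")
  cat("  subjects:        ", nrow(x$manifest), "\n")
  cat("  admissible grid: ", min(x$admissible_sparsity), "-",
      max(x$admissible_sparsity), "\n")
  cat("  abnormal ROIs:   ", paste(sort(unique(x$abnormal_nodes$node)),
                                   collapse = ", "), "\n")
  cat("  states (k):      ", x$selection$k_best, "\n")
  invisible(x)
}
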