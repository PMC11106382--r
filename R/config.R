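#' Default run configuration
#'
#' Holds every tunable the pipeline uses. Defaults follow the study design
#' the package emulates: sparsity grid 0.10-0.34 in steps of 0.01, sliding
#' window of 22 TR with step 1, TR = 2 s, VAR order 1, candidate state counts
#' 2-10, 100 degree-preserving null networks, alpha = 0.05, and a
#' 0.01-0.08 Hz passband.
#'
#' @param ... Named overrides of any default field.
#' @return A validated list of class `run_config`.
#' @export
#' @examples
#' cfg <- default_config(sparsity_max = 0.30)
#' cfg$window_length_tr * cfg$tr_seconds # window duration in seconds
default_config <- function(...) {
  cfg <- list(
    sparsity_min = 0.10,
    sparsity_max = 0.34,
    sparsity_step = 0.01,
    window_length_tr = 22L,
    window_step_tr = 1L,
    tr_seconds = 2,
    var_order = 1L,
    k_min = 2L,
    k_max = 10L,
    n_null_networks = 100L,
    rewires_per_edge = 10L,
    rng_seed = 1L,
    alpha = 0.05,
    bandpass_low_hz = 0.01,
    bandpass_high_hz = 0.08,
    rank_by = "signed",
    log_base = exp(1),
    n_restarts = 50L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "run_config"))
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!(sparsity_min > 0 && sparsity_min < sparsity_max && sparsity_max < 1))
      stop("invalid sparsity bounds: need 0 < sparsity_min < sparsity_max < 1")
    if (sparsity_step <= 0) stop("invalid sparsity_step: must be positive")
    if (window_length_tr < var_order + 2)
      stop("invalid window_length_tr: must be >= var_order + 2")
    if (window_step_tr < 1) stop("invalid window_step_tr: must be >= 1")
    if (tr_seconds <= 0) stop("invalid tr_seconds: must be positive")
    if (var_order < 1) stop("invalid var_order: must be a positive integer")
    if (k_min < 2) stop("invalid k_min: must be >= 2")
    if (k_max < k_min) stop("invalid k_max: must be >= k_min")
    if (n_null_networks < 1) stop("invalid n_null_networks")
    if (alpha <= 0 || alpha >= 1) stop("invalid alpha")
    if (!(bandpass_low_hz < bandpass_high_hz))
      stop("invalid bandpass: bandpass_low_hz must be < bandpass_high_hz")
    if (!rank_by %in% c("signed", "abs")) stop("invalid rank_by")
  })
  cfg
}

#' Load a run configuration from YAML or JSON
#'
#' Absent keys take the [default_config()] values; invariant violations are
#' rejected naming the offending field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for pure
#'   defaults.
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(default_config())
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be YAML or JSON, got .", ext)
  )
  if (is.null(raw)) raw <- list()
  do.call(default_config, raw)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Sparsity grid implied by a configuration
#'
#' @param cfg A `run_config`.
#' @return Numeric vector from `sparsity_min` to `sparsity_max` in steps of
#'   `sparsity_step`.
#' @export
sparsity_grid <- function(cfg = default_config()) {
  round(seq(cfg$sparsity_min, cfg$sparsity_max, by = cfg$sparsity_step), 10)
}

# Deterministic per-stage seed derived from the master seed: 32-bit hash of
# the stage name XOR'd with the seed, kept in [0, 2^31).
stage_seed <- function(master_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  bitwXor(as.integer(h), as.integer(master_seed)) %% 2147483647L
}
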