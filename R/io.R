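#' Read an atlas label table
#'
#' An atlas table maps 1-based node indices to ROI abbreviations and
#' hemispheres. The packaged default is the 90-node AAL cortical/subcortical
#' parcellation (45 regions per hemisphere, left = odd indices).
#'
#' @param path Path to a tab-separated file with columns `index`,
#'   `abbreviation`, `hemisphere`. `NULL` (default) loads the packaged
#'   AAL-90 table.
#' @return A tibble with columns `index` (integer), `abbreviation`
#'   (character, unique), `hemisphere` ("L"/"R").
#' @export
#' @examples
#' atlas <- read_atlas()
#' nrow(atlas) # 90
read_atlas <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aal90.tsv", package = "braindec")
  }
  atlas <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  atlas <- tibble::as_tibble(atlas)
  validate_atlas(atlas)
  atlas$index <- as.integer(atlas$index)
  atlas
}

validate_atlas <- function(atlas) {
  need <- c("index", "abbreviation", "hemisphere")
  if (!all(need %in% names(atlas))) {
    stop("atlas must have columns: ", paste(need, collapse = ", "))
  }
  n <- nrow(atlas)
  if (n < 2) stop("atlas must contain more than one node")
  if (!identical(as.integer(atlas$index), seq_len(n))) {
    stop("atlas indices must be consecutive 1..N")
  }
  if (anyDuplicated(atlas$abbreviation)) {
    stop("atlas abbreviations must be unique")
  }
  invisible(atlas)
}

#' Construct a subject time-series object
#'
#' Bundles one subject's T x N ROI signal matrix with its metadata. Rows are
#' time points sampled every `tr_seconds`; columns are atlas ROIs in atlas
#' order.
#'
#' @param data Numeric T x N matrix, finite entries, T >= 2.
#' @param subject_id Subject identifier.
#' @param group `"patient"` or `"control"`.
#' @param age Age in years.
#' @param sex `"M"` or `"F"`.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @return An object of class `subject_ts`.
#' @export
subject_ts <- function(data, subject_id, group = NA_character_,
                       age = NA_real_, sex = NA_character_, tr_seconds = 2) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("time series needs at least 2 time points")
  if (!all(is.finite(data))) stop("time series contains non-finite values")
  structure(
    list(data = data, subject_id = as.character(subject_id),
         group = group, age = age, sex = sex, tr_seconds = tr_seconds),
    class = "subject_ts"
  )
}

#' @export
print.subject_ts <- function(x, ...) {
  cat(sprintf("<subject_ts> %s (%s): %d time points x %d ROIs, TR = %gs\n",
              x$subject_id, x$group %||% "?", nrow(x$data), ncol(x$data),
              x$tr_seconds))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Read one subject's ROI time series
#'
#' Expects tab-separated text with one header row of ROI abbreviations and T
#' numeric rows. Columns are re-ordered to atlas order; every atlas ROI must
#' be present exactly once.
#'
#' @param path File path.
#' @param atlas Atlas tibble (see [read_atlas()]); defines the required
#'   columns and their order.
#' @param subject_id,group,age,sex,tr_seconds Metadata passed to
#'   [subject_ts()]; `subject_id` defaults to the file name.
#' @return A `subject_ts` whose columns follow atlas order.
#' @export
read_timeseries <- function(path, atlas = read_atlas(),
                            subject_id = NULL, group = NA_character_,
                            age = NA_real_, sex = NA_character_,
                            tr_seconds = 2) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!setequal(names(df), atlas$abbreviation) ||
      ncol(df) != nrow(atlas)) {
    stop("time-series columns do not match atlas ROI set in ", path)
  }
  df <- df[, atlas$abbreviation, drop = FALSE]
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cell in ", path)
  storage.mode(m) <- "double"
  colnames(m) <- atlas$abbreviation
  subject_ts(m, subject_id %||% sub("\\.[^.]*$", "", basename(path)),
             group = group, age = age, sex = sex, tr_seconds = tr_seconds)
}

#' Write / read a numeric matrix as headerless TSV
#'
#' Values are written with 15 significant digits so a write-then-read
#' round-trip reproduces them to at least 12 significant digits. When
#' `labels` or `kind` are given, a companion JSON sidecar
#' (`<path>.json`) records the row/column ROI labels and the matrix kind
#' (e.g. `"fc"`, `"z"`, `"adjacency"`, `"ec"`).
#'
#' @param m Numeric matrix with finite entries.
#' @param path File path.
#' @param labels Optional character vector of row/column labels for the
#'   sidecar.
#' @param kind Optional matrix kind string for the sidecar.
#' @return `read_matrix()` returns a numeric matrix (with a `sidecar`
#'   attribute when one is found); `write_matrix()` returns `path`
#'   invisibly.
#' @export
write_matrix <- function(m, path, labels = NULL, kind = NULL) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) stop("matrix contains non-finite entries")
  lines <- apply(m, 1, function(r) paste(sprintf("%.15g", r), collapse = "\t"))
  writeLines(lines, path)
  if (!is.null(labels) || !is.null(kind)) {
    jsonlite::write_json(
      list(labels = labels, kind = kind, nrow = nrow(m), ncol = ncol(m)),
      paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1) stop("ragged rows in ", path)
  m <- matrix(as.numeric(unlist(rows)), nrow = length(rows),
              ncol = widths[1], byrow = TRUE)
  if (anyNA(m)) stop("non-numeric cell in ", path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(m, "sidecar") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  m
}

#' Read a cohort manifest
#'
#' @param path Tab-separated file with columns `subject_id`, `group`
#'   (`patient`/`control`), `age`, `sex` (`M`/`F`).
#' @return A tibble; subject ids must be unique.
#' @export
read_manifest <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                            stringsAsFactors = FALSE))
  validate_manifest(df)
}

validate_manifest <- function(df) {
  need <- c("subject_id", "group", "age", "sex")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id in manifest")
  if (!all(df$group %in% c("patient", "control"))) {
    stop("manifest group must be 'patient' or 'control'")
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Read a clinical table
#'
#' @param path Tab-separated file with columns `subject_id`,
#'   `duration_months`, `nhs3` (seizure-severity score).
#' @param manifest Optional manifest tibble; if given, clinical subject ids
#'   must be a subset of its patient ids.
#' @return A tibble.
#' @export
read_clinical <- function(path, manifest = NULL) {
  df <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                            stringsAsFactors = FALSE))
  need <- c("subject_id", "duration_months", "nhs3")
  if (!all(need %in% names(df))) {
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$duration_months < 0) || any(df$nhs3 < 0)) {
    stop("duration_months and nhs3 must be non-negative")
  }
  df$subject_id <- as.character(df$subject_id)
  if (!is.null(manifest)) {
    pat <- manifest$subject_id[manifest$group == "patient"]
    if (!all(df$subject_id %in% pat)) {
      stop("clinical subject_ids must be a subset of manifest patient ids")
    }
  }
  df
}
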