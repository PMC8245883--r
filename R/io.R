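#' Load simulation settings from a JSON or YAML config file
#'
#' The config mirrors the [cohort_params()] field names exactly; any subset
#' may be given and the rest are filled from the defaults. A handful of study
#' settings (`n_replicates`, `alpha`, `n_grid`, `seed`) may sit alongside
#' them. Unknown keys are rejected by name; out-of-range values are rejected
#' with the violated bound.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file. An empty file (or
#'   empty mapping) yields the full default parameter set.
#' @return List with `params` (a [cohort_params()] object) and `study` (named
#'   list of study settings present in the file).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be .json, .yaml or .yml", call. = FALSE))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a mapping of named fields",
                          call. = FALSE)

  param_fields <- names(formals(cohort_params))
  study_fields <- c("n_replicates", "alpha", "n_grid", "seed")
  unknown <- setdiff(names(raw), c(param_fields, study_fields))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  params <- do.call(cohort_params, raw[intersect(names(raw), param_fields)])
  list(params = params, study = raw[intersect(names(raw), study_fields)])
}

#' Write cohort parameters to a config file
#'
#' Round-trips through [load_config()]: reloading reproduces the identical
#' parameter object.
#'
#' @param params A [cohort_params()] object.
#' @param path Output path; format chosen from the extension as in
#'   [load_config()].
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  params <- validate_cohort_params(params)
  ext <- tolower(tools::file_ext(path))
  x <- unclass(params)
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml = yaml::write_yaml(x, path),
    stop("config must be .json, .yaml or .yml", call. = FALSE))
  invisible(path)
}

cohort_csv_columns <- c("id", "exposed", "true_baseline_kb", "true_change_kb",
                        "true_followup_kb", "proxy_baseline", "proxy_followup")

#' Read and write cohort CSV files
#'
#' Wide format, one row per individual, header mandatory, '.' decimal
#' separator. Columns: `id, exposed, true_baseline_kb, true_change_kb,
#' true_followup_kb, proxy_baseline, proxy_followup`; the two proxy columns
#' may be absent (truth-only cohort). Numeric values are serialized with 17
#' significant digits so that write-then-read reproduces the cohort
#' bit-identically.
#'
#' @param cohort A `telo_cohort` (or compatible data frame).
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a `telo_cohort` (without generating
#'   parameters: user-supplied cohorts carry their data only).
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- intersect(cohort_csv_columns, names(cohort))
  if (!all(c("id", "exposed", "true_baseline_kb") %in% cols))
    stop("not a cohort: missing core columns", call. = FALSE)
  df <- as.data.frame(cohort)[cols]
  out <- df
  for (nm in setdiff(cols, c("id", "exposed")))
    out[[nm]] <- sprintf("%.17g", df[[nm]])
  out$exposed <- ifelse(df$exposed, "TRUE", "FALSE")
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  if (file.size(path) == 0)
    stop("empty cohort file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0) stop("cohort file has a header but no rows", call. = FALSE)

  required <- c("id", "exposed", "true_baseline_kb", "true_change_kb",
                "true_followup_kb")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("cohort file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), cohort_csv_columns)
  if (length(extra))
    stop("unexpected column(s) in cohort file: ",
         paste(extra, collapse = ", "), call. = FALSE)

  parse_num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                   col, bad[1], df[[col]][bad[1]]), call. = FALSE)
    v
  }
  out <- data.frame(
    id = as.integer(parse_num("id")),
    exposed = df$exposed %in% c("TRUE", "true", "1"),
    true_baseline_kb = parse_num("true_baseline_kb"),
    true_change_kb = parse_num("true_change_kb"),
    true_followup_kb = parse_num("true_followup_kb"),
    proxy_baseline = if ("proxy_baseline" %in% names(df))
      parse_num("proxy_baseline") else NA_real_,
    proxy_followup = if ("proxy_followup" %in% names(df))
      parse_num("proxy_followup") else NA_real_
  )
  structure(out, class = c("telo_cohort", "data.frame"))
}

#' Write a run manifest next to a result file
#'
#' Records everything needed to reproduce a pipeline run: the command label,
#' the fully resolved parameter set, the master seed, the package version, a
#' timestamp, and an MD5 digest of each output file. Re-running with the
#' manifest's parameters and seed reproduces deterministic outputs
#' byte-identically.
#'
#' @param path Manifest output path (JSON).
#' @param command Short label for the pipeline stage.
#' @param params A [cohort_params()] object (or any named list of settings).
#' @param seed The master seed used.
#' @param outputs Character vector of result-file paths to digest.
#' @param extra Optional named list of further settings to record.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, params, seed, outputs = character(),
                               extra = list()) {
  manifest <- list(
    command = command,
    parameters = if (inherits(params, "cohort_params")) unclass(params)
                 else params,
    settings = extra,
    master_seed = seed,
    package_version = as.character(utils::packageVersion("telosim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    output_md5 = as.list(tools::md5sum(outputs[file.exists(outputs)]))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
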