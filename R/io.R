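# Delimited-text and config readers/writers. CSVs use a header row, period
# decimal separator and UTF-8; structured reports are JSON. Values round-trip
# to full double precision (digits = NA on the JSON side, default format on
# the CSV side gives 15 significant digits).

#' Read / write a concentration-time CSV
#'
#' Columns `time_min, conc_ug_per_ml`, header required.
#'
#' @param path File path.
#' @return `read_cp_csv`: a data.frame with columns `time` (min) and `conc`
#'   (ug/mL).
#' @export
read_cp_csv <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  need <- c("time_min", "conc_ug_per_ml")
  if (!all(need %in% names(df)))
    .stopf("concentration CSV must have columns %s; missing: %s",
           paste(need, collapse = ", "),
           paste(setdiff(need, names(df)), collapse = ", "))
  data.frame(time = df$time_min, conc = df$conc_ug_per_ml)
}

#' @rdname read_cp_csv
#' @param samples A data.frame with columns `time` and `conc`.
#' @export
write_cp_csv <- function(samples, path) {
  samples <- as.data.frame(samples)
  if (!all(c("time", "conc") %in% names(samples)))
    .stopf("'samples' needs columns 'time' and 'conc'")
  out <- data.frame(time_min = format(samples$time, digits = 15, trim = TRUE),
                    conc_ug_per_ml = format(samples$conc, digits = 15, trim = TRUE))
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a Hill-parameter CSV
#'
#' Row layout mirroring the combination dose-response tables: columns
#' `label, bottom, top, steepness, ec50`.
#'
#' @param path File path.
#' @return `read_hill_csv`: a data.frame of curve parameters.
#' @export
read_hill_csv <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  need <- c("label", "bottom", "top", "steepness", "ec50")
  if (!all(need %in% names(df)))
    .stopf("Hill CSV must have columns %s; missing: %s",
           paste(need, collapse = ", "),
           paste(setdiff(need, names(df)), collapse = ", "))
  df[need]
}

#' @rdname read_hill_csv
#' @param rows A data.frame with the columns above.
#' @export
write_hill_csv <- function(rows, path) {
  need <- c("label", "bottom", "top", "steepness", "ec50")
  rows <- as.data.frame(rows)
  if (!all(need %in% names(rows)))
    .stopf("'rows' needs columns %s", paste(need, collapse = ", "))
  out <- rows[need]
  for (nm in need[-1]) out[[nm]] <- format(out[[nm]], digits = 15, trim = TRUE)
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a run configuration (JSON or YAML)
#'
#' Configuration keys mirror the constructor arguments of the objects they
#' describe (`pk_parameters`, `dose_regimen`, `simulation_grid`,
#' `hill_curve`, ...); drug/curve entries may instead name a bundled
#' fixture (for example `"gemcitabine"`).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                        simplifyDataFrame = FALSE,
                                        simplifyMatrix = FALSE),
                    error = function(e) .stopf("malformed JSON config '%s': %s",
                                               path, conditionMessage(e))),
    yaml = ,
    yml = tryCatch(yaml::read_yaml(path),
                   error = function(e) .stopf("malformed YAML config '%s': %s",
                                              path, conditionMessage(e))),
    .stopf("unsupported config extension '.%s' (use .json/.yaml/.yml)", ext))
  if (!is.list(cfg)) .stopf("config '%s' did not parse to a mapping", path)
  cfg
}

#' Write a structured report as JSON
#'
#' @param x A list (report).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

# Resolve a drug parameter spec: either a fixture name or an explicit list.
resolve_params <- function(spec, fixtures) {
  if (is.character(spec) && length(spec) == 1L) {
    if (!spec %in% names(fixtures$params))
      .stopf("unknown drug fixture '%s' (have: %s)", spec,
             paste(names(fixtures$params), collapse = ", "))
    return(fixtures$params[[spec]])
  }
  if (is.list(spec))
    return(pk_parameters(spec$Vd1, spec$Vd2, spec$CL, spec$k12, spec$k21,
                         drug = spec$drug))
  .stopf("drug parameters must be a fixture name or a parameter mapping")
}

resolve_regimen <- function(spec, fixtures) {
  if (is.character(spec) && length(spec) == 1L) {
    if (!spec %in% names(fixtures$regimens))
      .stopf("unknown regimen fixture '%s' (have: %s)", spec,
             paste(names(fixtures$regimens), collapse = ", "))
    return(fixtures$regimens[[spec]])
  }
  if (is.list(spec)) {
    args <- spec[intersect(names(spec),
                           c("route", "dose", "rate", "duration", "start_time",
                             "n_doses", "interval"))]
    return(do.call(dose_regimen, args))
  }
  .stopf("regimen must be a fixture name or a regimen mapping")
}

resolve_grid <- function(spec, default_t_end = 400) {
  if (is.null(spec)) return(simulation_grid(default_t_end))
  simulation_grid(t_end = spec$t_end %||% default_t_end,
                  h = spec$h %||% 0.02,
                  method = spec$method %||% "rk4")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
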