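# --- tidy table and config round-trips ------------------------------------

#' Read and write tidy trajectory tables
#'
#' Trajectories are exchanged as plain delimited text with columns
#' `cell_id`, `time_h` and one or more value columns (`value`, or one column
#' per model species). Both 15 and 20 minute sampling (or any mixture) are
#' preserved as-is.
#'
#' @param data a trajectory tibble.
#' @param path file path (`.csv`).
#' @return `write_trajectories()` returns `path` invisibly;
#'   `read_trajectories()` returns a validated tibble.
#' @export
write_trajectories <- function(data, path) {
  check_table(data, c("cell_id", "time_h"), "trajectory")
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_table(out, c("cell_id", "time_h"), "trajectory")
  if (!any(vapply(out, is.numeric, logical(1)))) {
    stop("trajectory table has no numeric value column", call. = FALSE)
  }
  out
}

#' Read and write pulse tables
#'
#' @param data a pulse tibble as returned by [detect_pulses()].
#' @param path file path.
#' @return `write_pulses()` returns `path` invisibly; `read_pulses()` a
#'   validated tibble.
#' @export
write_pulses <- function(data, path) {
  check_table(data, c("cell_id", "peak_time_h", "amplitude", "width_h"),
              "pulse")
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_pulses
#' @export
read_pulses <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_table(out, c("cell_id", "peak_time_h", "amplitude", "width_h"),
              "pulse")
  out
}

#' Read and write foci-count tables
#'
#' @param data a tibble with `cell_id`, `time_h`, `count`.
#' @param path file path.
#' @return `write_foci()` returns `path` invisibly; `read_foci()` a
#'   validated tibble.
#' @export
write_foci <- function(data, path) {
  check_table(data, c("cell_id", "time_h", "count"), "foci")
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_foci
#' @export
read_foci <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_table(out, c("cell_id", "time_h", "count"), "foci")
  if (any(out$count < 0)) stop("foci table: negative counts", call. = FALSE)
  out
}

check_table <- function(data, required, what) {
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    stop(what, " table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(data)
}

#' Save and load run configurations
#'
#' Configurations bundle the DSB process parameters, the ODE model
#' parameters and ensemble settings into one JSON file with a schema
#' validation on load; validation errors name the offending field.
#'
#' @param config a named list with any of the sections `dsb`, `model`,
#'   `ensemble` plus an optional `seed`.
#' @param path JSON file path.
#' @return `save_config()` returns `path` invisibly; `load_config()` the
#'   validated configuration with `dsb`/`model` realized as parameter
#'   objects.
#' @export
save_config <- function(config, path) {
  validate_config(config)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  config <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(config)
  if (!is.null(config$dsb)) config$dsb <- do.call(dsb_params, config$dsb)
  if (!is.null(config$model)) config$model <- do.call(p53_params, config$model)
  config
}

validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a named list", call. = FALSE)
  if (!is.null(config$dsb)) {
    known <- c("b_b", "b_s", "T_s", "r", "r_c", "f_c")
    bad <- setdiff(names(config$dsb), known)
    if (length(bad)) stop("config$dsb: unknown field(s) ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(config$dsb)) {
      v <- config$dsb[[nm]]
      if (!is.numeric(v) || !is.finite(v)) {
        stop("config$dsb$", nm, " must be a finite number", call. = FALSE)
      }
    }
  }
  if (!is.null(config$model)) {
    known <- names(p53_params())
    bad <- setdiff(names(config$model), known)
    if (length(bad)) stop("config$model: unknown field(s) ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(config$ensemble)) {
    known <- c("n_cells", "N_s", "meanlog", "sdlog", "t_end", "sample_dt",
               "responder_window", "min_amplitude")
    bad <- setdiff(names(config$ensemble), known)
    if (length(bad)) stop("config$ensemble: unknown field(s) ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (!is.null(config$ensemble$n_cells) && config$ensemble$n_cells < 1) {
      stop("config$ensemble$n_cells must be >= 1", call. = FALSE)
    }
  }
  invisible(config)
}
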