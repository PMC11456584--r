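#' Plain-text input/output
#'
#' Signal streams and event logs travel as delimited text (CSV with a
#' commented header line carrying the sampling rate), configurations as YAML,
#' and battery reports as JSON.
#'
#' @name io
NULL

#' Write / read an EMG recording as CSV
#'
#' The first line is a comment \code{# fs=<Hz>}; the body is one column per
#' channel.
#'
#' @param rec an [emg_recording()]
#' @param path file path
#' @return \code{read_emg_csv} returns an [emg_recording()];
#'   \code{write_emg_csv} returns \code{path} invisibly
#' @export
write_emg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec$fs), con)
  utils::write.csv(as.data.frame(rec$samples,
                                 col.names = rec$channel_labels),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emg_csv
#' @export
read_emg_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# fs=", first)) stop("missing '# fs=' header line")
  fs <- as.numeric(sub("^# fs=", "", first))
  df <- utils::read.csv(path, comment.char = "#")
  emg_recording(as.matrix(df), fs, channel_labels = names(df))
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a [sim_config()]
#' @param path file path
#' @return \code{read_config_yaml} returns a [sim_config()]
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$condition_params <- lapply(x$condition_params, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  cp <- lapply(x$condition_params, function(p) do.call(condition_params, p))
  sim_config(seed = x$seed, n_participants = x$n_participants,
             n_blocks_per_condition = x$n_blocks_per_condition,
             block_duration = x$block_duration, emg_fs = x$emg_fs,
             imu_fs = x$imu_fs, feature_rate = x$feature_rate,
             condition_params = cp)
}

#' Write a synthetic study dataset to a directory of CSV files
#'
#' Writes \code{attempts.csv}, \code{drt.csv}, \code{tlx.csv},
#' \code{order.csv} and \code{config.yaml}.
#'
#' @param dataset a [generate_condition_dataset()] result
#' @param dir output directory (created if absent)
#' @return \code{dir}, invisibly
#' @export
write_condition_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "condition_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("attempts", "drt", "tlx", "order")) {
    utils::write.csv(dataset[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  write_config_yaml(dataset$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_condition_dataset
#' @export
read_condition_dataset <- function(dir) {
  out <- lapply(c(attempts = "attempts", drt = "drt", tlx = "tlx",
                  order = "order"), function(nm) {
    df <- utils::read.csv(file.path(dir, paste0(nm, ".csv")))
    if ("participant" %in% names(df)) df$participant <- factor(df$participant)
    df
  })
  out$config <- read_config_yaml(file.path(dir, "config.yaml"))
  structure(out, class = "condition_dataset")
}

#' Write a battery report as JSON
#'
#' @param report a [run_full_battery()] result
#' @param path file path
#' @return \code{path}, invisibly
#' @export
write_battery_json <- function(report, path) {
  stopifnot(inherits(report, "battery_report"))
  jsonlite::write_json(report$table, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
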