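# Plain-text I/O: trial logs and trajectories as CSV, model configuration as
# YAML, fluorescence arrays as long-format CSV with a JSON sidecar.

#' Read a trial log from CSV
#'
#' Expects columns `trial`, `stimulus` (`S_PLUS`/`S_MINUS`), `response`.
#'
#' @param path CSV file path.
#' @return A [trial_log()].
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("trial", "stimulus", "response") %in% names(df)))
  df <- df[order(df$trial), ]
  trial_log(df$stimulus, df$response)
}

#' Write a trial log to CSV
#'
#' @param log A [trial_log()].
#' @param path CSV file path.
#' @export
write_trial_log <- function(log, path) {
  utils::write.csv(log[, c("trial", "stimulus", "response")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a learning trajectory to CSV
#'
#' Columns: `step,p_splus,p_sminus,performance,wE_c,wE_sm,wE_sp,wI_c,wI_sm,
#' wI_sp` (plus `stimulus,response,reward` in stochastic mode).
#'
#' @param traj An `rw_trajectory`.
#' @param path CSV file path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Read a model configuration from YAML
#'
#' Sections: `model` (`alpha`, `sigma`, `v`, `floor`, `seed`), `scenario`
#' (`common`, `weak`, `strong`, `larger_side`), `run` (`n_trials`, `mode`).
#'
#' @param path YAML file path.
#' @return A list with `params` ([rw_params()]), `scenario`
#'   ([recruitment_scenario()]) and `run` settings.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  m <- cfg$model
  s <- cfg$scenario
  list(
    params = rw_params(alpha = m$alpha %||% 0.01,
                       sigma = m$sigma %||% 0.6195,
                       v = m$v %||% 6,
                       floor = m$floor %||% 1e-6,
                       seed = m$seed),
    scenario = recruitment_scenario(common = s$common %||% 1,
                                    weak = s$weak %||% 1,
                                    strong = s$strong %||% 2,
                                    larger = s$larger_side %||% "S_PLUS"),
    run = cfg$run
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write probe results as JSON records
#'
#' @param probes A data frame with `probe` and `probability` columns (as in
#'   the `probes` table of [run_strategy_probe()]).
#' @param path JSON file path.
#' @export
write_probe_json <- function(probes, path) {
  jsonlite::write_json(probes, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Write a fluorescence dataset as long-format CSV with a JSON sidecar
#'
#' The traces go to `<path>.csv` with columns `neuron,trial,time,value`
#' (plus `neuropil` when present); frame rate, labels, and event times go to
#' `<path>.json`.
#'
#' @param dataset A [fluorescence_dataset()].
#' @param path Base path (without extension).
#' @export
write_fluorescence <- function(dataset, path) {
  d <- dim(dataset$traces)
  idx <- expand.grid(neuron = seq_len(d[1L]), trial = seq_len(d[2L]),
                     time = seq_len(d[3L]))
  df <- data.frame(idx, value = as.numeric(dataset$traces))
  if (!is.null(dataset$neuropil_traces))
    df$neuropil <- as.numeric(dataset$neuropil_traces)
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(frame_rate = dataset$frame_rate,
         stimulus_labels = dataset$stimulus_labels,
         onset_s = dataset$onset_s, offset_s = dataset$offset_s,
         dim = d),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fluorescence dataset written by [write_fluorescence()]
#'
#' @param path Base path (without extension).
#' @return A [fluorescence_dataset()].
#' @export
read_fluorescence <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(path, ".csv"))
  d <- as.integer(meta$dim)
  arr <- array(NA_real_, d)
  arr[cbind(df$neuron, df$trial, df$time)] <- df$value
  np <- NULL
  if ("neuropil" %in% names(df)) {
    np <- array(NA_real_, d)
    np[cbind(df$neuron, df$trial, df$time)] <- df$neuropil
  }
  fluorescence_dataset(arr, frame_rate = meta$frame_rate,
                       stimulus_labels = meta$stimulus_labels,
                       neuropil_traces = np,
                       onset_s = meta$onset_s, offset_s = meta$offset_s)
}
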