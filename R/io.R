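config_defaults <- function() {
  list(n_trials = 20L, duration = 2, dt = 1e-4, lambda = 50, threshold = 0.5,
       tau_ref = 2e-3, sigma_V = default_sigma_V(), delay = 0,
       master_seed = 1L, exclude = 0.5,
       signal = list(kind = "ramped", sigma_x = 1, eta_x = 0.5))
}

config_known_keys <- function() {
  c("M", "rho", "n_trials", "duration", "dt", "lambda", "threshold",
    "tau_ref", "sigma_V", "delay", "master_seed", "exclude", "signal",
    "perturbations")
}

#' Load a benchmark configuration from YAML or JSON
#'
#' Reads a run configuration (format chosen by file extension: `.yaml`/`.yml`
#' or `.json`), validates it strictly — unknown keys are an error naming the
#' key, missing required keys (`M`, `rho`) are an error listing them — fills
#' the declared defaults, and records which values came from defaults.
#'
#' Perturbations are given as a list of records with fields `kind`,
#' `targets` (`"all"` or indices), `magnitude`, `window` and optional `seed`.
#'
#' @param path path to the configuration file.
#' @return A [benchmark_config()] with attribute `defaults_used` naming the
#'   keys that were filled from defaults.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    stop("config must be a .yaml/.yml or .json file"))
  config_from_list(raw)
}

#' @rdname load_config
#' @param raw a named list with the same schema as the file contents.
#' @export
config_from_list <- function(raw) {
  unknown <- setdiff(names(raw), config_known_keys())
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  missing <- setdiff(c("M", "rho"), names(raw))
  if (length(missing))
    stop(sprintf("missing required config key(s): %s",
                 paste(missing, collapse = ", ")))
  defaults <- config_defaults()
  used <- setdiff(names(defaults), names(raw))
  # scalar keys may arrive as length-1 lists from a JSON reader
  raw[setdiff(names(raw), c("signal", "perturbations"))] <-
    lapply(raw[setdiff(names(raw), c("signal", "perturbations"))], unlist)
  full <- modifyList(defaults, raw)
  if (!is.null(full$signal))
    full$signal <- lapply(full$signal, function(v) unlist(v))
  perts <- NULL
  if (!is.null(full$perturbations)) {
    perts <- lapply(full$perturbations, function(p) {
      p <- lapply(as.list(p), unlist)
      targets <- p$targets %||% "all"
      if (!identical(targets, "all")) targets <- as.numeric(targets)
      perturbation(p$kind, targets = targets,
                   magnitude = if (is.null(p$magnitude)) NULL
                               else as.numeric(p$magnitude),
                   window = if (is.null(p$window)) NULL
                            else as.numeric(p$window),
                   seed = p$seed %||% NULL)
    })
  }
  cfg <- benchmark_config(
    M = full$M, rho = full$rho, n_trials = full$n_trials,
    duration = full$duration, dt = full$dt,
    params = network_params(lambda = full$lambda, threshold = full$threshold,
                            tau_ref = full$tau_ref, sigma_V = full$sigma_V,
                            delay = full$delay),
    signal = full$signal, perturbation = perts,
    master_seed = full$master_seed, exclude = full$exclude)
  attr(cfg, "defaults_used") <- used
  cfg
}

#' Save a benchmark configuration
#'
#' Writes the configuration back to YAML or JSON (by extension), such that
#' [load_config()] round-trips it.
#'
#' @param config a [benchmark_config()].
#' @param path destination path (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  lst <- list(M = config$M, rho = config$rho, n_trials = config$n_trials,
              duration = config$duration, dt = config$dt,
              lambda = config$params$lambda,
              threshold = config$params$threshold,
              tau_ref = config$params$tau_ref,
              sigma_V = config$params$sigma_V, delay = config$params$delay,
              master_seed = config$master_seed, exclude = config$exclude,
              signal = config$signal)
  if (!is.null(config$perturbation)) {
    lst$perturbations <- lapply(config$perturbation, function(p)
      Filter(Negate(is.null), list(kind = p$kind, targets = p$targets,
                                   magnitude = p$magnitude, window = p$window,
                                   seed = p$seed)))
  }
  lst$signal <- Filter(Negate(is.null), lst$signal)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(lst, path),
    json = jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                                null = "null"),
    stop("config must be written as .yaml/.yml or .json"))
  invisible(path)
}

#' Canned small networks for examples and tests
#'
#' Deterministic fixtures used across the test suite:
#' * `square4` — the square box: N = 4 axis-aligned decoders, M = 2, T = 0.5.
#' * `polygon21` — regular 21-gon decoders (the near-circular box).
#' * `random_2d_r10` — M = 2, rho = 10 random decoders (fixed seed).
#' * `delayed_2d_r50` — M = 2, rho = 50 random decoders with a 1 ms delay.
#' * `slow_oscillator` — N = 10 random decoders with a rotational slow matrix
#'   `A` generating a 2 Hz oscillation.
#'
#' @param name fixture name.
#' @return A list with `decoders` and `params` (and `A` inside `params` for
#'   the oscillator).
#' @export
make_fixture <- function(name) {
  switch(name,
    square4 = list(decoders = polygon_decoders(4),
                   params = network_params(threshold = 0.5)),
    polygon21 = list(decoders = polygon_decoders(21),
                     params = network_params(threshold = 0.5)),
    random_2d_r10 = list(decoders = random_unit_decoders(2, 20, seed = 101L),
                         params = network_params(threshold = 0.5)),
    delayed_2d_r50 = list(decoders = random_unit_decoders(2, 100, seed = 102L),
                          params = network_params(threshold = 0.5,
                                                  delay = 1e-3)),
    slow_oscillator = {
      # 2 Hz rotational dynamics; the slower leak (100 ms) lets the slow
      # recurrence sustain the oscillation against the readout decay
      om <- 2 * pi * 2
      list(decoders = random_unit_decoders(2, 10, seed = 282L),
           params = network_params(lambda = 10, threshold = 0.5,
                                   A = matrix(c(0, om, -om, 0), 2, 2)))
    },
    stop(sprintf("unknown fixture '%s'", name)))
}

#' Write / read a spike raster as CSV
#'
#' Two columns, `time_s` and `neuron_id`.
#'
#' @param spikes spike data frame (`time_s`, `neuron`).
#' @param path file path.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns the
#'   spike data frame.
#' @export
write_raster <- function(spikes, path) {
  df <- data.frame(time_s = spikes$time_s, neuron_id = spikes$neuron)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE)
  data.frame(time_s = df$time_s, neuron = as.integer(df$neuron_id))
}

#' Write simulation traces as CSV
#'
#' One row per time point: `time_s`, the M readout components, and optionally
#' the N voltages.
#'
#' @param result a `sim_result`.
#' @param path file path.
#' @param voltages include voltage columns (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_traces <- function(result, path, voltages = FALSE) {
  df <- data.frame(time_s = result$times, t(result$xhat))
  names(df) <- c("time_s", paste0("xhat", seq_len(nrow(result$xhat))))
  if (voltages && !is.null(result$V)) {
    Vd <- as.data.frame(t(result$V))
    names(Vd) <- paste0("V", seq_len(nrow(result$V)))
    df <- cbind(df, Vd)
  }
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' A JSON-serializable record from which an experiment can be re-run
#' bit-identically: the full configuration, the master seed, the package
#' version, every derived per-trial seed, and the output file inventory.
#'
#' @param config a [benchmark_config()].
#' @param outputs named character vector or list of output files.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, outputs = list()) {
  seeds <- do.call(rbind, lapply(seq_len(config$n_trials), function(i)
    data.frame(trial = i, decoder_seed = derive_seed(config$master_seed, i, 1L),
               signal_seed = derive_seed(config$master_seed, i, 2L),
               noise_seed = derive_seed(config$master_seed, i, 3L))))
  structure(list(
    package = "spikebox",
    version = as.character(utils::packageVersion("spikebox")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = config$master_seed,
    config = list(M = config$M, rho = config$rho, n_trials = config$n_trials,
                  duration = config$duration, dt = config$dt,
                  lambda = config$params$lambda,
                  threshold = config$params$threshold,
                  tau_ref = config$params$tau_ref,
                  sigma_V = config$params$sigma_V,
                  delay = config$params$delay, signal = config$signal),
    perturbations = lapply(config$perturbation %||% list(), unclass),
    trial_seeds = seeds,
    outputs = outputs
  ), class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest a [run_manifest()].
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", null = "null",
                       pretty = TRUE)
  invisible(path)
}
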