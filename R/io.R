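# Configuration parsing and session persistence.
#
# Matrices travel as CSV (header row = muscle/module labels, one time sample
# per row); configurations as YAML or JSON; a session is saved as a directory
# of CSV files plus the exact config snapshot. Numeric values are written
# with 17 significant digits so a save/load round trip is bit-exact.

fmt17 <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  })
  df
}

#' Write a numeric data.frame as CSV with lossless float precision
#'
#' @param df data.frame
#' @param path output path
#' @export
write_csv_exact <- function(df, path) {
  utils::write.csv(fmt17(as.data.frame(df)), path, row.names = FALSE,
                   quote = FALSE)
}

#' Write an activation/synergy/EMG matrix to CSV
#'
#' One time sample (or module) per row, a header row of column labels, and an
#' optional leading `time` column for traces.
#'
#' @param x an [activation_trace()], [synergy_matrix()],
#'   [muscle_activations()] or plain matrix
#' @param path output CSV path
#' @export
write_matrix_csv <- function(x, path) {
  if (inherits(x, "activation_trace")) {
    df <- data.frame(time = x$sample_times, x$commands, check.names = FALSE)
  } else if (inherits(x, "muscle_activations")) {
    df <- data.frame(time = x$sample_times, x$values, check.names = FALSE)
  } else if (inherits(x, "synergy_matrix")) {
    df <- as.data.frame(x$weights)
  } else {
    df <- as.data.frame(as.matrix(x))
  }
  write_csv_exact(df, path)
}

#' Read a matrix CSV written by [write_matrix_csv()]
#'
#' @param path CSV path
#' @param as one of `"matrix"`, `"activations"`, `"trace"`, `"synergy"`; the
#'   trace/activation forms expect a leading `time` column
#' @return the requested object
#' @export
read_matrix_csv <- function(path, as = c("matrix", "activations", "trace",
                                         "synergy")) {
  as <- match.arg(as)
  df <- utils::read.csv(path, check.names = FALSE)
  if (as %in% c("activations", "trace")) {
    if (names(df)[1] != "time") stop("expected a leading 'time' column")
    m <- as.matrix(df[, -1, drop = FALSE])
    if (as == "trace") activation_trace(m, df$time)
    else muscle_activations(m, df$time)
  } else if (as == "synergy") {
    synergy_matrix(as.matrix(df))
  } else {
    as.matrix(df)
  }
}

# Doubles are serialized as 17-significant-digit strings so the YAML/JSON
# round trip is bit-exact (the YAML emitter alone is not); load_config
# coerces them back.
num17 <- function(x) sprintf("%.17g", x)
as_num <- function(x) as.numeric(unlist(x))

config_to_list <- function(config) {
  list(
    sway = list(amplitude = num17(config$sway$amplitude),
                frequency = num17(config$sway$frequency),
                axis = config$sway$axis,
                start_cycle_percent = num17(config$sway$start_cycle_percent)),
    F_t = num17(config$F_t), F_s = num17(config$F_s),
    duration = num17(config$duration),
    stim_mode = config$stim_mode, seed = config$seed,
    quantization_step = num17(config$quantization_step),
    jitter = list(name = config$jitter$name,
                  sigma_ms = num17(config$jitter$sigma_ms),
                  trunc_sd = num17(config$jitter$trunc_sd),
                  shape = num17(config$jitter$shape)),
    channel_map = config$channel_map,
    channels = lapply(config$channels, function(ch) {
      list(channel_id = ch$channel_id, I_max = num17(ch$I_max),
           pulse_width_ms = num17(ch$pulse_width_ms), waveform = ch$waveform)
    }),
    command_table = apply(config$command_table$entries, 1L, num17,
                          simplify = FALSE),
    W = apply(config$W$weights, 1L, num17, simplify = FALSE),
    muscle_labels = config$W$muscle_labels
  )
}

list_to_config <- function(x) {
  required <- c("sway", "F_t", "F_s", "duration", "seed", "channel_map",
                "channels", "command_table", "W")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  entries <- do.call(rbind, lapply(x$command_table, as_num))
  if (nrow(entries) != 100L) {
    stop("command_table must have exactly 100 entries (1% cycle resolution)")
  }
  Wm <- do.call(rbind, lapply(x$W, as_num))
  jt <- if (is.null(x$jitter)) jitter_model("truncnorm", sigma_ms = 8) else {
    jitter_model(x$jitter$name,
                 sigma_ms = as_num(x$jitter$sigma_ms %||% 8),
                 trunc_sd = as_num(x$jitter$trunc_sd %||% 3),
                 shape = as_num(x$jitter$shape %||% 25))
  }
  session_config(
    sway = sway_reference(as_num(x$sway$amplitude), as_num(x$sway$frequency),
                          axis = x$sway$axis %||% "ML",
                          start_cycle_percent = as_num(x$sway$start_cycle_percent %||% 75)),
    command_table = structure(list(entries = entries, resolution_percent = 1L,
                                   K = ncol(entries)),
                              class = "neural_command_table"),
    W = synergy_matrix(Wm, muscle_labels = unlist(x$muscle_labels %||% list(NULL))),
    channel_map = as.integer(unlist(x$channel_map)),
    channels = lapply(x$channels, function(ch) {
      stim_channel_config(ch$channel_id, I_max = as_num(ch$I_max),
                          pulse_width_ms = as_num(ch$pulse_width_ms %||% 1),
                          waveform = ch$waveform %||% "biphasic")
    }),
    F_t = as_num(x$F_t), F_s = as_num(x$F_s), duration = as_num(x$duration),
    jitter = jt, seed = x$seed,
    stim_mode = x$stim_mode %||% "continuous",
    quantization_step = as_num(x$quantization_step %||% STIM_QUANT_STEP_MA)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a session configuration to YAML or JSON
#'
#' @param config a [session_config()]
#' @param path output path ending in `.yaml`, `.yml` or `.json`
#' @export
save_config <- function(config, path) {
  x <- config_to_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 17L)
  }
  invisible(path)
}

#' Load and validate a session configuration from YAML or JSON
#'
#' All [session_config()] invariants are enforced with actionable messages:
#' in particular F_s must be lower than F_t and a seed is mandatory.
#'
#' @param path config file path (`.yaml`, `.yml` or `.json`)
#' @return a validated [session_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  list_to_config(x)
}

#' Save a session log as a directory of CSV files
#'
#' Writes `frames.csv` (tick time, cycle percentage, commands, currents),
#' `periods.csv` (measured T_s, ms), `pulses.csv`, `cop_reference.csv`,
#' `cop_measured.csv`, `metronome.csv`, the exact config snapshot
#' (`config.yaml`) and a plain-text `run.log`.
#'
#' @param log a [run_session()] result
#' @param dir output directory (created if absent)
#' @return invisibly, the list of files written
#' @export
save_session <- function(log, dir) {
  stopifnot(inherits(log, "session_log"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames <- data.frame(time = log$times, cycle_percent = log$cycle_percent)
  cmd <- as.data.frame(log$commands)
  names(cmd) <- paste0("h", seq_len(ncol(cmd)))
  cur <- as.data.frame(log$currents)
  names(cur) <- paste0("current_ch", log$config$channel_map)
  frames <- cbind(frames, cmd, cur)
  files <- c(
    frames = file.path(dir, "frames.csv"),
    periods = file.path(dir, "periods.csv"),
    pulses = file.path(dir, "pulses.csv"),
    cop_reference = file.path(dir, "cop_reference.csv"),
    cop_measured = file.path(dir, "cop_measured.csv"),
    metronome = file.path(dir, "metronome.csv"),
    config = file.path(dir, "config.yaml"),
    runlog = file.path(dir, "run.log")
  )
  write_csv_exact(frames, files["frames"])
  write_csv_exact(data.frame(T_s_ms = log$T_s_ms), files["periods"])
  write_csv_exact(log$pulse_train$pulses, files["pulses"])
  write_csv_exact(log$reference_cop, files["cop_reference"])
  write_csv_exact(log$measured_cop, files["cop_measured"])
  write_csv_exact(data.frame(beat_time = log$metronome$beat_times),
                  files["metronome"])
  save_config(log$config, files["config"])
  writeLines(c(
    sprintf("frames dispatched: %d", length(log$times)),
    sprintf("duration: %g s; F_s: %g Hz; F_t: %g Hz",
            log$duration, log$config$F_s, log$config$F_t),
    sprintf("timing violations: %d", nrow(log$monitor$violations)),
    sprintf("stopped: %s%s", log$stopped,
            if (log$stopped) sprintf(" at t = %.3f s", log$stop_time) else "")
  ), files["runlog"])
  invisible(files)
}

#' Load the numeric arrays of a saved session
#'
#' @param dir a directory written by [save_session()]
#' @return list with `frames`, `periods`, `pulses`, `cop_reference`,
#'   `cop_measured`, `metronome` data.frames and the `config`
#' @export
load_session <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), check.names = FALSE)
  list(frames = rd("frames.csv"), periods = rd("periods.csv"),
       pulses = rd("pulses.csv"), cop_reference = rd("cop_reference.csv"),
       cop_measured = rd("cop_measured.csv"), metronome = rd("metronome.csv"),
       config = load_config(file.path(dir, "config.yaml")))
}

#' Write the standard synthetic fixture files
#'
#' Writes `H.csv`, `W.csv`, `M.csv` (noisy EMG) and `session.yaml` for the
#' default validation conditions.
#'
#' @param dir output directory
#' @param spec a [generator_spec()]; default the standard 3-module, 8-muscle
#'   conditions
#' @return invisibly, the directory
#' @export
generate_fixtures <- function(dir, spec = generator_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  H <- simulate_neural_commands(spec)
  W <- simulate_synergy_matrix(spec)
  M <- simulate_emg(H, W, noise_sigma = spec$noise_sigma, seed = spec$seed)
  write_matrix_csv(H, file.path(dir, "H.csv"))
  write_matrix_csv(W, file.path(dir, "W.csv"))
  write_matrix_csv(M, file.path(dir, "M.csv"))
  save_config(default_session_fixture(seed = spec$seed),
              file.path(dir, "session.yaml"))
  invisible(dir)
}
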