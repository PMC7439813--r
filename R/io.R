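# Seed substreams and artifact readers/writers.
#
# All randomness in the package flows from a single top-level integer seed
# through named substreams (connectivity, jitter, background noise, external
# Poisson), so changing the consumer of one stream does not perturb the
# others.

#' Derive a named substream seed from a top-level seed
#'
#' Deterministically maps `(seed, name)` to an integer in `[0, 2^31)` using a
#' small string hash, so that independent random streams (connectivity,
#' weight jitter, background noise, external spikes) can be seeded from one
#' top-level seed without interfering.
#'
#' @param seed Top-level integer seed.
#' @param name Substream name.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

csv_digits <- 9L  # significant digits for text round-trips

write_csv_table <- function(df, path) {
  df_fmt <- as.data.frame(lapply(df, function(col) {
    if (is.double(col)) signif(col, csv_digits) else col
  }))
  utils::write.csv(df_fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a simulation trace as CSV with a JSON sidecar
#'
#' Traces (mean-field or rate-network population series) are written as
#' plain CSV, with the run metadata (parameters, seed, flags) in a JSON
#' sidecar `<path>.json`. Values round-trip at 9 significant digits.
#'
#' @param trace A `meanfield_trace`, `rate_trace`, or plain data.frame.
#' @param path Output CSV path.
#' @param meta Optional named list of metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, meta = list()) {
  df <- if (inherits(trace, "rate_trace")) trace$trace else as.data.frame(trace)
  if (inherits(trace, "rate_trace")) meta$runaway <- trace$runaway
  write_csv_table(df, path)
  if (length(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(df, "meta") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  df
}

#' Write / read a scan outcome
#'
#' A scan outcome is serialised as one CSV row per grid point (grid value,
#' final mean rate, stability label) plus a JSON summary holding the
#' stability bracket (with explicit openness) and any analytic prediction.
#'
#' @param scan A `scan_outcome` from [scan_recurrence()] or
#'   [scan_homeostasis()].
#' @param path Output CSV path (summary goes to `<path>.json`).
#' @return `path`, invisibly ([read_scan()]: the reconstructed
#'   `scan_outcome`).
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "scan_outcome"))
  write_csv_table(scan$points, path)
  summ <- list(parameter = scan$parameter,
               bracket_stable = scan$bracket[1],
               bracket_unstable = scan$bracket[2],
               prediction = scan$prediction)
  jsonlite::write_json(summ, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  points <- utils::read.csv(path)
  summ <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  as_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  new_scan_outcome(points, parameter = summ$parameter,
                   bracket = c(as_na(summ$bracket_stable),
                               as_na(summ$bracket_unstable)),
                   prediction = if (is.null(summ$prediction)) NULL
                                else as.numeric(summ$prediction))
}

#' Write / read spiking event lists
#'
#' Spike data are stored as a two-column CSV (`time_s`, `neuron_id`).
#'
#' @param spikes A data.frame with columns `time_s`, `neuron_id`, or a
#'   `spike_data` object from [simulate_spiking()].
#' @param path Output CSV path.
#' @return `path`, invisibly ([read_spikes()]: the data.frame).
#' @export
write_spikes <- function(spikes, path) {
  if (inherits(spikes, "spike_data")) spikes <- spikes$spikes
  stopifnot(all(c("time_s", "neuron_id") %in% names(spikes)))
  write_csv_table(spikes[, c("time_s", "neuron_id")], path)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  utils::read.csv(path)
}
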