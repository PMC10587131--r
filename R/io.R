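# File formats: sequence/poke/trial CSVs with metadata headers, paradigm
# and agent configuration JSON. All event data is plain CSV (sessions are
# ~10^3 rows; human-auditable text is the right default), and every output
# file carries `# key: value` metadata lines (tool version, seed, config
# hash) so reruns are traceable and byte-identical.

meta_header <- function(seed = NULL, config = NULL) {
  lines <- c(sprintf("# tool: oddballr %s",
                     as.character(utils::packageVersion("oddballr"))))
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %d", as.integer(seed)))
  if (!is.null(config)) {
    lines <- c(lines, sprintf("# config_hash: %s", fnv1a_hash(config)))
  }
  lines
}

write_csv_with_meta <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(meta_header(seed, config), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE,
                     eol = "\n")
  invisible(path)
}

read_csv_with_meta <- function(path, required_cols) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 1L) {
    stop_oddballr(sprintf("%s: no header row", path), "parse_error")
  }
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    stop_oddballr(sprintf("%s: missing column(s) %s", path,
                          paste(missing, collapse = ", ")), "parse_error")
  }
  df
}

#' Write / read a stimulus sequence CSV
#'
#' Lossless round-trip of the sequence table
#' (`index,role,frequency_khz,nominal_onset_s,duration_ms`), with metadata
#' comment lines (`# key: value`) above the header. Onsets are written with
#' at least 3 decimals. The paradigm spec travels as a JSON sidecar string
#' in the metadata only if written via [write_run_config()]; `read_sequence`
#' therefore takes the spec explicitly (or reconstructs a minimal one).
#'
#' @param seq An `oddball_sequence`.
#' @param path Output file path.
#' @param seed Seed recorded in the metadata header.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path, seed = attr(seq, "spec")$seed) {
  spec <- attr(seq, "spec")
  df <- as.data.frame(seq)
  df$nominal_onset_s <- sprintf("%.3f", df$nominal_onset_s)
  write_csv_with_meta(df, path, seed = seed,
                      config = jsonlite::toJSON(unclass(spec), auto_unbox = TRUE,
                                                null = "null"))
}

#' @rdname write_sequence
#' @param spec A `paradigm_spec` to attach; when `NULL`, a minimal spec is
#'   inferred from the file (counts, ISI from onsets, default window).
#' @export
read_sequence <- function(path, spec = NULL) {
  df <- read_csv_with_meta(path, c("index", "role", "frequency_khz",
                                   "nominal_onset_s", "duration_ms"))
  bad <- which(!df$role %in% c("standard", "deviant"))
  if (length(bad) > 0L) {
    stop_oddballr(sprintf("%s: invalid role at data line %d", path, bad[1L]),
                  "parse_error")
  }
  df$index <- as.integer(df$index)
  df$nominal_onset_s <- as.numeric(df$nominal_onset_s)
  if (is.null(spec)) {
    n_dev <- sum(df$role == "deviant")
    isi <- if (nrow(df) > 1L) df$nominal_onset_s[2L] - df$nominal_onset_s[1L] else 1.5
    dev_f <- unique(df$frequency_khz[df$role == "deviant"])
    std_f <- df$frequency_khz[df$role == "standard"][1L]
    kind <- if (length(dev_f) > 1L) "many_deviant" else "oddball"
    spec <- paradigm_spec(kind, nrow(df), n_dev, std_f, dev_f, isi_s = isi,
                          lead_in = 0L, min_run = 0L,
                          duration_ms = df$duration_ms[1L])
  }
  structure(df, spec = spec, class = c("oddball_sequence", "data.frame"))
}

#' Write / read a nose-poke log CSV (`time_s`)
#'
#' @param pokes Numeric vector of poke times in seconds.
#' @param path File path.
#' @param seed Seed recorded in the metadata header.
#' @return `write_pokes`: `path`, invisibly. `read_pokes`: sorted numeric
#'   vector of poke times.
#' @export
write_pokes <- function(pokes, path, seed = NULL) {
  write_csv_with_meta(data.frame(time_s = sprintf("%.6f", pokes)), path,
                      seed = seed)
}

#' @rdname write_pokes
#' @export
read_pokes <- function(path) {
  df <- read_csv_with_meta(path, "time_s")
  as.numeric(df$time_s)
}

#' Write / read a scored trial table CSV
#'
#' Columns `index,role,frequency_khz,actual_onset_s,outcome,latency_s,`
#' `rewarded,timeout_applied`.
#'
#' @param trials Trial data frame from a `session_log`.
#' @param path File path.
#' @param seed Seed recorded in the metadata header.
#' @return `write_trials`: `path`, invisibly. `read_trials`: the trial data
#'   frame.
#' @export
write_trials <- function(trials, path, seed = NULL) {
  df <- trials
  df$actual_onset_s <- sprintf("%.6f", df$actual_onset_s)
  df$latency_s <- ifelse(is.na(df$latency_s), "",
                         sprintf("%.6f", df$latency_s))
  write_csv_with_meta(df, path, seed = seed)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read_csv_with_meta(path, c("index", "role", "frequency_khz",
                                   "actual_onset_s", "outcome", "latency_s",
                                   "rewarded", "timeout_applied"))
  df$latency_s <- suppressWarnings(as.numeric(df$latency_s))
  df$actual_onset_s <- as.numeric(df$actual_onset_s)
  df
}

#' Read a paradigm configuration JSON
#'
#' JSON keys mirror the [paradigm_spec()] fields; unknown keys are rejected
#' so silent typos cannot change an experiment.
#'
#' @param path JSON file path.
#' @return A `paradigm_spec`.
#' @export
read_paradigm_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  allowed <- c("kind", "n_tones", "n_deviant", "standard_khz", "deviant_khz",
               "isi_s", "response_window_s", "timeout_s", "lead_in",
               "min_run", "duration_ms", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    stop_oddballr(sprintf("unknown paradigm config key(s): %s",
                          paste(unknown, collapse = ", ")), "parse_error")
  }
  do.call(paradigm_spec, cfg)
}

#' Read agent parameters from JSON
#'
#' @param path JSON file path with keys mirroring [rat_agent_params()].
#' @return A `rat_agent_params`.
#' @export
read_agent_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  allowed <- names(formals(rat_agent_params))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    stop_oddballr(sprintf("unknown agent config key(s): %s",
                          paste(unknown, collapse = ", ")), "parse_error")
  }
  do.call(rat_agent_params, cfg)
}
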