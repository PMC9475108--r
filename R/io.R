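#' Write a recording bundle to disk
#'
#' Serializes a [recording_bundle()] into a directory: one CSV per stream
#' (`audio.csv`, `eeg.csv` with columns timestamp,value; `markers.csv` with
#' timestamp,label), one CSV per offset series (`offsets_<sender>.csv`), and
#' a JSON sidecar (`bundle.json`) holding stream metadata, the session
#' configuration, ground truth and seed.  Numeric values are rendered with
#' 17 significant digits so that `read_bundle(write_bundle(b))` reproduces
#' `b` exactly.
#'
#' @param bundle A [recording_bundle()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @seealso [read_bundle()]
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "recording_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = bundle$seed, streams = list(), offsets = list())

  write_stream_csv <- function(ts, col2, header, file) {
    con <- file(file.path(path, file), "w")
    on.exit(close(con))
    writeLines(header, con)
    if (length(ts)) {
      if (is.character(col2)) {
        writeLines(paste(sprintf("%.17g", ts), col2, sep = ","), con)
      } else {
        writeLines(paste(sprintf("%.17g", ts), sprintf("%.17g", col2), sep = ","), con)
      }
    }
  }

  for (nm in c("audio_stream", "eeg_stream")) {
    s <- bundle[[nm]]
    if (is.null(s)) next
    file <- paste0(sub("_stream$", "", nm), ".csv")
    write_stream_csv(s$timestamps, s$values, "timestamp,value", file)
    meta$streams[[nm]] <- list(name = s$name, clock_id = s$clock_id,
                               nominal_rate = s$nominal_rate, file = file)
  }
  if (!is.null(bundle$marker_stream)) {
    s <- bundle$marker_stream
    write_stream_csv(s$timestamps, s$labels, "timestamp,label", "markers.csv")
    meta$streams$marker_stream <- list(name = s$name, clock_id = s$clock_id,
                                       file = "markers.csv")
  }
  for (key in names(bundle$offsets)) {
    o <- bundle$offsets[[key]]
    file <- paste0("offsets_", key, ".csv")
    write_stream_csv(o$times, o$offsets, "time,offset", file)
    meta$offsets[[key]] <- list(receiver_clock_id = o$receiver_clock_id,
                                sender_clock_id = o$sender_clock_id,
                                file = file)
  }
  meta$ground_truth <- bundle$ground_truth
  meta$config <- config_to_list(bundle$config)
  jsonlite::write_json(meta, file.path(path, "bundle.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Read a recording bundle from disk
#'
#' Reads a directory written by [write_bundle()] back into a
#' [recording_bundle()] at full precision.
#'
#' @param path Bundle directory.
#' @return A [recording_bundle()].
#' @export
read_bundle <- function(path) {
  sidecar <- file.path(path, "bundle.json")
  if (!file.exists(sidecar)) {
    stop(sprintf("not a bundle directory: missing %s", sidecar), call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)

  read_csv_file <- function(file, numeric2 = TRUE) {
    fp <- file.path(path, file)
    if (!file.exists(fp)) {
      stop(sprintf("bundle is missing the file '%s' declared in bundle.json", file),
           call. = FALSE)
    }
    df <- tryCatch(
      utils::read.csv(fp, colClasses = c("numeric", if (numeric2) "numeric" else "character")),
      error = function(e) {
        stop(sprintf("malformed bundle file '%s': %s", fp, conditionMessage(e)),
             call. = FALSE)
      })
    df
  }

  get_stream <- function(key) {
    m <- meta$streams[[key]]
    if (is.null(m)) return(NULL)
    if (key == "marker_stream") {
      df <- read_csv_file(m$file, numeric2 = FALSE)
      marker_stream(m$name, m$clock_id, df[[1L]], df[[2L]])
    } else {
      df <- read_csv_file(m$file)
      sampled_stream(m$name, m$clock_id, m$nominal_rate, df[[1L]], df[[2L]])
    }
  }

  offsets <- list()
  for (key in names(meta$offsets)) {
    m <- meta$offsets[[key]]
    df <- read_csv_file(m$file)
    offsets[[key]] <- clock_offset_series(m$receiver_clock_id,
                                          m$sender_clock_id,
                                          df[[1L]], df[[2L]])
  }
  gt <- meta$ground_truth
  if (!is.null(gt)) gt <- lapply(gt, function(x) if (is.list(x)) x else x)
  recording_bundle(audio_stream = get_stream("audio_stream"),
                   marker_stream = get_stream("marker_stream"),
                   eeg_stream = get_stream("eeg_stream"),
                   offsets = offsets, ground_truth = gt,
                   config = config_from_list(meta$config),
                   seed = if (is.null(meta$seed)) NA else meta$seed)
}

# Session configs round-trip through plain lists (for the JSON sidecar and
# YAML/JSON config files of the command-line interface).
config_to_list <- function(config) {
  if (is.null(config)) return(NULL)
  stopifnot(inherits(config, "session_config"))
  lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
}

config_from_list <- function(lst) {
  if (is.null(lst) || length(lst) == 0L) return(NULL)
  build <- function(ctor, values) do.call(ctor, as.list(values))
  clock_fields <- function(v) {
    v <- as.list(v)
    v[names(v) %in% names(formals(clock_model))]
  }
  session_config(
    schedule = build(stimulus_schedule, lst$schedule),
    sender = build(sender_config, lst$sender),
    eeg_chain = build(eeg_chain_config, lst$eeg_chain),
    protocol = build(offset_protocol_config, lst$protocol),
    sender_clock = build(clock_model, clock_fields(lst$sender_clock)),
    eeg_clock = build(clock_model, clock_fields(lst$eeg_clock)),
    receiver_clock = build(clock_model, clock_fields(lst$receiver_clock)),
    pad = if (is.null(lst$pad)) 0.5 else lst$pad
  )
}

#' Read a session configuration from a YAML or JSON file
#'
#' The file mirrors the structure of [session_config()]: top-level keys
#' `schedule`, `sender`, `eeg_chain`, `protocol`, `sender_clock`,
#' `eeg_clock`, `receiver_clock`, `pad`, each holding the fields of the
#' corresponding constructor.  Missing keys take the constructor defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [session_config()].
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  config_from_list(lst)
}
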