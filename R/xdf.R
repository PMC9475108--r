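# Minimal XDF (Extensible Data Format) importer.
#
# XDF is the container format written by LSL recording tools: a "XDF:" magic
# followed by length-prefixed chunks (FileHeader, StreamHeader, Samples,
# ClockOffset, Boundary, StreamFooter).  This reader supports what a timing
# re-analysis needs -- per-sample timestamps (explicit or deduced from the
# nominal rate), numeric and string channel values, and the raw clock-offset
# records -- and imports everything untransformed: no de-jittering and no
# smoothing of clock offsets or timestamps is applied on load.

xdf_read_varint <- function(raw, pos) {
  nbytes <- as.integer(raw[pos])
  if (!nbytes %in% c(1L, 4L, 8L)) {
    stop(sprintf("invalid XDF varint length byte %d at offset %d", nbytes, pos),
         call. = FALSE)
  }
  val <- sum(as.numeric(raw[pos + seq_len(nbytes)]) * 256^(seq_len(nbytes) - 1))
  list(value = val, pos = pos + 1L + nbytes)
}

xdf_uint <- function(raw, pos, nbytes) {
  sum(as.numeric(raw[pos + seq_len(nbytes) - 1L]) * 256^(seq_len(nbytes) - 1))
}

xdf_double <- function(raw, pos) {
  readBin(raw[pos:(pos + 7L)], "double", n = 1L, size = 8L, endian = "little")
}

xdf_value_reader <- function(format) {
  switch(format,
    double64 = list(size = 8L, read = function(raw, pos, n)
      readBin(raw[pos:(pos + 8L * n - 1L)], "double", n = n, size = 8L,
              endian = "little")),
    float32 = list(size = 4L, read = function(raw, pos, n)
      readBin(raw[pos:(pos + 4L * n - 1L)], "double", n = n, size = 4L,
              endian = "little")),
    int32 = list(size = 4L, read = function(raw, pos, n)
      readBin(raw[pos:(pos + 4L * n - 1L)], "integer", n = n, size = 4L,
              endian = "little")),
    int16 = list(size = 2L, read = function(raw, pos, n)
      readBin(raw[pos:(pos + 2L * n - 1L)], "integer", n = n, size = 2L,
              endian = "little")),
    int8 = list(size = 1L, read = function(raw, pos, n)
      readBin(raw[pos:(pos + n - 1L)], "integer", n = n, size = 1L,
              endian = "little")),
    string = NULL,
    stop(sprintf("unsupported XDF channel format '%s'", format), call. = FALSE)
  )
}

# Parse an XDF file into per-stream records.
parse_xdf <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 4L || rawToChar(raw[1:4]) != "XDF:") {
    stop(sprintf("'%s' is not an XDF file (missing magic)", path), call. = FALSE)
  }
  pos <- 5L
  streams <- list()
  n <- length(raw)
  while (pos <= n) {
    v <- xdf_read_varint(raw, pos)
    chunk_len <- v$value
    pos <- v$pos
    tag <- xdf_uint(raw, pos, 2L)
    content <- pos + 2L
    content_len <- chunk_len - 2L
    pos <- pos + chunk_len

    if (tag == 2) {                       # StreamHeader
      sid <- as.character(xdf_uint(raw, content, 4L))
      xml_txt <- rawToChar(raw[(content + 4L):(content + content_len - 1L)])
      info <- xml2::as_list(xml2::read_xml(xml_txt))$info
      get1 <- function(key, default = NA) {
        x <- info[[key]]
        if (is.null(x) || length(x) == 0L) default else unlist(x)[[1L]]
      }
      streams[[sid]] <- list(
        name = get1("name", paste0("stream_", sid)),
        type = get1("type", ""),
        channel_count = as.integer(get1("channel_count", 1)),
        nominal_srate = as.numeric(get1("nominal_srate", 0)),
        channel_format = get1("channel_format", "float32"),
        timestamps = list(), values = list(),
        offset_times = numeric(0), offset_values = numeric(0)
      )
    } else if (tag == 3) {                # Samples
      sid <- as.character(xdf_uint(raw, content, 4L))
      st <- streams[[sid]]
      if (is.null(st)) {
        stop(sprintf("XDF samples for undeclared stream id %s", sid), call. = FALSE)
      }
      v <- xdf_read_varint(raw, content + 4L)
      nsamp <- v$value
      p <- v$pos
      rdr <- xdf_value_reader(st$channel_format)
      ts <- numeric(nsamp)
      vals <- if (is.null(rdr)) character(nsamp) else numeric(nsamp)
      last_ts <- if (length(st$timestamps)) {
        tt <- st$timestamps[[length(st$timestamps)]]
        tt[length(tt)]
      } else NA_real_
      for (i in seq_len(nsamp)) {
        tsb <- as.integer(raw[p]); p <- p + 1L
        if (tsb == 8L) {
          ts[i] <- xdf_double(raw, p); p <- p + 8L
        } else if (tsb == 0L) {
          if (is.na(last_ts) || st$nominal_srate <= 0) {
            stop("XDF sample with deduced timestamp but no previous timestamp/rate",
                 call. = FALSE)
          }
          ts[i] <- last_ts + 1 / st$nominal_srate
        } else {
          stop(sprintf("invalid XDF timestamp length byte %d", tsb), call. = FALSE)
        }
        last_ts <- ts[i]
        if (is.null(rdr)) {               # string channels
          sv <- character(st$channel_count)
          for (ch in seq_len(st$channel_count)) {
            lv <- xdf_read_varint(raw, p)
            p <- lv$pos
            sv[ch] <- if (lv$value > 0) {
              rawToChar(raw[p:(p + lv$value - 1L)])
            } else ""
            p <- p + lv$value
          }
          vals[i] <- sv[1L]
        } else {
          x <- rdr$read(raw, p, st$channel_count)
          p <- p + rdr$size * st$channel_count
          vals[i] <- x[1L]                # single-channel analysis model
        }
      }
      st$timestamps <- c(st$timestamps, list(ts))
      st$values <- c(st$values, list(vals))
      streams[[sid]] <- st
    } else if (tag == 4) {                # ClockOffset
      sid <- as.character(xdf_uint(raw, content, 4L))
      st <- streams[[sid]]
      if (!is.null(st)) {
        st$offset_times <- c(st$offset_times, xdf_double(raw, content + 4L))
        st$offset_values <- c(st$offset_values, xdf_double(raw, content + 12L))
        streams[[sid]] <- st
      }
    }
    # tags 1 (FileHeader), 5 (Boundary), 6 (StreamFooter): skipped
  }
  lapply(streams, function(st) {
    st$timestamps <- unlist(st$timestamps)
    st$values <- unlist(st$values)
    st
  })
}

#' Import an XDF recording as a recording bundle
#'
#' Reads a multi-stream XDF file and assembles a [recording_bundle()] from
#' the streams named in `stream_name_map`.  Timestamps, values and
#' clock-offset records are imported untransformed (no de-jittering, no
#' offset smoothing), so the analysis pipeline sees exactly what the
#' recorder wrote.  Offsets are attached as receiver-minus-sender series
#' with the recorder as receiver, ready for [map_timeline()].
#'
#' @param path Path to an XDF file.
#' @param stream_name_map Named list/character vector mapping bundle roles
#'   to stream names in the file; recognized roles are `markers`, `eeg` and
#'   `audio` (at least one of `markers`/`eeg` must be given).
#' @param receiver_clock_id Clock id to assign to the recorder's timeline
#'   (default `"receiver"`).
#' @return A [recording_bundle()] (with `ground_truth = NULL`).
#' @export
import_xdf <- function(path, stream_name_map,
                       receiver_clock_id = "receiver") {
  if (!file.exists(path)) stop(sprintf("XDF file not found: %s", path), call. = FALSE)
  stream_name_map <- as.list(stream_name_map)
  streams <- parse_xdf(path)
  available <- vapply(streams, function(s) s$name, "")

  find_stream <- function(role) {
    want <- stream_name_map[[role]]
    if (is.null(want)) return(NULL)
    hit <- which(available == want)
    if (length(hit) == 0L) {
      stop(sprintf("stream '%s' (role %s) not found in %s; available: %s",
                   want, role, path, paste(available, collapse = ", ")),
           call. = FALSE)
    }
    streams[[hit[1L]]]
  }

  offsets <- list()
  add_offsets <- function(st, clock_id) {
    if (length(st$offset_times)) {
      offsets[[clock_id]] <<- clock_offset_series(
        receiver_clock_id, clock_id, st$offset_times, st$offset_values)
    }
  }

  mk <- find_stream("markers")
  marker_str <- NULL
  if (!is.null(mk)) {
    clock_id <- paste0("clock_", mk$name)
    marker_str <- marker_stream(mk$name, clock_id, mk$timestamps,
                                as.character(mk$values))
    add_offsets(mk, clock_id)
  }
  eg <- find_stream("eeg")
  eeg_str <- NULL
  if (!is.null(eg)) {
    clock_id <- paste0("clock_", eg$name)
    eeg_str <- sampled_stream(eg$name, clock_id,
                              if (eg$nominal_srate > 0) eg$nominal_srate else 1,
                              eg$timestamps, as.numeric(eg$values))
    add_offsets(eg, clock_id)
  }
  au <- find_stream("audio")
  audio_str <- NULL
  if (!is.null(au)) {
    clock_id <- paste0("clock_", au$name)
    audio_str <- sampled_stream(au$name, clock_id,
                                if (au$nominal_srate > 0) au$nominal_srate else 1,
                                au$timestamps, as.numeric(au$values))
    add_offsets(au, clock_id)
  }
  if (is.null(marker_str) && is.null(eeg_str)) {
    stop("`stream_name_map` must name at least a 'markers' or 'eeg' stream",
         call. = FALSE)
  }
  recording_bundle(audio_stream = audio_str, marker_stream = marker_str,
                   eeg_stream = eeg_str, offsets = offsets,
                   ground_truth = NULL, config = NULL, seed = NA)
}
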