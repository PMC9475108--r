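# Minimal XDF writer used to build binary test fixtures at run time.  It is
# written directly from the published chunk layout (magic, varint-prefixed
# chunks, StreamHeader XML, Samples, ClockOffset) and is independent of the
# package's reader.

xdf_w_varint <- function(n) {
  # 4-byte little-endian length with a leading num-length byte
  c(as.raw(4L), writeBin(as.integer(n), raw(), size = 4L, endian = "little"))
}

xdf_w_uint32 <- function(n) writeBin(as.integer(n), raw(), size = 4L, endian = "little")
xdf_w_double <- function(x) writeBin(as.double(x), raw(), size = 8L, endian = "little")

xdf_w_chunk <- function(tag, content) {
  body <- c(writeBin(as.integer(tag), raw(), size = 2L, endian = "little")[1:2],
            content)
  c(xdf_w_varint(length(body)), body)
}

xdf_header_xml <- function(name, type, channel_count, srate, format) {
  sprintf(paste0(
    "<?xml version=\"1.0\"?><info><name>%s</name><type>%s</type>",
    "<channel_count>%d</channel_count><nominal_srate>%s</nominal_srate>",
    "<channel_format>%s</channel_format></info>"),
    name, type, channel_count, format(srate), format)
}

# streams: list of lists with fields
#   name, type, srate, format ("float32"/"double64"/"string"),
#   timestamps, values (numeric or character),
#   deduce (logical: write only the first timestamp explicitly),
#   offset_times, offset_values (optional)
write_xdf_file <- function(path, streams) {
  out <- charToRaw("XDF:")
  out <- c(out, xdf_w_chunk(1L, charToRaw("<?xml version=\"1.0\"?><info><version>1.0</version></info>")))
  for (i in seq_along(streams)) {
    st <- streams[[i]]
    hdr <- xdf_header_xml(st$name, st$type %||% "", 1L, st$srate, st$format)
    out <- c(out, xdf_w_chunk(2L, c(xdf_w_uint32(i), charToRaw(hdr))))
  }
  for (i in seq_along(streams)) {
    st <- streams[[i]]
    n <- length(st$timestamps)
    if (n > 0) {
      body <- c(xdf_w_uint32(i), xdf_w_varint(n))
      for (k in seq_len(n)) {
        explicit <- !(isTRUE(st$deduce) && k > 1L)
        body <- c(body,
                  if (explicit) c(as.raw(8L), xdf_w_double(st$timestamps[k]))
                  else as.raw(0L))
        body <- c(body, switch(st$format,
          double64 = xdf_w_double(st$values[k]),
          float32 = writeBin(as.double(st$values[k]), raw(), size = 4L,
                             endian = "little"),
          string = {
            sv <- charToRaw(as.character(st$values[k]))
            c(xdf_w_varint(length(sv)), sv)
          },
          stop("unsupported format in test writer")))
      }
      out <- c(out, xdf_w_chunk(3L, body))
    }
    for (k in seq_along(st$offset_times)) {
      out <- c(out, xdf_w_chunk(4L, c(xdf_w_uint32(i),
                                      xdf_w_double(st$offset_times[k]),
                                      xdf_w_double(st$offset_values[k]))))
    }
  }
  writeBin(out, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
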