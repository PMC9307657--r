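#' Read an EDF/EDF+ recording
#'
#' Parses the fixed-width EDF header and the 16-bit little-endian data
#' records, rescales to physical units, and maps vendor channel labels to
#' canonical roles through a synonym table. Channels whose labels do not
#' map are retained under their raw label and flagged. When several raw
#' labels map to one canonical role, the first wins and the collision is
#' reported as a warning.
#'
#' @param path EDF file path.
#' @param channel_synonyms named character vector mapping lower-case raw
#'   labels to canonical roles; see [default_channel_synonyms()].
#' @param meta optional [subject_meta()]; by default a skeleton built
#'   from the file name (metadata travels in a sidecar CSV, not in EDF
#'   headers).
#' @return a [psg_record()]. Unmapped channel labels are recorded in
#'   `record$flags`.
#' @export
read_edf <- function(path, channel_synonyms = default_channel_synonyms(),
                     meta = NULL) {
  if (!file.exists(path)) {
    stop_somnoage("EDF file not found: ", path, class = "somnoage_ingest_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 256)
  if (length(hdr_raw) < 256) {
    stop_somnoage("corrupt EDF: truncated header in ", path,
                  class = "somnoage_ingest_error")
  }
  fld <- function(raw, from, len) trimws(rawToChar(raw[from:(from + len - 1)]))
  version <- fld(hdr_raw, 1, 8)
  if (version != "0") {
    stop_somnoage("corrupt EDF: unexpected version field '", version, "'",
                  class = "somnoage_ingest_error")
  }
  start_date <- fld(hdr_raw, 169, 8)
  start_time <- fld(hdr_raw, 177, 8)
  n_records <- as.integer(fld(hdr_raw, 237, 8))
  record_dur <- as.numeric(fld(hdr_raw, 245, 8))
  ns <- as.integer(fld(hdr_raw, 253, 4))
  if (is.na(ns) || ns < 1 || is.na(n_records) || n_records < 1) {
    stop_somnoage("corrupt EDF: bad record counts in ", path,
                  class = "somnoage_ingest_error")
  }
  sig_raw <- readBin(con, "raw", 256 * ns)
  labels <- vapply(seq_len(ns), function(i)
    trimws(rawToChar(sig_raw[((i - 1) * 16 + 1):(i * 16)])), "")
  off0 <- 16 * ns
  units <- vapply(seq_len(ns), function(i)
    trimws(rawToChar(sig_raw[(off0 + 80 * ns + (i - 1) * 8 + 1):
                               (off0 + 80 * ns + i * 8)])), "")
  num_at <- function(base, len) {
    vapply(seq_len(ns), function(i)
      as.numeric(trimws(rawToChar(sig_raw[(base + (i - 1) * len + 1):
                                            (base + i * len)]))), 0)
  }
  base <- off0 + 80 * ns + 8 * ns
  phys_min <- num_at(base, 8)
  phys_max <- num_at(base + 8 * ns, 8)
  dig_min <- num_at(base + 16 * ns, 8)
  dig_max <- num_at(base + 24 * ns, 8)
  nsamp <- as.integer(num_at(base + 32 * ns + 80 * ns, 8))

  payload <- readBin(con, "integer", n = n_records * sum(nsamp), size = 2,
                     signed = TRUE, endian = "little")
  if (length(payload) < n_records * sum(nsamp)) {
    stop_somnoage("corrupt EDF: truncated data records in ", path,
                  class = "somnoage_ingest_error")
  }
  idx_end <- cumsum(nsamp)
  idx_start <- c(0L, head(idx_end, -1)) + 1L
  rec_len <- sum(nsamp)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)

  seen <- character(0)
  flags <- character(0)
  traces <- list()
  for (i in seq_len(ns)) {
    offs <- rep((seq_len(n_records) - 1) * rec_len, each = nsamp[i])
    pick <- rep(idx_start[i]:idx_end[i], times = n_records) + offs
    x <- phys_min[i] + gain[i] * (payload[pick] - dig_min[i])
    canon <- .canon_label(labels[i], channel_synonyms)
    lab <- if (!is.na(canon)) canon else labels[i]
    if (is.na(canon)) flags <- c(flags, paste0("unmapped:", labels[i]))
    if (lab %in% seen) {
      warning("label collision: '", labels[i], "' also maps to '", lab,
              "'; keeping the first occurrence", call. = FALSE)
      next
    }
    seen <- c(seen, lab)
    traces[[lab]] <- signal_trace(lab, x, nsamp[i] / record_dur, units[i])
  }
  if (!any(vapply(names(traces), function(l)
    l %in% unname(channel_synonyms) || grepl("^[A-Za-z]", l), TRUE))) {
    stop_somnoage("no mappable channels in ", path,
                  class = "somnoage_ingest_error")
  }
  if (length(traces) == 0) {
    stop_somnoage("no channels could be read from ", path,
                  class = "somnoage_ingest_error")
  }
  if (is.null(meta)) {
    meta <- subject_meta(sub("\\.edf$", "", basename(path), ignore.case = TRUE))
  }
  rec <- psg_record(meta, traces,
                    start_time = paste(start_date, start_time),
                    duration_s = n_records * record_dur)
  rec$flags <- flags
  rec
}

#' Write a PSG record to EDF
#'
#' Minimal EDF writer used by the synthetic generator and by tests
#' (ingest round-trips). Each trace must have an integer number of
#' samples per data record; the record duration is chosen as 1 s, so all
#' sampling rates must be integers (or 1/fs must divide the record
#' duration for sub-1 Hz rates).
#'
#' @param record a [psg_record()].
#' @param path destination path.
#' @param record_dur data-record duration in seconds.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path, record_dur = 1) {
  traces <- record$traces
  ns <- length(traces)
  nsamp <- vapply(traces, function(tr) tr$fs * record_dur, 0)
  if (any(abs(nsamp - round(nsamp)) > 1e-9)) {
    stop_somnoage("all fs * record_dur must be integers for EDF writing",
                  class = "somnoage_ingest_error")
  }
  nsamp <- as.integer(round(nsamp))
  n_records <- min(vapply(seq_len(ns), function(i)
    length(traces[[i]]$samples) %/% nsamp[i], 0L))
  if (n_records < 1) {
    stop_somnoage("record shorter than one EDF data record",
                  class = "somnoage_ingest_error")
  }
  pad <- function(x, w) {
    s <- substr(format(x, trim = TRUE), 1, w)
    paste0(s, strrep(" ", w - nchar(s)))
  }
  phys_min <- phys_max <- numeric(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- traces[[i]]$samples[seq_len(n_records * nsamp[i])]
    lo <- min(x); hi <- max(x)
    if (hi <= lo) hi <- lo + 1
    span <- (hi - lo) * 0.001
    phys_min[i] <- lo - span; phys_max[i] <- hi + span
    dig[[i]] <- as.integer(round(-32768 + (x - phys_min[i]) /
                                   (phys_max[i] - phys_min[i]) * 65535))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8),
    pad(record$meta$subject_id, 80),
    pad("somnoage", 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(256 * (1 + ns), 8),
    pad("", 44),
    pad(n_records, 8),
    pad(format(record_dur, trim = TRUE), 8),
    pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  wfield <- function(vals, w) for (v in vals) writeChar(pad(v, w), con, eos = NULL)
  wfield(vapply(traces, `[[`, "", "label"), 16)
  wfield(rep("", ns), 80)
  wfield(vapply(traces, `[[`, "", "unit"), 8)
  num8 <- function(v) vapply(v, function(x) {
    for (d in 7:1) {
      s <- formatC(x, digits = d, format = "g", width = 1)
      if (nchar(s) <= 8) return(s)
    }
    stop_somnoage("cannot format ", x, " into 8 EDF header bytes",
                  class = "somnoage_ingest_error")
  }, "")
  phys_min <- as.numeric(num8(phys_min))
  phys_max <- as.numeric(num8(phys_max))
  for (i in seq_len(ns)) {
    x <- traces[[i]]$samples[seq_len(n_records * nsamp[i])]
    dig[[i]] <- as.integer(round(pmax(-32768, pmin(32767,
      -32768 + (x - phys_min[i]) / (phys_max[i] - phys_min[i]) * 65535))))
  }
  wfield(num8(phys_min), 8)
  wfield(num8(phys_max), 8)
  wfield(rep("-32768", ns), 8)
  wfield(rep("32767", ns), 8)
  wfield(rep("", ns), 80)
  wfield(nsamp, 8)
  wfield(rep("", ns), 32)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      seg <- dig[[i]][((r - 1) * nsamp[i] + 1):(r * nsamp[i])]
      writeBin(seg, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
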