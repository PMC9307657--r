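#' Persist a preprocessed record
#'
#' Writes the C x T float32 signal stack, the per-channel substitution
#' mask and the record attributes (sampling rate, channel order, subject
#' id, metadata) to a single-file container: a JSON header line followed
#' by the raw little-endian payload. The round-trip is lossless at
#' float32 precision for the array and exact for mask and attributes.
#'
#' @param pre a `preprocessed_record` from [assemble()] /
#'   [preprocess_record()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_tensor_store <- function(pre, path) {
  stopifnot(inherits(pre, "preprocessed_record"))
  if (!all(is.finite(pre$x))) {
    stop_somnoage("preprocessed stack contains non-finite values",
                  class = "somnoage_store_error")
  }
  header <- jsonlite::toJSON(list(
    magic = "somnoage-tensor-v1",
    channels = pre$channels,
    C = nrow(pre$x), T = ncol(pre$x),
    fs = pre$fs,
    subject_id = pre$meta$subject_id,
    meta = pre$meta[c("age", "sex", "bmi", "cohort", "cpap_user",
                      "neuro_disorder", "age_truncated")]
  ), auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "wb")
  on.exit(close(con))
  hraw <- charToRaw(as.character(header))
  writeBin(length(hraw), con, size = 4, endian = "little")
  writeBin(hraw, con)
  writeBin(as.integer(pre$mask), con, size = 1)
  writeBin(as.numeric(t(pre$x)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a preprocessed record back from a tensor store
#'
#' @param path file written by [write_tensor_store()].
#' @param expect_channels optional character vector; if supplied, the
#'   stored channel order must match exactly.
#' @return a `preprocessed_record`.
#' @export
read_tensor_store <- function(path, expect_channels = NULL) {
  if (!file.exists(path)) {
    stop_somnoage("tensor store not found: ", path,
                  class = "somnoage_store_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  if (!identical(hdr$magic, "somnoage-tensor-v1")) {
    stop_somnoage("not a somnoage tensor store: ", path,
                  class = "somnoage_store_error")
  }
  C <- hdr$C; Tn <- hdr$T
  mask <- as.integer(readBin(con, "integer", C, size = 1, signed = FALSE))
  x <- readBin(con, "numeric", C * Tn, size = 4, endian = "little")
  if (length(x) != C * Tn) {
    stop_somnoage("tensor store payload shorter than declared shape",
                  class = "somnoage_store_error")
  }
  x <- t(matrix(x, nrow = Tn, ncol = C))
  if (!is.null(expect_channels) && !identical(hdr$channels, expect_channels)) {
    stop_somnoage("channel order mismatch: store has [",
                  paste(hdr$channels, collapse = ", "), "], expected [",
                  paste(expect_channels, collapse = ", "), "]",
                  class = "somnoage_store_error")
  }
  m <- hdr$meta
  meta <- subject_meta(hdr$subject_id,
                       age = m$age %||% NA_real_, sex = m$sex %||% NA_character_,
                       bmi = m$bmi %||% NA_real_, cohort = m$cohort %||% "default",
                       cpap_user = isTRUE(m$cpap_user),
                       neuro_disorder = isTRUE(m$neuro_disorder))
  rownames(x) <- hdr$channels
  structure(list(x = x, mask = mask, fs = hdr$fs, channels = hdr$channels,
                 meta = meta, excluded = FALSE, exclude_reason = NA_character_),
            class = "preprocessed_record")
}
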