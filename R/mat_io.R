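# Minimal MAT v5 reader: numeric (real) arrays only, which is all the
# single-channel EEG segment files contain. Little- and big-endian files are
# supported; compressed elements are inflated via memDecompress when the zlib
# stream is readable, otherwise a clear error is raised.

.mat_mi_types <- c(miINT8 = 1, miUINT8 = 2, miINT16 = 3, miUINT16 = 4,
                   miINT32 = 5, miUINT32 = 6, miSINGLE = 7, miDOUBLE = 9,
                   miINT64 = 12, miUINT64 = 13, miMATRIX = 14,
                   miCOMPRESSED = 15, miUTF8 = 16)

.mat_read_uint32 <- function(raw4, endian) {
  readBin(raw4, "integer", n = 1L, size = 4L, endian = endian, signed = TRUE)
}

.mat_numeric_payload <- function(data, mi_type, endian) {
  switch(as.character(mi_type),
    "1"  = readBin(data, "integer", n = length(data), size = 1L, signed = TRUE, endian = endian),
    "2"  = readBin(data, "integer", n = length(data), size = 1L, signed = FALSE, endian = endian),
    "3"  = readBin(data, "integer", n = length(data) %/% 2L, size = 2L, signed = TRUE, endian = endian),
    "4"  = readBin(data, "integer", n = length(data) %/% 2L, size = 2L, signed = FALSE, endian = endian),
    "5"  = readBin(data, "integer", n = length(data) %/% 4L, size = 4L, endian = endian),
    "6"  = {
      v <- readBin(data, "integer", n = length(data) %/% 4L, size = 4L, endian = endian)
      ifelse(v < 0, v + 2^32, v)
    },
    "7"  = readBin(data, "double", n = length(data) %/% 4L, size = 4L, endian = endian),
    "9"  = readBin(data, "double", n = length(data) %/% 8L, size = 8L, endian = endian),
    "12" = as.numeric(readBin(data, "double", n = length(data) %/% 8L, size = 8L, endian = endian)),
    stop("unsupported MAT numeric element type: ", mi_type)
  )
}

# Parse one data element starting at offset `pos` (1-based) in raw vector.
# Returns list(name=, value= numeric array or NULL, next_pos=).
.mat_parse_element <- function(buf, pos, endian) {
  type_raw <- buf[pos:(pos + 3L)]
  type_word <- .mat_read_uint32(type_raw, endian)
  small_nbytes <- bitwAnd(bitwShiftR(type_word, 16L), 0xFFFFL)
  if (small_nbytes != 0L) {  # small data element format
    mi_type <- bitwAnd(type_word, 0xFFFFL)
    nbytes <- small_nbytes
    data <- buf[(pos + 4L):(pos + 3L + nbytes)]
    return(list(mi_type = mi_type, data = data, next_pos = pos + 8L))
  }
  mi_type <- type_word
  nbytes <- .mat_read_uint32(buf[(pos + 4L):(pos + 7L)], endian)
  data <- if (nbytes > 0L) buf[(pos + 8L):(pos + 7L + nbytes)] else raw(0)
  # elements are padded to 8-byte boundaries (except inside compressed streams
  # the final element may omit trailing pad)
  adv <- 8L + nbytes
  pad <- (8L - adv %% 8L) %% 8L
  list(mi_type = mi_type, data = data, next_pos = pos + adv + pad)
}

.mat_parse_matrix <- function(data, endian) {
  pos <- 1L
  flags <- .mat_parse_element(data, pos, endian); pos <- flags$next_pos
  flag_word <- .mat_read_uint32(flags$data[1:4], endian)
  mx_class <- bitwAnd(flag_word, 0xFFL)
  is_complex <- bitwAnd(flag_word, bitwShiftL(1L, 11L)) != 0L
  dims_el <- .mat_parse_element(data, pos, endian); pos <- dims_el$next_pos
  dims <- readBin(dims_el$data, "integer", n = length(dims_el$data) %/% 4L,
                  size = 4L, endian = endian)
  name_el <- .mat_parse_element(data, pos, endian); pos <- name_el$next_pos
  name <- rawToChar(name_el$data[name_el$data != as.raw(0)])
  numeric_classes <- 6:13  # mxDOUBLE .. mxUINT32
  if (!(mx_class %in% numeric_classes))
    return(list(name = name, value = NULL))
  pr <- .mat_parse_element(data, pos, endian)
  vals <- .mat_numeric_payload(pr$data, pr$mi_type, endian)
  if (is_complex) warning("imaginary part of '", name, "' ignored")
  if (length(dims) == 2L) dim(vals) <- dims else if (length(dims) > 2L) dim(vals) <- dims
  list(name = name, value = vals)
}

#' Read numeric arrays from a MAT v5 file
#'
#' Parses Level-5 MAT files containing real numeric arrays (the layout used by
#' single-channel EEG segment corpora: one vector per file). Cell arrays,
#' structs, character and sparse matrices are skipped with their names
#' preserved so ambiguity errors can list them.
#'
#' @param path Path to a `.mat` file.
#' @return Named list of numeric arrays (skipped non-numeric variables appear
#'   as `NULL`).
#' @export
read_mat_v5 <- function(path) {
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 128L) stop("not a MAT v5 file (too short): ", path)
  magic <- rawToChar(buf[127:128])
  endian <- if (magic == "IM") "little" else if (magic == "MI") "big" else
    stop("not a MAT v5 file (bad endian indicator): ", path)
  pos <- 129L
  out <- list()
  while (pos + 7L <= length(buf)) {
    el <- .mat_parse_element(buf, pos, endian)
    pos <- el$next_pos
    if (el$mi_type == .mat_mi_types[["miCOMPRESSED"]]) {
      inflated <- tryCatch(memDecompress(el$data, type = "gzip"),
                           error = function(e) NULL)
      if (is.null(inflated))
        stop("compressed MAT element could not be inflated; ",
             "re-save the file without compression")
      sub <- .mat_parse_element(inflated, 1L, endian)
      if (sub$mi_type != .mat_mi_types[["miMATRIX"]]) next
      parsed <- .mat_parse_matrix(sub$data, endian)
    } else if (el$mi_type == .mat_mi_types[["miMATRIX"]]) {
      parsed <- .mat_parse_matrix(el$data, endian)
    } else {
      next
    }
    out[[parsed$name]] <- parsed$value
  }
  out
}

#' Read a single-channel EEG segment from a MAT v5 file
#'
#' Loads one numeric vector from a MAT file (e.g., the 1024-sample, 200 Hz
#' segments of sleep-center seizure corpora). If the file holds several
#' numeric vector variables and `variable` is not given, an error lists the
#' candidates rather than guessing.
#'
#' @param path Path to the `.mat` file.
#' @param variable Variable name to read; `NULL` (default) auto-selects when
#'   the file contains exactly one numeric vector.
#' @param fs Sampling frequency in Hz (default 200).
#' @param calibration Microvolt-per-unit factor (default 1).
#' @param label Optional state label.
#' @param recording_id Identifier; defaults to the file name without extension.
#' @param expected_duration_s If given, the vector length is checked against
#'   `fs * expected_duration_s` (tolerance one sample) and a mismatch errors.
#' @return An [recording()] object.
#' @export
read_mat_segment <- function(path, variable = NULL, fs = 200, calibration = 1,
                             label = NA_character_, recording_id = NULL,
                             expected_duration_s = NULL) {
  vars <- read_mat_v5(path)
  numeric_vars <- vars[!vapply(vars, is.null, logical(1))]
  if (length(numeric_vars) == 0L) stop("no numeric vector found in ", path)
  if (is.null(variable)) {
    if (length(numeric_vars) > 1L)
      stop("multiple numeric variables in ", path, "; specify `variable` as one of: ",
           paste(names(numeric_vars), collapse = ", "))
    variable <- names(numeric_vars)[1L]
  } else if (!variable %in% names(numeric_vars)) {
    stop("variable '", variable, "' not found in ", path, "; available: ",
         paste(names(numeric_vars), collapse = ", "))
  }
  vals <- as.numeric(numeric_vars[[variable]])
  if (!is.null(expected_duration_s)) {
    expected_n <- round(fs * expected_duration_s)
    if (abs(length(vals) - expected_n) > 1L)
      stop(sprintf("length %d does not match fs * duration = %d", length(vals), expected_n))
  }
  if (is.null(recording_id))
    recording_id <- sub("\\.[^.]*$", "", basename(path))
  recording(vals, fs = fs, recording_id = recording_id, label = label,
            calibration = calibration)
}
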