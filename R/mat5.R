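# Minimal reader/writer for the legacy (v5) MATLAB binary container, covering
# the subset the per-slice tumor collections use: little-endian files holding
# numeric matrices and scalar structs of numeric matrices. Compressed
# elements are inflated with memDecompress when the zlib stream allows it.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L; MI_UTF8 <- 16L
MX_STRUCT <- 2L; MX_CHAR <- 4L
MX_DOUBLE <- 6L; MX_SINGLE <- 7L; MX_INT8 <- 8L; MX_UINT8 <- 9L
MX_INT16 <- 10L; MX_UINT16 <- 11L; MX_INT32 <- 12L; MX_UINT32 <- 13L

# --- reading ----------------------------------------------------------------

mat5_cursor <- function(raw) {
  env <- new.env()
  env$raw <- raw
  env$pos <- 1L
  env
}

cur_read <- function(cur, n) {
  if (n == 0) return(raw(0))
  out <- cur$raw[cur$pos:(cur$pos + n - 1L)]
  cur$pos <- cur$pos + as.integer(n)
  out
}

cur_eof <- function(cur) cur$pos > length(cur$raw)

rd_int <- function(r, size, signed = TRUE) {
  readBin(r, "integer", n = length(r) %/% size, size = size, signed = signed,
          endian = "little")
}

decode_numeric <- function(r, type) {
  switch(as.character(type),
    "1" = rd_int(r, 1L),
    "2" = rd_int(r, 1L, signed = FALSE),
    "3" = rd_int(r, 2L),
    "4" = rd_int(r, 2L, signed = FALSE),
    "5" = rd_int(r, 4L),
    "6" = {
      v <- rd_int(r, 4L)                        # uint32 via int; fix sign
      ifelse(v < 0, v + 2^32, v)
    },
    "7" = readBin(r, "double", n = length(r) %/% 4L, size = 4L, endian = "little"),
    "9" = readBin(r, "double", n = length(r) %/% 8L, size = 8L, endian = "little"),
    "16" = rd_int(r, 1L, signed = FALSE),
    stop("unsupported element type ", type))
}

# Read one tagged data element: list(type, data raw). Handles the small
# (packed) element format and 8-byte alignment.
read_element <- function(cur) {
  tagraw <- cur_read(cur, 4L)
  type <- rd_int(tagraw, 4L)[1]
  if (type < 0) type <- type + 2^32
  small_n <- type %/% 65536
  if (small_n > 0) {
    type <- type %% 65536
    data <- cur_read(cur, 4L)[seq_len(small_n)]
    return(list(type = as.integer(type), data = data))
  }
  nbytes <- rd_int(cur_read(cur, 4L), 4L)[1]
  if (nbytes < 0) nbytes <- nbytes + 2^32
  data <- cur_read(cur, nbytes)
  padding <- (8L - nbytes %% 8L) %% 8L
  if (padding > 0 && !cur_eof(cur)) cur_read(cur, min(padding, length(cur$raw) - cur$pos + 1L))
  list(type = as.integer(type), data = data)
}

parse_matrix <- function(data) {
  cur <- mat5_cursor(data)
  flags <- read_element(cur)
  fl <- rd_int(flags$data, 4L)
  if (fl[1] < 0) fl[1] <- fl[1] + 2^32
  cls <- fl[1] %% 256
  dims_el <- read_element(cur)
  dims <- decode_numeric(dims_el$data, dims_el$type)
  name_el <- read_element(cur)
  name <- rawToChar(name_el$data)
  if (cls == MX_STRUCT) {
    fnl_el <- read_element(cur)
    fl_len <- decode_numeric(fnl_el$data, fnl_el$type)[1]
    fn_el <- read_element(cur)
    nfields <- length(fn_el$data) %/% fl_len
    fields <- vapply(seq_len(nfields), function(i) {
      b <- fn_el$data[((i - 1) * fl_len + 1):(i * fl_len)]
      rawToChar(b[b != as.raw(0)])
    }, character(1))
    vals <- vector("list", nfields)
    for (i in seq_len(nfields)) {
      el <- read_element(cur)
      if (el$type != MI_MATRIX) stop("malformed struct field")
      v <- parse_matrix(el$data)
      vals[[i]] <- v$value
    }
    return(list(name = name, value = stats::setNames(vals, fields)))
  }
  if (cls == MX_CHAR) {
    el <- read_element(cur)
    txt <- decode_numeric(el$data, el$type)
    return(list(name = name, value = intToUtf8(txt[txt > 0])))
  }
  el <- read_element(cur)
  vals <- decode_numeric(el$data, el$type)
  value <- if (length(dims) == 2) matrix(vals, dims[1], dims[2]) else
    array(vals, dims)
  list(name = name, value = value)
}

#' Read a legacy (v5) MATLAB container file
#'
#' Supports little-endian files with numeric matrices, character vectors and
#' scalar structs of such values — the subset used by per-slice MRI
#' collections. Compressed elements are inflated when possible.
#'
#' @param path file path.
#' @return named list of variables.
#' @export
read_mat5 <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 128) stop("file too short for a v5 container")
  endian <- rawToChar(raw[127:128])
  if (endian != "IM") stop("only little-endian v5 containers are supported")
  cur <- mat5_cursor(raw)
  cur$pos <- 129L
  out <- list()
  while (!cur_eof(cur)) {
    if (length(cur$raw) - cur$pos + 1L < 8L) break
    el <- read_element(cur)
    if (el$type == MI_COMPRESSED) {
      inflated <- tryCatch(memDecompress(el$data, type = "gzip"),
                           error = function(e) NULL)
      if (is.null(inflated))
        stop("cannot inflate compressed element; re-save the file uncompressed")
      el <- read_element(mat5_cursor(inflated))
    }
    if (el$type != MI_MATRIX) next
    v <- parse_matrix(el$data)
    out[[v$name]] <- v$value
  }
  out
}

# --- writing (used to build loader fixtures) --------------------------------

wr_element <- function(type, data_raw) {
  n <- length(data_raw)
  pad <- (8L - n %% 8L) %% 8L
  c(writeBin(c(as.integer(type), n), raw(), size = 4L, endian = "little"),
    data_raw, raw(pad))
}

wr_numeric <- function(type, values) {
  data <- switch(as.character(type),
    "9" = writeBin(as.numeric(values), raw(), size = 8L, endian = "little"),
    "5" = ,
    "6" = writeBin(as.integer(values), raw(), size = 4L, endian = "little"),
    "1" = writeBin(as.integer(values), raw(), size = 1L, endian = "little"),
    stop("unsupported write type ", type))
  wr_element(type, data)
}

wr_matrix_body <- function(name, value) {
  if (is.list(value)) {
    flags <- wr_numeric(MI_UINT32, c(MX_STRUCT, 0L))
    dims <- wr_numeric(MI_INT32, c(1L, 1L))
    nm <- wr_element(MI_INT8, charToRaw(name))
    fields <- names(value)
    fl_len <- 32L
    fnl <- wr_numeric(MI_INT32, fl_len)
    fnr <- raw(0)
    for (f in fields) {
      b <- charToRaw(f)
      fnr <- c(fnr, b, raw(fl_len - length(b)))
    }
    fn <- wr_element(MI_INT8, fnr)
    body <- raw(0)
    for (f in fields) {
      body <- c(body, wr_element(MI_MATRIX, wr_matrix_body("", value[[f]])))
    }
    return(c(flags, dims, nm, fnl, fn, body))
  }
  value <- as.matrix(value)
  flags <- wr_numeric(MI_UINT32, c(MX_DOUBLE, 0L))
  dims <- wr_numeric(MI_INT32, dim(value))
  nm <- wr_element(MI_INT8, charToRaw(name))
  dat <- wr_numeric(MI_DOUBLE, as.numeric(value))
  c(flags, dims, nm, dat)
}

#' Write a legacy (v5) MATLAB container file
#'
#' Writes numeric matrices and (nested) named lists as scalar structs, enough
#' to produce loader fixtures in the per-slice dialect.
#'
#' @param vars named list of numeric matrices and/or named lists.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path) {
  header <- charToRaw(sprintf("%-116s", "MATLAB 5.0 MAT-file, written by dsenet"))
  header <- c(header, raw(8),                                 # subsys offset
              writeBin(c(256L), raw(), size = 2L, endian = "little"),
              charToRaw("IM"))
  body <- raw(0)
  for (nm in names(vars)) {
    body <- c(body, wr_element(MI_MATRIX, wr_matrix_body(nm, vars[[nm]])))
  }
  writeBin(c(header, body), path)
  invisible(path)
}
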