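# Minimal reader/writer for the NumPy .npy array format (version 1.0),
# restricted to dense 2-D numeric arrays. Supports little-endian float64/
# float32 and the common integer dtypes; both C and Fortran element order.

.npy_magic <- as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59))

.npy_dtypes <- list(
  "<f8" = list(what = "double",  size = 8L, signed = TRUE),
  "<f4" = list(what = "double",  size = 4L, signed = TRUE),
  "<i8" = list(what = "integer", size = 8L, signed = TRUE),
  "<i4" = list(what = "integer", size = 4L, signed = TRUE),
  "<i2" = list(what = "integer", size = 2L, signed = TRUE),
  "|i1" = list(what = "integer", size = 1L, signed = TRUE),
  "<i1" = list(what = "integer", size = 1L, signed = TRUE),
  "|u1" = list(what = "integer", size = 1L, signed = FALSE),
  "<u1" = list(what = "integer", size = 1L, signed = FALSE)
)

#' Read a 2-D array from a .npy file
#'
#' Reads a NumPy binary array file holding a dense two-dimensional numeric
#' array. Only format version 1.0 with the standard little-endian numeric
#' dtypes is supported, which covers genotype matrices exported from Python.
#'
#' @param path Path to the `.npy` file.
#' @return A numeric matrix. `NaN` entries are returned as stored.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (length(magic) < 6L || !identical(magic, .npy_magic)) {
    stop("'", path, "' is not a .npy file (bad magic bytes)", call. = FALSE)
  }
  ver <- readBin(con, "integer", 2L, size = 1L, signed = FALSE)
  if (ver[1] != 1L) {
    stop("unsupported .npy format version ", ver[1], ".", ver[2],
         " in '", path, "'", call. = FALSE)
  }
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little",
                  signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- .npy_header_field(header, "descr", path)
  fortran <- identical(.npy_header_field(header, "fortran_order", path), "True")
  shape <- .npy_header_shape(header, path)
  dt <- .npy_dtypes[[descr]]
  if (is.null(dt)) {
    stop("unsupported .npy dtype '", descr, "' in '", path, "'", call. = FALSE)
  }
  n_elem <- prod(shape)
  vals <- readBin(con, dt$what, n = n_elem, size = dt$size,
                  endian = "little", signed = dt$signed)
  if (length(vals) < n_elem) {
    stop("file '", path, "' truncated: expected ", n_elem, " elements (",
         n_elem * dt$size, " data bytes), got ", length(vals),
         " at byte offset ", 10L + hlen + length(vals) * dt$size,
         call. = FALSE)
  }
  vals <- as.numeric(vals)
  if (length(shape) == 1L) {
    return(matrix(vals, nrow = 1L))
  }
  if (length(shape) != 2L) {
    stop(".npy array in '", path, "' has ", length(shape),
         " dimensions; only 2-D matrices are supported", call. = FALSE)
  }
  if (fortran) {
    matrix(vals, nrow = shape[1], ncol = shape[2])
  } else {
    t(matrix(vals, nrow = shape[2], ncol = shape[1]))
  }
}

#' Write a matrix to a .npy file
#'
#' Writes a numeric matrix as a NumPy format 1.0 binary array. With
#' `dtype = "|i1"` values are stored as signed bytes (genotype counts plus a
#' negative missing code); `NA`/`NaN` values are then written as `na_code`.
#'
#' @param x Numeric matrix.
#' @param path Output path.
#' @param dtype Storage dtype: `"<f8"` (default, `NA` stored as `NaN`) or
#'   `"|i1"`.
#' @param na_code Integer sentinel used for missing values when writing an
#'   integer dtype.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path, dtype = c("<f8", "|i1"), na_code = -9L) {
  dtype <- match.arg(dtype)
  x <- as.matrix(x)
  header <- sprintf(
    "{'descr': '%s', 'fortran_order': True, 'shape': (%d, %d), }",
    dtype, nrow(x), ncol(x))
  # pad so that magic(6) + version(2) + hlen(2) + header is a multiple of 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.npy_magic, con)
  writeBin(as.raw(c(1L, 0L)), con)
  writeBin(nchar(header), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  if (dtype == "<f8") {
    vals <- as.numeric(x)
    vals[is.na(vals)] <- NaN
    writeBin(vals, con, size = 8L, endian = "little")
  } else {
    vals <- as.integer(round(as.numeric(x)))
    vals[is.na(vals)] <- as.integer(na_code)
    writeBin(vals, con, size = 1L)
  }
  invisible(path)
}

.npy_header_field <- function(header, key, path) {
  pat <- paste0("'", key, "'\\s*:\\s*('([^']*)'|True|False)")
  m <- regmatches(header, regexec(pat, header))[[1]]
  if (length(m) == 0L) {
    stop("malformed .npy header in '", path, "': missing '", key, "'",
         call. = FALSE)
  }
  if (nzchar(m[3])) m[3] else m[2]
}

.npy_header_shape <- function(header, path) {
  m <- regmatches(header, regexec("'shape'\\s*:\\s*\\(([^)]*)\\)", header))[[1]]
  if (length(m) == 0L) {
    stop("malformed .npy header in '", path, "': missing 'shape'",
         call. = FALSE)
  }
  parts <- strsplit(m[2], ",")[[1]]
  parts <- trimws(parts)
  as.integer(parts[nzchar(parts)])
}
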