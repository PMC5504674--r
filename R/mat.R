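# Minimal MATLAB Level-5 MAT-file reader.
#
# Supports the subset needed to import recording-session records:
# uncompressed numeric arrays (int8..uint64, single, double), character
# arrays, cell arrays and struct arrays.  Compressed (zlib) elements,
# sparse matrices and objects are rejected with an informative error.

MI_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L,
                  `6` = 4L, `7` = 4L, `9` = 8L, `12` = 8L, `13` = 8L,
                  `16` = 1L, `17` = 2L)

mat5_read_numeric <- function(raw, type, n, endian) {
  con <- rawConnection(raw)
  on.exit(close(con))
  switch(as.character(type),
    `1` = readBin(con, "integer", n, size = 1L, signed = TRUE,
                  endian = endian),
    `2` = readBin(con, "integer", n, size = 1L, signed = FALSE,
                  endian = endian),
    `3` = readBin(con, "integer", n, size = 2L, signed = TRUE,
                  endian = endian),
    `4` = readBin(con, "integer", n, size = 2L, signed = FALSE,
                  endian = endian),
    `5` = readBin(con, "integer", n, size = 4L, signed = TRUE,
                  endian = endian),
    `6` = {  # uint32: no native support; widen from signed int32
      v <- readBin(con, "integer", n, size = 4L, endian = endian)
      out <- as.numeric(v)
      out[out < 0] <- out[out < 0] + 4294967296
      out
    },
    `7` = readBin(con, "numeric", n, size = 4L, endian = endian),
    `9` = readBin(con, "numeric", n, size = 8L, endian = endian),
    `12` = readBin(con, "numeric", n, size = 8L, endian = endian),
    `13` = readBin(con, "numeric", n, size = 8L, endian = endian),
    `16` = readBin(con, "integer", n, size = 1L, signed = FALSE,
                   endian = endian),
    `17` = readBin(con, "integer", n, size = 2L, signed = FALSE,
                   endian = endian),
    stop("MAT reader: unsupported data type ", type)
  )
}

# one tagged data element starting at pos (1-based); returns value + new pos
mat5_element <- function(bytes, pos, endian) {
  w1 <- mat5_uint32(bytes, pos, endian)
  small_nbytes <- bitwAnd(bitwShiftR(w1, 16L), 0xFFFFL)
  if (small_nbytes > 0L) {
    type <- bitwAnd(w1, 0xFFFFL)
    nbytes <- small_nbytes
    data <- bytes[(pos + 4L):(pos + 3L + nbytes)]
    newpos <- pos + 8L
  } else {
    type <- w1
    nbytes <- mat5_uint32(bytes, pos + 4L, endian)
    data <- if (nbytes > 0L) bytes[(pos + 8L):(pos + 7L + nbytes)] else raw(0)
    pad <- (8L - nbytes %% 8L) %% 8L
    newpos <- pos + 8L + nbytes + pad
  }
  list(type = type, data = data, nbytes = nbytes, pos = newpos)
}

mat5_uint32 <- function(bytes, pos, endian) {
  b <- as.integer(bytes[pos:(pos + 3L)])
  if (endian == "little") {
    b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
  } else {
    b[4] + b[3] * 256 + b[2] * 65536 + b[1] * 16777216
  }
}

mat5_chars <- function(vals) {
  vals <- vals[vals > 0L]
  if (!length(vals)) return("")
  intToUtf8(vals)
}

# parse a miMATRIX payload into an R value; returns list(name, value)
mat5_matrix <- function(data, endian) {
  pos <- 1L
  el <- mat5_element(data, pos, endian); pos <- el$pos
  flags <- mat5_uint32(el$data, 1L, endian)
  class_id <- bitwAnd(flags, 0xFFL)
  el <- mat5_element(data, pos, endian); pos <- el$pos
  dims <- mat5_read_numeric(el$data, 5L, el$nbytes / 4L, endian)
  el <- mat5_element(data, pos, endian); pos <- el$pos
  name <- mat5_chars(mat5_read_numeric(el$data, 1L, el$nbytes, endian))
  n_elem <- prod(dims)

  if (class_id == 5L) stop("MAT reader: sparse arrays not supported")
  if (class_id == 1L) {                      # cell array
    cells <- vector("list", n_elem)
    for (i in seq_len(n_elem)) {
      el <- mat5_element(data, pos, endian); pos <- el$pos
      if (el$type != 14L) stop("MAT reader: malformed cell array")
      sub <- mat5_matrix(el$data, endian)
      cells[[i]] <- sub$value
    }
    return(list(name = name, value = cells))
  }
  if (class_id == 2L) {                      # struct array
    el <- mat5_element(data, pos, endian); pos <- el$pos
    namelen <- mat5_read_numeric(el$data, 5L, 1L, endian)
    el <- mat5_element(data, pos, endian); pos <- el$pos
    nfields <- el$nbytes / namelen
    fnames <- vapply(seq_len(nfields), function(i) {
      off <- (i - 1L) * namelen
      mat5_chars(mat5_read_numeric(el$data[(off + 1L):(off + namelen)],
                                   1L, namelen, endian))
    }, "")
    out <- vector("list", n_elem)
    for (e in seq_len(n_elem)) {
      rec <- stats::setNames(vector("list", nfields), fnames)
      for (f in seq_len(nfields)) {
        el <- mat5_element(data, pos, endian); pos <- el$pos
        if (el$type != 14L) stop("MAT reader: malformed struct field")
        sub <- mat5_matrix(el$data, endian)
        rec[[f]] <- sub$value
      }
      out[[e]] <- rec
    }
    value <- if (n_elem == 1L) out[[1L]] else out
    return(list(name = name, value = value))
  }
  if (class_id == 4L) {                      # char array
    el <- mat5_element(data, pos, endian)
    sz <- MI_TYPE_SIZE[[as.character(el$type)]]
    vals <- mat5_read_numeric(el$data, el$type, el$nbytes / sz, endian)
    if (length(dims) == 2L && dims[1] > 1L) {
      m <- matrix(vals, nrow = dims[1])   # column-major char matrix: rows
      return(list(name = name,
                  value = apply(m, 1L, mat5_chars)))
    }
    return(list(name = name, value = mat5_chars(vals)))
  }
  if (class_id == 3L || class_id > 15L) {
    stop("MAT reader: unsupported array class ", class_id)
  }
  # numeric array (possibly stored in a narrower integer type)
  el <- mat5_element(data, pos, endian)
  sz <- MI_TYPE_SIZE[[as.character(el$type)]]
  vals <- as.numeric(mat5_read_numeric(el$data, el$type, el$nbytes / sz,
                                       endian))
  value <- if (length(dims) > 1L && prod(dims) == length(vals)) {
    array(vals, dim = dims)
  } else {
    vals
  }
  if (is.array(value) && length(dim(value)) == 2L &&
      any(dim(value) == 1L) && length(value) > 0L) {
    value <- as.vector(value)              # collapse 1 x n / n x 1
  }
  list(name = name, value = value)
}

#' Read an uncompressed Level-5 MAT-file
#'
#' A purpose-written reader for the subset of the MAT format used by
#' recording-session containers: numeric, character, cell and struct
#' arrays.  Compressed elements are not supported.
#'
#' @param path path to the `.mat` file.
#' @return a named list of the top-level variables.
#' @export
read_mat <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 128L) stop("MAT reader: file too short")
  endian_tag <- rawToChar(bytes[127:128])
  endian <- if (endian_tag == "IM") "little" else if (endian_tag == "MI")
    "big" else stop("MAT reader: not a Level-5 MAT-file")
  pos <- 129L
  out <- list()
  while (pos + 7L <= length(bytes)) {
    el <- mat5_element(bytes, pos, endian)
    pos <- el$pos
    if (el$type == 15L) {
      stop("MAT reader: compressed MAT elements not supported; ",
           "re-save the file uncompressed")
    }
    if (el$type != 14L) next
    parsed <- mat5_matrix(el$data, endian)
    out[[parsed$name]] <- parsed$value
  }
  out
}

#' Import a BioPatRec-style `recSession` MAT-file
#'
#' Reads a MAT-file containing a `recSession` struct and maps it onto a
#' [recording_session()].  Field names vary across releases, so the mapping
#' is lenient: sampling rate from `sF`/`fs`/`sampling_rate`, contraction and
#' rest durations from `cT`/`rT` (or `contraction_s`/`rest_s`), repetitions
#' from `nR`, movement names from `mvs`/`movements`, and the signal from
#' `tdata` (samples x channels x movements tensor, movements concatenated in
#' order) or a plain samples x channels matrix.  Unknown extra fields are
#' ignored with a warning.
#'
#' @param path path to the `.mat` file.
#' @return a validated [recording_session()].
#' @export
read_biopatrec_mat <- function(path) {
  vars <- read_mat(path)
  rec <- vars[["recSession"]]
  if (is.null(rec)) {
    structs <- Filter(function(v) is.list(v) && !is.null(names(v)), vars)
    if (!length(structs)) stop("malformed session: no recSession struct in ", path)
    rec <- structs[[1L]]
  }
  pick <- function(...) {
    for (nm in c(...)) if (!is.null(rec[[nm]])) return(rec[[nm]])
    NULL
  }
  fs <- pick("sF", "fs", "sampling_rate", "sampling_rate_hz")
  ct <- pick("cT", "contraction_s", "ct")
  rt <- pick("rT", "rest_s", "rt")
  nrep <- pick("nR", "n_repetitions", "nr")
  mvs <- pick("mvs", "movements", "mov")
  tdata <- pick("tdata", "sdata", "signal")
  if (is.null(fs) || is.null(ct) || is.null(rt) || is.null(nrep) ||
      is.null(mvs) || is.null(tdata)) {
    stop("malformed session: recSession missing required field(s)")
  }
  if (is.list(mvs)) mvs <- vapply(mvs, function(x) as.character(x)[1], "")
  known <- c("sF", "fs", "sampling_rate", "sampling_rate_hz", "cT", "ct",
             "contraction_s", "rT", "rt", "rest_s", "nR", "nr",
             "n_repetitions", "mvs", "movements", "mov", "tdata", "sdata",
             "signal", "nM", "nCh", "adc_bits", "ADC")
  extra <- setdiff(names(rec), known)
  if (length(extra)) {
    warning("recSession: ignoring unknown field(s) ",
            paste(extra, collapse = ", "))
  }
  if (is.array(tdata) && length(dim(tdata)) == 3L) {
    nm <- dim(tdata)[3]
    sig <- do.call(rbind, lapply(seq_len(nm), function(m) tdata[, , m]))
  } else {
    sig <- as.matrix(tdata)
  }
  adc <- pick("adc_bits", "ADC")
  recording_session(
    signal = sig, sampling_rate_hz = as.numeric(fs)[1],
    movements = as.character(mvs), n_repetitions = as.numeric(nrep)[1],
    contraction_s = as.numeric(ct)[1], rest_s = as.numeric(rt)[1],
    adc_bits = if (is.null(adc)) NULL else as.numeric(adc)[1]
  )
}
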