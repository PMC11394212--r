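# Minimal FCS 3.0/3.1 list-mode reader and writer.
#
# Supports $MODE L with $DATATYPE F (32-bit float), D (64-bit float) or
# I (unsigned integers of $PnB = 8/16/32 bits), little- or big-endian
# ($BYTEORD 1,2,3,4 or 4,3,2,1). Other versions and modes are rejected.
# Compensation/spillover is never applied; inputs are assumed to be
# compensated upstream.

parse_fcs_text <- function(raw_text) {
  delim <- rawToChar(raw_text[1])
  body <- rawToChar(raw_text[-1])
  Encoding(body) <- "latin1"
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  # trailing delimiter yields a final empty part; drop it
  if (length(parts) %% 2 == 1 && parts[length(parts)] == "") parts <- parts[-length(parts)]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- trimws(parts[seq(1, length(parts), by = 2)])
  vals <- parts[seq(2, length(parts), by = 2)]
  stats::setNames(as.list(vals), toupper(keys))
}

read_fcs_raw <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(raw) < 58) stop_binbat("binbat_io_error", sprintf("not an FCS file: %s", path))
  version <- trimws(rawToChar(raw[1:6]))
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop_binbat("binbat_io_error", sprintf(
      "unsupported FCS version '%s' (only FCS 3.0/3.1 are supported)", version))
  off <- function(i, j) as.numeric(trimws(rawToChar(raw[i:j])))
  text_beg <- off(11, 18); text_end <- off(19, 26)
  data_beg <- off(27, 34); data_end <- off(35, 42)
  kw <- parse_fcs_text(raw[(text_beg + 1):(text_end + 1)])
  if (is.na(data_beg) || data_beg == 0) data_beg <- as.numeric(kw[["$BEGINDATA"]])
  if (is.na(data_end) || data_end == 0) data_end <- as.numeric(kw[["$ENDDATA"]])
  mode <- toupper(trimws(kw[["$MODE"]] %||% "L"))
  if (mode != "L") stop_binbat("binbat_io_error", "only list-mode ($MODE L) FCS data is supported")
  npar <- as.integer(kw[["$PAR"]]); ntot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(trimws(kw[["$DATATYPE"]]))
  byteord <- gsub("\\s", "", kw[["$BYTEORD"]] %||% "1,2,3,4")
  endian <- if (byteord %in% c("1,2,3,4", "1,2", "1")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else stop_binbat("binbat_io_error", sprintf("unsupported $BYTEORD '%s'", byteord))
  bits <- vapply(seq_len(npar), function(i) as.integer(kw[[sprintf("$P%dB", i)]]), integer(1))
  names_ <- vapply(seq_len(npar), function(i) kw[[sprintf("$P%dN", i)]], character(1))
  con <- rawConnection(raw[(data_beg + 1):(data_end + 1)])
  on.exit(close(con))
  vals <- if (dtype == "F") {
    if (any(bits != 32)) stop_binbat("binbat_io_error", "$DATATYPE F requires $PnB 32")
    readBin(con, what = "numeric", n = npar * ntot, size = 4, endian = endian)
  } else if (dtype == "D") {
    if (any(bits != 64)) stop_binbat("binbat_io_error", "$DATATYPE D requires $PnB 64")
    readBin(con, what = "numeric", n = npar * ntot, size = 8, endian = endian)
  } else if (dtype == "I") {
    if (!all(bits %in% c(8L, 16L, 32L)) || length(unique(bits)) != 1L)
      stop_binbat("binbat_io_error", "$DATATYPE I requires uniform $PnB of 8, 16 or 32")
    v <- readBin(con, what = "integer", n = npar * ntot, size = bits[1] / 8,
                 signed = bits[1] < 32, endian = endian)
    v <- as.numeric(v)
    v[v < 0] <- v[v < 0] + 2^32  # 32-bit values read as signed
    if (bits[1] < 32) v[v < 0] <- v[v < 0] + 2^bits[1]
    v
  } else {
    stop_binbat("binbat_io_error", sprintf("unsupported $DATATYPE '%s'", dtype))
  }
  if (length(vals) != npar * ntot)
    stop_binbat("binbat_io_error", "truncated FCS data segment")
  mat <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE)
  colnames(mat) <- names_
  list(values = mat, keywords = kw)
}

#' Write an event table to a minimal FCS 3.1 file
#'
#' Writes list-mode, little-endian 32-bit float data. Used by the
#' simulator (`binbat simulate`) and by tests to build FCS inputs in
#' code. Event values survive a write/read round trip to single
#' precision (relative error below 1e-6).
#'
#' @param t an `event_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(t, path) {
  mat <- t$values
  npar <- ncol(mat); ntot <- nrow(mat)
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0", "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$MODE" = "L", "$DATATYPE" = "F", "$BYTEORD" = "1,2,3,4",
    "$NEXTDATA" = "0", "$PAR" = as.character(npar), "$TOT" = as.character(ntot))
  for (i in seq_len(npar)) {
    kw[sprintf("$P%dN", i)] <- t$channel_names[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- format(max(1, ceiling(max(0, mat[, i], na.rm = TRUE)) + 1),
                                      scientific = FALSE)
  }
  build_text <- function(kw) paste0("/", paste0(names(kw), "/", kw, "/", collapse = ""))
  # fixed-width data offsets so TEXT length is stable when they are filled in
  text0 <- build_text(kw)
  text_beg <- 256L
  text_len <- nchar(text0, type = "bytes") + 2L * (12L - 4L)  # %BD%/%ED% -> 12 digits
  data_beg <- text_beg + text_len
  data_end <- data_beg + 4L * npar * ntot - 1L
  kw["$BEGINDATA"] <- sprintf("%012d", data_beg)
  kw["$ENDDATA"] <- sprintf("%012d", data_end)
  text <- build_text(kw)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", text_beg, data_beg - 1L,
                    data_beg, data_end, 0L, 0L)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeBin(raw(text_beg - nchar(header, type = "bytes")), con)  # pad with NULs
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}
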