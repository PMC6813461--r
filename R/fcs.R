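# Minimal FCS 3.0/3.1 list-mode reader and writer.
#
# Supports the TEXT + DATA segment layout with float (F), double (D) or
# integer (I) storage and little- or big-endian byte order. Marker names are
# taken from $PnS with $PnN as fallback, matching how acquisition software
# stores stain names vs channel names. Analysis segments, FCS 2.0 and
# mixed-width integer data are out of scope.

fcs_read_text_segment <- function(raw, beg, end) {
  txt <- rawToChar(raw[(beg + 1):(end + 1)])
  delim <- substr(txt, 1, 1)
  body <- substring(txt, 2)
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  parts <- parts[seq_len(length(parts) - length(parts) %% 2)]
  keys <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  vals <- trimws(parts[seq(2, length(parts), by = 2)])
  setNames(as.list(vals), keys)
}

fcs_keyword <- function(kw, key, numeric = FALSE) {
  v <- kw[[key]]
  if (is.null(v) || !nzchar(v)) {
    abort(paste0("malformed FCS file: missing required keyword ", key),
          class = "cytoforge_format_error")
  }
  if (numeric) as.numeric(v) else v
}

read_fcs <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(raw) < 58) {
    abort("malformed FCS file: truncated HEADER segment",
          class = "cytoforge_format_error")
  }
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    abort(paste0("malformed FCS file: unsupported version '", version, "'"),
          class = "cytoforge_format_error")
  }
  offsets <- vapply(0:5, function(i) {
    as.numeric(trimws(rawToChar(raw[(11 + 8 * i):(18 + 8 * i)])))
  }, numeric(1))
  kw <- fcs_read_text_segment(raw, offsets[1], offsets[2])

  n_par <- as.integer(fcs_keyword(kw, "$PAR", numeric = TRUE))
  n_tot <- as.integer(fcs_keyword(kw, "$TOT", numeric = TRUE))
  mode <- fcs_keyword(kw, "$MODE")
  if (mode != "L") {
    abort("malformed FCS file: only list mode supported ($MODE)",
          class = "cytoforge_format_error")
  }
  dtype <- fcs_keyword(kw, "$DATATYPE")
  byteord <- fcs_keyword(kw, "$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4", "1,2", "1")) "little" else "big"

  data_beg <- as.numeric(kw[["$BEGINDATA"]] %||% "0")
  data_end <- as.numeric(kw[["$ENDDATA"]] %||% "0")
  if (data_beg <= 0) { data_beg <- offsets[3]; data_end <- offsets[4] }

  n_values <- n_par * n_tot
  if (dtype == "F") {
    vals <- readBin(raw[(data_beg + 1):(data_end + 1)], what = "numeric",
                    n = n_values, size = 4, endian = endian)
  } else if (dtype == "D") {
    vals <- readBin(raw[(data_beg + 1):(data_end + 1)], what = "numeric",
                    n = n_values, size = 8, endian = endian)
  } else if (dtype == "I") {
    bits <- as.integer(fcs_keyword(kw, "$P1B", numeric = TRUE))
    vals <- readBin(raw[(data_beg + 1):(data_end + 1)], what = "integer",
                    n = n_values, size = bits / 8, endian = endian,
                    signed = bits > 16)
  } else {
    abort(paste0("malformed FCS file: unsupported $DATATYPE '", dtype, "'"),
          class = "cytoforge_format_error")
  }
  if (length(vals) < n_values) {
    abort("malformed FCS file: DATA segment shorter than $TOT x $PAR",
          class = "cytoforge_format_error")
  }
  mat <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  nms <- vapply(seq_len(n_par), function(i) {
    s <- kw[[paste0("$P", i, "S")]]
    if (is.null(s) || !nzchar(s)) s <- kw[[paste0("$P", i, "N")]]
    if (is.null(s) || !nzchar(s)) {
      abort(paste0("malformed FCS file: no $P", i, "N name for channel ", i),
            class = "cytoforge_format_error")
    }
    trimws(s)
  }, character(1))
  colnames(mat) <- nms
  mat
}

write_fcs <- function(mat, path) {
  n_tot <- nrow(mat)
  n_par <- ncol(mat)
  d <- "/"
  ranges <- vapply(seq_len(n_par), function(i) {
    r <- suppressWarnings(max(mat[, i], 0))
    format(ceiling(max(r, 1)), scientific = FALSE)
  }, character(1))
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    # fixed-width so the TEXT segment length does not depend on the offsets
    "$BEGINDATA" = sprintf("%012d", 0), "$ENDDATA" = sprintf("%012d", 0),
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot)
  )
  for (i in seq_len(n_par)) {
    kw[[paste0("$P", i, "N")]] <- colnames(mat)[i]
    kw[[paste0("$P", i, "S")]] <- colnames(mat)[i]
    kw[[paste0("$P", i, "B")]] <- "32"
    kw[[paste0("$P", i, "E")]] <- "0,0"
    kw[[paste0("$P", i, "R")]] <- ranges[i]
  }
  text_body <- paste0(d, paste0(names(kw), d, unname(kw), d, collapse = ""))
  header_len <- 58
  text_beg <- header_len
  text_end <- text_beg + nchar(text_body) - 1
  data_beg <- text_end + 1
  data_end <- data_beg + 4 * n_par * n_tot - 1
  text_body <- sub(paste0("$BEGINDATA", d, sprintf("%012d", 0)),
                   paste0("$BEGINDATA", d, sprintf("%012d", data_beg)),
                   text_body, fixed = TRUE)
  text_body <- sub(paste0("$ENDDATA", d, sprintf("%012d", 0)),
                   paste0("$ENDDATA", d, sprintf("%012d", data_end)),
                   text_body, fixed = TRUE)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_beg, text_end,
                    if (data_end <= 99999999) data_beg else 0,
                    if (data_end <= 99999999) data_end else 0, 0, 0)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeChar(header, con, eos = NULL)
  writeChar(text_body, con, eos = NULL)
  writeBin(as.numeric(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}
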