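# FCS 3.0 list-mode reader/writer.
#
# Layout recap (per dataset): a 58-byte HEADER ("FCS3.0" + 4 spaces + six
# 8-char right-justified ASCII offsets: TEXT begin/end, DATA begin/end,
# ANALYSIS begin/end), a TEXT segment of delimiter-separated keyword/value
# pairs, and a DATA segment. Merged files chain datasets through the
# $NEXTDATA keyword. All offsets in this dialect are relative to the start
# of the dataset's own HEADER (0 for a single-dataset file, where they
# coincide with absolute offsets); $NEXTDATA is likewise relative, which is
# also how flowCore-family readers walk chained files.

FCS_HEADER_BYTES <- 58L

# Precedence list for the well-identity keyword; instrument software does
# not agree on a single name, so the first present wins.
WELL_KEYWORDS <- c("$WELLID", "WELLID", "WELL ID", "WELL", "$SMNO")

read_header_offsets <- function(raw, base) {
  magic <- rawToChar(raw[(base + 1):(base + 6)])
  if (!magic %in% c("FCS3.0", "FCS3.1"))
    md_stop(sprintf("not an FCS 3.0/3.1 dataset at byte %d (magic '%s')",
                    base, magic), "myodiff_parse_error")
  fields <- vapply(0:5, function(i) {
    txt <- rawToChar(raw[(base + 11 + 8 * i):(base + 18 + 8 * i)])
    v <- suppressWarnings(as.numeric(trimws(txt)))
    if (is.na(v))
      md_stop(sprintf("HEADER offset field %d at byte %d is not an integer",
                      i + 1, base + 10 + 8 * i), "myodiff_parse_error")
    v
  }, numeric(1))
  list(text_beg = fields[1], text_end = fields[2],
       data_beg = fields[3], data_end = fields[4])
}

parse_text_segment <- function(raw, base, beg, end) {
  txt <- rawToChar(raw[(base + beg + 1):(base + end + 1)])
  delim <- substr(txt, 1, 1)
  body <- substring(txt, 2)
  # strip one trailing delimiter (required by the standard)
  if (substring(body, nchar(body)) == delim)
    body <- substring(body, 1, nchar(body) - 1)
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 != 0 || any(parts == ""))
    md_stop(sprintf("inconsistent TEXT delimiters in segment starting at byte %d",
                    base + beg), "myodiff_parse_error")
  kw <- parts[seq(2, length(parts), by = 2)]
  names(kw) <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  kw
}

kw_num <- function(kw, key, default = NA_real_) {
  if (!key %in% names(kw)) return(default)
  suppressWarnings(as.numeric(trimws(kw[[key]])))
}

#' Read an FCS 3.0 file
#'
#' Reads list-mode FCS 3.0 (or 3.1) files, including merged files in which
#' several datasets are chained through the next-dataset offset. Supported
#' storage types are float32 (`$DATATYPE F`) and unsigned integers up to
#' 32 bit (`$DATATYPE I`); integer data carrying a log-amplification
#' keyword (`$PnE` with decades > 0) is linearized to RFU on read as
#' `f2 * 10^(decades * v / range)` (with a stored offset `f2` of 0 read
#' as 1), because all gating in this package operates on the linear scale.
#'
#' The plate well is taken from the first keyword present among
#' `$WELLID`, `WELLID`, `WELL ID`, `WELL`, `$SMNO`.
#'
#' @param path Path to an `.fcs` file.
#' @return A list of [fcs_sample()] objects, one per dataset, in file order.
#' @export
read_fcs <- function(path) {
  if (!file.exists(path))
    md_stop(sprintf("file not found: %s", path), "myodiff_io_error")
  raw <- readBin(path, "raw", n = file.size(path))
  base_id <- sub("\\.fcs$", "", basename(path), ignore.case = TRUE)
  samples <- list()
  base <- 0
  repeat {
    off <- read_header_offsets(raw, base)
    kw <- parse_text_segment(raw, base, off$text_beg, off$text_end)

    dtype <- toupper(trimws(kw[["$DATATYPE"]]))
    if (dtype %in% c("A", "D"))
      md_stop(sprintf("unsupported FCS datatype '%s' (only 'F' and 'I' list-mode data are read)",
                      dtype), "myodiff_unsupported_format")
    if (!dtype %in% c("F", "I"))
      md_stop(sprintf("unknown FCS datatype '%s'", dtype), "myodiff_parse_error")
    if (toupper(trimws(kw_chr(kw, "$MODE", "L"))) != "L")
      md_stop("only list-mode ($MODE L) data is supported",
              "myodiff_unsupported_format")

    p <- as.integer(kw_num(kw, "$PAR"))
    n <- as.integer(kw_num(kw, "$TOT"))
    byteord <- trimws(kw_chr(kw, "$BYTEORD", "1,2,3,4"))
    endian <- switch(byteord, "1,2,3,4" = "little", "4,3,2,1" = "big",
                     md_stop(sprintf("unsupported $BYTEORD '%s'", byteord),
                             "myodiff_unsupported_format"))

    data_beg <- off$data_beg
    data_end <- off$data_end
    if (data_beg == 0 && data_end == 0) {
      data_beg <- kw_num(kw, "$BEGINDATA", 0)
      data_end <- kw_num(kw, "$ENDDATA", 0)
    }

    ch_names <- vapply(seq_len(p), function(i)
      kw_chr(kw, sprintf("$P%dN", i), sprintf("P%d", i)), character(1))
    ranges <- vapply(seq_len(p), function(i)
      kw_num(kw, sprintf("$P%dR", i), 10000), numeric(1))
    bits <- vapply(seq_len(p), function(i)
      kw_num(kw, sprintf("$P%dB", i), 32), numeric(1))
    pne <- t(vapply(seq_len(p), function(i) {
      v <- strsplit(kw_chr(kw, sprintf("$P%dE", i), "0,0"), ",")[[1]]
      as.numeric(v[1:2])
    }, numeric(2)))

    bytes_per <- if (dtype == "F") 4L else as.integer(unique(bits) / 8)
    if (dtype == "I" && (length(unique(bits)) != 1L ||
                         !unique(bits) %in% c(8, 16, 32)))
      md_stop("integer data must use a uniform $PnB of 8, 16 or 32 bits",
              "myodiff_unsupported_format")

    n_values <- n * p
    if (n_values > 0) {
      seg_size <- data_end - data_beg + 1
      if (seg_size != n_values * bytes_per)
        md_stop(sprintf(
          "DATA segment size (%d bytes) disagrees with $TOT x $PAR (%d x %d x %d bytes)",
          seg_size, n, p, bytes_per), "myodiff_integrity_error")
      con <- raw[(base + data_beg + 1):(base + data_end + 1)]
      if (dtype == "F") {
        vals <- readBin(con, "double", n = n_values, size = 4L, endian = endian)
      } else {
        if (bytes_per < 4L) {
          vals <- readBin(con, "integer", n = n_values, size = bytes_per,
                          signed = FALSE, endian = endian)
        } else {
          vals <- readBin(con, "integer", n = n_values, size = 4L,
                          endian = endian)
          vals <- ifelse(vals < 0, vals + 2^32, vals)
        }
        vals <- as.numeric(vals)
      }
      events <- matrix(vals, ncol = p, byrow = TRUE)
    } else {
      events <- matrix(numeric(0), ncol = p)
    }

    if (dtype == "I") {
      for (i in seq_len(p)) {
        f1 <- pne[i, 1]; f2 <- pne[i, 2]
        if (!is.na(f1) && f1 > 0) {
          f2x <- if (is.na(f2) || f2 == 0) 1 else f2
          events[, i] <- f2x * 10^(f1 * events[, i] / ranges[i])
        }
      }
    }

    ordinal <- length(samples) + 1L
    well <- NULL
    for (wk in WELL_KEYWORDS) {
      if (wk %in% names(kw)) { well <- kw[[wk]]; break }
    }
    samples[[ordinal]] <- fcs_sample(
      events = events,
      channels = data.frame(name = ch_names, range = ranges,
                            decades = pne[, 1], offset = pne[, 2],
                            stringsAsFactors = FALSE),
      sample_id = if (kw_num(kw, "$NEXTDATA", 0) > 0 || ordinal > 1)
        sprintf("%s_%02d", base_id, ordinal) else base_id,
      well_id = well, keywords = kw)

    nextdata <- kw_num(kw, "$NEXTDATA", 0)
    if (is.na(nextdata) || nextdata <= 0) break
    base <- base + nextdata
    if (base >= length(raw))
      md_stop("next-dataset offset points past end of file",
              "myodiff_parse_error")
  }
  samples
}

kw_chr <- function(kw, key, default = NA_character_) {
  if (key %in% names(kw)) kw[[key]] else default
}

# zero-padded fixed-width offset values keep the TEXT length independent of
# the values so offsets can be computed in one pass
pad10 <- function(x) sprintf("%010d", as.integer(x))

#' Write samples to an FCS 3.0 file
#'
#' Emits list-mode FCS 3.0: float32, little-endian, TEXT delimiter `/`,
#' linear amplification (`$PnE` `0,0`). Multiple samples are chained into
#' one merged file via the next-dataset offset. A file written by this
#' function reads back bit-exactly at float32 precision.
#'
#' @param samples A single [fcs_sample()] or a list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fcs <- function(samples, path) {
  if (inherits(samples, "fcs_sample")) samples <- list(samples)
  if (length(samples) == 0L)
    md_stop("no samples to write", "myodiff_invalid_sample")
  con <- file(path, "wb")
  on.exit(close(con))
  for (k in seq_along(samples)) {
    s <- samples[[k]]
    if (!inherits(s, "fcs_sample"))
      md_stop("write_fcs expects fcs_sample objects", "myodiff_invalid_sample")
    p <- nrow(s$channels)
    if (p == 0L)
      md_stop("cannot write a sample with an empty channel list",
              "myodiff_invalid_sample")
    n <- nrow(s$events)

    kw <- c(
      "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
      "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
      "$BEGINDATA" = pad10(0), "$ENDDATA" = pad10(0),
      "$NEXTDATA" = pad10(0),
      "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
      "$TOT" = as.character(n), "$PAR" = as.character(p)
    )
    for (i in seq_len(p)) {
      kw[sprintf("$P%dN", i)] <- s$channels$name[i]
      kw[sprintf("$P%dB", i)] <- "32"
      kw[sprintf("$P%dR", i)] <- format(s$channels$range[i], scientific = FALSE)
      kw[sprintf("$P%dE", i)] <- "0,0"
    }
    if (!is.null(s$well_id)) kw["$WELLID"] <- s$well_id
    extra <- s$keywords[setdiff(names(s$keywords), names(kw))]
    extra <- extra[nzchar(names(extra))]
    kw <- c(kw, extra)
    kw[!nzchar(kw)] <- " "
    if (any(grepl("/", kw, fixed = TRUE) | grepl("/", names(kw), fixed = TRUE)))
      md_stop("keyword names/values may not contain the TEXT delimiter '/'",
              "myodiff_invalid_sample")

    build_text <- function(kw) {
      paste0("/", paste(rbind(names(kw), unname(kw)), collapse = "/"), "/")
    }
    text_len <- nchar(build_text(kw), type = "bytes")
    text_beg <- FCS_HEADER_BYTES
    text_end <- text_beg + text_len - 1L
    data_size <- 4L * n * p
    data_beg <- if (data_size > 0) text_end + 1L else 0L
    data_end <- if (data_size > 0) data_beg + data_size - 1L else 0L
    dataset_size <- FCS_HEADER_BYTES + text_len + data_size
    kw["$BEGINDATA"] <- pad10(data_beg)
    kw["$ENDDATA"] <- pad10(data_end)
    kw["$NEXTDATA"] <- pad10(if (k < length(samples)) dataset_size else 0L)

    header <- paste0("FCS3.0    ",
                     sprintf("%8d", text_beg), sprintf("%8d", text_end),
                     if (data_beg <= 99999999) sprintf("%8d", data_beg) else sprintf("%8d", 0),
                     if (data_end <= 99999999) sprintf("%8d", data_end) else sprintf("%8d", 0),
                     sprintf("%8d", 0), sprintf("%8d", 0))
    writeChar(header, con, eos = NULL)
    writeChar(build_text(kw), con, eos = NULL)
    if (data_size > 0)
      writeBin(as.numeric(t(s$events)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Export population statistics as CSV
#'
#' Writes the population table with the exact header `sample,pop,count`,
#' counts as plain integers — the layout downstream statistics tools expect.
#'
#' @param stats Data frame with columns `sample`, `pop`, `count`
#'   (see [population_stats()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_population_stats <- function(stats, path) {
  stats <- as.data.frame(stats, stringsAsFactors = FALSE)
  if (!identical(names(stats)[1:3], c("sample", "pop", "count")))
    md_stop("stats must have columns sample, pop, count",
            "myodiff_input_error")
  if (nrow(stats) > 0) {
    if (any(stats$count < 0) || any(stats$count != as.integer(stats$count)))
      md_stop("counts must be non-negative integers", "myodiff_input_error")
    if (any(grepl(",", c(stats$sample, stats$pop))))
      md_stop("sample/pop values may not contain commas", "myodiff_input_error")
  }
  lines <- c("sample,pop,count",
             if (nrow(stats) > 0)
               paste(stats$sample, stats$pop, as.integer(stats$count), sep = ","))
  writeLines(lines, path)
  invisible(path)
}
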