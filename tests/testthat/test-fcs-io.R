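# FCS 3.0 reader/writer and CSV export.

# Bytes are laid out by hand, independently of write_fcs: 58-byte header,
# TEXT segment with '/' delimiter, float32 little-endian DATA.
hand_fcs_bytes <- function(text_body, data_values = NULL, datatype = "F",
                           int_size = 2L) {
  text <- paste0("/", text_body, "/")
  text_beg <- 58L
  text_end <- text_beg + nchar(text) - 1L
  if (!is.null(data_values)) {
    size <- if (datatype == "F") 4L else int_size
    data_beg <- text_end + 1L
    data_end <- data_beg + size * length(data_values) - 1L
  } else data_beg <- data_end <- 0L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d", text_beg, text_end,
                    data_beg, data_end, 0L, 0L)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (!is.null(data_values)) {
    if (datatype == "F") writeBin(as.numeric(data_values), con, size = 4L,
                                  endian = "little")
    else writeBin(as.integer(data_values), con, size = int_size,
                  endian = "little")
  }
  rawConnectionValue(con)
}

write_tmp <- function(bytes) {
  path <- tempfile(fileext = ".fcs")
  writeBin(bytes, path)
  path
}

test_that("hand-authored float32 file parses to the exact event matrix", {
  text <- paste("$DATATYPE/F/$MODE/L/$BYTEORD/1,2,3,4/$PAR/4/$TOT/3",
                "$P1N/FSC-HLin/$P2N/SSC-HLin/$P3N/GRN-B-HLin/$P4N/RED-R-HLin",
                "$NEXTDATA/0/$WELLID/A05", sep = "/")
  path <- write_tmp(hand_fcs_bytes(text, data_values = 1:12))
  samples <- read_fcs(path)
  expect_length(samples, 1L)
  s <- samples[[1]]
  expect_identical(unname(s$events), matrix(as.numeric(1:12), ncol = 4,
                                            byrow = TRUE))
  expect_identical(s$channels$name,
                   c("FSC-HLin", "SSC-HLin", "GRN-B-HLin", "RED-R-HLin"))
  expect_identical(s$well_id, "A05")
})

test_that("integer data with log amplification is linearized to RFU", {
  # $P1E = "4,1": rfu = 1 * 10^(4 * v / 1024); v = 512 -> 100, v = 1024 -> 1e4
  text <- paste("$DATATYPE/I/$MODE/L/$BYTEORD/1,2,3,4/$PAR/1/$TOT/2",
                "$P1N/GRN-B-HLin/$P1B/16/$P1R/1024/$P1E/4,1/$NEXTDATA/0",
                sep = "/")
  path <- write_tmp(hand_fcs_bytes(text, data_values = c(512L, 1024L),
                                   datatype = "I"))
  s <- read_fcs(path)[[1]]
  expect_equal(as.numeric(s$events), c(100, 10000), tolerance = 1e-12)
})

test_that("unsupported datatypes and malformed TEXT are rejected loudly", {
  bad_type <- write_tmp(hand_fcs_bytes(
    "$DATATYPE/A/$MODE/L/$PAR/1/$TOT/0/$P1N/X/$NEXTDATA/0"))
  expect_error_class(read_fcs(bad_type), "myodiff_unsupported_format")

  # doubled delimiter -> empty field -> parse error naming the byte offset
  bad_text <- write_tmp(hand_fcs_bytes(
    "$DATATYPE/F/$MODE/L//$PAR/1/$TOT/0/$P1N/X/$NEXTDATA/0"))
  err <- tryCatch(read_fcs(bad_text), error = identity)
  expect_s3_class(err, "myodiff_parse_error")
  expect_match(conditionMessage(err), "byte 58")
})

test_that("event-count keyword must agree with the DATA segment size", {
  text <- paste("$DATATYPE/F/$MODE/L/$BYTEORD/1,2,3,4/$PAR/2/$TOT/5",
                "$P1N/A/$P2N/B/$NEXTDATA/0", sep = "/")
  path <- write_tmp(hand_fcs_bytes(text, data_values = 1:6))  # only 3 events
  expect_error_class(read_fcs(path), "myodiff_integrity_error")
})

test_that("write_fcs / read_fcs round-trips event data bit-exactly at float32", {
  set.seed(7)
  s <- simulate_sample(small_sim_config(n_events = 30000), "target",
                       sample_id = "t", well_id = "B02")
  path <- tempfile(fileext = ".fcs")
  write_fcs(s, path)
  back <- read_fcs(path)[[1]]
  # expected values are the float32 image of the original doubles
  f32 <- function(x) readBin(writeBin(as.numeric(x), raw(), size = 4L),
                             "double", n = length(x), size = 4L)
  expect_identical(as.numeric(t(back$events)), f32(t(s$events)))
  expect_identical(back$channels$name, s$channels$name)
  expect_identical(back$well_id, "B02")
  # writing the read-back sample again reproduces the payload byte for byte
  path2 <- tempfile(fileext = ".fcs")
  write_fcs(back, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("zero-event samples survive a round trip", {
  s <- make_sample(0)
  path <- tempfile(fileext = ".fcs")
  write_fcs(s, path)
  back <- read_fcs(path)[[1]]
  expect_identical(nrow(back$events), 0L)
  expect_identical(back$channels$name, s$channels$name)
})

test_that("merged files chain datasets and preserve order and wells", {
  for (len in c(1L, 2L, 3L, 10L)) {
    wells <- sprintf("A%02d", seq_len(len))
    samples <- lapply(seq_len(len), function(i)
      make_sample(5, gfp = i * 10, sample_id = paste0("s", i),
                  well_id = wells[i]))
    path <- tempfile(fileext = ".fcs")
    write_fcs(samples, path)
    back <- read_fcs(path)
    expect_length(back, len)
    expect_identical(vapply(back, function(s) s$well_id, character(1)), wells)
    for (i in seq_len(len))
      expect_equal(back[[i]]$events[, "GRN-B-HLin"], rep(i * 10, 5))
  }
})

test_that("empty channel lists are rejected by the writer", {
  expect_error_class(
    fcs_sample(matrix(numeric(0), ncol = 0), character(0), "x"),
    "myodiff_invalid_sample")
})

test_that("population CSV export uses the exact header and re-parses identically", {
  path <- tempfile(fileext = ".csv")
  export_population_stats(
    data.frame(sample = character(0), pop = character(0),
               count = integer(0)), path)
  expect_identical(readLines(path), "sample,pop,count")

  export_population_stats(
    data.frame(sample = "s1", pop = "/NonDebris", count = 29500L), path)
  expect_identical(readLines(path), c("sample,pop,count",
                                      "s1,/NonDebris,29500"))

  # full hierarchy for two samples: 2 x 6 rows, child <= parent on re-read
  pops <- c("root", "/NonDebris", "/NonDebris/GFP+",
            "/NonDebris/GFP+/GFP-low", "/NonDebris/GFP+/GFP-medium",
            "/NonDebris/GFP+/GFP-low/MyHC+")
  stats <- do.call(rbind, lapply(c("s1", "s2"), function(id)
    data.frame(sample = id, pop = pops,
               count = c(30000L, 29000L, 12000L, 5000L, 4000L, 2000L))))
  export_population_stats(stats, path)
  back <- read.csv(path, colClasses = c("character", "character", "integer"))
  expect_identical(back, stats, ignore_attr = TRUE)
  expect_identical(nrow(back), 12L)
  for (id in c("s1", "s2")) {
    b <- back[back$sample == id, ]
    get <- function(p) b$count[b$pop == p]
    expect_lte(get("/NonDebris"), get("root"))
    expect_lte(get("/NonDebris/GFP+"), get("/NonDebris"))
    expect_lte(get("/NonDebris/GFP+/GFP-low"), get("/NonDebris/GFP+"))
    expect_lte(get("/NonDebris/GFP+/GFP-low/MyHC+"),
               get("/NonDebris/GFP+/GFP-low"))
  }
})
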