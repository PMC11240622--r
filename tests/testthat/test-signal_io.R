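test_that("ecg_record validates its invariants", {
  expect_s3_class(ecg_record(c(0, 1, 0), 100), "ecg_record")
  expect_error(ecg_record(c(0, NA), 100), "non-finite")
  expect_error(ecg_record(c(0, 1), 0), "positive")
  expect_error(ecg_record(c(0, 1, 0), 100, r_peaks = c(2, 1)), "increasing")
  expect_error(ecg_record(c(0, 1, 0), 100, r_peaks = 5), "length")
  expect_error(ecg_record(c(0, 1, 0), 100, r_peaks = 1, labels = c("a", "b")),
               "one entry per R-peak")
})

test_that("CSV signal reading handles one and two columns, headers, errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.0", "1.0", "0.0"), p)
  rec <- read_csv_signal(p, fs = 100)
  expect_equal(rec$samples, c(0, 1, 0))
  expect_equal(rec$fs, 100)

  # two columns: amplitude column used, fs cross-checked
  writeLines(c("time,amplitude", "0.00,0.5", "0.01,1.5", "0.02,0.5"), p)
  rec2 <- read_csv_signal(p, fs = 100)
  expect_equal(rec2$samples, c(0.5, 1.5, 0.5))
  expect_error(read_csv_signal(p, fs = 250), "disagrees")

  writeLines(character(0), p)
  expect_error(read_csv_signal(p, fs = 100), "empty")

  writeLines(c("0.1", "oops", "0.3"), p)
  expect_error(read_csv_signal(p, fs = 100), "line 2")
})

test_that("signal CSV write -> read round-trips to 1e-12", {
  p <- withr::local_tempfile(fileext = ".csv")
  set.seed(42)
  rec <- ecg_record(rnorm(500), 250)
  write_csv_signal(rec, p)
  back <- read_csv_signal(p, fs = 250)
  expect_lt(max(abs(back$samples - rec$samples)), 1e-12)
})

test_that("feature table round-trips, quotes awkward names, rejects bad input", {
  p <- withr::local_tempfile(fileext = ".csv")
  set.seed(1)
  fm <- feature_matrix(matrix(rnorm(6), 2, 3),
                       c("plain", "with,comma", "fdct_01"),
                       c("normal", "anomalous"))
  write_feature_table(fm, p)
  back <- read_feature_table(p)
  expect_equal(back$names, fm$names)
  expect_equal(back$labels, fm$labels)
  expect_lt(max(abs(back$values - fm$values)), 1e-12)

  expect_error(feature_matrix(matrix(0, 0, 2), c("a", "b"), character(0)),
               "at least one row")
  expect_error(feature_matrix(matrix(0, 1, 2), c("a", "a"), "x"), "duplicate")
})

test_that("WFDB reader agrees with the independent fixture writer", {
  dir <- withr::local_tempdir()
  set.seed(9)
  adc <- matrix(as.integer(round(200 * sin(2 * pi * 5 * (0:999) / 360))),
                nrow = 1)
  ann <- data.frame(index = c(100L, 400L, 750L), code = c(1L, 5L, 1L))
  write_wfdb_fixture(dir, "rec01", adc, fs = 360, gain = 200, baseline = 0,
                     ann = ann)
  rec <- read_wfdb_record(file.path(dir, "rec01"))
  expect_equal(length(rec$samples), 1000L)
  expect_equal(rec$fs, 360)
  expect_lt(max(abs(rec$samples - adc[1, ] / 200)), 1e-12)
  expect_equal(rec$r_peaks, c(100L, 400L, 750L))
  expect_true(all(diff(rec$r_peaks) > 0))
  expect_equal(rec$labels, c("N", "V", "N"))
})

test_that("WFDB reader errors name the file / channel / gain problem", {
  dir <- withr::local_tempdir()
  expect_error(read_wfdb_record(file.path(dir, "nope")), "missing WFDB header")
  adc <- matrix(0:9, nrow = 1)
  write_wfdb_fixture(dir, "tiny", adc, fs = 250)
  expect_error(read_wfdb_record(file.path(dir, "tiny"), channel = 3),
               "out of range")
  # corrupt gain
  hea <- readLines(file.path(dir, "tiny.hea"))
  hea[2] <- sub("200\\(0\\)/mV", "0(0)/mV", hea[2])
  writeLines(hea, file.path(dir, "tiny.hea"))
  expect_error(read_wfdb_record(file.path(dir, "tiny")), "gain")
})

test_that("minimal two-sample record round-trips through the WFDB reader", {
  dir <- withr::local_tempdir()
  write_wfdb_fixture(dir, "mini", matrix(c(100L, -100L), nrow = 1), fs = 500)
  rec <- read_wfdb_record(file.path(dir, "mini"))
  expect_equal(length(rec$samples), 2L)
  expect_equal(rec$fs, 500)
  expect_equal(rec$samples, c(0.5, -0.5))
})

test_that("format 212 packing is decoded correctly", {
  dir <- withr::local_tempdir()
  # two signals, format 212: pack pairs (s1, s2) into 3 bytes
  s1 <- c(10L, -5L, 300L, -300L)
  s2 <- c(0L, 100L, -100L, 7L)
  to12 <- function(v) ifelse(v < 0L, v + 4096L, v)
  con <- file(file.path(dir, "p212.dat"), "wb")
  for (i in seq_along(s1)) {
    a <- to12(s1[i]); b <- to12(s2[i])
    bytes <- c(a %% 256L, (a %/% 256L) + 16L * (b %/% 256L), b %% 256L)
    writeBin(as.integer(bytes), con, size = 1L)
  }
  close(con)
  writeLines(c("p212 2 360 4",
               "p212.dat 212 200(0)/mV 12 0 0 0 0 a",
               "p212.dat 212 200(0)/mV 12 0 0 0 0 b"),
             file.path(dir, "p212.hea"))
  r1 <- read_wfdb_record(file.path(dir, "p212"), channel = 1)
  r2 <- read_wfdb_record(file.path(dir, "p212"), channel = 2)
  expect_equal(r1$samples * 200, s1)
  expect_equal(r2$samples * 200, s2)
})
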