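# Minimal WFDB reader: header (.hea), signal (.dat, formats 16 and 212) and
# beat annotations (.atr, MIT annotation format). Only what the pipeline
# needs: one record per header, single-segment, amplitudes converted to
# physical units via the per-signal gain/baseline.

# Annotation codes -> symbols for the common MIT beat alphabet.
.wfdb_symbols <- c("N", "L", "R", "a", "V", "F", "J", "A", "S", "E", "j",
                   "/", "Q", "~", "[15]", "|", "[17]", "s", "T", "*", "D",
                   "\"", "=", "p", "t", "u", "`", "'", "^", "[30]", "[31]",
                   "[32]", "@", "(", ")", "p", "t", "x", "[39]", "(", ")")
.wfdb_beat_codes <- c(1:13, 25, 34, 35, 38, 41)

parse_wfdb_header <- function(hea_path) {
  if (!file.exists(hea_path)) stop("missing WFDB header: ", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("corrupt WFDB header (empty): ", hea_path)
  rec <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(rec) < 2L) stop("corrupt WFDB header record line: ", hea_path)
  nsig <- as.integer(rec[[2L]])
  fs <- if (length(rec) >= 3L) as.numeric(sub("/.*$", "", rec[[3L]])) else 250
  nsamp <- if (length(rec) >= 4L) as.integer(rec[[4L]]) else NA_integer_
  if (!is.finite(fs) || fs <= 0) stop("corrupt WFDB header fs: ", hea_path)
  if (length(lines) < 1L + nsig) stop("corrupt WFDB header (missing signal lines): ", hea_path)
  sig <- lapply(lines[1L + seq_len(nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) < 2L) stop("corrupt WFDB signal line: ", ln)
    fmt <- as.integer(sub("x.*$", "", f[[2L]]))
    gain_field <- if (length(f) >= 3L) f[[3L]] else "200"
    gain <- suppressWarnings(as.numeric(sub("\\(.*$", "", sub("/.*$", "", gain_field))))
    baseline <- NA_real_
    if (grepl("\\(", gain_field))
      baseline <- suppressWarnings(as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field)))
    adczero <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[[5L]])) else 0
    if (!is.finite(gain) || gain == 0)
      stop("unreadable gain in WFDB header ", hea_path, " line: ", ln)
    if (!is.finite(baseline)) baseline <- if (is.finite(adczero)) adczero else 0
    list(file = f[[1L]], fmt = fmt, gain = gain, baseline = baseline)
  })
  list(record = rec[[1L]], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_wfdb_dat <- function(dat_path, fmt, nsig, nsamp = NA_integer_) {
  if (!file.exists(dat_path)) stop("missing WFDB signal file: ", dat_path)
  raw <- readBin(dat_path, "raw", n = file.size(dat_path))
  if (fmt == 16L) {
    v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
    m <- matrix(v[seq_len((length(v) %/% nsig) * nsig)], nrow = nsig)
  } else if (fmt == 212L) {
    n <- (length(raw) %/% 3L) * 3L
    b <- as.integer(raw[seq_len(n)])
    b0 <- b[seq(1L, n, 3L)]; b1 <- b[seq(2L, n, 3L)]; b2 <- b[seq(3L, n, 3L)]
    s1 <- b0 + bitwShiftL(bitwAnd(b1, 0x0FL), 8L)
    s2 <- b2 + bitwShiftL(bitwAnd(bitwShiftR(b1, 4L), 0x0FL), 8L)
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    v <- as.vector(rbind(s1, s2))
    m <- matrix(v[seq_len((length(v) %/% nsig) * nsig)], nrow = nsig)
  } else stop("unsupported WFDB format ", fmt, " in ", dat_path)
  if (is.finite(nsamp) && ncol(m) >= nsamp) m <- m[, seq_len(nsamp), drop = FALSE]
  m
}

read_wfdb_annotations <- function(atr_path) {
  raw <- readBin(atr_path, "raw", n = file.size(atr_path))
  n <- length(raw) %/% 2L
  idx <- integer(0); sym <- character(0); codes <- integer(0)
  t <- 0; i <- 1L
  while (i <= n) {
    lo <- as.integer(raw[2L * i - 1L]); hi <- as.integer(raw[2L * i])
    word <- lo + bitwShiftL(hi, 8L)
    code <- bitwShiftR(word, 10L)
    dt <- bitwAnd(word, 1023L)
    if (word == 0L) break                       # EOF
    if (code == 59L) {                          # SKIP: 4-byte interval follows
      if (i + 2L > n) break
      w1 <- as.integer(raw[2L * i + 1L]) + bitwShiftL(as.integer(raw[2L * i + 2L]), 8L)
      w2 <- as.integer(raw[2L * i + 3L]) + bitwShiftL(as.integer(raw[2L * i + 4L]), 8L)
      t <- t + bitwShiftL(w1, 16L) + w2
      i <- i + 3L
      next
    } else if (code == 63L) {                   # AUX: skip payload (even-padded)
      i <- i + 1L + (dt + dt %% 2L) %/% 2L
      next
    } else if (code %in% c(60L, 61L, 62L)) {    # NUM/SUB/CHN modifiers
      i <- i + 1L
      next
    }
    t <- t + dt
    if (code >= 1L && code <= length(.wfdb_symbols)) {
      idx <- c(idx, t)
      sym <- c(sym, .wfdb_symbols[code])
      codes <- c(codes, code)
    }
    i <- i + 1L
  }
  data.frame(index = idx, symbol = sym, is_beat = codes %in% .wfdb_beat_codes)
}

#' Read a WFDB record
#'
#' Parses the `.hea` header, decodes the `.dat` signal file (formats 16 and
#' 212) and, when a `.atr` annotation file is present, attaches beat
#' annotations as R-peak indices with their WFDB symbols as labels. Raw ADC
#' units are converted to millivolts with the header gain and baseline;
#' records whose gain cannot be read are rejected rather than returned in raw
#' units.
#'
#' @param path Path to the record, with or without the `.hea` extension.
#' @param channel 1-based lead index to extract (default 1). Multi-lead
#'   records require an explicit choice; no lead averaging is done.
#' @return An [ecg_record]; `labels` hold the WFDB beat symbols.
#' @export
read_wfdb_record <- function(path, channel = 1L) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  h <- parse_wfdb_header(hea)
  if (channel < 1L || channel > h$nsig)
    stop(sprintf("channel %d out of range (record has %d signals)", channel, h$nsig))
  dat <- file.path(dirname(hea), h$signals[[channel]]$file)
  m <- read_wfdb_dat(dat, h$signals[[channel]]$fmt, h$nsig, h$nsamp)
  s <- h$signals[[channel]]
  mv <- (m[channel, ] - s$baseline) / s$gain
  atr <- file.path(dirname(hea), paste0(h$record, ".atr"))
  r_peaks <- NULL; labels <- NULL
  if (file.exists(atr)) {
    ann <- read_wfdb_annotations(atr)
    beats <- ann[ann$is_beat & ann$index >= 0 & ann$index < length(mv), , drop = FALSE]
    if (nrow(beats)) {
      r_peaks <- beats$index
      labels <- beats$symbol
    }
  }
  ecg_record(mv, h$fs, r_peaks = r_peaks, labels = labels,
             meta = list(source = hea, record = h$record, channel = channel))
}
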