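#' Write a recording to EDF
#'
#' Writes a standard European Data Format (EDF) file: 16-bit samples with
#' per-channel physical scaling, one data record per second. The physical
#' range is set symmetrically per channel from the data, so the round-trip
#' error is at most half a quantization step
#' (`(phys_max - phys_min) / (dig_max - dig_min)`).
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF export requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  x <- rec$data
  nch <- nrow(x)
  n <- ncol(x)
  n_rec <- ceiling(n / fs)
  if (n_rec * fs > n) {  # pad the final partial second with zeros
    x <- cbind(x, matrix(0, nch, n_rec * fs - n))
  }

  phys_max <- pmax(apply(abs(x), 1, max), 1)
  phys_max <- signif(phys_max * 1.0001, 7)  # headroom so no sample clips
  dig_max <- 32767L
  dig_min <- -32768L

  pad <- function(s, width) {
    s <- substr(as.character(s), 1, width)
    formatC(s, width = width, flag = "-")
  }
  num <- function(v, width) vapply(v, function(z) pad(format(z, digits = 7), width),
                                   character(1))

  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con), add = TRUE)

  header <- paste0(
    pad("0", 8),
    pad(paste("X X X", rec$subject_id), 80),
    pad(paste("Startdate 01-JAN-2000", rec$session, rec$condition), 80),
    "01.01.00", "00.00.00",
    pad(256 * (1 + nch), 8),
    pad("", 44),
    pad(n_rec, 8),
    pad(1, 8),
    pad(nch, 4)
  )
  writeChar(header, con, nchars = nchar(header), eos = NULL)
  labels <- rec$montage$channel_names
  sig <- c(
    vapply(labels, function(l) pad(paste("EEG", l), 16), character(1)),
    rep(pad("AgAgCl electrode", 80), nch),
    rep(pad("uV", 8), nch),
    num(-phys_max, 8),
    num(phys_max, 8),
    rep(pad(dig_min, 8), nch),
    rep(pad(dig_max, 8), nch),
    rep(pad("", 80), nch),
    rep(pad(fs, 8), nch),
    rep(pad("", 32), nch)
  )
  sig <- paste(sig, collapse = "")
  writeChar(sig, con, nchars = nchar(sig), eos = NULL)

  scale <- (2 * phys_max) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    dig <- round(sweep(x[, idx, drop = FALSE] + phys_max, 1, scale, "/")) +
      dig_min
    dig <- pmin(pmax(dig, dig_min), dig_max)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads an EDF file written by [write_edf()] (or any single-rate,
#' equal-samples-per-record EDF) back into an [eeg_recording()]. Session and
#' condition are recovered from the recording-id header field when present.
#'
#' @param path Path to an EDF file.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  rd(8)                       # version
  patient <- rd(80)
  recinfo <- rd(80)
  rd(8); rd(8)                # date, time
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rd(8)                       # record duration (1 s)
  nch <- as.integer(rd(4))

  rdv <- function(nc) vapply(seq_len(nch), function(i) rd(nc), character(1))
  labels <- sub("^EEG ", "", rdv(16))
  rdv(80)                     # transducer
  rdv(8)                      # physical dimension
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  rdv(80)                     # prefiltering
  spr <- as.integer(rdv(8))
  rdv(32)

  fs <- spr[1]
  x <- matrix(0, nch, n_rec * fs)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = nch * fs, size = 2, endian = "little")
    block <- matrix(raw, nrow = fs, ncol = nch)
    x[, ((r - 1) * fs + 1):(r * fs)] <-
      t(block) * scale + (phys_min - dig_min * scale)
  }

  parts <- strsplit(recinfo, " +")[[1]]
  session <- if ("post" %in% parts) "post" else "pre"
  condition <- if ("eyes_open" %in% parts) "eyes_open" else "eyes_closed"
  subject <- utils::tail(strsplit(patient, " +")[[1]], 1)
  montage <- if (identical(labels, montage_1020()$channel_names)) {
    montage_1020()
  } else {
    montage_spec(labels)
  }
  eeg_recording(x, fs, montage, subject, session, condition)
}
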