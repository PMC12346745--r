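## Minimal WFDB (PhysioNet waveform database) support: format 16, one
## multiplexed .dat per record, as used by the PTB-XL 100 Hz / 500 Hz trees.
## Only the fields the package writes and reads back are handled.

#' Read a WFDB record (format 16)
#'
#' Parses a WFDB header (`.hea`) and its multiplexed 16-bit little-endian
#' signal file, returning the signal in physical units (millivolts for ECG).
#'
#' @param path path to the record, with or without the `.hea` extension.
#' @return list with `signal` (samples x channels numeric matrix, physical
#'   units), `fs` (sampling rate, Hz), `sig_names` (channel descriptions)
#'   and `record_name`.
#' @export
read_wfdb_record <- function(path) {
  hea <- sub("\\.hea$", "", path)
  hea_file <- paste0(hea, ".hea")
  if (!file.exists(hea_file)) {
    stop("WFDB header not found: ", hea_file, call. = FALSE)
  }
  lines <- readLines(hea_file, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(rec) < 4) stop("malformed WFDB record line", call. = FALSE)
  record_name <- rec[[1]]
  n_sig <- as.integer(rec[[2]])
  fs <- as.numeric(rec[[3]])
  n_samp <- as.integer(rec[[4]])
  if (length(lines) < 1 + n_sig) {
    stop("WFDB header lists ", n_sig, " signals but has ",
         length(lines) - 1L, " signal lines", call. = FALSE)
  }

  gain <- numeric(n_sig); baseline <- numeric(n_sig)
  fmt <- character(n_sig); dat_file <- character(n_sig)
  sig_names <- character(n_sig)
  for (i in seq_len(n_sig)) {
    f <- strsplit(trimws(lines[[i + 1L]]), "\\s+")[[1]]
    dat_file[i] <- f[[1]]
    fmt[i] <- f[[2]]
    spec <- if (length(f) >= 3) f[[3]] else "200"
    # gain spec: gain(baseline)/units, every part optional
    g <- suppressWarnings(as.numeric(sub("[(/].*$", "", spec)))
    if (is.na(g) || g == 0) g <- 200           # WFDB default gain
    b <- regmatches(spec, regexec("\\(([-0-9]+)\\)", spec))[[1]]
    baseline[i] <- if (length(b) == 2) as.numeric(b[[2]]) else
      if (length(f) >= 5) as.numeric(f[[5]]) else 0   # fall back to ADC zero
    gain[i] <- g
    sig_names[i] <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
  }
  if (any(fmt != "16")) {
    stop("only WFDB format 16 is supported (got ", paste(unique(fmt), collapse = ", "),
         ")", call. = FALSE)
  }
  if (length(unique(dat_file)) != 1L) {
    stop("only single multiplexed .dat records are supported", call. = FALSE)
  }

  dat_path <- file.path(dirname(hea_file), dat_file[[1]])
  if (!file.exists(dat_path)) stop("WFDB signal file not found: ", dat_path, call. = FALSE)
  raw <- readBin(dat_path, what = "integer", n = n_samp * n_sig + 1L,
                 size = 2L, signed = TRUE, endian = "little")
  if (length(raw) != n_samp * n_sig) {
    stop("truncated or oversized WFDB signal file: expected ",
         n_samp * n_sig, " samples, read ", length(raw), call. = FALSE)
  }
  adc <- matrix(raw, ncol = n_sig, byrow = TRUE)
  signal <- sweep(sweep(adc, 2, baseline, "-"), 2, gain, "/")
  colnames(signal) <- sig_names
  list(signal = signal, fs = fs, sig_names = sig_names, record_name = record_name)
}

#' Write a WFDB record (format 16)
#'
#' Quantizes a physical-units signal with the given ADC gain and writes a
#' header/signal pair in the dialect of the PTB-XL record trees.  The
#' amplitude resolution of the round trip is `1/gain` units (0.001 mV at
#' the default gain), so `|written - read| <= 0.5/gain`.
#'
#' @param signal samples x channels numeric matrix in physical units.
#' @param record_name record stem (files `<record_name>.hea` / `.dat`).
#' @param dir output directory (created if needed).
#' @param fs sampling rate in Hz.
#' @param gain ADC units per physical unit (default 1000 /mV).
#' @param units physical units string (default `"mV"`).
#' @param sig_names channel descriptions; defaults to [ECG_LEADS] when the
#'   signal has 12 channels.
#' @return invisibly, the path to the written header.
#' @export
write_wfdb_record <- function(signal, record_name, dir, fs,
                              gain = 1000, units = "mV", sig_names = NULL) {
  signal <- as.matrix(signal)
  n_sig <- ncol(signal); n_samp <- nrow(signal)
  if (is.null(sig_names)) {
    sig_names <- if (n_sig == 12L) ECG_LEADS else paste0("ch", seq_len(n_sig))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  adc <- round(signal * gain)
  adc[adc > 32767] <- 32767; adc[adc < -32768] <- -32768
  storage.mode(adc) <- "integer"
  # 16-bit checksum of each channel's samples, as wrsamp computes it
  chk <- vapply(seq_len(n_sig), function(j) {
    s <- sum(as.numeric(adc[, j])) %% 65536
    as.integer(if (s >= 32768) s - 65536 else s)
  }, integer(1))

  dat <- paste0(record_name, ".dat")
  hea <- c(
    paste(record_name, n_sig, fs, n_samp),
    vapply(seq_len(n_sig), function(j) {
      paste(dat, "16", sprintf("%g(0)/%s", gain, units), "16", "0",
            adc[1L, j], chk[j], "0", sig_names[j])
    }, character(1))
  )
  writeLines(hea, file.path(dir, paste0(record_name, ".hea")))
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  invisible(file.path(dir, paste0(record_name, ".hea")))
}
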