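# Minimal EDF (European Data Format) writer/reader for continuous
# multichannel recordings: 16-bit samples, one-second data records, all
# header fields ASCII fixed-width per the format definition. Events travel
# in a TSV sidecar (see write_recording), as base EDF has no annotations.

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

write_edf <- function(rec, path) {
  if (rec$fs != round(rec$fs)) {
    abort("EDF writer requires an integer sampling rate per one-second record.")
  }
  fs <- as.integer(rec$fs)
  nchan <- nrow(rec$samples)
  n <- ncol(rec$samples)
  n_rec <- as.integer(ceiling(n / fs))
  # physical range per channel; digital range fixed at the int16 extremes
  pmin <- apply(rec$samples, 1, min)
  pmax <- apply(rec$samples, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field("X X X X", 80),
    edf_field("Startdate X X X X", 80),
    edf_field("01.01.00", 8),
    edf_field("00.00.00", 8),
    edf_field(256 * (nchan + 1), 8),
    edf_field(sprintf("NS=%d", n), 44),     # true sample count (reserved field)
    edf_field(n_rec, 8),
    edf_field(1, 8),
    edf_field(nchan, 4))
  writeChar(hdr, con, eos = NULL)
  per_sig <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_field, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  per_sig(rec$channel_names, 16)
  per_sig(rep("", nchan), 80)
  per_sig(rep("uV", nchan), 8)
  per_sig(formatC(pmin, digits = 6, format = "g"), 8)
  per_sig(formatC(pmax, digits = 6, format = "g"), 8)
  per_sig(rep(dmin, nchan), 8)
  per_sig(rep(dmax, nchan), 8)
  per_sig(rep("", nchan), 80)
  per_sig(rep(fs, nchan), 8)
  per_sig(rep("", nchan), 32)

  # quantize to int16
  scale <- (dmax - dmin) / (pmax - pmin)
  padded <- cbind(rec$samples,
                  matrix(0, nchan, n_rec * fs - n))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- padded[, idx, drop = FALSE]
    dig <- round((block - pmin) * scale + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  ver <- rd(8)
  if (!nzchar(ver) || ver != "0") {
    abort(sprintf("'%s': not an EDF file (version field '%s').", path, ver))
  }
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nchan <- as.integer(rd(4))
  if (is.na(nchan) || nchan < 1 || is.na(n_rec)) {
    abort(sprintf("'%s': malformed EDF header (signal/record counts).", path))
  }
  rds <- function(width) vapply(seq_len(nchan), function(i) rd(width), "")
  labels <- rds(16); rds(80); rds(8)
  pmin <- as.numeric(rds(8)); pmax <- as.numeric(rds(8))
  dmin <- as.numeric(rds(8)); dmax <- as.numeric(rds(8))
  rds(80)
  spr <- as.integer(rds(8))   # samples per record, per signal
  rds(32)
  if (any(is.na(pmin)) || any(is.na(pmax))) {
    abort(sprintf("'%s': malformed EDF header (physical min/max).", path))
  }
  if (length(unique(spr)) != 1L) {
    abort("mixed per-signal sampling rates are not supported.")
  }
  fs <- spr[1] / rec_dur
  raw <- readBin(con, "integer", n = n_rec * nchan * spr[1], size = 2,
                 signed = TRUE, endian = "little")
  arr <- array(raw, c(spr[1], nchan, n_rec))
  dig <- matrix(aperm(arr, c(2, 1, 3)), nchan, n_rec * spr[1])
  phys <- (dig - dmin) * (pmax - pmin) / (dmax - dmin) + pmin
  # true (unpadded) sample count, if the writer stashed it
  m <- regmatches(reserved, regexec("NS=([0-9]+)", reserved))[[1]]
  if (length(m) == 2L) phys <- phys[, seq_len(as.integer(m[2])), drop = FALSE]
  eeg_recording(phys, fs = fs, channel_names = labels)
}

# quantization step of the EDF encoding, per channel
edf_quantum <- function(rec) {
  pmin <- apply(rec$samples, 1, min)
  pmax <- apply(rec$samples, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  (pmax - pmin) / 65535
}
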