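# Minimal WFDB support: header (.hea) + signal (.dat, formats 16 and 212) +
# MIT-format beat annotations (.atr/.qrs). Covers single- and multi-channel
# records with the first-listed lead selected, which is all the pipeline
# needs; it is not a general-purpose WFDB library.

WFDB_BEAT_CODES <- c(
  "N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L, "F" = 6L, "J" = 7L,
  "A" = 8L, "S" = 9L, "E" = 10L, "j" = 11L, "/" = 12L, "Q" = 13L,
  "e" = 34L, "n" = 35L, "f" = 38L, "r" = 41L
)

#' Write an ECG record as a WFDB record
#'
#' Writes `<id>.hea`, `<id>.dat` (format 16, little-endian 16-bit ADC units)
#' and, when annotations are present, `<id>.atr` in the MIT annotation
#' format. Amplitudes are quantised with the given gain (ADC units per
#' signal unit), so the round-trip error is at most one ADC unit.
#'
#' @param record An [ecg_record()] tibble.
#' @param dir Output directory (created if needed).
#' @param gain ADC units per signal unit (default 200, the MIT-BIH
#'   convention).
#' @return The header path, invisibly.
#' @export
write_wfdb <- function(record, dir, gain = 200) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- ecg_id(record)
  fs <- ecg_fs(record)
  x <- record$amplitude
  adc <- as.integer(pmin(32767, pmax(-32768, round(x * gain))))
  checksum <- sum(adc) %% 65536L
  if (checksum > 32767L) checksum <- checksum - 65536L

  hea <- file.path(dir, paste0(id, ".hea"))
  dat <- file.path(dir, paste0(id, ".dat"))
  lines <- c(
    sprintf("%s 1 %s %d", id, format(fs), length(adc)),
    sprintf("%s.dat 16 %s 16 0 %d %d 0 ECG", id, format(gain), adc[1], checksum)
  )
  writeLines(lines, hea)
  con <- file(dat, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(adc, con, size = 2L, endian = "little")

  ann <- ecg_annotations(record)
  if (nrow(ann) > 0) {
    write_wfdb_annotations(ann, file.path(dir, paste0(id, ".atr")))
  }
  invisible(hea)
}

write_wfdb_annotations <- function(ann, path) {
  codes <- WFDB_BEAT_CODES[ann$label]
  codes[is.na(codes)] <- WFDB_BEAT_CODES[["Q"]]
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  prev <- 0L
  for (i in seq_len(nrow(ann))) {
    delta <- ann$sample[i] - prev
    prev <- ann$sample[i]
    if (delta > 1023L) {
      # SKIP pseudo-annotation: code 59, time 0, then the 32-bit interval in
      # PDP-11 order (high 16 bits first, each word little-endian)
      writeBin(as.integer(bitwShiftL(59L, 10L)), con, size = 2L, endian = "little")
      hi <- delta %/% 65536L
      lo <- delta %% 65536L
      if (lo > 32767L) lo <- lo - 65536L
      writeBin(as.integer(hi), con, size = 2L, endian = "little")
      writeBin(as.integer(lo), con, size = 2L, endian = "little")
      delta <- 0L
    }
    word <- bitwOr(bitwShiftL(codes[i], 10L), delta)
    if (word > 32767L) word <- word - 65536L
    writeBin(as.integer(word), con, size = 2L, endian = "little")
  }
  writeBin(0L, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a WFDB record
#'
#' Parses the header, decodes the signal file (formats 16 and 212), selects
#' one channel (the first listed by default, matching the convention for
#' multi-lead records) and attaches beat annotations from `<id>.atr` or
#' `<id>.qrs` when present. Non-beat annotation codes are dropped.
#'
#' @param path Path to the `.hea` header (or the record prefix without
#'   extension).
#' @param channel 1-based channel to extract (default 1: first listed).
#' @return An [ecg_record()] tibble.
#' @export
read_wfdb <- function(path, channel = 1L) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) abort(sprintf("WFDB header not found: %s", hea))
  lines <- trimws(readLines(hea, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  top <- strsplit(lines[1], "\\s+")[[1]]
  id <- sub("/.*$", "", top[1])
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*$", "", top[3])) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  if (channel > nsig) abort(sprintf("record %s has %d signal(s); channel %d requested.", id, nsig, channel))

  sig_lines <- lines[2:(1 + nsig)]
  sigs <- lapply(strsplit(sig_lines, "\\s+"), function(f) {
    gain_field <- f[3]
    gain <- as.numeric(sub("^([-0-9.]+).*$", "\\1", gain_field))
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    } else if (length(f) >= 5) as.numeric(f[5]) else 0
    list(file = f[1], fmt = sub("x.*$", "", f[2]), gain = gain, baseline = baseline)
  })
  fmt <- sigs[[channel]]$fmt
  datfile <- file.path(dirname(hea), sigs[[channel]]$file)
  if (!file.exists(datfile)) abort(sprintf("WFDB signal file not found: %s", datfile))
  raw_bytes <- readBin(datfile, "raw", n = file.info(datfile)$size)

  all_samples <- switch(fmt,
    "16" = decode_fmt16(raw_bytes),
    "212" = decode_fmt212(raw_bytes),
    abort(sprintf("unsupported WFDB signal format '%s' (have 16, 212).", fmt))
  )
  sig <- all_samples[seq(channel, length(all_samples), by = nsig)]
  if (!is.na(nsamp)) sig <- sig[seq_len(min(nsamp, length(sig)))]
  gain <- sigs[[channel]]$gain
  if (!is.finite(gain) || gain == 0) gain <- 200
  x <- (sig - sigs[[channel]]$baseline) / gain

  ann <- NULL
  for (ext in c(".atr", ".qrs")) {
    afile <- file.path(dirname(hea), paste0(sub("\\.hea$", "", basename(hea)), ext))
    if (file.exists(afile)) {
      ann <- read_wfdb_annotations(afile)
      ann <- ann[ann$sample >= 0 & ann$sample < length(x), , drop = FALSE]
      break
    }
  }
  ecg_record(x, fs = fs, record_id = id, annotations = ann)
}

decode_fmt16 <- function(bytes) {
  n <- length(bytes) %/% 2L
  readBin(bytes, "integer", n = n, size = 2L, endian = "little", signed = TRUE)
}

# Format 212: 3 bytes hold two 12-bit two's-complement samples.
decode_fmt212 <- function(bytes) {
  b <- as.integer(bytes)
  n3 <- length(b) %/% 3L
  b0 <- b[seq(1, 3 * n3, 3)]
  b1 <- b[seq(2, 3 * n3, 3)]
  b2 <- b[seq(3, 3 * n3, 3)]
  s1 <- b0 + bitwShiftL(bitwAnd(b1, 0x0FL), 8L)
  s2 <- b2 + bitwShiftL(bitwShiftR(b1, 4L), 8L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  as.integer(rbind(s1, s2))
}

#' @rdname read_wfdb
#' @param ann_path Path to a `.atr`/`.qrs` MIT-format annotation file.
#' @export
read_wfdb_annotations <- function(ann_path) {
  bytes <- readBin(ann_path, "raw", n = file.info(ann_path)$size)
  words <- readBin(bytes, "integer", n = length(bytes) %/% 2L, size = 2L,
                   endian = "little", signed = FALSE)
  code_of <- WFDB_BEAT_CODES
  rev_codes <- stats::setNames(names(code_of), code_of)
  t_now <- 0
  i <- 1L
  samples <- integer(0)
  labels <- character(0)
  pending_skip <- 0
  while (i <= length(words)) {
    w <- words[i]
    code <- bitwShiftR(w, 10L)
    tm <- bitwAnd(w, 1023L)
    if (code == 0L && tm == 0L) break
    if (code == 59L) {
      hi <- words[i + 1L]
      lo <- words[i + 2L]
      if (lo > 32767L) lo <- lo - 65536L
      pending_skip <- pending_skip + hi * 65536 + lo
      i <- i + 3L
      next
    }
    if (code %in% c(60L, 61L, 62L)) { # NUM/SUB/CHN modifiers: no time advance
      i <- i + 1L
      next
    }
    if (code == 63L) { # AUX: skip its payload (padded to even length)
      i <- i + 1L + (tm + tm %% 2L) %/% 2L
      next
    }
    t_now <- t_now + pending_skip + tm
    pending_skip <- 0
    if (code %in% code_of) {
      samples <- c(samples, as.integer(t_now))
      labels <- c(labels, rev_codes[[as.character(code)]])
    }
    i <- i + 1L
  }
  tibble(sample = samples, label = labels)
}
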