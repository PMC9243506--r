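# Minimal EDF+ writer/reader: 16-bit samples, one annotation signal carrying
# the flash markers as time-stamped annotation lists (TALs).  Covers exactly
# what the package needs -- continuous recordings plus flash annotations --
# not the full breadth of the format (no discontinuous files, one annotation
# signal, fixed 1 s data records).

edf_pad <- function(s, n) {
  s <- substr(s, 1, n)
  formatC(s, width = -n, flag = " ")
}

# Print a number into at most `n` ASCII chars, reducing precision as needed.
edf_num <- function(x, n = 8) {
  for (d in seq(10, 1)) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= n) return(s)
  }
  substr(s, 1, n)
}

TAL_SEP <- "\x14"  # 0x14 separates onset from annotation text

write_recording_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stopf("EDF writer requires an integer sampling rate (got %g)", fs)
  }
  fs <- as.integer(round(fs))
  dat <- rec$data
  nch <- nrow(dat)
  n <- ncol(dat)
  n_rec <- max(1L, as.integer(ceiling(n / fs)))

  # physical/digital scaling (symmetric, shared across channels)
  pm <- max(abs(dat), 1)
  pm <- as.numeric(edf_num(pm * 1.000001))      # printed value is authoritative
  gain <- pm / 32767
  dig <- round(dat / gain)
  dig[dig > 32767] <- 32767
  dig[dig < -32767] <- -32767

  # one TAL per flash marker + a bookkeeping annotation with the true sample
  # count (records are zero-padded to a whole second)
  mk <- rec$markers
  ev_rec <- if (nrow(mk) > 0) pmin(floor(mk$onset_sample / fs), n_rec - 1L) else integer(0)
  ev_tal <- if (nrow(mk) > 0) {
    sprintf("+%.7f%sFLASH %d %d %d%s", mk$onset_sample / fs, TAL_SEP,
            mk$line_index, as.integer(mk$is_target), mk$code, TAL_SEP)
  } else character(0)
  rec_tals <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    tals <- sprintf("+%d%s%s", r - 1L, TAL_SEP, TAL_SEP)  # record timestamp
    if (r == 1L) tals <- c(tals, sprintf("+0%sNSAMP %d%s", TAL_SEP, n, TAL_SEP))
    tals <- c(tals, ev_tal[ev_rec == r - 1L])
    rec_tals[[r]] <- tals
  }
  bytes_per_rec <- vapply(rec_tals, function(t) sum(nchar(t, "bytes")) + length(t), 0)
  ann_spr <- as.integer(ceiling(max(bytes_per_rec) / 2) + 8)

  ns <- nch + 1L
  header <- paste0(
    edf_pad("0", 8),
    edf_pad(ifelse(is.na(rec$subject_id), "X", rec$subject_id), 80),
    edf_pad("Startdate 01-JAN-2000 X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(as.character(256L * (ns + 1L)), 8),
    edf_pad("EDF+C", 44),
    edf_pad(as.character(n_rec), 8),
    edf_pad("1", 8),
    edf_pad(as.character(ns), 4)
  )
  labels <- c(rec$channel_names, "EDF Annotations")
  sig_field <- function(vals, width) paste(vapply(vals, edf_pad, "", n = width), collapse = "")
  header <- paste0(
    header,
    sig_field(labels, 16),
    sig_field(rep("", ns), 80),                                  # transducer
    sig_field(c(rep("uV", nch), ""), 8),                         # physical dim
    sig_field(c(rep(edf_num(-pm), nch), "-1"), 8),               # phys min
    sig_field(c(rep(edf_num(pm), nch), "1"), 8),                 # phys max
    sig_field(c(rep("-32767", nch), "-32768"), 8),               # dig min
    sig_field(c(rep("32767", nch), "32767"), 8),                 # dig max
    sig_field(rep("", ns), 80),                                  # prefiltering
    sig_field(as.character(c(rep(fs, nch), ann_spr)), 8),        # samples/rec
    sig_field(rep("", ns), 32)                                   # reserved
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    seg <- matrix(0L, nch, fs)
    keep <- idx <= n
    seg[, keep] <- dig[, idx[keep], drop = FALSE]
    writeBin(as.integer(t(seg)), con, size = 2, endian = "little")
    ann <- unlist(lapply(rec_tals[[r]], function(t) c(charToRaw(t), as.raw(0))))
    ann <- c(ann, raw(2L * ann_spr - length(ann)))
    writeBin(ann, con)
  }
  invisible(path)
}

read_recording_edf <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  raw <- readBin(path, "raw", n = file.size(path))
  get_str <- function(from, len) {
    trimws(rawToChar(raw[from:(from + len - 1L)]))
  }
  if (length(raw) < 256) stopf("'%s' is not an EDF file (truncated header)", path)
  subject_id <- get_str(9, 80)
  n_rec <- as.integer(get_str(237, 8))
  rec_dur <- as.numeric(get_str(245, 8))
  ns <- as.integer(get_str(253, 4))
  sig <- function(field_off, width) {
    base <- 256L + field_off * ns
    vapply(seq_len(ns), function(s) get_str(base + (s - 1L) * width + 1L, width), "")
  }
  labels <- sig(0L, 16L)
  dims <- sig(16L + 80L, 8L)
  # offsets of the per-signal fields within the signal header block
  off <- cumsum(c(0L, 16L, 80L, 8L, 8L, 8L, 8L, 8L, 80L, 8L))
  phys_min <- as.numeric(sig(off[4], 8L))
  phys_max <- as.numeric(sig(off[5], 8L))
  dig_min <- as.numeric(sig(off[6], 8L))
  dig_max <- as.numeric(sig(off[7], 8L))
  spr <- as.integer(sig(off[9], 8L))

  ann_sig <- which(labels == "EDF Annotations")
  if (length(ann_sig) == 0) {
    stopf("'%s' has no 'EDF Annotations' signal; flash markers are missing", path)
  }
  ann_sig <- ann_sig[1]
  data_sigs <- setdiff(seq_len(ns), ann_sig)
  fs <- spr[data_sigs[1]] / rec_dur
  if (any(spr[data_sigs] != spr[data_sigs[1]])) {
    stopf("'%s': heterogeneous sampling rates are not supported", path)
  }

  unit_scale <- vapply(tolower(dims), function(d) {
    switch(d, "uv" = 1, "µv" = 1, "mv" = 1000, "v" = 1e6, 1)
  }, 0)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_max - gain * dig_max

  rec_words <- sum(spr)
  body <- raw[-(1:(256L * (ns + 1L)))]
  if (length(body) < 2L * rec_words * n_rec) {
    stopf("'%s' is truncated: expected %d data bytes, found %d", path,
          2L * rec_words * n_rec, length(body))
  }
  sig_start <- cumsum(c(0L, spr))
  nchd <- length(data_sigs)
  dat <- matrix(0, nchd, n_rec * spr[data_sigs[1]])
  ann_text <- raw(0)
  for (r in seq_len(n_rec)) {
    base <- 2L * rec_words * (r - 1L)
    for (j in seq_along(data_sigs)) {
      s <- data_sigs[j]
      b0 <- base + 2L * sig_start[s]
      v <- readBin(body[(b0 + 1L):(b0 + 2L * spr[s])], "integer", n = spr[s],
                   size = 2, signed = TRUE, endian = "little")
      cols <- ((r - 1L) * spr[s] + 1L):(r * spr[s])
      dat[j, cols] <- (v * gain[s] + offset[s]) * unit_scale[s]
    }
    b0 <- base + 2L * sig_start[ann_sig]
    ann_text <- c(ann_text, body[(b0 + 1L):(b0 + 2L * spr[ann_sig])])
  }

  # parse TALs: each is "onset(\x15dur)?\x14text\x14...\x00"; NUL terminators
  # are mapped to newlines so the raw block can be split as text
  ann_text[ann_text == as.raw(0)] <- as.raw(10)
  chunks <- strsplit(rawToChar(ann_text), "\n", fixed = TRUE)[[1]]
  onset <- numeric(0); line <- integer(0); tgt <- logical(0); code <- integer(0)
  nsamp <- NA_integer_
  for (tal in chunks) {
    if (!nzchar(tal)) next
    parts <- strsplit(tal, TAL_SEP, fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    t0 <- as.numeric(sub("\x15.*$", "", parts[1]))
    for (txt in parts[-1]) {
      if (grepl("^FLASH ", txt)) {
        f <- as.integer(strsplit(sub("^FLASH ", "", txt), " ")[[1]])
        onset <- c(onset, t0); line <- c(line, f[1])
        tgt <- c(tgt, f[2] == 1L); code <- c(code, f[3])
      } else if (grepl("^NSAMP ", txt)) {
        nsamp <- as.integer(sub("^NSAMP ", "", txt))
      }
    }
  }
  if (!is.na(nsamp) && nsamp <= ncol(dat)) dat <- dat[, seq_len(nsamp), drop = FALSE]
  markers <- flash_markers(round(onset * fs), line, tgt, code)
  continuous_recording(dat, fs, labels[data_sigs], markers, subject_id)
}
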