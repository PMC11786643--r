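# EDF / BDF readers implemented directly from the format layout:
# 256-byte fixed header + 256 bytes per signal, then data records of
# little-endian 16-bit (EDF) or 24-bit (BDF) integers, scaled to physical
# units via the per-signal digital/physical min/max calibration.

read_edf_file <- function(path, bdf = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))

  magic <- readBin(con, "raw", 8L)
  if (bdf) {
    if (magic[1L] != as.raw(0xFF) ||
        !identical(rawToChar(magic[2:8]), "BIOSEMI"))
      stop("not a BDF file (bad magic bytes): ", path)
  } else {
    if (!identical(trimws(rawToChar(magic)), "0"))
      stop("not an EDF file (bad version field): ", path)
  }

  rd_str <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd_num <- function(n) {
    x <- suppressWarnings(as.numeric(rd_str(n)))
    if (is.na(x)) stop("malformed numeric field in header of ", path)
    x
  }

  rd_str(80L); rd_str(80L)            # patient / recording id
  rd_str(8L); rd_str(8L)              # start date / time
  rd_num(8L)                          # header byte count
  rd_str(44L)                         # reserved
  n_records <- rd_num(8L)
  rec_dur <- rd_num(8L)
  ns <- as.integer(rd_num(4L))
  if (ns < 1L) stop("EDF/BDF header reports no signals: ", path)
  if (rec_dur <= 0) stop("EDF/BDF format error: non-positive record duration (no fs derivable): ", path)

  per_sig_str <- function(width)
    vapply(seq_len(ns), function(i) rd_str(width), character(1))
  per_sig_num <- function(width)
    vapply(seq_len(ns), function(i) rd_num(width), numeric(1))

  labels <- per_sig_str(16L)
  per_sig_str(80L)                    # transducer
  per_sig_str(8L)                     # physical dimension
  phys_min <- per_sig_num(8L)
  phys_max <- per_sig_num(8L)
  dig_min <- per_sig_num(8L)
  dig_max <- per_sig_num(8L)
  per_sig_str(80L)                    # prefiltering
  spr <- as.integer(per_sig_num(8L))  # samples per record, per signal
  per_sig_str(32L)                    # reserved

  annot <- grepl("Annotations", labels)
  keep <- which(!annot)
  if (!length(keep)) stop("EDF file contains only annotation channels: ", path)

  bps <- if (bdf) 3L else 2L
  gain <- (phys_max - phys_min) / (dig_max - dig_min)

  chunks <- vector("list", ns)
  for (i in seq_len(ns)) chunks[[i]] <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      raw_bytes <- readBin(con, "raw", spr[i] * bps)
      if (length(raw_bytes) < spr[i] * bps)
        stop("truncated data record ", r, " in ", path)
      if (!annot[i]) {
        dig <- if (bdf) int24le_to_int(raw_bytes)
               else readBin(raw_bytes, "integer", spr[i], size = 2L,
                            signed = TRUE, endian = "little")
        chunks[[i]][[r]] <- (dig - dig_min[i]) * gain[i] + phys_min[i]
      }
    }
  }

  samples <- do.call(rbind, lapply(keep, function(i) unlist(chunks[[i]])))
  fs <- spr[keep] / rec_dur
  if (length(unique(fs)) > 1L)
    stop("mixed sampling rates across signals are not supported: ", path)
  recording(samples, fs[1L], labels = labels[keep])
}

# signed little-endian 24-bit integers packed in a raw vector
int24le_to_int <- function(bytes) {
  n <- length(bytes) %/% 3L
  b <- matrix(as.integer(bytes[seq_len(3L * n)]), nrow = 3L)
  v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
  ifelse(v >= 8388608, v - 16777216, v)
}
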