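# Minimal European Data Format (EDF) I/O.
#
# EDF: 256-byte fixed-width ASCII global header, 256 bytes of ASCII header
# per signal, then data records of little-endian int16 samples interleaved
# per signal. Physical values are recovered by the linear digital->physical
# map stored in the header. Only uniform-rate continuous recordings are
# supported (every signal must yield one common sampling rate).

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

# Read an EDF file; returns list(channels = list of sampled_signal).
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii(con, 8L)
  if (version != "0") stop("unsupported EDF version field: '", version, "'")
  readBin(con, "raw", 80L + 80L + 8L + 8L)        # patient, recording, date, time
  header_bytes <- as.integer(read_ascii(con, 8L))
  readBin(con, "raw", 44L)                        # reserved
  n_records <- as.integer(read_ascii(con, 8L))
  record_dur <- as.numeric(read_ascii(con, 8L))
  ns <- as.integer(read_ascii(con, 4L))
  if (is.na(ns) || ns < 1L) stop("EDF header: invalid signal count")
  if (is.na(n_records) || n_records < 1L)
    stop("EDF header: unknown record count not supported")
  field <- function(width) vapply(seq_len(ns), function(i)
    read_ascii(con, width), character(1))
  labels    <- field(16L)
  field(80L); field(8L)                           # transducer, phys dim
  phys_min  <- as.numeric(field(8L))
  phys_max  <- as.numeric(field(8L))
  dig_min   <- as.numeric(field(8L))
  dig_max   <- as.numeric(field(8L))
  field(80L)                                      # prefiltering
  spr       <- as.integer(field(8L))              # samples per record
  field(32L)                                      # reserved
  expected <- 256L + 256L * ns
  if (!is.na(header_bytes) && header_bytes != expected)
    stop("EDF header length field disagrees with signal count")
  fs <- spr / record_dur
  if (length(unique(fs)) != 1L)
    stop("EDF signals with differing sampling rates are not supported")
  data <- vector("list", ns)
  for (i in seq_len(ns)) data[[i]] <- numeric(n_records * spr[i])
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      if (length(d) != spr[i]) stop("EDF file truncated at record ", r)
      data[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- d
    }
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  channels <- lapply(seq_len(ns), function(i)
    sampled_signal(phys_min[i] + gain[i] * (data[[i]] - dig_min[i]),
                   fs = fs[[1L]], label = labels[i]))
  list(channels = channels)
}

# Write an mc_recording as EDF (int16 quantization over the per-channel
# physical range). Used to build round-trip fixtures; quantization error is
# bounded by (max-min)/65534 per sample.
write_edf <- function(rec, path, record_dur = 1) {
  stopifnot(inherits(rec, "mc_recording"))
  ns <- length(rec$channels)
  spr <- as.integer(round(rec$fs * record_dur))
  if (abs(spr - rec$fs * record_dur) > 1e-9)
    stop("fs * record_dur must be an integer number of samples")
  n_records <- ceiling(rec$n_samples / spr)
  pad_to <- n_records * spr
  f <- function(x, w) {
    s <- formatC(as.character(x), width = w, flag = "-")
    if (any(nchar(s) > w)) stop("EDF header field overflow")
    s
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    f("0", 8), f("X X X X", 80), f("Startdate X X X X", 80),
    f("01.01.26", 8), f("00.00.00", 8), f(256L + 256L * ns, 8), f("", 44),
    f(n_records, 8), f(format(record_dur), 8), f(ns, 4)), con, eos = NULL)
  labs <- names(rec$channels)
  pmin_ <- pmax_ <- numeric(ns)
  for (i in seq_len(ns)) {
    v <- rec$channels[[i]]$values
    pmin_[i] <- min(v); pmax_[i] <- max(v)
    if (pmax_[i] == pmin_[i]) pmax_[i] <- pmin_[i] + 1
  }
  hdr <- function(vals, w) writeChar(paste(f(vals, w), collapse = ""),
                                     con, eos = NULL)
  hdr(labs, 16); hdr(rep("", ns), 80); hdr(rep("uV", ns), 8)
  hdr(formatC(pmin_, format = "g", digits = 6), 8)
  hdr(formatC(pmax_, format = "g", digits = 6), 8)
  hdr(rep(-32767L, ns), 8); hdr(rep(32767L, ns), 8)
  hdr(rep("", ns), 80); hdr(rep(spr, ns), 8); hdr(rep("", ns), 32)
  # re-read the rounded physical extrema so the scaling is self-consistent
  pmin_ <- as.numeric(formatC(pmin_, format = "g", digits = 6))
  pmax_ <- as.numeric(formatC(pmax_, format = "g", digits = 6))
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    v <- rec$channels[[i]]$values
    v <- c(v, rep(v[length(v)], pad_to - length(v)))
    d <- round((v - pmin_[i]) / (pmax_[i] - pmin_[i]) * 65534) - 32767
    dig[[i]] <- as.integer(pmin(pmax(d, -32767L), 32767L))
  }
  for (r in seq_len(n_records))
    for (i in seq_len(ns))
      writeBin(dig[[i]][((r - 1L) * spr + 1L):(r * spr)], con, size = 2L,
               endian = "little")
  invisible(path)
}
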