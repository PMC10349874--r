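#' Load a multichannel recording from CSV/TSV or EDF
#'
#' CSV/TSV files carry one header row of channel labels and one row per
#' sample (delimiter auto-detected among comma and tab, UTF-8). A leading
#' column whose header is `"time"` (case-insensitive) is dropped. EDF files
#' (European Data Format) carry the sampling rate in their header.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"edf"`. Default guesses from the file extension.
#' @param fs Sampling rate in Hz; required for CSV input, ignored for EDF.
#' @param group_map Named list mapping roles (`"EEG"`, `"ECG"`, `"RESP"`) to
#'   channel labels; every label must exist in the file.
#' @return An [mc_recording] with channels in file order.
#' @export
load_recording <- function(path, format = c("auto", "csv", "edf"), fs = NULL,
                           group_map = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "csv") {
    if (is.null(fs)) stop("'fs' must be supplied for csv input")
    mat <- read_signal_table(path)
    channels <- lapply(colnames(mat), function(lab)
      sampled_signal(mat[, lab], fs = fs, label = lab))
  } else {
    edf <- read_edf(path)
    channels <- edf$channels
  }
  mc_recording(channels, groups = group_map)
}

# CSV/TSV -> numeric matrix with channel labels as colnames; the "time"
# column (if first) is dropped; any non-numeric token is an error naming
# its data row and column.
read_signal_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "auto",
                          colClasses = "character", data.table = FALSE,
                          encoding = "UTF-8")
  if (ncol(dt) < 1L || nrow(dt) < 1L) stop("empty table: ", path)
  if (tolower(trimws(colnames(dt)[1L])) == "time") dt <- dt[, -1L, drop = FALSE]
  if (ncol(dt) < 1L) stop("no signal columns in ", path)
  mat <- matrix(NA_real_, nrow = nrow(dt), ncol = ncol(dt),
                dimnames = list(NULL, colnames(dt)))
  for (j in seq_len(ncol(dt))) {
    col <- suppressWarnings(as.numeric(dt[[j]]))
    bad <- which(is.na(col))
    if (length(bad))
      stop(sprintf("non-numeric or missing value at row %d, column '%s'",
                   bad[1L], colnames(dt)[j]))
    mat[, j] <- col
  }
  mat
}

#' Write a recording (or signals) to the standard CSV dialect
#'
#' One header row of labels, one row per sample, comma-separated.
#'
#' @param rec An [mc_recording].
#' @param path Output path.
#' @param time_column If `TRUE`, prepend a `time` column in seconds.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, time_column = FALSE) {
  stopifnot(inherits(rec, "mc_recording"))
  df <- as.data.frame(lapply(rec$channels, function(ch) ch$values),
                      check.names = FALSE)
  if (time_column)
    df <- cbind(time = (seq_len(rec$n_samples) - 1L) / rec$fs, df)
  data.table::fwrite(df, path)
  invisible(path)
}

# Symmetric FIR kernel for a given response type; taps forced odd so the
# linear-phase delay (taps-1)/2 is integral and the high-pass is type I.
fir_kernel <- function(fs, cutoff, type, taps = NULL) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist rate fs/2")
  if (is.null(taps)) taps <- ceiling(3 * fs / cutoff)
  taps <- as.integer(taps)
  if (taps %% 2L == 0L) taps <- taps + 1L
  if (taps < 3L) taps <- 3L
  h <- signal::fir1(taps - 1L, cutoff / (fs / 2), type = type)
  # pin unit gain in the passband (fir1's own scaling drifts for narrow bands)
  if (type == "low") h / sum(h)
  else h / sum(h * (-1)^(seq_along(h) - 1L))
}

# Zero-phase application: reflect-pad by one kernel length, filter forward,
# then backward (squares the magnitude response, cancels the phase), trim.
filtfilt_reflect <- function(x, h) {
  n <- length(x)
  L <- length(h)
  pad <- min(L, n - 1L)
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  fwd <- function(v) {
    y <- if (length(v) > 4L * L)
      signal::fftfilt(h, v)
    else
      as.numeric(stats::filter(v, h, method = "convolution", sides = 1L))
    y[is.na(y)] <- 0
    y
  }
  y <- fwd(xp)
  y <- rev(fwd(rev(y)))
  # each causal pass delays by (L-1)/2; forward+backward delays cancel
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase high-pass FIR filter
#'
#' Applies a linear-phase FIR high-pass forward and backward (zero net
#' phase, doubled attenuation). Edges are handled by odd-reflection padding
#' of one kernel length, trimmed after filtering. Default length is
#' `3 * fs / cutoff` taps rounded up to odd.
#'
#' @param sig A [sampled_signal].
#' @param cutoff Cutoff frequency in Hz, in (0, fs/2).
#' @param taps Optional FIR length (forced odd).
#' @return A [sampled_signal] of the same length and rate.
#' @export
highpass_zero_phase <- function(sig, cutoff, taps = NULL) {
  stopifnot(inherits(sig, "sampled_signal"))
  h <- fir_kernel(sig$fs, cutoff, "high", taps)
  sampled_signal(filtfilt_reflect(sig$values, h), sig$fs, sig$label)
}

#' Zero-phase low-pass FIR filter
#'
#' Mirror of [highpass_zero_phase] with a low-pass response.
#'
#' @inheritParams highpass_zero_phase
#' @return A [sampled_signal] of the same length and rate.
#' @export
lowpass_zero_phase <- function(sig, cutoff, taps = NULL) {
  stopifnot(inherits(sig, "sampled_signal"))
  h <- fir_kernel(sig$fs, cutoff, "low", taps)
  sampled_signal(filtfilt_reflect(sig$values, h), sig$fs, sig$label)
}

#' Re-reference a role group to its instantaneous average
#'
#' Subtracts, at every sample, the mean over the channels of `role` from each
#' of those channels (common average reference). Channels outside the role
#' are untouched. After the operation the role channels sum to zero at every
#' sample; applying it twice is a no-op.
#'
#' @param rec An [mc_recording] whose `groups` contain `role`.
#' @param role Role to re-reference (default `"EEG"`).
#' @return The recording with the role channels re-referenced.
#' @export
rereference_average <- function(rec, role = "EEG") {
  stopifnot(inherits(rec, "mc_recording"))
  labs <- role_labels(rec, role)
  if (length(labs) < 2L)
    stop("average re-referencing needs at least 2 '", role, "' channels")
  mat <- vapply(rec$channels[labs], function(ch) ch$values,
                numeric(rec$n_samples))
  avg <- rowMeans(mat)
  for (lab in labs)
    rec$channels[[lab]]$values <- rec$channels[[lab]]$values - avg
  rec
}

#' Integer-factor decimation with anti-alias filtering
#'
#' For `factor > 1` an anti-alias zero-phase low-pass at 0.45 times the new
#' Nyquist rate is applied before keeping every `factor`-th sample (sample
#' `k` of the output is sample `k * factor` of the input, 0-based).
#'
#' @param sig A [sampled_signal].
#' @param factor Positive integer decimation factor.
#' @return A [sampled_signal] at `fs / factor` with `ceiling(n / factor)`
#'   samples.
#' @export
downsample <- function(sig, factor) {
  stopifnot(inherits(sig, "sampled_signal"))
  if (length(factor) != 1L || !is.finite(factor) || factor < 1 ||
      factor != round(factor))
    stop("'factor' must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(sig)
  new_fs <- sig$fs / factor
  h <- fir_kernel(sig$fs, 0.45 * (new_fs / 2), "low")
  y <- filtfilt_reflect(sig$values, h)
  keep <- seq.int(1L, length(y), by = factor)
  sampled_signal(y[keep], new_fs, sig$label)
}
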