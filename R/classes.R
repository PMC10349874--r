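#' Construct a uniformly sampled single-channel signal
#'
#' The elementary container of the package: one channel of uniformly sampled
#' values together with its sampling rate and a label. All conditioning and
#' scaling operations consume and produce this type.
#'
#' @param values Numeric vector of sample values (arbitrary physical units).
#'   Must be non-empty and free of `NA`/`NaN`/`Inf`.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Channel name.
#' @return An object of class `sampled_signal`: a list with elements
#'   `values`, `fs` and `label`.
#' @export
#' @examples
#' s <- sampled_signal(sin(seq(0, 2 * pi, length.out = 100)), fs = 100)
#' s
sampled_signal <- function(values, fs, label = "signal") {
  if (!is.numeric(values) || length(values) < 1L)
    stop("'values' must be a non-empty numeric vector")
  if (anyNA(values) || any(!is.finite(values)))
    stop("signal '", label, "' contains undefined (NA/NaN/Inf) values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number")
  structure(list(values = as.numeric(values), fs = as.numeric(fs),
                 label = as.character(label)),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> '%s': %d samples @ %g Hz (%.2f s)\n",
              x$label, length(x$values), x$fs, length(x$values) / x$fs))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$values)

#' Construct a multichannel recording
#'
#' Bundles simultaneously acquired channels sharing one sampling rate and
#' length, with an optional mapping of physiological roles (e.g. `"EEG"`,
#' `"ECG"`, `"RESP"`) to channel labels.
#'
#' @param channels List of [sampled_signal] objects with identical `fs` and
#'   length and unique labels.
#' @param groups Named list mapping a role to a character vector of channel
#'   labels; every label must exist among `channels`.
#' @return An object of class `mc_recording`.
#' @export
mc_recording <- function(channels, groups = list()) {
  if (!is.list(channels) || length(channels) < 1L)
    stop("'channels' must be a non-empty list of sampled_signal objects")
  if (!all(vapply(channels, inherits, logical(1), "sampled_signal")))
    stop("every channel must be a sampled_signal")
  fs <- vapply(channels, function(ch) ch$fs, numeric(1))
  ns <- vapply(channels, function(ch) length(ch$values), integer(1))
  if (length(unique(fs)) != 1L)
    stop("all channels must share one sampling rate")
  if (length(unique(ns)) != 1L)
    stop("all channels must have identical length")
  labels <- vapply(channels, function(ch) ch$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  names(channels) <- labels
  if (length(groups)) {
    if (is.null(names(groups)) || any(!nzchar(names(groups))))
      stop("'groups' must be a named list")
    missing <- setdiff(unlist(groups), labels)
    if (length(missing))
      stop("group labels not present in recording: ",
           paste(missing, collapse = ", "))
  }
  structure(list(channels = channels, groups = groups,
                 fs = fs[[1L]], n_samples = ns[[1L]]),
            class = "mc_recording")
}

#' @export
print.mc_recording <- function(x, ...) {
  cat(sprintf("<mc_recording> %d channels x %d samples @ %g Hz\n",
              length(x$channels), x$n_samples, x$fs))
  if (length(x$groups))
    for (role in names(x$groups))
      cat(sprintf("  %s: %d channel(s)\n", role, length(x$groups[[role]])))
  invisible(x)
}

#' Labels of channels holding a given role
#' @param rec An [mc_recording].
#' @param role Role name present in `rec$groups`.
#' @return Character vector of channel labels.
#' @export
role_labels <- function(rec, role) {
  stopifnot(inherits(rec, "mc_recording"))
  if (is.null(rec$groups[[role]]))
    stop("recording has no '", role, "' role group")
  rec$groups[[role]]
}
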