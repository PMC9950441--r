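#' EpochArray: trials x channels x samples voltage tensor
#'
#' The central EEG container: single-trial epochs time-locked to movement
#' onset, with a time axis in seconds, channel names, and per-trial
#' metadata (participant, group, correctness, confidence, movement onset).
#' Several participants can share one `epoch_array`; participant identity
#' lives in `metadata$participant`.
#'
#' @param data numeric array `trials x channels x samples`, microvolts.
#' @param channels character vector of channel names (unique).
#' @param times numeric vector of sample times, seconds relative to
#'   movement onset, strictly increasing and evenly spaced.
#' @param fs sampling rate in Hz (must match `times` spacing).
#' @param metadata data.frame with one row per trial; must contain a
#'   `participant` column.
#' @return an object of class `epoch_array`.
#' @export
epoch_array <- function(data, channels, times, fs, metadata) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[2] != length(channels))
    stop("channel dimension mismatch")
  if (dim(data)[3] != length(times))
    stop("time dimension mismatch")
  if (anyDuplicated(channels)) stop("channel names must be unique")
  if (nrow(metadata) != dim(data)[1])
    stop("metadata rows must equal trial count")
  if (!"participant" %in% names(metadata))
    stop("metadata must contain a participant column")
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - 1 / fs)) > 1e-6))
    stop("times must be evenly spaced at 1/fs")
  dimnames(data) <- list(NULL, channels, NULL)
  structure(list(data = data, channels = channels, times = times,
                 fs = fs, metadata = metadata),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  cat(sprintf(
    "<epoch_array> %d trials x %d channels x %d samples @ %g Hz [%.3f, %.3f] s\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
    min(x$times), max(x$times)))
  cat(sprintf("  participants: %d  channels: %s%s\n",
              length(unique(x$metadata$participant)),
              paste(head(x$channels, 6), collapse = ", "),
              if (length(x$channels) > 6) ", ..." else ""))
  invisible(x)
}

#' @export
dim.epoch_array <- function(x) dim(x$data)

#' Subset an epoch array by trials and/or channels
#'
#' @param x an `epoch_array`.
#' @param trials integer or logical index over trials.
#' @param channels character, integer or logical index over channels.
#' @return an `epoch_array`.
#' @export
subset_epochs <- function(x, trials = NULL, channels = NULL) {
  stopifnot(inherits(x, "epoch_array"))
  ti <- trials %||% seq_len(dim(x$data)[1])
  ci <- channels %||% seq_len(dim(x$data)[2])
  if (is.character(ci)) ci <- match(ci, x$channels)
  if (anyNA(ci)) stop("unknown channel in subset")
  epoch_array(x$data[ti, ci, , drop = FALSE], x$channels[ci], x$times,
              x$fs, x$metadata[ti, , drop = FALSE])
}

#' Concatenate epoch arrays over trials
#'
#' @param ... `epoch_array` objects sharing channels, times and fs.
#' @return a single `epoch_array`.
#' @export
bind_epochs <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "epoch_array"))
    xs <- xs[[1]]
  stopifnot(length(xs) >= 1)
  ref <- xs[[1]]
  for (x in xs[-1]) {
    if (!identical(x$channels, ref$channels) ||
        max(abs(x$times - ref$times)) > 1e-9 || x$fs != ref$fs)
      stop("epoch arrays are not compatible")
  }
  n <- vapply(xs, function(x) dim(x$data)[1], 0L)
  out <- array(0, c(sum(n), dim(ref$data)[2], dim(ref$data)[3]))
  at <- 0L
  for (x in xs) {
    if (dim(x$data)[1] > 0)
      out[at + seq_len(dim(x$data)[1]), , ] <- x$data
    at <- at + dim(x$data)[1]
  }
  md <- do.call(rbind, lapply(xs, `[[`, "metadata"))
  rownames(md) <- NULL
  epoch_array(out, ref$channels, ref$times, ref$fs, md)
}
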