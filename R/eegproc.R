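#' Continuous multichannel EEG record
#'
#' In-memory continuous record: a samples x channels matrix plus sampling
#' rate and channel names. Plain-text round trip via `write.csv` /
#' [read_continuous_csv()]. (EDF ingestion is not provided: no EDF reader
#' is available in the supported dependency set; convert externally to
#' CSV.)
#'
#' @param data samples x channels numeric matrix, microvolts.
#' @param fs sampling rate in Hz.
#' @param channels channel names.
#' @return object of class `continuous_record`.
#' @export
continuous_record <- function(data, fs, channels) {
  data <- as.matrix(data)
  stopifnot(ncol(data) == length(channels), fs > 0)
  if (anyDuplicated(channels)) stop("channel names must be unique")
  colnames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels),
            class = "continuous_record")
}

#' Read a continuous record from CSV
#'
#' Wide CSV: one column per channel, one row per sample.
#'
#' @param path CSV path.
#' @param fs sampling rate in Hz.
#' @return a [continuous_record()].
#' @export
read_continuous_csv <- function(path, fs) {
  d <- read.csv(path, check.names = FALSE)
  continuous_record(as.matrix(d), fs, names(d))
}

#' Filter and downsample a continuous recording
#'
#' Resamples to `fs_out` (Fourier interpolation, zero phase), then applies
#' zero-phase FIR high-pass and low-pass filters. Defaults follow the
#' standard pipeline: 128 Hz, 0.5-45 Hz pass-band.
#'
#' @param record a [continuous_record()] sampled at >= 2 x `fs_out`.
#' @param montage optional montage; all montage channels must be present.
#' @param fs_out output rate (Hz).
#' @param hp,lp high-/low-pass edges (Hz); `NULL` disables either.
#' @return a filtered [continuous_record()] at `fs_out`.
#' @export
preprocess_continuous <- function(record, montage = NULL, fs_out = 128,
                                  hp = 0.5, lp = 45) {
  stopifnot(inherits(record, "continuous_record"))
  if (record$fs < 2 * fs_out)
    stop("input sampling rate must be at least twice the output rate")
  if (!is.null(montage)) {
    miss <- setdiff(montage$channel, record$channels)
    if (length(miss))
      stop("channels missing from record: ", paste(miss, collapse = ", "))
  }
  x <- resample_fft(record$data, record$fs, fs_out)
  if (!is.null(hp)) x <- fir_filter(x, design_fir(fs_out, low = hp,
                                                  transition = 0.5))
  if (!is.null(lp)) x <- fir_filter(x, design_fir(fs_out, high = lp,
                                                  transition = 1))
  continuous_record(x, fs_out, record$channels)
}

#' Derive horizontal and vertical EOG channels
#'
#' hEOG = AF8 - AF7; vEOG = FPz - AFz.
#'
#' @param x a [continuous_record()] or [epoch_array()] containing channels
#'   AF7, AF8, AFz, FPz.
#' @return for a continuous record, a samples x 2 matrix (`hEOG`, `vEOG`);
#'   for epochs, a trials x 2 x samples array.
#' @export
derive_eog <- function(x) {
  need <- c("AF7", "AF8", "AFz", "FPz")
  if (inherits(x, "continuous_record")) {
    if (!all(need %in% x$channels)) stop("EOG source channels missing")
    cbind(hEOG = x$data[, "AF8"] - x$data[, "AF7"],
          vEOG = x$data[, "FPz"] - x$data[, "AFz"])
  } else if (inherits(x, "epoch_array")) {
    if (!all(need %in% x$channels)) stop("EOG source channels missing")
    i <- match(need, x$channels)
    out <- array(0, c(dim(x$data)[1], 2, dim(x$data)[3]),
                 dimnames = list(NULL, c("hEOG", "vEOG"), NULL))
    out[, 1, ] <- x$data[, i[2], ] - x$data[, i[1], ]
    out[, 2, ] <- x$data[, i[4], ] - x$data[, i[3], ]
    out
  } else stop("unsupported input")
}

#' Epoch a continuous record around movement onsets
#'
#' @param record a [continuous_record()].
#' @param onsets event times in seconds (start of record = 0).
#' @param metadata data.frame, one row per event.
#' @param window epoch window in seconds around each event.
#' @return an [epoch_array()]; events whose window falls outside the
#'   record are dropped (with a warning).
#' @export
epoch_continuous <- function(record, onsets, metadata,
                             window = c(-1, 2)) {
  stopifnot(inherits(record, "continuous_record"),
            nrow(metadata) == length(onsets))
  fs <- record$fs
  rel <- seq(round(window[1] * fs), round(window[2] * fs))
  times <- rel / fs
  n_samp <- nrow(record$data)
  idx0 <- round(onsets * fs) + 1
  ok <- idx0 + rel[1] >= 1 & idx0 + rel[length(rel)] <= n_samp
  if (!all(ok)) warning(sum(!ok), " events outside the record were dropped")
  idx0 <- idx0[ok]
  dat <- array(0, c(length(idx0), ncol(record$data), length(rel)))
  for (i in seq_along(idx0))
    dat[i, , ] <- t(record$data[idx0[i] + rel, , drop = FALSE])
  epoch_array(dat, record$channels, times, fs,
              metadata[ok, , drop = FALSE])
}

#' Re-reference epochs to the common average
#'
#' Subtracts, at every trial and time sample, the mean over all scalp
#' channels; afterwards the channel mean is zero everywhere. Idempotent.
#'
#' @param epochs an [epoch_array()].
#' @param scalp channel names entering the average (default: all).
#' @return re-referenced [epoch_array()].
#' @export
rereference_common_average <- function(epochs, scalp = NULL) {
  stopifnot(inherits(epochs, "epoch_array"))
  ci <- if (is.null(scalp)) seq_along(epochs$channels)
        else match(scalp, epochs$channels)
  if (anyNA(ci)) stop("unknown scalp channel")
  avg <- colMeans(aperm(epochs$data[, ci, , drop = FALSE], c(2, 1, 3)))
  epochs$data <- epochs$data - aperm(
    array(avg, c(dim(avg), dim(epochs$data)[2])), c(1, 3, 2))
  epochs
}

#' Participant-level baseline correction
#'
#' For each participant and channel subtracts ONE scalar: the mean over
#' the baseline window pooled across all of that participant's retained
#' trials. Using a cross-trial scalar (instead of per-trial baselines)
#' avoids transferring pre-movement effects into the epoch; trial-to-trial
#' baseline differences are preserved. Idempotent.
#'
#' @param epochs an [epoch_array()].
#' @param window baseline window in seconds, default `c(-0.7, -0.2)`
#'   (700 to 200 ms before movement onset).
#' @return baseline-corrected [epoch_array()].
#' @export
baseline_correct <- function(epochs, window = c(-0.7, -0.2)) {
  stopifnot(inherits(epochs, "epoch_array"))
  sel <- epochs$times >= window[1] & epochs$times <= window[2]
  if (!any(sel)) stop("baseline window is empty")
  parts <- unique(epochs$metadata$participant)
  for (p in parts) {
    rows <- which(epochs$metadata$participant == p)
    base <- apply(epochs$data[rows, , sel, drop = FALSE], 2, mean)
    epochs$data[rows, , ] <- epochs$data[rows, , , drop = FALSE] -
      rep(base, each = length(rows))
  }
  epochs
}

#' Trim extreme-amplitude trials per participant
#'
#' Drops, separately for each participant, the `ceil(n * fraction)` trials
#' with the lowest and the highest maximum absolute amplitude (first and
#' last percentiles by default). Ties are broken by trial index.
#'
#' @param epochs an [epoch_array()].
#' @param fraction tail fraction, default 0.01.
#' @return an [epoch_array()] with trimmed trials removed; the number
#'   dropped per participant is attached as attribute `"trimmed"`.
#' @export
trim_amplitude_percentiles <- function(epochs, fraction = 0.01) {
  stopifnot(inherits(epochs, "epoch_array"), fraction >= 0, fraction < 0.5)
  maxamp <- apply(abs(epochs$data), 1, max)
  keep <- rep(TRUE, length(maxamp))
  dropped <- integer(0)
  for (p in unique(epochs$metadata$participant)) {
    rows <- which(epochs$metadata$participant == p)
    k <- ceiling(length(rows) * fraction)
    if (k == 0 || 2 * k >= length(rows)) next
    ord <- rows[order(maxamp[rows], rows)]
    keep[c(head(ord, k), tail(ord, k))] <- FALSE
    dropped[p] <- 2L * k
  }
  out <- subset_epochs(epochs, trials = keep)
  attr(out, "trimmed") <- dropped
  out
}

#' Surrogate artifact rejection
#'
#' Replacement for ICA-based artifact removal (deliberately out of scope):
#' drops epochs whose peak-to-peak amplitude on any scalp channel exceeds
#' `ptp_threshold`, or whose derived EOG exceeds `eog_threshold` when the
#' EOG source channels are present. Logged as a documented deviation from
#' component-based pipelines.
#'
#' @param epochs an [epoch_array()].
#' @param ptp_threshold peak-to-peak rejection threshold, microvolts.
#' @param eog_threshold absolute EOG threshold, microvolts.
#' @return an [epoch_array()]; rejected count in attribute `"rejected"`.
#' @export
reject_artifact_epochs <- function(epochs, ptp_threshold = 150,
                                   eog_threshold = 150) {
  stopifnot(inherits(epochs, "epoch_array"))
  ptp <- apply(epochs$data, 1, function(m) max(m) - min(m))
  bad <- ptp > ptp_threshold
  if (all(c("AF7", "AF8", "AFz", "FPz") %in% epochs$channels)) {
    eog <- derive_eog(epochs)
    bad <- bad | apply(abs(eog), 1, max) > eog_threshold
  }
  out <- subset_epochs(epochs, trials = !bad)
  attr(out, "rejected") <- sum(bad)
  out
}

#' Variance-based participant exclusion
#'
#' Per channel, each participant's signal variance (over all retained
#' epochs) is compared with the across-participant pool: channels
#' exceeding pool mean + 2 pooled SD count as noisy; participants with
#' strictly more than `max_bad` such channels are excluded.
#'
#' @param epochs an [epoch_array()] holding all participants.
#' @param n_sd threshold in pooled standard deviations, default 2.
#' @param max_bad maximum tolerated noisy channels (exclusion requires
#'   MORE than this many), default 10.
#' @return character vector of excluded participant ids (possibly empty),
#'   with the per-participant noisy-channel counts as attribute
#'   `"n_bad_channels"`.
#' @export
exclude_participant_by_variance <- function(epochs, n_sd = 2, max_bad = 10) {
  stopifnot(inherits(epochs, "epoch_array"))
  parts <- unique(epochs$metadata$participant)
  nc <- length(epochs$channels)
  v <- matrix(NA_real_, length(parts), nc,
              dimnames = list(parts, epochs$channels))
  for (i in seq_along(parts)) {
    rows <- which(epochs$metadata$participant == parts[i])
    for (ch in seq_len(nc))
      v[i, ch] <- var(as.vector(epochs$data[rows, ch, ]))
  }
  thr <- colMeans(v) + n_sd * apply(v, 2, sd)
  nbad <- rowSums(sweep(v, 2, thr, ">"))
  out <- parts[nbad > max_bad]
  attr(out, "n_bad_channels") <- nbad
  out
}

#' Standard epoch-level preprocessing pipeline
#'
#' Applies, in this fixed order: common-average re-reference, surrogate
#' artifact rejection, participant-level baseline correction, and
#' amplitude-percentile trimming. Returns the cleaned epochs plus a
#' machine-readable retention log accounting for every dropped trial.
#'
#' @param epochs an [epoch_array()] (already filtered and epoched).
#' @param baseline_window seconds, default `c(-0.7, -0.2)`.
#' @param ptp_threshold artifact rejection threshold, microvolts.
#' @param trim_fraction percentile trim fraction per tail.
#' @return list with `epochs` (cleaned) and `log` (data.frame per
#'   participant: input, artifact-rejected, trimmed, retained).
#' @export
preprocess_epochs <- function(epochs, baseline_window = c(-0.7, -0.2),
                              ptp_threshold = 150, trim_fraction = 0.01) {
  stopifnot(inherits(epochs, "epoch_array"))
  count_by <- function(e) {
    tab <- table(e$metadata$participant)
    setNames(as.integer(tab), names(tab))
  }
  n0 <- count_by(epochs)
  e1 <- rereference_common_average(epochs)
  e2 <- reject_artifact_epochs(e1, ptp_threshold = ptp_threshold)
  n2 <- count_by(e2)
  e3 <- baseline_correct(e2, window = baseline_window)
  e4 <- trim_amplitude_percentiles(e3, fraction = trim_fraction)
  n4 <- count_by(e4)
  parts <- names(n0)
  log <- data.frame(
    participant = parts,
    n_input = as.integer(n0),
    n_artifact = as.integer(n0 - ifelse(is.na(n2[parts]), 0L, n2[parts])),
    n_trimmed = as.integer(ifelse(is.na(n2[parts]), 0L, n2[parts]) -
                           ifelse(is.na(n4[parts]), 0L, n4[parts])),
    stringsAsFactors = FALSE)
  log$n_retained <- log$n_input - log$n_artifact - log$n_trimmed
  list(epochs = e4, log = log)
}
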