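#' Design a windowed-sinc FIR filter
#'
#' Hamming-windowed sinc design. The kernel is symmetric (linear phase),
#' so applying it once with group-delay compensation yields zero-phase
#' filtering. Transition width is approximately `3.3 / n_taps * fs` Hz.
#'
#' @param fs sampling rate (Hz).
#' @param low high-pass edge in Hz, or `NULL` for no high-pass.
#' @param high low-pass edge in Hz, or `NULL` for no low-pass.
#' @param transition transition bandwidth in Hz (sets the kernel length).
#' @return numeric vector of filter taps (odd length).
#' @export
design_fir <- function(fs, low = NULL, high = NULL, transition = 0.5) {
  stopifnot(!is.null(low) || !is.null(high), transition > 0)
  n <- ceiling(3.3 * fs / transition)
  if (n %% 2 == 0) n <- n + 1
  m <- (n - 1) / 2
  k <- seq(-m, m)
  sinc <- function(fc) {
    h <- 2 * fc / fs * sinc0(2 * fc / fs * k)
    h
  }
  if (!is.null(high) && is.null(low)) {
    h <- sinc(high)                        # low-pass
  } else if (!is.null(low) && is.null(high)) {
    h <- -sinc(low); h[m + 1] <- h[m + 1] + 1   # spectral inversion
  } else {
    h <- sinc(high) - sinc(low)            # band-pass
  }
  w <- 0.54 + 0.46 * cos(pi * k / m)       # Hamming
  h <- h * w
  # normalize: unity gain in the pass-band center
  if (is.null(low)) h / sum(h)
  else {
    fc <- if (is.null(high)) (low + fs / 2) / 2 else sqrt(low * high)
    g <- abs(sum(h * exp(-2i * pi * fc / fs * seq_along(h))))
    h / g
  }
}

sinc0 <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Zero-phase FIR filtering of a multichannel signal
#'
#' Applies a symmetric FIR kernel by FFT convolution with edge-value
#' padding and exact group-delay compensation, so the output has no phase
#' distortion and the same length as the input.
#'
#' @param x numeric matrix, samples x channels (a vector is treated as one
#'   channel).
#' @param h FIR kernel from [design_fir()] (odd length).
#' @return filtered matrix of the same dimensions.
#' @export
fir_filter <- function(x, h) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x); m <- (length(h) - 1) / 2
  stopifnot(length(h) %% 2 == 1)
  pad_top <- x[rep(1, m), , drop = FALSE]
  pad_bot <- x[rep(n, m), , drop = FALSE]
  xp <- rbind(pad_top, x, pad_bot)
  np <- nrow(xp)
  nfft <- nextn(np + length(h) - 1, 2)
  H <- fft(c(h, rep(0, nfft - length(h))))
  X <- mvfft(rbind(xp, matrix(0, nfft - np, ncol(xp))))
  y <- Re(mvfft(X * H, inverse = TRUE)) / nfft
  out <- y[(2 * m + 1):(2 * m + n), , drop = FALSE]
  if (vec) drop(out) else out
}

#' Resample a multichannel signal by Fourier interpolation
#'
#' Exact spectrum-truncation resampling (zero-phase): the Fourier
#' transform is cropped (or zero-padded) to the new Nyquist band and
#' inverted at the new length. Handles non-integer rate ratios such as
#' 1200 -> 128 Hz.
#'
#' @param x samples x channels matrix or vector.
#' @param fs_in,fs_out input and output sampling rates (Hz).
#' @return resampled matrix with `round(n * fs_out / fs_in)` rows.
#' @export
resample_fft <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  n_out <- round(n * fs_out / fs_in)
  X <- mvfft(x)
  Y <- matrix(0 + 0i, n_out, ncol(x))
  keep <- min(n, n_out)
  h1 <- ceiling(keep / 2)            # positive freqs incl. DC
  h2 <- keep - h1                    # negative freqs
  Y[seq_len(h1), ] <- X[seq_len(h1), , drop = FALSE]
  if (h2 > 0)
    Y[n_out - h2 + seq_len(h2), ] <- X[n - h2 + seq_len(h2), , drop = FALSE]
  y <- Re(mvfft(Y, inverse = TRUE)) / n
  if (vec) drop(y) else y
}
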