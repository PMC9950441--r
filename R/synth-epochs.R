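#' Spectrally shaped 1/f ("pink") noise
#'
#' Columns of independent pink noise generated by shaping the spectrum of
#' white Gaussian noise with `1/sqrt(f)` (flat below `f_floor` to avoid a
#' DC singularity), then rescaling each column to unit standard deviation.
#'
#' @param n_samples samples per column.
#' @param n_cols number of independent columns.
#' @param fs sampling rate in Hz.
#' @param f_floor frequency (Hz) below which the spectrum is flat.
#' @return `n_samples x n_cols` matrix with column sd 1.
#' @export
pink_noise <- function(n_samples, n_cols, fs = 128, f_floor = 1) {
  stopifnot(n_samples > 2, n_cols >= 1)
  w <- matrix(rnorm(n_samples * n_cols), n_samples, n_cols)
  f <- seq(0, fs, length.out = n_samples + 1)[seq_len(n_samples)]
  f <- pmin(f, fs - f)                # two-sided spectrum
  h <- 1 / sqrt(pmax(f, f_floor))
  h[1] <- 0                           # remove DC
  x <- Re(mvfft(mvfft(w) * h, inverse = TRUE)) / n_samples
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  sds[sds == 0] <- 1
  sweep(x, 2, sds, "/")
}

# Dipolar component topography, expressed in average-reference space.
#
# Scalp potentials have no absolute reference, so the generator emits
# average-referenced voltages directly: a Gaussian lobe at the component
# center plus a broader posterior-inferior counter-lobe (balanced over
# the full 64-channel layout, as for a physical dipole whose field
# integrates to ~0 over the scalp), projected onto the zero-mean space of
# the target montage and scaled to exactly 1 at the center channel. The
# common-average reference is then a no-op on the injected signal, so the
# nominal gain equals the analyzed contrast at the center channel.
erp_topography <- function(component, montage) {
  full <- load_montage()
  ci <- match(component$center, full$channel)
  if (is.na(ci)) stop("unknown center channel: ", component$center)
  cx <- full$x[ci]; cy <- full$y[ci]
  ox <- cx; oy <- cy - 1.5
  s <- component$spread
  lobe <- function(x, y)
    exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2)) -
      sum(exp(-((full$x - cx)^2 + (full$y - cy)^2) / (2 * s^2))) /
      sum(exp(-((full$x - ox)^2 + (full$y - oy)^2) / (2 * (1.8 * s)^2))) *
      exp(-((x - ox)^2 + (y - oy)^2) / (2 * (1.8 * s)^2))
  w <- lobe(montage$x, montage$y)
  w <- w - mean(w)                      # average-reference projection
  wc <- lobe(cx, cy) - mean(lobe(montage$x, montage$y))
  if (abs(wc) < 1e-8) stop("degenerate topography for ", component$center)
  w / wc
}

erp_kernel <- function(component, times) {
  exp(-(times - component$peak)^2 / (2 * component$width^2))
}

modulator_values <- function(component, trials) {
  switch(component$modulator,
    correctness = as.numeric(trials$correct),
    confidence  = zscore_by(trials$confidence, trials$participant),
    movementRT  = zscore_by(trials$onset, trials$participant),
    constant    = rep(1, nrow(trials)))
}

#' Simulate movement-locked EEG epochs
#'
#' Deterministic signal plus noise: the expected value at channel c and
#' time t is `participant intercept + sum over components of
#' gain * modulator * topography(c) * kernel(t)`; 1/f and white noise are
#' added per trial and channel, plus optional transient artifacts and
#' noisy ("bad") channels. With all noise sds zero the output equals the
#' analytic template exactly.
#'
#' @param trials data.frame of trial records (see [simulate_behavior()]);
#'   one epoch is generated per row.
#' @param templates list of [erp_component()]s.
#' @param noise a [noise_spec()].
#' @param montage a `montage` data.frame (see [default_montage()]).
#' @param fs sampling rate, Hz.
#' @param window epoch window in seconds relative to movement onset.
#' @param seed integer seed fixing all noise.
#' @return an [epoch_array()].
#' @export
simulate_epochs <- function(trials, templates = default_erp_templates(),
                            noise = noise_spec(),
                            montage = default_montage(8),
                            fs = 128, window = c(-1, 2), seed = 1L) {
  stopifnot(is.data.frame(trials), inherits(noise, "noise_spec"))
  if (!inherits(montage, "montage") ||
      !all(c("channel", "x", "y") %in% names(montage)))
    stop("montage mismatch: need a montage with channel/x/y columns")
  if (inherits(templates, "erp_component")) templates <- list(templates)
  n <- nrow(trials)
  chans <- montage$channel
  nc <- length(chans)
  times <- seq(window[1], window[2], by = 1 / fs)
  ns <- length(times)
  for (cmp in templates) {
    if (cmp$peak < window[1] || cmp$peak > window[2])
      stop("component kernel not supported within the epoch window")
    if (!is.finite(cmp$gain)) stop("component gain must be finite")
  }
  dat <- array(0, c(n, nc, ns))
  if (n == 0) {
    return(epoch_array(dat, chans, times, fs, trials))
  }
  for (cmp in templates) {
    topo <- erp_topography(cmp, montage)
    kern <- erp_kernel(cmp, times)
    mod <- modulator_values(cmp, trials)
    pat <- cmp$gain * (topo %o% kern)       # nc x ns
    dat <- dat + outer(mod, pat)
  }
  set.seed(seed)
  parts <- unique(trials$participant)
  icpt <- setNames(rnorm(length(parts), 0, noise$intercept_sd), parts)
  dat <- dat + icpt[trials$participant]     # recycles over channels/samples
  if (noise$pink_sd > 0) {
    ncols_tot <- n * nc
    block <- max(1L, min(ncols_tot, floor(4e6 / ns)))
    done <- 0L
    pn <- matrix(0, ns, ncols_tot)
    while (done < ncols_tot) {
      k <- min(block, ncols_tot - done)
      pn[, done + seq_len(k)] <- pink_noise(ns, k, fs)
      done <- done + k
    }
    dat <- dat + noise$pink_sd * aperm(array(pn, c(ns, n, nc)), c(2, 3, 1))
  }
  if (noise$white_sd > 0)
    dat <- dat + array(rnorm(length(dat), 0, noise$white_sd), dim(dat))
  if (noise$artifact_rate > 0) {
    hit <- which(runif(n) < noise$artifact_rate)
    for (i in hit) {
      ctr <- runif(1, window[1], window[2])
      blip <- noise$artifact_amp * sign(runif(1) - 0.5) *
        exp(-(times - ctr)^2 / (2 * 0.08^2))
      # uneven spatial profile: common-mode artifacts would vanish under
      # the common-average reference
      wch <- runif(nc, 0.1, 1)
      dat[i, , ] <- dat[i, , ] + wch %o% blip
    }
  }
  if (noise$bad_channels > 0) {
    for (p in parts) {
      bad <- sample.int(nc, min(noise$bad_channels, nc))
      rows <- which(trials$participant == p)
      extra <- array(rnorm(length(rows) * length(bad) * ns, 0,
                           9 * max(noise$pink_sd, 1)),
                     c(length(rows), length(bad), ns))
      dat[rows, bad, ] <- dat[rows, bad, ] + extra
    }
  }
  epoch_array(dat, chans, times, fs, trials)
}
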