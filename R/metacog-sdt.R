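#' Confidence-binned signal-detection counts
#'
#' Builds, for each participant, the `stimulus x response x confidence
#' bin` count array that meta-d-prime estimation consumes. Confidence is
#' discretized into `bins` per-participant equal-quantile bins.
#' Trials with confidence below 50 are excluded first (they indicate a
#' post-response change of mind), so bins span the 50-100 range.
#'
#' @param trials trial table with columns `participant`, `stim_side`
#'   (-1/1), `response_side` (-1/1), `confidence` (0-100).
#' @param bins number of confidence bins (default 4).
#' @param min_confidence exclusion threshold (default 50; trials strictly
#'   below are dropped).
#' @return named list, one `2 x 2 x bins` array per participant
#'   (dimensions: stimulus left/right, response left/right, bin).
#' @export
sdt_counts <- function(trials, bins = 4, min_confidence = 50) {
  stopifnot(bins >= 2)
  keep <- trials$confidence >= min_confidence
  tr <- trials[keep, , drop = FALSE]
  out <- list()
  for (p in unique(tr$participant)) {
    d <- tr[tr$participant == p, ]
    qs <- quantile(d$confidence, probs = seq(0, 1, length.out = bins + 1))
    bin <- findInterval(d$confidence, qs[-c(1, bins + 1)]) + 1L
    cnt <- array(0L, c(2, 2, bins),
                 dimnames = list(c("left", "right"), c("left", "right"),
                                 paste0("bin", seq_len(bins))))
    for (i in seq_len(nrow(d))) {
      s <- if (d$stim_side[i] > 0) 2L else 1L
      r <- if (d$response_side[i] > 0) 2L else 1L
      cnt[s, r, bin[i]] <- cnt[s, r, bin[i]] + 1L
    }
    out[[p]] <- cnt
  }
  out
}

rate_correct <- function(k, n) {
  # extreme-rate correction: replace 0 and 1 with 1/(2n), 1 - 1/(2n)
  r <- k / n
  r[r == 0] <- 1 / (2 * n[r == 0])
  r[r == 1] <- 1 - 1 / (2 * n[r == 1])
  r
}

#' Type-1 signal-detection sensitivity
#'
#' `d' = z(hit rate) - z(false-alarm rate)` treating "right" as the
#' signal, with the 1/(2N) correction for extreme rates.
#'
#' @param counts a `2 x 2 x bins` array from [sdt_counts()] (bins are
#'   collapsed), or a `2 x 2` stimulus x response count matrix.
#' @return list with `dprime`, `criterion`, `hit_rate`, `fa_rate`.
#' @export
compute_dprime <- function(counts) {
  m <- if (length(dim(counts)) == 3) apply(counts, c(1, 2), sum) else counts
  n_right <- sum(m[2, ]); n_left <- sum(m[1, ])
  if (n_right == 0 || n_left == 0) stop("need trials for both stimuli")
  h <- rate_correct(m[2, 2], n_right)
  f <- rate_correct(m[1, 2], n_left)
  list(dprime = qnorm(h) - qnorm(f),
       criterion = -0.5 * (qnorm(h) + qnorm(f)),
       hit_rate = h, fa_rate = f)
}

# Response-collapsed type-2 confidence-bin probabilities
# P(bin | stimulus, response) under the meta-SDT model: confidence
# criteria are symmetric offsets delta (increasing, > 0) from the
# meta-level type-1 criterion; bin 1 is least confident. Returns a
# 2 x 2 x bins array (stimulus, response, bin).
type2_probs <- function(meta_d, delta, t1) {
  bins <- length(delta) + 1
  meta_c <- if (t1$dprime != 0) t1$criterion * meta_d / t1$dprime
            else t1$criterion
  bounds_hi <- c(meta_c, meta_c + delta, Inf)       # response "right"
  bounds_lo <- c(-Inf, meta_c - rev(delta), meta_c) # response "left"
  pr <- array(0, c(2, 2, bins))
  for (s in 1:2) {
    mu <- if (s == 2) meta_d / 2 else -meta_d / 2
    ph <- pnorm(bounds_hi - mu)
    pr[s, 2, ] <- diff(ph) / max(1 - ph[1], 1e-12)
    pl <- pnorm(bounds_lo - mu)
    pr[s, 1, ] <- rev(diff(pl)) / max(pl[length(pl)], 1e-12)
  }
  pr
}

# type-2 log-likelihood of confidence-conditional counts given meta_d
type2_loglik <- function(meta_d, delta, counts, t1) {
  pr <- type2_probs(meta_d, delta, t1)
  sum(counts * log(pmax(pr, 1e-12)))
}

#' Simulate signal-detection counts with known metacognitive efficiency
#'
#' Draws a `stimulus x response x confidence bin` count array directly
#' from the (equal-variance, response-collapsed) meta-SDT model: type-1
#' responses from sensitivity `d` and criterion `c`, confidence bins from
#' the type-2 conditional distributions at metacognitive sensitivity
#' `meta_d`. The generative meta-d' (and hence M-ratio `meta_d / d`) is
#' exact by construction, which makes this the ground-truth generator for
#' recovery tests of [fit_meta_d_mle()] and [fit_hierarchical_mratio()].
#'
#' @param n trials.
#' @param d type-1 sensitivity.
#' @param meta_d metacognitive sensitivity.
#' @param criterion type-1 criterion (default 0).
#' @param delta confidence-criterion offsets (length bins - 1).
#' @return a `2 x 2 x bins` integer count array.
#' @export
simulate_sdt_counts <- function(n, d, meta_d, criterion = 0,
                                delta = c(0.5, 1.0, 1.5)) {
  bins <- length(delta) + 1
  t1 <- list(dprime = d, criterion = criterion)
  pr <- type2_probs(meta_d, delta, t1)
  cnt <- array(0L, c(2, 2, bins),
               dimnames = list(c("left", "right"), c("left", "right"),
                               paste0("bin", seq_len(bins))))
  n_s <- as.vector(rmultinom(1, n, c(0.5, 0.5)))
  for (s in 1:2) {
    mu <- if (s == 2) d / 2 else -d / 2
    p_right <- 1 - pnorm(criterion - mu)
    n_r <- rbinom(1, n_s[s], p_right)
    n_resp <- c(n_s[s] - n_r, n_r)
    for (r in 1:2) if (n_resp[r] > 0)
      cnt[s, r, ] <- cnt[s, r, ] + as.integer(rmultinom(1, n_resp[r],
                                                        pr[s, r, ]))
  }
  cnt
}

delta_from_eta <- function(eta) cumsum(exp(eta))

#' Maximum-likelihood meta-d-prime and M-ratio
#'
#' Fits the metacognitive sensitivity meta-d': the sensitivity of an
#' equal-variance SDT observer whose confidence ratings would produce the
#' observed confidence-conditional (type-2) counts, with the type-1
#' criterion carried over at the same relative position. Confidence
#' criteria are response-collapsed (one symmetric set of offsets).
#' M-ratio = meta-d' / d' is metacognitive efficiency (1 = ideal use of
#' the first-order evidence).
#'
#' @param counts a `2 x 2 x bins` array from [sdt_counts()].
#' @return list with `meta_d`, `mratio`, `dprime`, `criterion`, `delta`
#'   (fitted confidence criteria offsets), `loglik`, `convergence`.
#' @export
fit_meta_d_mle <- function(counts) {
  bins <- dim(counts)[3]
  resp_tot <- apply(counts, 2, sum)
  nz <- apply(counts, c(2, 3), sum) > 0
  if (any(rowSums(nz) < 2))
    stop("need counts in at least 2 confidence bins per response")
  t1 <- compute_dprime(counts)
  start <- c(t1$dprime, rep(log(0.4), bins - 1))
  obj <- function(par)
    -type2_loglik(par[1], delta_from_eta(par[-1]), counts, t1)
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  # polish from a second start to escape poor simplex collapses
  opt2 <- optim(c(0.5 * t1$dprime, rep(log(0.6), bins - 1)), obj,
                method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-10))
  if (opt2$value < opt$value) opt <- opt2
  opt3 <- optim(opt$par, obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-12))
  if (opt3$value < opt$value) opt <- opt3
  list(meta_d = opt$par[1], mratio = opt$par[1] / t1$dprime,
       dprime = t1$dprime, criterion = t1$criterion,
       delta = delta_from_eta(opt$par[-1]), loglik = -opt$value,
       convergence = opt$convergence)
}
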