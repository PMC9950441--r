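make_epochs <- function(data, parts, fs = 128, t0 = -1) {
  n <- dim(data)[1]
  times <- t0 + seq_len(dim(data)[3]) / fs - 1 / fs
  epoch_array(data, paste0("ch", seq_len(dim(data)[2])), times, fs,
              data.frame(participant = parts,
                         group = "a", correct = TRUE,
                         confidence = 80, onset = 1))
}

test_that("filtering meets its band specification", {
  fs <- 256
  t <- seq(0, 8, by = 1 / fs)
  rec <- continuous_record(cbind(l60 = sin(2 * pi * 60 * t),
                                 l10 = sin(2 * pi * 10 * t),
                                 dc = rep(2, length(t))),
                           fs, c("l60", "l10", "dc"))
  out <- preprocess_continuous(rec)
  expect_equal(out$fs, 128)
  amp_at <- function(v, f) {
    n <- length(v); 2 * Mod(fft(v))[round(f * n / 128) + 1] / n
  }
  expect_lt(20 * log10(amp_at(out$data[, 1], 60)), -20)  # >= 20 dB down
  expect_equal(amp_at(out$data[, 2], 10), 1, tolerance = 0.05)
  expect_lt(max(abs(out$data[100:900, 3])), 0.05)        # DC removed
  expect_error(preprocess_continuous(continuous_record(cbind(a = t), 100,
                                                       "a")),
               "twice")
  mont <- default_montage(8)
  expect_error(preprocess_continuous(rec, montage = mont), "missing")
})

test_that("EOG derivations are plain channel arithmetic", {
  n <- 100
  base <- matrix(rnorm(4 * n), n, 4)
  chans <- c("AF7", "AF8", "AFz", "FPz")
  rec <- continuous_record(base, 128, chans)
  eog <- derive_eog(rec)
  expect_equal(eog[, "hEOG"], base[, 2] - base[, 1])
  expect_equal(eog[, "vEOG"], base[, 4] - base[, 3])
  # AF8 = AF7 + 1 -> hEOG = 1
  rec2 <- continuous_record(cbind(base[, 1], base[, 1] + 1,
                                  base[, 3:4]), 128, chans)
  expect_equal(unname(derive_eog(rec2)[, "hEOG"]), rep(1, n))
  # blink template on FPz only -> vEOG equals the template
  blink <- dnorm(seq_len(n), 50, 5) * 100
  rec3 <- continuous_record(cbind(base[, 1:3] * 0, blink), 128, chans)
  expect_equal(unname(derive_eog(rec3)[, "vEOG"]), blink)
  expect_error(derive_eog(continuous_record(base, 128,
                                            c("a", "b", "c", "d"))),
               "missing")
})

test_that("epoching a continuous record extracts aligned windows", {
  fs <- 128
  n <- fs * 30
  ramp <- seq_len(n) / fs         # value equals time in seconds
  rec <- continuous_record(cbind(r = ramp, z = 0), fs, c("r", "z"))
  md <- data.frame(participant = c("p1", "p1"), trial = 1:2)
  ep <- epoch_continuous(rec, onsets = c(5, 10), md, window = c(-1, 2))
  expect_equal(dim(ep$data), c(2, 2, 385))
  # ramp channel must read (onset + t) at epoch time t
  expect_equal(ep$data[1, 1, ], 5 + ep$times + 1 / fs, tolerance = 1e-9)
  expect_warning(epoch_continuous(rec, c(29.9), md[1, , drop = FALSE]),
                 "dropped")
})

test_that("common-average reference zeroes the channel mean, idempotently", {
  set.seed(301)
  ep <- make_epochs(array(rnorm(5 * 6 * 40), c(5, 6, 40)), rep("p1", 5))
  rr <- rereference_common_average(ep)
  expect_lt(max(abs(apply(rr$data, c(1, 3), mean))), 1e-10)
  rr2 <- rereference_common_average(rr)
  expect_equal(rr2$data, rr$data, tolerance = 1e-12)
  # two channels +1 / -1 are unchanged
  two <- make_epochs(array(rep(c(1, -1), each = 1, times = 40 * 2),
                           c(2, 2, 40)) * 0 +
                     aperm(array(c(1, -1), c(2, 2, 40)), c(2, 1, 3)),
                     rep("p1", 2))
  expect_equal(rereference_common_average(two)$data, two$data)
})

test_that("baseline correction subtracts one scalar per participant/channel", {
  # two trials with baseline-window means 1 and 3 -> both shifted by -2
  fs <- 128
  ns <- 385
  dat <- array(0, c(2, 1, ns))
  dat[1, 1, ] <- 1; dat[2, 1, ] <- 3
  ep <- make_epochs(dat, c("p1", "p1"), fs = fs)
  bc <- baseline_correct(ep)
  expect_equal(bc$data[1, 1, ], rep(-1, ns))
  expect_equal(bc$data[2, 1, ], rep(1, ns))
  # trial-to-trial baseline differences are preserved
  set.seed(302)
  dat2 <- array(rnorm(8 * 2 * ns), c(8, 2, ns))
  off <- rnorm(8, sd = 5)
  dat2 <- dat2 + off   # per-trial offsets
  ep2 <- make_epochs(dat2, rep("p1", 8), fs = fs)
  bc2 <- baseline_correct(ep2)
  win <- ep2$times >= -0.7 & ep2$times <= -0.2
  bm_before <- apply(dat2[, 1, win], 1, mean)
  bm_after <- apply(bc2$data[, 1, win], 1, mean)
  expect_equal(diff(bm_before), diff(bm_after), tolerance = 1e-10)
  # constant input -> all zeros; idempotent
  cst <- make_epochs(array(7, c(3, 2, ns)), rep("p1", 3), fs = fs)
  expect_true(all(baseline_correct(cst)$data == 0))
  expect_equal(baseline_correct(baseline_correct(ep2))$data, bc2$data,
               tolerance = 1e-12)
  expect_error(baseline_correct(ep, window = c(5, 6)), "empty")
})

test_that("percentile trimming drops ceil(n/100) per tail with index ties", {
  set.seed(303)
  for (n in c(100, 300)) {
    ep <- make_epochs(array(rnorm(n * 2 * 30), c(n, 2, 30)),
                      rep("p1", n))
    tt <- trim_amplitude_percentiles(ep)
    expect_equal(dim(tt$data)[1], n - 2 * ceiling(n * 0.01))
  }
  # all-identical trials: ties broken by trial index, count still dropped
  ep <- make_epochs(array(1, c(100, 2, 30)), rep("p1", 100))
  tt <- trim_amplitude_percentiles(ep)
  expect_equal(dim(tt$data)[1], 98)
  expect_equal(attr(tt, "trimmed")[["p1"]], 2L)
})

test_that("variance-based participant exclusion applies the >10 rule", {
  set.seed(304)
  nch <- 14
  mk <- function(p, scale = 1, nbad = 0) {
    d <- array(rnorm(20 * nch * 30), c(20, nch, 30))
    if (nbad > 0) d[, seq_len(nbad), ] <- d[, seq_len(nbad), ] * 10
    make_epochs(d * scale, rep(p, 20))
  }
  homog <- bind_epochs(lapply(sprintf("p%d", 1:6), mk))
  expect_length(exclude_participant_by_variance(homog), 0)
  # one participant with 12 loud channels -> excluded
  bad12 <- bind_epochs(c(lapply(sprintf("p%d", 1:6), mk),
                         list(mk("px", nbad = 12))))
  expect_equal(as.character(exclude_participant_by_variance(bad12)), "px")
  # exactly 10 loud channels -> retained ("more than 10")
  bad10 <- bind_epochs(c(lapply(sprintf("p%d", 1:6), mk),
                         list(mk("py", nbad = 10))))
  expect_length(exclude_participant_by_variance(bad10), 0)
})

test_that("preprocessing pipeline keeps retention accounting consistent", {
  set.seed(305)
  tr <- simulate_behavior(cohort_spec(2, 2, 120, seed = 55))
  tr <- tr[tr$exclusion_true == "none", ]
  ep <- simulate_epochs(tr, default_erp_templates(),
                        noise_spec(artifact_rate = 0.05),
                        default_montage(8), window = c(-1, 1), seed = 56)
  pp <- preprocess_epochs(ep)
  log <- pp$log
  expect_equal(log$n_input, log$n_artifact + log$n_trimmed + log$n_retained)
  expect_equal(sum(log$n_retained), dim(pp$epochs$data)[1])
  expect_gt(sum(log$n_artifact), 0)   # injected artifacts were caught
})
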