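#' Simulate behavioural trials for a two-group cohort
#'
#' Runs an independent staircase per participant (performance matching),
#' then generates movement onsets, confidence ratings and generative
#' exclusion truth. Confidence is an ideal-observer read-out of the
#' internal evidence, `plogis(2 * d * |x|)`, shifted by
#' `coupling * z(onset)` and Gaussian noise, then expressed on the 0-100
#' scale. Incorrect responses get slightly slower onsets
#' (a lognormal multiplier), reproducing the usual error-slowing.
#'
#' The generative exclusion label (`exclusion_true`) applies the same
#' precedence as [apply_trial_exclusions()] so that detector output can be
#' scored against truth.
#'
#' @param cohort a [cohort_spec()].
#' @param observer_a,observer_b [observer_spec()] for groups a and b.
#' @return data.frame of trial records, one row per trial.
#' @export
simulate_behavior <- function(cohort,
                              observer_a = observer_spec(),
                              observer_b = observer_spec(
                                confidence_rt_coupling = -0.01)) {
  stopifnot(inherits(cohort, "cohort_spec"))
  n_tot <- cohort$n_group_a + cohort$n_group_b
  groups <- rep(cohort$labels, c(cohort$n_group_a, cohort$n_group_b))
  out <- vector("list", n_tot)
  for (p in seq_len(n_tot)) {
    obs <- if (groups[p] == cohort$labels[1]) observer_a else observer_b
    set.seed(derive_seed(cohort$seed, paste0("behavior/", p)))
    out[[p]] <- simulate_participant(
      obs, cohort$trials_per_participant,
      participant = sprintf("p%02d", p), group = groups[p])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

simulate_participant <- function(obs, n_trials, participant, group) {
  if (n_trials == 0) {
    return(data.frame(participant = character(), group = character(),
                      trial = integer(), coherence = numeric(),
                      stim_side = integer(), response_side = integer(),
                      correct = logical(), evidence = numeric(),
                      onset = numeric(), confidence = numeric(),
                      com_true = logical(), early_true = logical(),
                      late_true = logical(), exclusion_true = character(),
                      stringsAsFactors = FALSE))
  }
  st <- simulate_staircase(obs, max(n_trials, 50))[seq_len(n_trials), ]
  m <- obs$mean_onset; s <- obs$onset_sd
  sdlog <- sqrt(log(1 + s^2 / m^2))
  meanlog <- log(m) - sdlog^2 / 2
  onset <- rlnorm(n_trials, meanlog, sdlog)
  onset <- onset * exp(0.12 * !st$correct)   # error slowing
  # confidence couples to the standardized decision time BEFORE the
  # early/late artifact classes are stamped in (those trials are excluded
  # from every analysis; letting their extreme onsets into the
  # standardization would shrink the coupling on retained trials)
  z_on <- if (n_trials > 1) as.numeric(scale(onset)) else 0
  early <- runif(n_trials) < obs$p_early
  late <- !early & runif(n_trials) < obs$p_late
  onset[early] <- runif(sum(early), 0.02, 0.095)
  onset[late] <- runif(sum(late), 6.05, 7.2)
  d <- obs$sensitivity * st$coherence
  # ideal-observer confidence plogis(2 d |x|) compressed into [0.5, 0.92]
  # so that rating-scale clipping stays rare; without the compression the
  # ceiling truncates the onset coupling well below its nominal slope
  # The <50 change-of-mind exclusion truncates the analysis sample from
  # below and the rating ceiling compresses it from above; together they
  # attenuate a latent confidence~onset slope by ~0.47 in the fitted
  # retained-trial regression. The nominal coupling is defined as the
  # slope recovered on RETAINED trials, so the latent slope is inflated
  # by the inverse factor (calibrated once; see methods vignette).
  conf <- 0.5 + 0.42 * (2 * plogis(2 * d * abs(st$evidence)) - 1) +
    2.1 * obs$confidence_rt_coupling * z_on +
    rnorm(n_trials, 0, obs$confidence_noise_sd)
  conf <- clip(conf, 0, 1) * 100
  com <- runif(n_trials) < obs$p_com
  lab <- ifelse(early, "early",
         ifelse(late, "late",
         ifelse(com, "com_pre",
         ifelse(conf < 50, "com_post", "none"))))
  data.frame(participant = participant, group = group,
             trial = st$trial, coherence = st$coherence,
             stim_side = st$stim_side, response_side = st$response_side,
             correct = st$correct, evidence = st$evidence,
             onset = onset, confidence = conf,
             com_true = com, early_true = early, late_true = late,
             exclusion_true = lab, stringsAsFactors = FALSE)
}

#' Simulate a mouse trajectory for one trial
#'
#' Screen coordinates are normalized to `[0,1] x [0,1]`: start point at
#' bottom-center (0.5, 0.05), response targets at the top corners
#' ((0.1, 0.95) left, (0.9, 0.95) right), midline at x = 0.5. Before the
#' movement onset the cursor jitters in place; the reach itself follows a
#' minimal-jerk profile (bell-shaped speed). A change-of-mind trial first
#' heads toward the opposite target for the early part of the movement and
#' then curves to the final target, crossing the midline after the
#' 20-percent progress mark.
#'
#' The default movement duration (0.65 s) makes the 20-percent-of-peak
#' velocity crossing of a minimal-jerk reach occur ~83 ms after the true
#' movement start, so that the five-frame detector offset is unbiased for
#' typical reaches.
#'
#' @param onset true movement onset, seconds from stimulus onset (< 6 s
#'   unless simulating a late trial).
#' @param target_side `"left"` or `"right"` (final response).
#' @param com logical: generate a pre-response change of mind.
#' @param frame_rate display frame rate in Hz (default 60).
#' @param movement_duration duration of the reach in seconds.
#' @param jitter_sd sd of positional jitter before the reach.
#' @return data.frame `t`, `x`, `y` (one row per frame).
#' @export
simulate_trajectory <- function(onset, target_side = c("right", "left"),
                                com = FALSE, frame_rate = 60,
                                movement_duration = 0.65,
                                jitter_sd = 5e-4) {
  target_side <- match.arg(target_side)
  start <- c(0.5, 0.05)
  tx <- if (target_side == "right") 0.9 else 0.1
  ox <- if (target_side == "right") 0.1 else 0.9
  target <- c(tx, 0.95); other <- c(ox, 0.95)
  dur <- if (com) movement_duration * 1.4 else movement_duration
  t_end <- min(onset + dur + 0.25, 7.5)
  t <- seq(0, t_end, by = 1 / frame_rate)
  n <- length(t)
  pos <- matrix(rep(start, each = n), ncol = 2)
  moving <- t >= onset
  tau <- clip((t[moving] - onset) / dur, 0, 1)
  if (com) {
    # piecewise: toward the wrong target until 35% of movement time,
    # then minimal-jerk from the turn point to the true target
    t_sw <- 0.35
    turn <- start + (other - start) * minjerk_s(0.45)
    seg1 <- outer(minjerk_s(clip(tau / t_sw, 0, 1) * 0.45), other - start) +
      rep(start, each = sum(moving))
    s2 <- minjerk_s(clip((tau - t_sw) / (1 - t_sw), 0, 1))
    seg2 <- outer(s2, target - turn) + rep(turn, each = sum(moving))
    pos[moving, ] <- ifelse(matrix(tau <= t_sw, sum(moving), 2), seg1, seg2)
  } else {
    s <- minjerk_s(tau)
    pos[moving, ] <- outer(s, target - start) + rep(start, each = sum(moving))
  }
  pos <- pos + matrix(rnorm(2 * n, 0, jitter_sd), ncol = 2)
  data.frame(t = t, x = clip(pos[, 1], 0, 1), y = clip(pos[, 2], 0, 1))
}

# minimal-jerk position profile on [0, 1]
minjerk_s <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
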