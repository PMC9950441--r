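#' Compute instantaneous mouse speed
#'
#' Speed between consecutive samples: Euclidean displacement divided by
#' the time step, assigned to interval midpoints (length n - 1).
#'
#' @param traj data.frame with columns `t`, `x`, `y`; `t` strictly
#'   increasing, at least 2 samples.
#' @param smooth logical: apply a centered 3-sample moving average to the
#'   speed series (off by default; useful for noisy real recordings).
#' @return data.frame with columns `t` (interval midpoints) and `speed`
#'   (normalized screen units per second).
#' @export
compute_velocity <- function(traj, smooth = FALSE) {
  stopifnot(is.data.frame(traj), all(c("t", "x", "y") %in% names(traj)))
  if (nrow(traj) < 2) stop("need at least 2 samples")
  dt <- diff(traj$t)
  if (any(dt <= 0)) stop("duplicate or non-increasing timestamps")
  sp <- sqrt(diff(traj$x)^2 + diff(traj$y)^2) / dt
  if (smooth && length(sp) >= 3) {
    sm <- stats::filter(sp, rep(1 / 3, 3), sides = 2)
    sp <- ifelse(is.na(sm), sp, as.numeric(sm))
  }
  data.frame(t = traj$t[-length(traj$t)] + dt / 2, speed = sp)
}

#' Detect movement onset from a mouse trajectory
#'
#' Movement onset is the time of the first sample whose speed reaches
#' 20 percent of the trial's maximum speed, minus a fixed offset of five
#' display frames (~83 ms at 60 Hz) to better capture movement
#' initiation. The result is floored at 0 (with a `floored` attribute when
#' the floor applied). Returns `NA` when the trajectory contains no
#' movement (maximum speed 0).
#'
#' @param traj trajectory data.frame (`t`, `x`, `y`).
#' @param threshold_fraction fraction of peak speed, default 0.20;
#'   the comparison is closed (`>=`), earliest sample wins ties.
#' @param offset_frames number of display frames subtracted, default 5.
#' @param frame_rate display frame rate in Hz, default 60.
#' @param smooth passed to [compute_velocity()].
#' @return onset in seconds, or `NA_real_` if no movement.
#' @export
detect_movement_onset <- function(traj, threshold_fraction = 0.20,
                                  offset_frames = 5, frame_rate = 60,
                                  smooth = FALSE) {
  v <- compute_velocity(traj, smooth = smooth)
  vmax <- max(v$speed)
  if (vmax == 0) return(NA_real_)
  idx <- which(v$speed >= threshold_fraction * vmax)[1]
  onset <- v$t[idx] - offset_frames / frame_rate
  if (onset < 0) {
    onset <- 0
    attr(onset, "floored") <- TRUE
  }
  onset
}

#' Detect a pre-response change of mind
#'
#' A trial counts as a change of mind when, after the cursor has covered
#' 20 percent of the vertical distance between its initial position and
#' the y-projection of the target, the trajectory crosses the midline
#' between the two response targets (i.e. is found on the side opposite
#' the finally chosen target).
#'
#' @param traj trajectory data.frame (`t`, `x`, `y`).
#' @param target_side final response side, `"left"` or `"right"`.
#' @param travel_fraction progress threshold, default 0.20.
#' @param midline x-coordinate of the midline, default 0.5.
#' @param target_y y-coordinate of the response targets, default 0.95.
#' @param margin how far past the midline (screen units) counts as a
#'   crossing; 0 by default.
#' @return logical flag.
#' @export
detect_change_of_mind <- function(traj, target_side = c("right", "left"),
                                  travel_fraction = 0.20, midline = 0.5,
                                  target_y = 0.95, margin = 0) {
  target_side <- match.arg(target_side)
  stopifnot(nrow(traj) >= 1)
  y0 <- traj$y[1]
  total <- target_y - y0
  if (total == 0) return(FALSE)
  prog <- (traj$y - y0) / total
  after <- which(prog >= travel_fraction)
  if (!length(after)) return(FALSE)
  xs <- traj$x[after[1]:nrow(traj)]
  if (target_side == "right") any(xs < midline - margin)
  else any(xs > midline + margin)
}

#' Apply the trial exclusion rules
#'
#' Precedence: `no_movement` (no detectable onset) > `early`
#' (onset < 100 ms) > `late` (onset > 6 s) > `com_pre` (pre-response change
#' of mind) > `com_post` (confidence strictly below 50) > `none`.
#' A confidence of exactly 50 is not a post-response change of mind.
#'
#' @param onset detected movement onset in seconds, or `NA`.
#' @param confidence confidence rating on the 0-100 scale.
#' @param com_pre logical change-of-mind flag from
#'   [detect_change_of_mind()].
#' @param early_ms,late_s exclusion bounds (100 ms, 6 s).
#' @return a single exclusion label (character).
#' @export
apply_trial_exclusions <- function(onset, confidence, com_pre,
                                   early_ms = 100, late_s = 6) {
  if (length(confidence) != 1 || is.na(confidence) ||
      confidence < 0 || confidence > 100)
    stop("confidence must be a single value in [0, 100]")
  if (is.na(onset)) return("no_movement")
  if (onset < early_ms / 1000) return("early")
  if (onset > late_s) return("late")
  if (isTRUE(com_pre)) return("com_pre")
  if (confidence < 50) return("com_post")
  "none"
}

#' Kinematic analysis of a table of trajectories
#'
#' Long-format interface: takes trajectories as a single data.frame with
#' columns `trial_id`, `t`, `x`, `y`, plus a per-trial table with the
#' final response side and confidence, and returns one row per trial with
#' onset, peak speed, change-of-mind flags and the exclusion label.
#'
#' @param traj_long long-format trajectory table.
#' @param trials data.frame with columns `trial_id`, `target_side`
#'   (`"left"`/`"right"`), `confidence` (0-100).
#' @param ... passed to [detect_movement_onset()] and
#'   [detect_change_of_mind()].
#' @return data.frame: `trial_id`, `onset`, `peak_speed`, `com_pre`,
#'   `com_post`, `exclusion`.
#' @export
analyze_trajectories <- function(traj_long, trials, ...) {
  stopifnot(all(c("trial_id", "t", "x", "y") %in% names(traj_long)),
            all(c("trial_id", "target_side", "confidence") %in% names(trials)))
  res <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- traj_long[traj_long$trial_id == trials$trial_id[i], , drop = FALSE]
    onset <- detect_movement_onset(tr, ...)
    peak <- max(compute_velocity(tr)$speed)
    com <- detect_change_of_mind(tr, trials$target_side[i])
    lab <- apply_trial_exclusions(onset, trials$confidence[i], com)
    data.frame(trial_id = trials$trial_id[i],
               onset = as.numeric(onset), peak_speed = peak,
               com_pre = com, com_post = trials$confidence[i] < 50,
               exclusion = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
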