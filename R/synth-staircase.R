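p_correct_at <- function(observer, coherence) {
  d <- observer$sensitivity * coherence
  observer$lapse * 0.5 + (1 - observer$lapse) * pnorm(d)
}

#' Simulate a 1-up-2-down adaptive staircase
#'
#' Motion coherence is decreased (multiplicatively) after two consecutive
#' correct responses and increased after every error, the classic rule
#' whose accuracy asymptote is the coherence where p(correct)^2 = 0.5,
#' i.e. ~70.7 percent correct. The observer answers through an
#' equal-variance signal-detection channel: internal evidence
#' `x ~ N(side * sensitivity * coherence, 1)`, response = sign(x), with an
#' occasional lapse. Evidence draws are returned so that confidence can be
#' generated from the same internal signal.
#'
#' @param observer an [observer_spec()].
#' @param n_trials number of trials (>= 50).
#' @param initial_coherence starting coherence, must be > 0.
#' @param step_factor multiplicative step; an error multiplies coherence by
#'   `step_factor`, two consecutive correct divide by it.
#' @param coherence_range allowed `[floor, ceiling]` for coherence.
#' @return data.frame with columns `trial`, `coherence`, `stim_side`
#'   (-1 left / +1 right), `evidence`, `response_side`, `correct`,
#'   `step` (-1 down, 0 none, +1 up, applied after the trial).
#' @export
simulate_staircase <- function(observer, n_trials,
                               initial_coherence = 0.5,
                               step_factor = 1.1,
                               coherence_range = c(0.02, 1)) {
  stopifnot(inherits(observer, "observer_spec"), n_trials >= 50)
  if (initial_coherence <= 0) stop("initial coherence must be positive")
  stopifnot(step_factor > 1)
  coh <- numeric(n_trials); stim <- integer(n_trials)
  ev <- numeric(n_trials); resp <- integer(n_trials)
  corr <- logical(n_trials); step <- integer(n_trials)
  cur <- initial_coherence
  streak <- 0L
  for (i in seq_len(n_trials)) {
    coh[i] <- cur
    stim[i] <- if (runif(1) < 0.5) -1L else 1L
    d <- observer$sensitivity * cur
    ev[i] <- rnorm(1, mean = stim[i] * d, sd = 1)
    r <- if (ev[i] >= 0) 1L else -1L
    if (runif(1) < observer$lapse) r <- if (runif(1) < 0.5) -1L else 1L
    resp[i] <- r
    corr[i] <- r == stim[i]
    if (corr[i]) {
      streak <- streak + 1L
      if (streak == 2L) {
        cur <- cur / step_factor
        step[i] <- -1L
        streak <- 0L
      }
    } else {
      cur <- cur * step_factor
      step[i] <- 1L
      streak <- 0L
    }
    cur <- clip(cur, coherence_range[1], coherence_range[2])
  }
  data.frame(trial = seq_len(n_trials), coherence = coh, stim_side = stim,
             evidence = ev, response_side = resp, correct = corr,
             step = step)
}
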