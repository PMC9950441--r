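#' Bayesian confidence ~ movement-onset regression
#'
#' Regression of confidence (0-1 scale) on standardized movement onset x
#' correctness x group with a participant random intercept, fitted with
#' the package's Gibbs sampler (standard-normal priors on slopes, vague
#' intercept). Reports a directional evidence ratio per term: the onset
#' main effect is hypothesized negative (confidence drops with slower
#' movements), the group x onset interaction positive (weaker coupling in
#' the second group); other terms default to positive.
#'
#' @param trials trial table (see [simulate_behavior()]); rows whose
#'   `exclusion` / `exclusion_true` column is not `"none"` are dropped
#'   when present.
#' @param iter,warmup,chains,seed sampler settings.
#' @return a `posterior_summary` with `evidence_ratio` per term.
#' @export
confidence_rt_model <- function(trials, iter = 2000, warmup = 1000,
                                chains = 4, seed = 1L) {
  excl <- trials$exclusion %||% trials$exclusion_true
  if (!is.null(excl)) trials <- trials[excl == "none", , drop = FALSE]
  md <- data.frame(
    confidence01 = trials$confidence / 100,
    z_movementRT = zscore_by(trials$onset, trials$participant),
    correctness = as.numeric(trials$correct),
    group = as.numeric(factor(trials$group)) - 1,
    participant = trials$participant)
  X <- stats::model.matrix(~ z_movementRT * correctness * group, md)
  pm <- rep(0, ncol(X)); ps <- c(10, rep(1, ncol(X) - 1))
  fit <- gibbs_lmm(md$confidence01, X,
                   random = list(p = list(factor = md$participant, x = NULL)),
                   prior_mean = pm, prior_sd = ps,
                   iter = iter, warmup = warmup, chains = chains,
                   seed = seed)
  dirs <- setNames(rep("positive", ncol(X)), colnames(X))
  dirs["z_movementRT"] <- "negative"
  fit$summary$direction <- dirs[fit$summary$term]
  fit$summary$evidence_ratio <- vapply(seq_len(ncol(X)), function(j)
    evidence_ratio(fit$draws[, j], dirs[colnames(X)[j]]), 0)
  fit
}

#' Cognitive-insight composite score
#'
#' Composite = self-reflectiveness - self-certainty (exact arithmetic).
#'
#' @param self_reflectiveness,self_certainty subscale scores (points).
#' @return composite score in points.
#' @export
bcis_composite <- function(self_reflectiveness, self_certainty) {
  stopifnot(is.numeric(self_reflectiveness), is.numeric(self_certainty))
  self_reflectiveness - self_certainty
}

#' Two-group comparison with default Bayes factor
#'
#' Welch two-sample t-test plus the JZS default Bayes factor
#' ([jzs_two_sample_bf()]) computed from the same t statistic. A Bayes
#' factor above 3 (below 1/3) is conventionally labelled moderate
#' evidence for a difference (for the null).
#'
#' @param x,y numeric samples for the two groups.
#' @return data.frame: means, t, df, p, bf10, and an evidence label.
#' @export
group_compare <- function(x, y) {
  tt <- tryCatch(t.test(x, y), error = function(e)
    list(statistic = c(t = 0), parameter = c(df = NA_real_), p.value = 1))
  bf <- jzs_two_sample_bf(unname(tt$statistic), length(x), length(y))
  lab <- if (bf > 3) "moderate+ H1" else if (bf < 1 / 3) "moderate+ H0"
         else "inconclusive"
  data.frame(mean_x = mean(x), mean_y = mean(y),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, bf10 = bf, evidence = lab)
}
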