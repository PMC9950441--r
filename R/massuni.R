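#' Fit one of the pipeline's linear mixed models
#'
#' Front-end over the two engines: the package's closed-form REML solver
#' (`engine = "closed"`, default; exact for random-intercept structures)
#' and lme4 (`engine = "lme4"`). Random slopes are deliberately absent at
#' the scanning stages (they produce convergence failures at single-trial
#' scale); the full random-slope structures live in the Bayesian
#' cluster-level models. With the lme4 engine, a convergence failure
#' triggers a refit with the simplified random structure
#' `(1|participant)` and sets `flag = "simplified"`.
#'
#' @param formula fixed-effects formula, e.g. `amplitude ~ correctness * group`.
#' @param data data.frame containing the response, fixed covariates, and
#'   `participant` (plus `electrode` when `nested = TRUE`).
#' @param nested add an electrode-within-participant random intercept.
#' @param engine `"closed"` or `"lme4"`.
#' @return list with `coefficients` (data.frame: estimate, se, z, p),
#'   variance components, `engine`, `flag` and `remlcrit`.
#' @export
fit_lmm <- function(formula, data, nested = FALSE,
                    engine = c("closed", "lme4")) {
  engine <- match.arg(engine)
  stopifnot("participant" %in% names(data))
  if (nested) stopifnot("electrode" %in% names(data))
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (engine == "closed") {
    fit <- lmm_closed(y, X, data$participant,
                      if (nested) data$electrode else NULL)
    co <- data.frame(term = names(fit$beta), estimate = fit$beta,
                     se = fit$se, z = fit$z, p = fit$p,
                     row.names = NULL)
    return(list(coefficients = co, sigma2 = fit$sigma2,
                var_participant = fit$var_participant,
                var_electrode = fit$var_electrode,
                engine = engine, flag = "ok", remlcrit = fit$remlcrit))
  }
  rnd <- if (nested) "(1 | participant / electrode)" else "(1 | participant)"
  full <- stats::as.formula(paste(deparse(formula), "+", rnd))
  flag <- "ok"
  m <- tryCatch(lme4::lmer(full, data = data, REML = TRUE),
                error = function(e) NULL, warning = function(w) NULL)
  if (is.null(m) && nested) {
    flag <- "simplified"
    full <- stats::as.formula(paste(deparse(formula), "+ (1 | participant)"))
    m <- lme4::lmer(full, data = data, REML = TRUE)
  }
  if (is.null(m)) stop("lme4 fit failed")
  if (lme4::isSingular(m) && flag == "ok") flag <- "singular"
  sm <- summary(m)$coefficients
  z <- sm[, "t value"]
  co <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                   se = sm[, "Std. Error"], z = z,
                   p = 2 * pnorm(-abs(z)), row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(m))
  list(coefficients = co,
       sigma2 = vc$vcov[vc$grp == "Residual"],
       var_participant = sum(vc$vcov[grepl("^participant$", vc$grp)]),
       var_electrode = sum(vc$vcov[grepl(":", vc$grp)]),
       engine = engine, flag = flag, remlcrit = lme4::REMLcrit(m))
}

#' Benjamini-Hochberg step-up FDR procedure
#'
#' @param p vector of p-values.
#' @param alpha target false discovery rate.
#' @return list with `reject` (logical mask), `q` (adjusted p-values,
#'   always >= p), and `n` (family size).
#' @export
benjamini_hochberg <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  q[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q <- pmin(q, 1)
  list(reject = q <= alpha, q = q, n = n)
}

# fixed-effect designs for the three scanning models
build_scan_design <- function(metadata, term = c("correctness",
                                                 "confidence",
                                                 "movementRT")) {
  term <- match.arg(term)
  # group is centered (-0.5 / +0.5) so that the scanned term is the main
  # effect across groups, not the reference group's simple effect
  md <- data.frame(
    participant = metadata$participant,
    correctness = as.numeric(metadata$correct),
    group = as.numeric(factor(metadata$group)) - 1.5,
    z_confidence = zscore_by(metadata$confidence, metadata$participant),
    z_movementRT = zscore_by(metadata$onset, metadata$participant))
  one_group <- length(unique(md$group)) < 2
  f <- if (one_group) switch(term,
    correctness = ~ correctness,
    confidence  = ~ z_confidence + z_movementRT,
    movementRT  = ~ z_movementRT + z_confidence)
  else switch(term,
    correctness = ~ correctness * group,
    confidence  = ~ z_confidence * group + z_movementRT,
    movementRT  = ~ z_movementRT * group + z_confidence)
  X <- stats::model.matrix(f, md)
  coef_name <- switch(term, correctness = "correctness",
                      confidence = "z_confidence",
                      movementRT = "z_movementRT")
  list(X = X, coef = coef_name, covars = md, formula = f)
}

#' Step 1: mass-univariate scan for responsive electrodes
#'
#' For each electrode and time sample in the scan window (0-500 ms
#' post-movement by default) fits the single-trial mixed model for the
#' requested term with a participant random intercept, then applies
#' Benjamini-Hochberg FDR jointly over the whole electrodes x samples
#' family for that term. Electrodes with at least one significant sample,
#' intersected with the region of interest, are returned for cluster
#' analysis.
#'
#' @param epochs a preprocessed [epoch_array()].
#' @param term `"correctness"`, `"confidence"` or `"movementRT"`.
#' @param roi character vector of ROI channel names (must be non-empty);
#'   see [roi_frontocentral()].
#' @param alpha FDR level.
#' @param window scan window in seconds, closed interval, default
#'   `c(0, 0.5)`.
#' @return list with `electrodes` (selected, in ROI), `responsive` (all
#'   electrodes with a significant sample), `grid` (ScanGrid data.frame:
#'   electrode, time, estimate, se, z, p, q, significant) and
#'   `family_size`.
#' @export
scan_responsive_electrodes <- function(epochs, term, roi = roi_frontocentral(),
                                       alpha = 0.05, window = c(0, 0.5)) {
  stopifnot(inherits(epochs, "epoch_array"))
  if (!length(roi)) stop("empty ROI")
  des <- build_scan_design(epochs$metadata, term)
  sel <- which(epochs$times >= window[1] - 1e-9 &
               epochs$times <= window[2] + 1e-9)
  nc <- length(epochs$channels)
  d <- epochs$data[, , sel, drop = FALSE]
  Y <- matrix(d, nrow = dim(d)[1])          # cols: channel fastest
  res <- lmm_scan_columns(Y, des$X, epochs$metadata$participant, des$coef)
  bh <- benjamini_hochberg(res$p, alpha)
  grid <- data.frame(
    electrode = rep(epochs$channels, times = length(sel)),
    time = rep(epochs$times[sel], each = nc),
    estimate = res$estimate, se = res$se, z = res$z, p = res$p,
    q = bh$q, significant = bh$reject)
  responsive <- unique(grid$electrode[grid$significant])
  list(electrodes = intersect(responsive, roi),
       responsive = responsive, grid = grid,
       alpha = alpha, family_size = bh$n, term = term)
}

#' Step 2: cluster regression over selected electrodes
#'
#' Restricted to the electrodes selected at step 1, fits the same
#' fixed-effects model at every time sample with electrode nested within
#' participant as random intercepts, FDR-corrects the term's p-values over
#' samples, and keeps maximal runs of significant adjacent samples
#' strictly longer than `min_duration` (50 ms: at 128 Hz a run needs >= 7
#' samples). The step-2 window extends before movement onset by default
#' (confidence effects can start pre-movement).
#'
#' @param epochs a preprocessed [epoch_array()].
#' @param electrodes electrode set from [scan_responsive_electrodes()].
#' @param term scanned term.
#' @param alpha FDR level over samples.
#' @param window analysis window in seconds, default `c(-0.2, 0.75)`.
#' @param min_duration minimal strict cluster duration in seconds.
#' @return list with `clusters` (list of `cluster_result`) and `samples`
#'   (per-sample statistics data.frame).
#' @export
cluster_regression <- function(epochs, electrodes, term, alpha = 0.05,
                               window = c(-0.2, 0.75),
                               min_duration = 0.05) {
  stopifnot(inherits(epochs, "epoch_array"), length(electrodes) >= 1)
  ei <- match(electrodes, epochs$channels)
  if (anyNA(ei)) stop("unknown electrode")
  des <- build_scan_design(epochs$metadata, term)
  sel <- which(epochs$times >= window[1] - 1e-9 &
               epochs$times <= window[2] + 1e-9)
  n <- dim(epochs$data)[1]; ne <- length(ei); m <- length(sel)
  d <- epochs$data[, ei, sel, drop = FALSE]
  Y <- matrix(d, n * ne, m)
  part <- rep(epochs$metadata$participant, times = ne)
  elec <- rep(electrodes, each = n)
  Xl <- des$X[rep(seq_len(n), times = ne), , drop = FALSE]
  ci <- match(des$coef, colnames(Xl))
  ss <- lmm_suffstats(Xl, part, if (ne > 1) elec else NULL)
  Ysum <- rowsum(Y, ss$cell)
  XtY <- crossprod(Xl, Y)
  yy <- colSums(Y^2)
  est <- se <- pv <- lam1 <- numeric(m)
  for (j in seq_len(m)) {
    ys <- Ysum[, j, drop = FALSE]
    if (ss$nested) {
      opt <- optim(c(0, 0), function(lth)
        lmm_remlcrit(exp(lth[1]), exp(lth[2]), ss, ys,
                     XtY[, j, drop = FALSE], yy[j]),
        method = "Nelder-Mead", control = list(reltol = 1e-8))
      fit <- lmm_finalize(exp(opt$par[1]), exp(opt$par[2]), ss, ys,
                          XtY[, j, drop = FALSE], yy[j], opt$value)
    } else {
      opt <- optimize(function(lth)
        lmm_remlcrit(exp(lth), 0, ss, ys, XtY[, j, drop = FALSE], yy[j]),
        interval = c(-16, 12), tol = 1e-8)
      fit <- lmm_finalize(exp(opt$minimum), 0, ss, ys,
                          XtY[, j, drop = FALSE], yy[j], opt$objective)
    }
    est[j] <- fit$beta[ci]; se[j] <- fit$se[ci]; pv[j] <- fit$p[ci]
    lam1[j] <- fit$lambda[1]
  }
  bh <- benjamini_hochberg(pv, alpha)
  samples <- data.frame(time = epochs$times[sel], estimate = est, se = se,
                        z = est / se, p = pv, q = bh$q,
                        significant = bh$reject)
  clusters <- find_clusters(samples, epochs$fs, electrodes, term,
                            min_duration)
  list(clusters = clusters, samples = samples, alpha = alpha, term = term)
}

# maximal runs of significant samples; duration k/fs must be strictly
# greater than min_duration
find_clusters <- function(samples, fs, electrodes, term, min_duration) {
  r <- rle(samples$significant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    len <- r$lengths[k]
    if (len / fs <= min_duration) next
    idx <- starts[k]:ends[k]
    peak <- idx[which.max(abs(samples$z[idx]))]
    out[[length(out) + 1]] <- structure(list(
      electrodes = electrodes,
      window = c(samples$time[starts[k]], samples$time[ends[k]]),
      peak_time = samples$time[peak],
      peak_z = samples$z[peak],
      n_samples = len, term = term), class = "cluster_result")
  }
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster> %s: %d samples [%.3f, %.3f] s, peak %.3f s (z = %.2f)\n  electrodes: %s\n",
              x$term, x$n_samples, x$window[1], x$window[2], x$peak_time,
              x$peak_z, paste(x$electrodes, collapse = ", ")))
  invisible(x)
}

#' Per-participant tertile labels
#'
#' Empirical tertiles with ties going to the lower bin:
#' `bin = ceiling(3 * rank / n)` with minimum-rank ties. With all values
#' equal, everything is labelled `low`.
#'
#' @param values numeric vector (one participant's values).
#' @return factor with levels `low`, `mid`, `high`.
#' @export
assign_tertiles <- function(values) {
  r <- rank(values, ties.method = "min")
  b <- ceiling(3 * r / length(values))
  factor(c("low", "mid", "high")[b], levels = c("low", "mid", "high"))
}

#' Effect amplitude over a cluster's peak window
#'
#' Average condition difference over the cluster's electrodes and a 50 ms
#' window centred on the cluster peak: correct minus incorrect trials for
#' the correctness contrast; top minus bottom per-participant confidence
#' (or movement-onset) tertile otherwise. Differences are computed within
#' participant and averaged across participants contributing both
#' conditions. The window shrinks symmetrically (and reports it) when the
#' peak sits close to an epoch edge.
#'
#' @param epochs an [epoch_array()].
#' @param cluster a `cluster_result`.
#' @param contrast `"correctness"`, `"confidence"` or `"movementRT"`.
#' @param halfwidth window half-width, seconds (default 0.025).
#' @return effect amplitude in microvolts; attribute `"halfwidth"` gives
#'   the (possibly shrunk) half-width actually used.
#' @export
effect_amplitude <- function(epochs, cluster,
                             contrast = c("correctness", "confidence",
                                          "movementRT"),
                             halfwidth = 0.025) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(epochs, "epoch_array"),
            inherits(cluster, "cluster_result"))
  hw <- min(halfwidth,
            cluster$peak_time - min(epochs$times),
            max(epochs$times) - cluster$peak_time)
  sel <- which(abs(epochs$times - cluster$peak_time) <= hw + 1e-9)
  ei <- match(cluster$electrodes, epochs$channels)
  if (anyNA(ei)) stop("cluster window/electrodes outside epochs")
  md <- epochs$metadata
  trialmean <- apply(epochs$data[, ei, sel, drop = FALSE], 1, mean)
  cond <- switch(contrast,
    correctness = factor(ifelse(md$correct, "high", "low"),
                         levels = c("low", "mid", "high")),
    confidence = {
      f <- factor(rep(NA_character_, nrow(md)),
                  levels = c("low", "mid", "high"))
      for (p in unique(md$participant)) {
        i <- md$participant == p
        f[i] <- assign_tertiles(md$confidence[i])
      }
      f
    },
    movementRT = {
      f <- factor(rep(NA_character_, nrow(md)),
                  levels = c("low", "mid", "high"))
      for (p in unique(md$participant)) {
        i <- md$participant == p
        f[i] <- assign_tertiles(md$onset[i])
      }
      f
    })
  diffs <- vapply(unique(md$participant), function(p) {
    i <- md$participant == p
    a <- trialmean[i & cond == "high"]
    b <- trialmean[i & cond == "low"]
    if (!length(a) || !length(b)) return(NA_real_)
    mean(a) - mean(b)
  }, 0)
  out <- mean(diffs, na.rm = TRUE)
  attr(out, "halfwidth") <- hw
  out
}
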