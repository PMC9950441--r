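# Shared fixtures and independent oracles for the test suite.

# Brute-force movement-onset oracle: scan the speed array directly.
oracle_onset <- function(traj, frac = 0.2, offset_frames = 5, fr = 60) {
  dt <- diff(traj$t)
  sp <- sqrt(diff(traj$x)^2 + diff(traj$y)^2) / dt
  tm <- traj$t[-nrow(traj)] + dt / 2
  mx <- max(sp)
  if (mx == 0) return(NA_real_)
  max(tm[which(sp >= frac * mx)[1]] - offset_frames / fr, 0)
}

# Monte-Carlo oracle for the JZS two-sample Bayes factor: average the
# likelihood ratio over draws from the Cauchy effect-size prior.
oracle_jzs <- function(t, n1, n2, r = sqrt(2) / 2, B = 2e5, seed = 42) {
  set.seed(seed)
  nu <- n1 + n2 - 2
  N <- n1 * n2 / (n1 + n2)
  delta <- r * tan(pi * (runif(B) - 0.5))
  suppressWarnings(mean(dt(t, nu, ncp = delta * sqrt(N)) / dt(t, nu)))
}

# Two-stage grid-search maximizer of the type-2 likelihood: an
# independent route to the meta-d' MLE (profile over meta_d on a grid,
# nlminb over the criterion offsets at each grid point).
oracle_meta_d_grid <- function(counts) {
  t1 <- compute_dprime(counts)
  bins <- dim(counts)[3]
  prof <- function(md) {
    o <- stats::nlminb(rep(log(0.4), bins - 1), function(eta)
      -confclust:::type2_loglik(md, cumsum(exp(eta)), counts, t1))
    -o$objective
  }
  coarse <- seq(-1, 2.5 * max(t1$dprime, 0.5), by = 0.05)
  lc <- vapply(coarse, prof, 0)
  m0 <- coarse[which.max(lc)]
  fine <- seq(m0 - 0.06, m0 + 0.06, by = 0.005)
  lf <- vapply(fine, prof, 0)
  fine[which.max(lf)]
}

# Small preprocessed synthetic study used by several massuni/bayes tests
# (built once per test run).
tiny_study <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    tr <- simulate_behavior(cohort_spec(6, 6, 150, seed = 303))
    tr <- tr[tr$exclusion_true == "none", ]
    ep <- simulate_epochs(tr, default_erp_templates(-0.6, 0.3, 0.3),
                          noise_spec(), default_montage(8),
                          window = c(-1, 1), seed = 304)
    cache <<- preprocess_epochs(ep)$epochs
    cache
  }
})
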