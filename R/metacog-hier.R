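#' Hierarchical Bayesian group M-ratio
#'
#' Group-level model of metacognitive efficiency: each participant's log
#' M-ratio is drawn from a group Gaussian, `log mratio_i ~ N(mu_g,
#' sigma_g^2)` with priors `mu_g ~ N(0, 1)` and `sigma_g ~ halfN(0, 1)`.
#' Participant-level type-1 parameters (d', criterion) are fixed at their
#' corrected point estimates; log M-ratios and confidence-criterion
#' offsets are sampled by adaptive random-walk Metropolis within Gibbs
#' against the type-2 likelihood of [fit_meta_d_mle()]. Group M-ratio
#' summaries are posteriors of `exp(mu_g)`; the group difference gets a
#' Savage-Dickey Bayes factor on `mu_a - mu_b` (prior `N(0, sqrt(2))`).
#'
#' @param counts_list named list of `2 x 2 x bins` arrays (one per
#'   participant), e.g. from [sdt_counts()].
#' @param groups character vector of group labels aligned with
#'   `counts_list`.
#' @param iter,warmup iterations per chain.
#' @param chains number of chains.
#' @param seed integer seed.
#' @return list with `group` (data.frame: group, posterior mean M-ratio,
#'   95 percent HDI), `bf01` / `bf10` for the group difference,
#'   `participants` (MLE and posterior-mean M-ratio per participant),
#'   `mu_draws`, and `warnings`.
#' @export
fit_hierarchical_mratio <- function(counts_list, groups,
                                    iter = 2000, warmup = 1000,
                                    chains = 2, seed = 1L) {
  np <- length(counts_list)
  stopifnot(length(groups) == np, np >= 2)
  glev <- unique(groups)
  stopifnot(length(glev) <= 2)
  warns <- character(0)
  for (g in glev) if (sum(groups == g) < 2)
    warns <- c(warns, paste0("group ", g,
      " has a single participant: posterior is prior-dominated"))
  t1 <- lapply(counts_list, compute_dprime)
  mle <- lapply(counts_list, function(cc)
    tryCatch(fit_meta_d_mle(cc), error = function(e) NULL))
  bins <- dim(counts_list[[1]])[3]
  gi <- match(groups, glev)
  ng <- length(glev)
  # state
  rho <- vapply(seq_len(np), function(i) {
    m <- mle[[i]]
    if (is.null(m) || !is.finite(m$mratio) || m$mratio <= 0.05) log(0.5)
    else log(min(m$mratio, 3))
  }, 0)
  eta <- lapply(seq_len(np), function(i) {
    m <- mle[[i]]
    if (is.null(m)) rep(log(0.4), bins - 1)
    else log(pmax(diff(c(0, m$delta)), 1e-3))
  })
  loglik_i <- function(i, rho_i, eta_i) {
    md <- exp(rho_i) * t1[[i]]$dprime
    type2_loglik(md, delta_from_eta(eta_i), counts_list[[i]], t1[[i]])
  }
  ll <- vapply(seq_len(np), function(i) loglik_i(i, rho[i], eta[[i]]), 0)
  mu <- rep(0, ng); sig <- rep(0.5, ng)
  scale_i <- rep(0.3, np); acc_i <- rep(0, np)
  n_keep <- (iter - warmup) * chains
  mu_draws <- matrix(NA_real_, n_keep, ng, dimnames = list(NULL, glev))
  rho_acc <- rep(0, np)
  kk <- 0L
  for (ch in seq_len(chains)) {
    set.seed(derive_seed(seed, paste0("hmratio/", ch)))
    for (it in seq_len(iter)) {
      for (i in seq_len(np)) {
        rho_p <- rho[i] + rnorm(1, 0, scale_i[i])
        eta_p <- eta[[i]] + rnorm(bins - 1, 0, scale_i[i] * 0.6)
        ll_p <- loglik_i(i, rho_p, eta_p)
        g <- gi[i]
        lr <- ll_p - ll[i] +
          dnorm(rho_p, mu[g], sig[g], log = TRUE) -
          dnorm(rho[i], mu[g], sig[g], log = TRUE)
        if (is.finite(lr) && log(runif(1)) < lr) {
          rho[i] <- rho_p; eta[[i]] <- eta_p; ll[i] <- ll_p
          acc_i[i] <- acc_i[i] + 1
        }
        if (it <= warmup && it %% 50 == 0) {
          rate <- acc_i[i] / 50
          scale_i[i] <- clip(scale_i[i] * exp(rate - 0.3), 0.02, 2)
          acc_i[i] <- 0
        }
      }
      for (g in seq_len(ng)) {
        idx <- which(gi == g); n_g <- length(idx)
        prec <- n_g / sig[g]^2 + 1
        m <- sum(rho[idx]) / sig[g]^2 / prec
        mu[g] <- rnorm(1, m, 1 / sqrt(prec))
        # half-normal prior on sigma, random walk on log sigma
        sp <- sig[g] * exp(rnorm(1, 0, 0.25))
        lr <- sum(dnorm(rho[idx], mu[g], sp, log = TRUE)) -
          sum(dnorm(rho[idx], mu[g], sig[g], log = TRUE)) +
          (-sp^2 / 2) - (-sig[g]^2 / 2) + log(sp) - log(sig[g])
        if (is.finite(lr) && log(runif(1)) < lr) sig[g] <- sp
      }
      if (it > warmup) {
        kk <- kk + 1L
        mu_draws[kk, ] <- mu
        rho_acc <- rho_acc + rho / ((iter - warmup) * chains)
      }
    }
  }
  hdi <- function(x, level = 0.95) {
    xs <- sort(x); n <- length(xs); w <- floor(level * n)
    i <- which.min(xs[(w + 1):n] - xs[1:(n - w)])
    c(xs[i], xs[i + w])
  }
  grp <- do.call(rbind, lapply(seq_len(ng), function(g) {
    mr <- exp(mu_draws[, g])
    data.frame(group = glev[g], mratio_mean = mean(mr),
               hdi_lo = hdi(mr)[1], hdi_hi = hdi(mr)[2])
  }))
  bf01 <- NA_real_
  if (ng == 2) {
    delta <- mu_draws[, 1] - mu_draws[, 2]
    bf01 <- as.numeric(savage_dickey_bf01(delta, 0, sqrt(2)))
  }
  participants <- data.frame(
    participant = names(counts_list) %||% as.character(seq_len(np)),
    group = groups,
    dprime = vapply(t1, `[[`, 0, "dprime"),
    mratio_mle = vapply(mle, function(m)
      if (is.null(m)) NA_real_ else m$mratio, 0),
    mratio_post = exp(rho_acc), row.names = NULL)
  list(group = grp, bf01 = bf01, bf10 = 1 / bf01,
       participants = participants, mu_draws = mu_draws,
       warnings = warns)
}
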