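# Conjugate Gibbs sampler for Gaussian linear mixed models with
# independent Gaussian priors on fixed effects and inverse-gamma priors
# on the variance components. Random-effect design columns within one
# term (one grouping factor x one covariate) are mutually orthogonal, so
# each term's coefficients update elementwise; everything runs on
# precomputed cross-products, making per-iteration cost independent of
# the number of observations.

#' Bayesian Gaussian linear mixed model by Gibbs sampling
#'
#' Samples from the posterior of `y = X beta + sum_k Z_k b_k + e` with
#' `beta_j ~ N(prior_mean_j, prior_sd_j^2)`, `b_k ~ N(0, tau_k^2 I)`,
#' `tau_k^2 ~ InvGamma(1.5, 0.5)` and `sigma^2 ~ InvGamma(0.001, 0.001)`.
#' Each random term is one grouping factor optionally multiplied by a
#' covariate (random slope); intercept-slope correlations are not
#' modelled.
#'
#' @param y response vector.
#' @param X fixed-effects model matrix.
#' @param random named list of random terms; each element is
#'   `list(factor = <grouping factor>, x = <covariate or NULL>)`.
#' @param prior_mean,prior_sd vectors of Gaussian prior parameters for the
#'   columns of `X` (recycled if length 1).
#' @param iter iterations per chain (including warmup).
#' @param warmup warmup iterations discarded per chain.
#' @param chains number of chains.
#' @param seed integer seed.
#' @return object of class `posterior_summary`: `draws` (matrix of
#'   post-warmup fixed-effect draws, all chains stacked), `chain` (chain
#'   index per draw), `summary` (mean, sd, 2.5/97.5 percent quantiles,
#'   R-hat per term), `tau` (posterior means of random-term sds),
#'   `sigma`, and `converged` (all R-hat < 1.05).
#' @export
gibbs_lmm <- function(y, X, random, prior_mean = 0, prior_sd = 10,
                      iter = 2000, warmup = 1000, chains = 4, seed = 1L) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  stopifnot(nrow(X) == n, warmup < iter)
  pm <- rep_len(prior_mean, p); ps <- rep_len(prior_sd, p)
  K <- length(random)
  Z <- vector("list", K)
  for (k in seq_len(K)) {
    f <- as.factor(random[[k]]$factor)
    xk <- random[[k]]$x %||% rep(1, n)
    Z[[k]] <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f),
                                   x = xk, dims = c(n, nlevels(f)))
  }
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)
  ZtX <- lapply(Z, function(z) as.matrix(Matrix::crossprod(z, X)))
  Zty <- lapply(Z, function(z) as.vector(Matrix::crossprod(z, y)))
  Ztd <- lapply(Z, function(z) Matrix::colSums(z^2))   # diagonal of Z'Z
  ZtZ <- list()
  for (k in seq_len(K)) for (j in seq_len(K))
    if (j != k) ZtZ[[paste(k, j)]] <- Matrix::crossprod(Z[[k]], Z[[j]])
  qk <- vapply(Z, ncol, 0L)
  a_tau <- 1.5; b_tau <- 0.5
  a_sig <- 0.001; b_sig <- 0.001
  n_keep <- iter - warmup
  draws <- matrix(NA_real_, n_keep * chains, p,
                  dimnames = list(NULL, colnames(X)))
  chain_id <- rep(seq_len(chains), each = n_keep)
  tau_acc <- matrix(0, chains, K)
  sig_acc <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed(derive_seed(seed, paste0("gibbs/", ch)))
    beta <- pm
    b <- lapply(qk, function(q) numeric(q))
    tau2 <- rep(1, K)
    sig2 <- stats::var(y) %||% 1
    if (!is.finite(sig2) || sig2 <= 0) sig2 <- 1
    collapse1 <- K == 1 && is.null(random[[1]]$x)
    if (collapse1) {
      ns_g <- Ztd[[1]]
      Xs_g <- ZtX[[1]]
      icol <- which(colnames(X) == "(Intercept)")
    }
    for (it in seq_len(iter)) {
      # fixed effects
      if (collapse1) {
        # collapse the random intercept out of the beta update
        # (Woodbury): avoids the intercept/random-intercept random walk
        lam <- tau2[1] / sig2
        wv <- lam / (1 + lam * ns_g)
        A <- (XtX - crossprod(Xs_g * wv, Xs_g)) / sig2 + diag(1 / ps^2, p)
        rhs <- (Xty - crossprod(Xs_g * wv, Zty[[1]])) / sig2 + pm / ps^2
      } else {
        r <- Xty
        for (k in seq_len(K)) r <- r - crossprod(ZtX[[k]], b[[k]])
        A <- XtX / sig2 + diag(1 / ps^2, p)
        rhs <- r / sig2 + pm / ps^2
      }
      Rc <- chol(A)
      mu <- backsolve(Rc, backsolve(Rc, rhs, transpose = TRUE))
      beta <- as.vector(mu + backsolve(Rc, rnorm(p)))
      # random terms
      for (k in seq_len(K)) {
        rk <- Zty[[k]] - as.vector(ZtX[[k]] %*% beta)
        for (j in seq_len(K)) if (j != k)
          rk <- rk - as.vector(ZtZ[[paste(k, j)]] %*% b[[j]])
        v <- 1 / (Ztd[[k]] / sig2 + 1 / tau2[k])
        b[[k]] <- rnorm(qk[k], mean = v * rk / sig2, sd = sqrt(v))
        tau2[k] <- 1 / rgamma(1, a_tau + qk[k] / 2,
                              b_tau + sum(b[[k]]^2) / 2)
      }
      # residual variance
      rss <- yty - 2 * sum(beta * Xty) + as.vector(t(beta) %*% XtX %*% beta)
      for (k in seq_len(K)) {
        rss <- rss - 2 * sum(b[[k]] * Zty[[k]]) +
          2 * sum(b[[k]] * (ZtX[[k]] %*% beta)) +
          sum(b[[k]]^2 * Ztd[[k]])
        for (j in seq_len(K)) if (j != k)
          rss <- rss + sum(b[[k]] * as.vector(ZtZ[[paste(k, j)]] %*% b[[j]]))
      }
      rss <- max(rss, 1e-12)
      sig2 <- 1 / rgamma(1, a_sig + n / 2, b_sig + rss / 2)
      # interweaving recentering sweep: shift the mean of each random
      # intercept block into the fixed intercept (deterministic-proposal
      # Metropolis; likelihood invariant, prior ratio decides)
      icol <- which(colnames(X) == "(Intercept)")
      if (!collapse1 && length(icol) == 1) {
        for (k in seq_len(K)) {
          if (!is.null(random[[k]]$x)) next
          mshift <- mean(b[[k]])
          lr <- sum(dnorm(b[[k]] - mshift, 0, sqrt(tau2[k]), log = TRUE)) -
            sum(dnorm(b[[k]], 0, sqrt(tau2[k]), log = TRUE)) +
            dnorm(beta[icol] + mshift, pm[icol], ps[icol], log = TRUE) -
            dnorm(beta[icol], pm[icol], ps[icol], log = TRUE)
          if (is.finite(lr) && log(runif(1)) < lr) {
            b[[k]] <- b[[k]] - mshift
            beta[icol] <- beta[icol] + mshift
          }
        }
      }
      if (it > warmup) {
        draws[(ch - 1) * n_keep + it - warmup, ] <- beta
        tau_acc[ch, ] <- tau_acc[ch, ] + sqrt(tau2) / n_keep
        sig_acc[ch] <- sig_acc[ch] + sqrt(sig2) / n_keep
      }
    }
  }
  rh <- apply(draws, 2, split_rhat, chains = chains)
  smry <- data.frame(
    term = colnames(X),
    mean = colMeans(draws),
    sd = apply(draws, 2, sd),
    q2.5 = apply(draws, 2, quantile, 0.025),
    q97.5 = apply(draws, 2, quantile, 0.975),
    rhat = rh, row.names = NULL)
  structure(list(draws = draws, chain = chain_id, summary = smry,
                 tau = colMeans(tau_acc), sigma = mean(sig_acc),
                 chains = chains, iter = iter, warmup = warmup,
                 converged = all(is.finite(rh)) && all(rh < 1.05)),
            class = "posterior_summary")
}

# split-half R-hat (rank-free classic formula on split chains)
split_rhat <- function(x, chains) {
  m <- matrix(x, ncol = chains)
  half <- floor(nrow(m) / 2)
  sub <- cbind(m[seq_len(half), , drop = FALSE],
               m[half + seq_len(half), , drop = FALSE])
  mns <- colMeans(sub); vrs <- apply(sub, 2, var)
  nsub <- nrow(sub); msub <- ncol(sub)
  W <- mean(vrs); B <- nsub * var(mns)
  if (W <= 0) return(NA_real_)
  sqrt(((nsub - 1) / nsub * W + B / nsub) / W)
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> %d chains x %d draws (warmup %d)%s\n",
              x$chains, x$iter - x$warmup, x$warmup,
              if (x$converged) "" else "  ** NOT CONVERGED (R-hat >= 1.05) **"))
  print(x$summary, digits = 3)
  invisible(x)
}
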