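# Closed-form REML machinery for random-intercept linear mixed models.
#
# The mass-univariate scans fit the same fixed-effects design to thousands
# of (electrode, sample) voltage series; a general-purpose LMM fitter is
# orders of magnitude too slow for that. For models whose random part is
# an intercept per participant -- optionally plus an intercept per
# electrode nested in participant -- the covariance
#   V/sigma^2 = I + lambda1 Z1 Z1' + lambda2 Z2 Z2'
# can be inverted analytically (Woodbury within electrode cells, then
# Sherman-Morrison across a participant's cells), so the REML criterion
# profiles down to a 1-D or 2-D optimization over variance ratios with
# O(#cells) cost per evaluation. lme4 serves as the independent oracle in
# the test suite.

lmm_suffstats <- function(X, participant, electrode = NULL) {
  part <- droplevels(as.factor(participant))
  cell <- if (is.null(electrode)) part
          else interaction(part, as.factor(electrode), drop = TRUE)
  Xs <- rowsum(X, cell)                    # cell sums of design rows
  ncell <- as.vector(rowsum(rep(1, nrow(X)), cell))
  cell_part <- part[match(rownames(Xs), as.character(cell))]
  list(X = X, n = nrow(X), p = ncol(X), cell = cell, part = part,
       nested = !is.null(electrode),
       XtX = crossprod(X), Xs = Xs, ncell = ncell,
       cell_part = cell_part)
}

# Quadratic-form reducer: given cell sums U (ncell x a), V (ncell x b),
# raw cross-product UV (a x b), return U' W V for
# W = (V/sigma^2)^{-1}. Weights precomputed in wts.
lmm_qform <- function(UV, Ucell, Vcell, wts, ss) {
  out <- UV - crossprod(Ucell * wts$a, Vcell)
  Up <- rowsum(Ucell * wts$u, ss$cell_part)
  Vp <- rowsum(Vcell * wts$u, ss$cell_part)
  out - crossprod(Up * wts$cpart, Vp)
}

lmm_weights <- function(lambda1, lambda2, ss) {
  if (ss$nested) {
    u <- 1 / (1 + lambda2 * ss$ncell)
    a <- lambda2 * u
    s_i <- as.vector(rowsum(ss$ncell * u, ss$cell_part))
    cpart <- lambda1 / (1 + lambda1 * s_i)
    logdet <- sum(log1p(lambda2 * ss$ncell)) + sum(log1p(lambda1 * s_i))
  } else {
    u <- rep(1, length(ss$ncell))
    a <- lambda1 / (1 + lambda1 * ss$ncell)
    cpart <- rep(0, nlevels(ss$cell_part))
    logdet <- sum(log1p(lambda1 * ss$ncell))
  }
  list(u = u, a = a, cpart = cpart, logdet = logdet)
}

# -2 REML log-likelihood (full constant, comparable to lme4::REMLcrit)
lmm_remlcrit <- function(lambda1, lambda2, ss, ys, Xty, yy) {
  w <- lmm_weights(lambda1, lambda2, ss)
  XtWX <- lmm_qform(ss$XtX, ss$Xs, ss$Xs, w, ss)
  XtWy <- lmm_qform(Xty, ss$Xs, ys, w, ss)
  yWy <- as.vector(lmm_qform(yy, ys, ys, w, ss))
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  beta <- backsolve(ch, backsolve(ch, XtWy, transpose = TRUE))
  q <- yWy - sum(XtWy * beta)
  np <- ss$n - ss$p
  if (q <= 0) return(Inf)
  np * (1 + log(2 * pi * q / np)) + w$logdet + 2 * sum(log(diag(ch)))
}

#' Fit a random-intercept linear mixed model in closed form
#'
#' REML fit of `y = X beta + (1|participant)` or
#' `y = X beta + (1|participant/electrode)` by analytic profiling of the
#' variance ratios (see source for the Woodbury identities). Fixed-effect
#' p-values use the normal-approximation Wald test (no Satterthwaite
#' degrees of freedom; documented choice).
#'
#' @param y response vector.
#' @param X fixed-effects model matrix (full column rank).
#' @param participant grouping factor.
#' @param electrode optional second factor, nested within participant.
#' @return list with `beta`, `se`, `z`, `p` (named by columns of `X`),
#'   variance components `sigma2`, `var_participant`, `var_electrode`,
#'   and `remlcrit` (comparable to `lme4::REMLcrit`).
#' @export
lmm_closed <- function(y, X, participant, electrode = NULL) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient fixed-effects design: ",
         "drop aliased columns before fitting")
  if (length(unique(participant)) < 2)
    stop("need at least 2 participants")
  ss <- lmm_suffstats(X, participant, electrode)
  ys <- rowsum(matrix(y, ncol = 1), ss$cell)
  Xty <- crossprod(X, y)
  yy <- sum(y^2)
  if (ss$nested) {
    opt <- optim(c(0, 0), function(lth)
      lmm_remlcrit(exp(lth[1]), exp(lth[2]), ss, ys, Xty, yy),
      method = "Nelder-Mead",
      control = list(reltol = 1e-10, maxit = 500))
    l1 <- exp(opt$par[1]); l2 <- exp(opt$par[2]); crit <- opt$value
  } else {
    opt <- optimize(function(lth)
      lmm_remlcrit(exp(lth), 0, ss, ys, Xty, yy),
      interval = c(-16, 12), tol = 1e-9)
    l1 <- exp(opt$minimum); l2 <- 0; crit <- opt$objective
  }
  lmm_finalize(l1, l2, ss, ys, Xty, yy, crit)
}

lmm_finalize <- function(l1, l2, ss, ys, Xty, yy, crit) {
  w <- lmm_weights(l1, l2, ss)
  XtWX <- lmm_qform(ss$XtX, ss$Xs, ss$Xs, w, ss)
  XtWy <- lmm_qform(Xty, ss$Xs, ys, w, ss)
  yWy <- as.vector(lmm_qform(yy, ys, ys, w, ss))
  Vinv <- solve(XtWX)
  beta <- as.vector(Vinv %*% XtWy)
  q <- yWy - sum(XtWy * beta)
  sigma2 <- q / (ss$n - ss$p)
  se <- sqrt(pmax(diag(Vinv), 0) * sigma2)
  z <- beta / se
  nm <- colnames(ss$X)
  list(beta = setNames(beta, nm), se = setNames(se, nm),
       z = setNames(z, nm), p = setNames(2 * pnorm(-abs(z)), nm),
       sigma2 = sigma2, var_participant = l1 * sigma2,
       var_electrode = if (ss$nested) l2 * sigma2 else 0,
       lambda = c(l1, l2), remlcrit = crit)
}

# Vectorized scan over many response columns sharing one design.
# Y: n x m response matrix; returns per-column estimate/se/z/p for the
# requested coefficient, plus the profiled lambda per column.
# Single grouping level only (step-1 scans use (1|participant)).
lmm_scan_columns <- function(Y, X, participant, coef_name,
                             grid = seq(-14, 10, by = 0.25)) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  ci <- match(coef_name, colnames(X))
  if (is.na(ci)) stop("unknown coefficient: ", coef_name)
  part <- droplevels(as.factor(participant))
  Xs <- rowsum(X, part)
  npart <- as.vector(rowsum(rep(1, n), part))
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  Ys <- rowsum(Y, part)
  yy <- colSums(Y^2)
  np <- n - p
  crit <- matrix(NA_real_, length(grid), m)
  for (gi in seq_along(grid)) {
    lam <- exp(grid[gi])
    wv <- lam / (1 + lam * npart)
    XtWX <- XtX - crossprod(Xs * wv, Xs)
    XtWY <- XtY - crossprod(Xs * wv, Ys)
    yWy <- yy - colSums(Ys^2 * wv)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) { crit[gi, ] <- Inf; next }
    beta <- backsolve(ch, backsolve(ch, XtWY, transpose = TRUE))
    q <- yWy - colSums(XtWY * beta)
    logdet <- sum(log1p(lam * npart)) + 2 * sum(log(diag(ch)))
    cr <- np * (1 + log(2 * pi * q / np)) + logdet
    cr[!is.finite(cr) | q <= yy * 1e-10] <- Inf
    crit[gi, ] <- cr
  }
  crit[is.na(crit)] <- Inf
  best <- apply(crit, 2, which.min)
  # parabolic refinement of the profiled log-lambda
  lhat <- vapply(seq_len(m), function(j) {
    b <- best[j]
    if (b == 1 || b == length(grid)) return(grid[b])
    y3 <- crit[(b - 1):(b + 1), j]
    denom <- y3[1] - 2 * y3[2] + y3[3]
    if (denom <= 0) return(grid[b])
    grid[b] + 0.5 * (y3[1] - y3[3]) / denom * (grid[2] - grid[1])
  }, 0)
  est <- se <- numeric(m)
  for (j in seq_len(m)) {
    lam <- exp(lhat[j])
    Vi <- NULL
    while (is.null(Vi)) {
      wv <- lam / (1 + lam * npart)
      XtWX <- XtX - crossprod(Xs * wv, Xs)
      Vi <- tryCatch(solve(XtWX), error = function(e) NULL)
      if (is.null(Vi)) lam <- lam / 10   # back off from a singular boundary
    }
    XtWy <- XtY[, j] - as.vector(crossprod(Xs * wv, Ys[, j]))
    beta <- as.vector(Vi %*% XtWy)
    q <- yy[j] - colSums(Ys[, j, drop = FALSE]^2 * wv) -
      sum(XtWy * beta)
    sigma2 <- max(q, 1e-300) / np
    est[j] <- beta[ci]
    se[j] <- sqrt(max(Vi[ci, ci], 0) * sigma2)
  }
  z <- est / se
  list(estimate = est, se = se, z = z, p = 2 * pnorm(-abs(z)),
       lambda = exp(lhat))
}
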