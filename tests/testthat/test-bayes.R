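test_that("evidence ratio equals brute-force sign counting", {
  expect_equal(evidence_ratio(c(1, 1, 1, -1), "positive"), 3)
  expect_equal(evidence_ratio(c(1, 1, 1, -1), "negative"), 1 / 3)
  set.seed(501)
  for (i in 1:20) {
    d <- rnorm(sample(50:500, 1), mean = runif(1, -1, 1))
    expect_identical(as.numeric(evidence_ratio(d, "positive")),
                     if (all(d > 0)) length(d)
                     else sum(d > 0) / sum(d <= 0))
  }
  # symmetric draws give ER ~ 1
  set.seed(502)
  expect_equal(evidence_ratio(rnorm(40000), "positive"), 1,
               tolerance = 0.05)
  # all draws on the hypothesized side -> capped at the draw count
  er <- evidence_ratio(abs(rnorm(4000)) + 0.01, "positive")
  expect_equal(as.numeric(er), 4000)
  expect_true(isTRUE(attr(er, "capped")))
})

test_that("Savage-Dickey BF01 matches the conjugate normal oracle", {
  set.seed(503)
  # y ~ N(theta, 1), theta ~ N(0,1): posterior N(sum(y)/(n+1), 1/(n+1))
  for (truth in c(0, 0.4)) {
    n <- 60
    y <- rnorm(n, truth)
    pv <- 1 / (n + 1); pm <- sum(y) * pv
    draws <- rnorm(50000, pm, sqrt(pv))
    bf <- as.numeric(savage_dickey_bf01(draws, 0, 1))
    exact <- dnorm(0, pm, sqrt(pv)) / dnorm(0, 0, 1)
    expect_equal(bf, exact, tolerance = 0.05)
  }
  # posterior = prior (no data) -> BF01 ~ 1
  set.seed(504)
  expect_equal(as.numeric(savage_dickey_bf01(rnorm(50000, 0, 1), 0, 1)), 1,
               tolerance = 0.05)
  # sharp posterior at 0 vs diffuse prior -> large BF01
  expect_gt(as.numeric(savage_dickey_bf01(rnorm(5000, 0, 0.01), 0, 1)), 20)
})

test_that("JZS Bayes factor matches the Monte-Carlo integration oracle", {
  set.seed(505)
  cases <- data.frame(t = c(0, 2.5, -1.3, 4.2, 0.8, 3.1, -2.2, 1.7, 5,
                            -0.4),
                      n1 = c(19, 19, 12, 25, 8, 40, 15, 10, 30, 22),
                      n2 = c(14, 14, 18, 25, 9, 35, 15, 12, 28, 20))
  for (i in seq_len(nrow(cases))) {
    a <- jzs_two_sample_bf(cases$t[i], cases$n1[i], cases$n2[i])
    b <- oracle_jzs(cases$t[i], cases$n1[i], cases$n2[i])
    expect_lt(abs(a - b) / b, 0.01)
  }
  # null-favouring at t = 0; monotone in |t|
  expect_lt(jzs_two_sample_bf(0, 19, 14), 1)
  bfs <- vapply(c(0, 1, 2, 3, 4), jzs_two_sample_bf, 0, n1 = 20, n2 = 20)
  expect_true(all(diff(bfs) > 0))
})

test_that("Gibbs sampler recovers known coefficients with shrinkage priors", {
  set.seed(506)
  n <- 600; P <- 12
  part <- factor(rep(seq_len(P), length.out = n))
  x <- rnorm(n)
  b <- rnorm(P, 0, 0.8)
  y <- 1.5 + 0.6 * x + b[as.integer(part)] + rnorm(n, 0, 0.7)
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- gibbs_lmm(y, X, list(p = list(factor = part, x = NULL)),
                   prior_mean = 0, prior_sd = 10,
                   iter = 1200, warmup = 400, chains = 2, seed = 77)
  expect_true(fit$converged)
  sm <- fit$summary
  expect_lt(abs(sm$mean[sm$term == "x"] - 0.6), 2 * sm$sd[sm$term == "x"])
  expect_lt(abs(sm$mean[sm$term == "(Intercept)"] - 1.5),
            3 * sm$sd[sm$term == "(Intercept)"])
  # residual and random sds in the right region
  expect_equal(fit$sigma, 0.7, tolerance = 0.15)
  # reproducibility at fixed seed
  fit2 <- gibbs_lmm(y, X, list(p = list(factor = part, x = NULL)),
                    prior_mean = 0, prior_sd = 10,
                    iter = 1200, warmup = 400, chains = 2, seed = 77)
  expect_identical(fit$draws, fit2$draws)
})

test_that("cluster model separates signal from null terms", {
  ep <- tiny_study()
  sc <- scan_responsive_electrodes(ep, "correctness")
  cl <- cluster_regression(ep, sc$electrodes, "correctness")
  amp <- cluster_amplitudes(ep, cl$clusters[[1]])
  fit <- fit_cluster_model(amp, 4, iter = 800, warmup = 400, chains = 2,
                           seed = 41)
  sm <- fit$summary
  # injected negative correctness contrast: directional evidence
  expect_gt(sm$evidence_ratio[sm$term == "correctness"], 3)
  expect_lt(sm$mean[sm$term == "correctness"], 0)
  # no group effect / interaction injected: null-supporting BF01
  expect_gt(sm$bf01[sm$term == "correctness:group"], 1)
  expect_equal(sort(unique(amp$electrode)), sort(cl$clusters[[1]]$electrodes))
})

test_that("prior-predictive simulation is recovered by the cluster model", {
  set.seed(507)
  # simulate from model 4's likelihood with known coefficients
  P <- 8; E <- 2; m <- 40
  md <- expand.grid(participant = sprintf("p%d", seq_len(P)),
                    electrode = c("Cz", "C1"), trial = seq_len(m))
  md$correctness <- rbinom(nrow(md), 1, 0.7)
  md$group <- as.numeric(md$participant %in% sprintf("p%d", 1:4))
  bp <- rnorm(P, 0, 0.5); names(bp) <- sprintf("p%d", seq_len(P))
  beta <- c(0.2, -0.8, 0.1, 0.05)  # icpt, correctness, group, interaction
  md$amplitude <- beta[1] + beta[2] * md$correctness + beta[3] * md$group +
    beta[4] * md$correctness * md$group + bp[md$participant] +
    rnorm(nrow(md), 0, 1)
  md$z_confidence <- 0; md$z_movementRT <- 0
  fit <- fit_cluster_model(md, 4, iter = 800, warmup = 400, chains = 2,
                           seed = 43)
  sm <- fit$summary
  expect_lt(abs(sm$mean[sm$term == "correctness"] - beta[2]),
            2 * sm$sd[sm$term == "correctness"] + 0.05)
})

test_that("zero-signal data produce null-supporting summaries", {
  set.seed(508)
  P <- 10
  md <- expand.grid(participant = sprintf("p%d", seq_len(P)),
                    electrode = "Cz", trial = 1:60)
  md$correctness <- rbinom(nrow(md), 1, 0.7)
  md$group <- as.numeric(md$participant %in% sprintf("p%d", 1:5))
  md$amplitude <- rnorm(nrow(md))
  fit <- fit_cluster_model(md, 4, iter = 800, warmup = 400, chains = 2,
                           seed = 45)
  sm <- fit$summary
  expect_gt(sm$bf01[sm$term == "group"], 1)
  expect_gt(sm$bf01[sm$term == "correctness:group"], 1)
  expect_lt(abs(sm$mean[sm$term == "group"]), 0.3)
})
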