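test_that("benjamini_hochberg implements the step-up procedure", {
  # all p = 1 -> nothing
  expect_false(any(benjamini_hochberg(rep(1, 10))$reject))
  # hand-computed step-up: thresholds 0.0125/0.025/0.0375/0.05
  bh <- benjamini_hochberg(c(0.001, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(bh$reject))
  # single p = 0.04 at alpha = .05
  expect_true(benjamini_hochberg(0.04)$reject)
  # q >= p elementwise; monotone in alpha
  set.seed(401)
  p <- runif(200)^2
  bh2 <- benjamini_hochberg(p, 0.05)
  expect_true(all(bh2$q >= p - 1e-12))
  bh3 <- benjamini_hochberg(p, 0.2)
  expect_true(all(bh3$reject | !bh2$reject))  # larger alpha never shrinks
  # agrees with stats::p.adjust
  expect_equal(bh2$q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("closed-form REML engine matches lme4 (the independent oracle)", {
  set.seed(402)
  n <- 60; P <- 10
  part <- factor(rep(seq_len(P), each = n / P))
  d <- data.frame(x = rnorm(n), g = rep(0:1, each = n / 2),
                  participant = part,
                  electrode = factor(rep(c("e1", "e2"), n / 2)))
  b <- rnorm(P, 0, 0.7)
  d$y <- 1 + 0.5 * d$x - 0.3 * d$g + b[as.integer(part)] + rnorm(n)
  fc <- fit_lmm(y ~ x + g, d, engine = "closed")
  fl <- fit_lmm(y ~ x + g, d, engine = "lme4")
  expect_equal(fc$coefficients$estimate, fl$coefficients$estimate,
               tolerance = 1e-5)
  expect_equal(fc$coefficients$se, fl$coefficients$se, tolerance = 1e-4)
  expect_equal(fc$remlcrit, fl$remlcrit, tolerance = 1e-5)
  # nested random structure
  pe <- as.integer(interaction(d$participant, d$electrode, drop = TRUE))
  be <- rnorm(max(pe), 0, 0.5)
  d$y2 <- d$y + be[pe]
  fc2 <- fit_lmm(y2 ~ x + g, d, nested = TRUE, engine = "closed")
  fl2 <- fit_lmm(y2 ~ x + g, d, nested = TRUE, engine = "lme4")
  expect_equal(fc2$remlcrit, fl2$remlcrit, tolerance = 1e-4)
  expect_equal(fc2$coefficients$estimate, fl2$coefficients$estimate,
               tolerance = 1e-3)
})

test_that("zero grouping variance reduces the LMM to OLS", {
  set.seed(403)
  n <- 200
  part <- factor(rep(1:10, each = 20))
  x <- rnorm(n)
  y <- 2 + 0.4 * x + rnorm(n)          # no participant effect at all
  f <- lmm_closed(y, cbind("(Intercept)" = 1, x = x), part)
  ols <- coef(lm(y ~ x))
  expect_equal(unname(f$beta), unname(ols), tolerance = 1e-5)
  expect_error(lmm_closed(y, cbind(1, x, x), part), "rank-deficient")
  expect_error(lmm_closed(y[1:20], cbind(1, x[1:20]), part[1:20]),
               "2 participants")
})

test_that("balanced random-intercept variance components match ANOVA", {
  set.seed(404)
  P <- 12; m <- 20
  part <- factor(rep(seq_len(P), each = m))
  b <- rnorm(P, 0, 1.5)
  y <- 3 + b[as.integer(part)] + rnorm(P * m, 0, 0.8)
  f <- lmm_closed(y, matrix(1, P * m, 1,
                            dimnames = list(NULL, "(Intercept)")), part)
  # closed-form one-way ANOVA REML estimators for balanced data
  gm <- tapply(y, part, mean)
  msb <- m * var(gm)
  msw <- sum((y - gm[part])^2) / (P * m - P)
  expect_equal(f$sigma2, msw, tolerance = 1e-4)
  expect_equal(f$var_participant, (msb - msw) / m, tolerance = 1e-4)
})

test_that("scan selects injected electrodes and respects the ROI", {
  ep <- tiny_study()
  sc <- scan_responsive_electrodes(ep, "correctness")
  expect_true("Cz" %in% sc$electrodes)
  expect_true(all(sc$electrodes %in% roi_frontocentral()))
  expect_true(all(sc$grid$q >= sc$grid$p - 1e-12))
  expect_equal(sc$family_size, nrow(sc$grid))
  expect_error(scan_responsive_electrodes(ep, "correctness", roi = character(0)),
               "ROI")
  # scan window is the closed interval 0..500 ms
  expect_true(all(sc$grid$time >= 0 & sc$grid$time <= 0.5))
})

test_that("cluster contiguity rule is strict at 50 ms", {
  mk_samples <- function(sig) {
    k <- length(sig)
    data.frame(time = seq(0, by = 1 / 128, length.out = k),
               estimate = 1, se = 1, z = 2, p = 0.01, q = 0.04,
               significant = sig)
  }
  # 7 significant samples = 54.7 ms > 50 ms -> one cluster
  cl7 <- confclust:::find_clusters(mk_samples(c(FALSE, rep(TRUE, 7), FALSE)),
                                   128, "Cz", "correctness", 0.05)
  expect_length(cl7, 1)
  expect_equal(cl7[[1]]$n_samples, 7)
  # 6 samples = 46.9 ms -> none
  cl6 <- confclust:::find_clusters(mk_samples(c(FALSE, rep(TRUE, 6), FALSE)),
                                   128, "Cz", "correctness", 0.05)
  expect_length(cl6, 0)
  # nothing significant -> empty list
  expect_length(confclust:::find_clusters(mk_samples(rep(FALSE, 10)),
                                          128, "Cz", "x", 0.05), 0)
})

test_that("cluster regression finds the injected correctness cluster", {
  ep <- tiny_study()
  sc <- scan_responsive_electrodes(ep, "correctness")
  cl <- cluster_regression(ep, sc$electrodes, "correctness")
  expect_gte(length(cl$clusters), 1)
  cst <- cl$clusters[[1]]
  expect_gt(cst$peak_time, 0.15)
  expect_lt(cst$peak_time, 0.40)       # injected peak at 266 ms
  expect_gt(cst$n_samples / 128, 0.05)
  expect_true(all(cl$samples$q >= cl$samples$p - 1e-12))
})

test_that("effect amplitude matches hand-computed toy contrasts", {
  # three trials, one electrode, constant signals 5 / 3 / 2
  dat <- array(0, c(3, 1, 385))
  dat[1, 1, ] <- 5; dat[2, 1, ] <- 3; dat[3, 1, ] <- 2
  ep <- epoch_array(dat, "Cz", seq(-1, 2, by = 1 / 128), 128,
                    data.frame(participant = rep("p1", 3),
                               group = "a",
                               correct = c(TRUE, FALSE, FALSE),
                               confidence = c(90, 50, 10),
                               onset = c(1, 1.5, 2)))
  cst <- structure(list(electrodes = "Cz", window = c(0, 0.4),
                        peak_time = 0.25, peak_z = 3, n_samples = 10,
                        term = "correctness"), class = "cluster_result")
  expect_equal(as.numeric(effect_amplitude(ep, cst, "correctness")), 2.5)
  expect_equal(as.numeric(effect_amplitude(ep, cst, "confidence")), 3)
  # identical conditions -> 0
  dat0 <- dat; dat0[2, 1, ] <- 5; dat0[3, 1, ] <- 5
  ep0 <- ep; ep0$data <- dat0
  expect_equal(as.numeric(effect_amplitude(ep0, cst, "correctness")), 0)
  # peak near the epoch edge shrinks the window symmetrically
  cst_edge <- cst; cst_edge$peak_time <- 1.995
  ea <- effect_amplitude(ep, cst_edge, "correctness")
  expect_lt(attr(ea, "halfwidth"), 0.025 + 1e-9)
})

test_that("effect amplitude recovers the injected contrast", {
  ep <- tiny_study()
  sc <- scan_responsive_electrodes(ep, "correctness")
  cl <- cluster_regression(ep, sc$electrodes, "correctness")
  ea <- as.numeric(effect_amplitude(ep, cl$clusters[[1]], "correctness"))
  expect_lt(abs(ea - (-0.6)), 0.3)     # injected -0.6 uV at Cz
  expect_lt(ea, 0)
})

test_that("tertile assignment follows the ceil-boundary convention", {
  expect_equal(as.vector(table(assign_tertiles(rnorm(9)))), c(3, 3, 3))
  expect_true(all(assign_tertiles(rep(2, 8)) == "low"))
  t10 <- assign_tertiles(1:10)
  expect_equal(as.character(t10),
               c(rep("low", 3), rep("mid", 3), rep("high", 4)))
})
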