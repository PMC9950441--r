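test_that("d-prime matches the inverse-normal closed form", {
  # hit = fa = 0.5 -> 0
  cnt <- array(0L, c(2, 2, 2))
  cnt[1, , 1] <- c(50, 50); cnt[2, , 1] <- c(50, 50)
  expect_equal(compute_dprime(cnt)$dprime, 0)
  # hit .8 / fa .2 -> 2 * qnorm(.8)
  cnt2 <- array(0L, c(2, 2, 2))
  cnt2[2, , 1] <- c(20, 80); cnt2[1, , 1] <- c(80, 20)
  expect_equal(compute_dprime(cnt2)$dprime, 2 * qnorm(0.8),
               tolerance = 1e-10)
  expect_equal(compute_dprime(cnt2)$criterion, 0, tolerance = 1e-10)
  # extreme rates stay finite under the 1/(2N) correction
  cnt3 <- array(0L, c(2, 2, 2))
  cnt3[2, 2, 1] <- 100; cnt3[1, 1, 1] <- 100
  expect_true(is.finite(compute_dprime(cnt3)$dprime))
})

test_that("sdt_counts bins retained confidence per participant", {
  tr <- data.frame(participant = rep(c("a", "b"), each = 100),
                   stim_side = rep(c(-1, 1), 100),
                   response_side = rep(c(-1, 1), 100),
                   confidence = c(seq(50, 100, length.out = 100),
                                  seq(30, 100, length.out = 100)))
  cc <- sdt_counts(tr, bins = 4)
  expect_named(cc, c("a", "b"))
  expect_equal(sum(cc$a), 100)
  expect_equal(sum(cc$b), sum(tr$confidence[101:200] >= 50))
  expect_equal(dim(cc$a), c(2, 2, 4))
})

test_that("meta-d' MLE recovers generative truth from the exact model", {
  set.seed(601)
  f1 <- fit_meta_d_mle(simulate_sdt_counts(10000, 1.5, 1.5))
  expect_equal(f1$mratio, 1, tolerance = 0.1)   # ideal observer
  f2 <- fit_meta_d_mle(simulate_sdt_counts(10000, 1.5, 0.75))
  expect_equal(f2$mratio, 0.5, tolerance = 0.12)
  # confidence independent of accuracy -> meta-d' ~ 0
  f0 <- fit_meta_d_mle(simulate_sdt_counts(8000, 1.5, 0))
  expect_lt(abs(f0$meta_d), 0.15)
  # degenerate counts are rejected with a diagnostic
  cnt <- array(0L, c(2, 2, 4)); cnt[, , 1] <- 50L
  expect_error(fit_meta_d_mle(cnt), "confidence bins")
})

test_that("meta-d' MLE equals the independent grid-search maximizer", {
  set.seed(602)
  for (i in 1:25) {
    cnt <- simulate_sdt_counts(sample(200:600, 1),
                               d = runif(1, 0.8, 2.2),
                               meta_d = runif(1, 0.2, 2.0),
                               criterion = runif(1, -0.3, 0.3))
    fit <- fit_meta_d_mle(cnt)
    grid <- oracle_meta_d_grid(cnt)
    expect_lt(abs(fit$meta_d - grid), 0.011)
  }
})

test_that("hierarchical model recovers the group M-ratio regime", {
  set.seed(603)
  counts <- lapply(1:16, function(i) simulate_sdt_counts(600, 1.2, 0.72))
  names(counts) <- sprintf("p%02d", 1:16)
  h <- fit_hierarchical_mratio(counts, rep(c("a", "b"), each = 8),
                               iter = 1500, warmup = 700, seed = 9)
  expect_true(all(h$group$mratio_mean > 0.45 & h$group$mratio_mean < 0.75))
  expect_gt(h$bf01, 1)                  # equal groups: null supported
  expect_true(all(h$group$hdi_lo < h$group$mratio_mean))
  expect_true(all(h$group$hdi_hi > h$group$mratio_mean))
})

test_that("hierarchical estimates shrink toward the group mean", {
  set.seed(604)
  counts <- lapply(1:12, function(i) simulate_sdt_counts(150, 1.2, 0.72))
  names(counts) <- sprintf("p%02d", 1:12)
  h <- fit_hierarchical_mratio(counts, rep("a", 12),
                               iter = 1200, warmup = 600, seed = 11)
  pp <- h$participants
  gm <- exp(mean(log(pmax(pp$mratio_mle, 0.05))))
  toward <- abs(pp$mratio_post - gm) <= abs(pp$mratio_mle - gm) + 0.06
  expect_gte(mean(toward), 0.9)         # shrinkage for (almost) everyone
  # single-participant group warns about a prior-dominated posterior
  h2 <- fit_hierarchical_mratio(counts[1:3], c("a", "a", "b"),
                                iter = 400, warmup = 200, seed = 12)
  expect_true(any(grepl("single participant", h2$warnings)))
})

test_that("separated groups yield a difference Bayes factor > 3", {
  set.seed(605)
  counts <- c(lapply(1:10, function(i) simulate_sdt_counts(250, 1.2, 0.48)),
              lapply(1:10, function(i) simulate_sdt_counts(250, 1.2, 1.2)))
  names(counts) <- sprintf("p%02d", 1:20)
  h <- fit_hierarchical_mratio(counts, rep(c("lo", "hi"), each = 10),
                               iter = 1500, warmup = 700, seed = 13)
  expect_gt(h$bf10, 3)
  expect_lt(h$group$mratio_mean[h$group$group == "lo"],
            h$group$mratio_mean[h$group$group == "hi"])
})

test_that("confidence~onset model recovers couplings and their interaction", {
  tr <- simulate_behavior(cohort_spec(19, 14, 300, seed = 606))
  fit <- confidence_rt_model(tr, seed = 607)
  sm <- fit$summary
  main <- sm[sm$term == "z_movementRT", ]
  inter <- sm[sm$term == "z_movementRT:group", ]
  expect_lt(main$mean, 0)                       # negative coupling
  expect_gt(main$evidence_ratio, 100)
  expect_gt(inter$mean, 0)                      # weaker coupling in group b
  expect_gt(inter$evidence_ratio, 3)
  # zero coupling in both groups -> all onset ERs near 1
  obs0 <- observer_spec(confidence_rt_coupling = 0)
  tr0 <- simulate_behavior(cohort_spec(6, 6, 150, seed = 608), obs0, obs0)
  fit0 <- confidence_rt_model(tr0, iter = 1000, warmup = 500, chains = 2,
                              seed = 609)
  er0 <- fit0$summary$evidence_ratio[fit0$summary$term == "z_movementRT"]
  expect_lt(er0, 19)                            # no decisive false signal
})

test_that("BCIS composite is exact arithmetic", {
  expect_equal(bcis_composite(16.0, 10.3), 5.7, tolerance = 1e-12)
  expect_equal(bcis_composite(8.6, 9.5), -0.9, tolerance = 1e-12)
  expect_identical(bcis_composite(12, 12), 0)
})

test_that("group comparison couples Welch t with the JZS Bayes factor", {
  set.seed(610)
  x <- rnorm(20)
  same <- group_compare(x, x)
  expect_equal(same$t, 0)
  expect_lt(same$bf10, 1)
  big <- group_compare(rnorm(40), rnorm(40) + 2)
  expect_gt(big$bf10, 3)
  expect_equal(big$evidence, "moderate+ H1")
  # BF matches the MC oracle through the shared t statistic
  gc <- group_compare(rnorm(19), rnorm(14) + 0.8)
  expect_equal(gc$bf10, oracle_jzs(gc$t, 19, 14), tolerance = 0.01)
})
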