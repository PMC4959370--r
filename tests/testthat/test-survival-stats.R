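# Frozen fixture values below were computed with the risk-table,
# product-limit and partial-likelihood oracles in helper-oracles.R and
# cross-checked against an independent survival-analysis implementation.

test_that("log-rank test matches the frozen risk-table fixture", {
  ta <- c(3, 6, 8, 12, 15); ea <- c(1, 0, 1, 1, 0)
  tb <- c(2, 4, 5, 9, 11);  eb <- c(1, 1, 0, 1, 1)
  lr <- logrank_test(ta, ea, tb, eb)
  expect_equal(lr$statistic, 1.1981555123, tolerance = 1e-9)
  expect_equal(lr$p_value, 0.2736906438, tolerance = 1e-9)
  o <- oracle_logrank(c(ta, tb), c(ea, eb), rep(c(TRUE, FALSE), each = 5))
  expect_equal(lr$observed[["A"]] - lr$expected[["A"]], o$o_minus_e,
               tolerance = 1e-9)
})

test_that("log-rank symmetry, degeneracy, and time-transform invariance", {
  t1 <- c(1, 3, 5, 7); e1 <- c(1, 0, 1, 1)
  # identical multisets -> no difference
  same <- logrank_test(t1, e1, t1, e1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # swapping labels leaves statistic and p unchanged
  t2 <- c(2, 4, 6, 8); e2 <- c(1, 1, 0, 1)
  ab <- logrank_test(t1, e1, t2, e2)
  ba <- logrank_test(t2, e2, t1, e1)
  expect_equal(ab$statistic, ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
  # zero total events -> degenerate, not an error
  deg <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_true(deg$degenerate)
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)
  # empty group -> error
  expect_error(logrank_test(numeric(0), numeric(0), t1, e1), "empty")
  # rank statistic: invariant under strictly increasing time transforms
  tf <- function(x) exp(x / 3) + x^2
  ab_tf <- logrank_test(tf(t1), e1, tf(t2), e2)
  expect_equal(ab_tf$statistic, ab$statistic, tolerance = 1e-12)
})

test_that("log-rank agrees with the risk-table oracle on random fixtures", {
  for (seed in 1:8) {
    fx <- random_surv_fixture(n = 10 + 2 * seed, seed = 100 + seed)
    lr <- logrank_test(fx$time[fx$group], fx$event[fx$group],
                       fx$time[!fx$group], fx$event[!fx$group])
    o <- oracle_logrank(fx$time, fx$event, fx$group)
    expect_equal(lr$statistic, o$statistic, tolerance = 1e-9)
    expect_equal(lr$p_value, o$p_value, tolerance = 1e-9)
  }
})

test_that("hazard ratio matches the partial-likelihood grid oracle", {
  ca <- c(2, 3, 5, 7, 9, 11);   cea <- c(1, 1, 0, 1, 1, 0)
  cb <- c(4, 6, 8, 10, 12, 14); ceb <- c(1, 0, 1, 1, 1, 1)
  expect_equal(hazard_ratio(ca, cea, cb, ceb), 2.07986290,
               tolerance = 1e-6)
  # reciprocity under group swap
  expect_equal(hazard_ratio(cb, ceb, ca, cea),
               1 / hazard_ratio(ca, cea, cb, ceb), tolerance = 1e-8)
  # identical groups -> HR 1
  expect_equal(hazard_ratio(ca, cea, ca, cea), 1, tolerance = 1e-8)
  # zero events in one group -> undefined, reported missing
  expect_true(is.na(hazard_ratio(ca, rep(0, 6), cb, ceb)))
  # Pike O/E estimator is a sane alternative on the same fixture
  pike <- hazard_ratio(ca, cea, cb, ceb, estimator = "pike")
  expect_gt(pike, 1)
})

test_that("Cox HR recovers a true twofold hazard on simulated data", {
  set.seed(42)
  reps <- 25
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 200
    t_a <- rexp(n, 0.2)          # true HR = 2 for group A
    t_b <- rexp(n, 0.1)
    cens <- rexp(2 * n, 0.05)
    time <- pmin(c(t_a, t_b), cens)
    event <- as.numeric(c(t_a, t_b) <= cens)
    est[r] <- hazard_ratio(time[1:n], event[1:n],
                           time[(n + 1):(2 * n)], event[(n + 1):(2 * n)])
  }
  expect_lt(abs(mean(est) - 2) / 2, 0.15)
})

test_that("Kaplan-Meier estimator matches hand-computed product limits", {
  km <- km_curve(c(1, 2, 2, 3, 4, 5), c(1, 0, 1, 1, 0, 1))
  expect_equal(km$time, 1:5)
  expect_equal(km$surv, c(5 / 6, 2 / 3, 4 / 9, 4 / 9, 0), tolerance = 1e-12)
  expect_true(all(diff(km$surv) <= 0))
  # all censored -> flat at 1
  flat <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(flat$surv == 1))
  # no censoring -> empirical survivor function
  tt <- c(2, 5, 5, 9, 12)
  emp <- km_curve(tt, rep(1, 5))
  for (i in seq_along(emp$time))
    expect_equal(emp$surv[i], mean(tt > emp$time[i]))
  # single subject with an event -> drops to zero
  one <- km_curve(3, 1)
  expect_equal(one$surv, 0)
})

test_that("KM curves agree with the product-limit oracle on random fixtures", {
  for (seed in 1:6) {
    fx <- random_surv_fixture(n = 15 + seed, seed = 300 + seed)
    km <- km_curve(fx$time, fx$event)
    o <- oracle_km(fx$time, fx$event)
    expect_equal(km$time, o$time)
    expect_equal(km$surv, o$surv, tolerance = 1e-9)
  }
})

test_that("p-value adjustment follows the BH step-up formula", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_pvalues(p), oracle_bh(p))
  expect_equal(adjust_pvalues(p), rep(0.04, 4))  # p*m/rank all equal 0.04
  # all equal stay equal; a single p is unchanged under BH
  expect_equal(adjust_pvalues(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(adjust_pvalues(0.037), 0.037)
  # random vectors match the direct formula; NA entries pass through
  set.seed(9)
  pr <- runif(50)
  expect_equal(adjust_pvalues(pr), oracle_bh(pr))
  expect_true(is.na(adjust_pvalues(c(0.1, NA))[2]))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
  expect_equal(adjust_pvalues(p, method = "bonferroni"), pmin(1, p * 4))
})

test_that("log-rank type-I error is calibrated under the null", {
  set.seed(1234)
  sims <- 2000
  rej <- 0
  for (s in seq_len(sims)) {
    time <- rexp(40, 0.2)
    event <- rbinom(40, 1, 0.8)
    lr <- logrank_test(time[1:20], event[1:20], time[21:40], event[21:40])
    if (lr$p_value < 0.05) rej <- rej + 1
  }
  rate <- rej / sims
  mc_se <- sqrt(0.05 * 0.95 / sims)
  expect_lt(abs(rate - 0.05), 2 * mc_se + 1e-12)
})
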