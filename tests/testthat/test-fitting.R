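test_that("negative log-likelihood is additive and floored", {
  truth <- ref_pos()
  tr <- sim_session(truth, per_distance = 10, seed = 3)
  nll1 <- negloglik(truth, tr)
  nll2 <- negloglik(truth, rbind(tr, tr))
  expect_equal(nll2, 2 * nll1)
  # a trial with rt below the non-decision time hits the density floor
  floor_trial <- tr[1, ]
  floor_trial$rt <- truth$ndt - 0.05
  expect_equal(negloglik(truth, rbind(tr, floor_trial)),
               nll1 - log(1e-10))
  expect_error(negloglik(truth, tr[0, ]), "no usable trials")
})

test_that("the likelihood prefers the generating drift over perturbed ones", {
  truth <- ref_pos()
  worse_hi <- ddm_params(dr = truth$dr * 1.5, sym = truth$sym, bo = truth$bo,
                         ic = truth$ic, ndt = truth$ndt)
  worse_lo <- ddm_params(dr = truth$dr * 0.5, sym = truth$sym, bo = truth$bo,
                         ic = truth$ic, ndt = truth$ndt)
  wins <- 0
  for (s in 1:3) {
    tr <- sim_session(truth, per_distance = 30, seed = 30 + s)
    nt <- negloglik(truth, tr)
    if (nt < negloglik(worse_hi, tr) && nt < negloglik(worse_lo, tr))
      wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("fits demand enough data and reproduce bit-for-bit", {
  truth <- ref_pos()
  expect_error(ddm_fit(data.frame(rt = numeric(), correct = logical(),
                                  log_distance = numeric())),
               "insufficient data")
  tr <- sim_session(truth, per_distance = 3, seed = 2)
  expect_error(ddm_fit(tr, control = fit_control(min_trials = 100)),
               "insufficient data")

  tr <- sim_session(truth, per_distance = 20, seed = 5)
  f1 <- ddm_fit(tr, seed = 11, control = fast_control())
  f2 <- ddm_fit(tr, seed = 11, control = fast_control())
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$nll, f2$nll)
  # estimates respect the bounds box
  cf <- coef(f1)
  b <- fit_bounds()
  expect_true(cf["DR"] >= b$dr[1] && cf["DR"] <= b$dr[2])
  expect_true(cf["SYM"] >= 0 && cf["SYM"] <= 1)
  expect_true(cf["IC"] <= 0.95 * cf["BO"])
})

test_that("fit methods expose the usual modelling interface", {
  truth <- ref_pos()
  tr <- sim_session(truth, per_distance = 20, seed = 6)
  fit <- ddm_fit(tr, seed = 3, control = fast_control())
  expect_s3_class(fit, "ddm_fit")
  expect_named(coef(fit), c("DR", "SYM", "BO", "IC", "NDT"))
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 5L)
  expect_equal(as.numeric(ll), -fit$nll)
  pred <- predict(fit, newdata = data.frame(log_distance = c(0.3, 1.2)))
  expect_equal(nrow(pred), 2)
  expect_true(all(pred$accuracy > 0.5 & pred$accuracy <= 1))
  expect_gt(pred$accuracy[2], pred$accuracy[1] - 1e-9)
  res <- residuals(fit)
  expect_true(all(abs(res$residual) < 0.25))
  sim <- simulate(fit, seed = 1)
  expect_equal(nrow(sim), nrow(tr))
  expect_output(print(summary(fit)), "By numerical distance")
})

test_that("Holm-Sidak adjustment follows the step-down formula", {
  adj <- holm_sidak(c(0.01, 0.03, 0.04))
  expect_equal(round(adj, 4), c(0.0297, 0.0591, 0.0591))
  # order-invariance and monotonicity
  p <- c(0.2, 0.001, 0.04, 0.7)
  adj2 <- holm_sidak(p)
  expect_equal(order(adj2), order(p))
  expect_true(all(adj2 >= p))
  expect_true(all(adj2 <= 1))
  # larger family sizes only increase the adjusted values
  expect_true(all(holm_sidak(p, m = 15) >= adj2))
  expect_error(holm_sidak(p, m = 2), "family size")
})

test_that("parameter comparisons detect planted differences and flag degenerate ones", {
  set.seed(42)
  n <- 50
  base <- data.frame(subject = 1:n,
                     dr = rnorm(n, 2.46, 0.5), sym = rnorm(n, 0.09, 0.05),
                     bo = rnorm(n, 0.77, 0.1), ic = rnorm(n, 0.22, 0.05),
                     ndt = rnorm(n, 0.41, 0.04))
  shifted <- base
  shifted$dr <- shifted$dr + rnorm(n, 0.4, 0.1)
  cmp <- compare_params(base, shifted, n_comparisons = 15)
  expect_equal(cmp$parameter, c("dr", "sym", "bo", "ic", "ndt"))
  expect_lt(cmp$p_adjusted[cmp$parameter == "dr"], 0.05)
  expect_gt(cmp$mean_abs_diff[cmp$parameter == "dr"], 0.3)

  same <- compare_params(base, base)
  expect_true(all(same$degenerate))
  expect_true(all(same$mean_abs_diff == 0))
  expect_true(all(is.na(same$p)))

  expect_error(compare_params(base, shifted[-1, ]), "paired")
})

test_that("per-participant fitting flags degenerate cells instead of fitting them", {
  truth <- ref_pos()
  good <- sim_session(truth, per_distance = 8, seed = 13)
  good$subject <- 1
  good$numeral_type <- "positive"
  bad <- good
  bad$subject <- 2
  set.seed(99)
  bad$correct <- runif(nrow(bad)) < 0.5    # guessing-level accuracy
  fits <- fit_participants(rbind(good, bad), seed = 1,
                           control = fast_control())
  expect_equal(nrow(fits), 2)
  expect_false(fits$degenerate[fits$subject == 1])
  expect_true(fits$degenerate[fits$subject == 2])
  expect_true(is.na(fits$dr[fits$subject == 2]))
  expect_false(is.na(fits$dr[fits$subject == 1]))
})
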