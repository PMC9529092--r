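test_that("trial drift follows the distance-compression law", {
  p <- ddm_params(dr = 2.46, sym = 0, bo = 0.77)
  expect_equal(drift_for_distance(p, 0.134), 2.46)
  p2 <- ddm_params(dr = 2.46, sym = 0.09, bo = 0.77)
  expect_equal(drift_for_distance(p2, 1.0), 2.46)
  expect_equal(round(drift_for_distance(p2, 0.134), 3), 2.053)
  expect_error(drift_for_distance(p2, 0), "log_distance")
  expect_error(drift_for_distance(p2, -1), "log_distance")
})

test_that("parameter validation enforces the model's constraints", {
  expect_error(ddm_params(dr = -1, sym = 0, bo = 1), "DR")
  expect_error(ddm_params(dr = 1, sym = 1.2, bo = 1), "SYM")
  expect_error(ddm_params(dr = 1, sym = 0, bo = 1, ic = 1), "IC")
  expect_error(ddm_params(dr = 1, sym = 0, bo = 1, un = -2), "UN")
})

test_that("closed-form oracles have the right limits and symmetry", {
  expect_equal(analytic_accuracy(0, 0.77), 0.5)
  expect_equal(round(analytic_accuracy(2.05, 0.77), 3), 0.959)
  expect_equal(analytic_accuracy(-1.3, 0.9),
               1 - analytic_accuracy(1.3, 0.9))
  expect_equal(round(analytic_mean_dt(2, 0.77), 3), 0.351)
  expect_equal(analytic_mean_dt(0, 1.0), 1.0)
  expect_lt(analytic_mean_dt(50, 0.77), 0.02)
  expect_error(analytic_accuracy(1, -1), "bound")
})

test_that("overwhelming drift and zero drift behave as expected", {
  p <- ddm_params(dr = 100, sym = 0, bo = 0.5)
  s <- simulate_trials(p, data.frame(log_distance = rep(1, 2000)), seed = 1)
  expect_gt(mean(s$choice == "upper"), 0.999)

  p0 <- ddm_params(dr = 1e-9, sym = 0, bo = 0.5, ic = 0)
  s0 <- simulate_trials(p0, data.frame(log_distance = rep(1, 10000)),
                        seed = 2)
  s0 <- s0[s0$choice != "timeout", ]
  se <- sqrt(0.25 / nrow(s0))
  expect_lt(abs(mean(s0$choice == "upper") - 0.5), 3 * se)
})

test_that("simulated accuracy and decision time match the diffusion oracles", {
  cfg <- sim_config(dt = 5e-4, deadline_s = 30)
  set.seed(11)
  for (v in c(0.5, 2)) {
    for (b in c(0.5, 0.77)) {
      p <- ddm_params(dr = v, sym = 0, bo = b, ic = 0, ndt = 0)
      s <- simulate_trials(p, data.frame(log_distance = rep(1, 5000)), cfg)
      s <- s[s$choice != "timeout", ]
      acc <- mean(s$correct)
      th <- analytic_accuracy(v, b)
      expect_lt(abs(acc - th), 3 * sqrt(th * (1 - th) / nrow(s)))
      expect_lt(abs(mean(s$rt) - analytic_mean_dt(v, b)),
                3 * sd(s$rt) / sqrt(nrow(s)))
    }
  }
})

test_that("changing only NDT shifts every response time by exactly that", {
  d <- data.frame(log_distance = rep(1, 500))
  p1 <- ddm_params(dr = 2, sym = 0, bo = 0.77, ic = 0.2, ndt = 0.3)
  p2 <- ddm_params(dr = 2, sym = 0, bo = 0.77, ic = 0.2, ndt = 0.5)
  s1 <- simulate_trials(p1, d, seed = 9)
  s2 <- simulate_trials(p2, d, seed = 9)
  ok <- s1$choice != "timeout" & s2$choice != "timeout"
  expect_equal(s2$rt[ok] - s1$rt[ok], rep(0.2, sum(ok)))
  expect_identical(s1$choice[ok], s2$choice[ok])
})

test_that("accuracy grows with numerical distance when SYM > 0", {
  p <- ddm_params(dr = 2, sym = 0.5, bo = 0.77)
  d <- data.frame(log_distance = rep(c(0.134, 0.511, 1.386), each = 4000))
  s <- simulate_trials(p, d, seed = 4)
  s <- s[s$choice != "timeout", ]
  acc <- tapply(s$correct, s$log_distance, mean)
  expect_true(all(diff(acc) > 0))
})

test_that("first-passage solver agrees with the logistic hit probability", {
  for (v in c(0.5, 2.05)) {
    for (b in c(0.5, 0.77)) {
      p <- ddm_params(dr = v, sym = 0, bo = b, ic = 0)
      fp <- first_passage_density(p, 1, horizon = 20)
      up <- sum(fp$upper) * fp$dt
      lo <- sum(fp$lower) * fp$dt
      expect_lt(abs(up - analytic_accuracy(v, b)), 1e-3)
      expect_lt(abs(up + lo + fp$survivor - 1), 1e-6)
    }
  }
})

test_that("first-passage densities match a Monte-Carlo histogram", {
  p <- ddm_params(dr = 2.05, sym = 0, bo = 0.77, ic = 0.2)
  fp <- first_passage_density(p, 1, dt = 0.005, horizon = 10)
  n <- 5e4
  s <- simulate_trials(p, data.frame(log_distance = rep(1, n)),
                       sim_config(dt = 5e-4, deadline_s = 10), seed = 21)
  breaks <- seq(0, 1.5, by = 0.1)
  for (side in c("upper", "lower")) {
    keep <- s$choice == side & s$rt < 1.5
    h <- hist(s$rt[keep], breaks = breaks, plot = FALSE)
    dens_in_bin <- sapply(seq_len(length(breaks) - 1), function(i) {
      sel <- fp$time >= breaks[i] & fp$time < breaks[i + 1]
      sum(fp[[side]][sel]) * fp$dt
    })
    p_hat <- h$counts / n
    se <- sqrt(pmax(dens_in_bin * (1 - dens_in_bin), 1e-6) / n)
    expect_true(all(abs(p_hat - dens_in_bin) < 5 * se))
  }
})

test_that("solver grid preconditions are enforced", {
  p <- ddm_params(dr = 2, sym = 0, bo = 0.77)
  expect_error(first_passage_density(p, 1, dt = 0.01), "5 ms")
  expect_error(first_passage_density(p, -1), "log_distance")
})
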