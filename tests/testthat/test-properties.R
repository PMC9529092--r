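make_proxy_trials <- function(n = 600, n_subjects = 3, informative = TRUE,
                              seed = 1) {
  set.seed(seed)
  d <- sample(c(0.2, 0.5, 0.8, 1.1, 1.4), n, replace = TRUE)
  correct <- runif(n) < 0.6 + 0.25 * d
  proxy <- if (informative) as.numeric(correct) * 0.4 + 0.3 +
    rnorm(n, 0, 0.1) else runif(n)
  data.frame(subject = rep_len(seq_len(n_subjects), n), log_distance = d,
             correct = correct, confidence = proxy,
             num_a = 7, num_b = round(7 / exp(d)))
}

test_that("accuracy rises across bins of an informative proxy", {
  tr <- make_proxy_trials(informative = TRUE)
  res <- bin_accuracy_by_confidence(tr, n_bins = 5)
  expect_true(res$passed)
  expect_gt(res$slope["estimate"], 0.5)
  expect_equal(sum(res$curve$n), nrow(tr))
  expect_gt(res$curve$accuracy[5], res$curve$accuracy[1])
})

test_that("an uninformative proxy fails the binning signature most of the time", {
  fails <- 0
  for (r in 1:10) {
    tr <- make_proxy_trials(informative = FALSE, seed = 100 + r)
    if (!bin_accuracy_by_confidence(tr, n_bins = 5)$passed) fails <- fails + 1
  }
  expect_gte(fails, 8)
  const <- make_proxy_trials()
  const$confidence <- 0.5
  expect_error(bin_accuracy_by_confidence(const, n_bins = 5), "degenerate")
  expect_error(bin_accuracy_by_confidence(make_proxy_trials(n = 60),
                                          n_bins = 5), "at least")
})

test_that("correct trials carry the higher proxy when the effect is planted", {
  set.seed(7)
  n <- 800
  d <- sample(c(0.2, 0.5, 0.8, 1.1), n, replace = TRUE)
  correct <- runif(n) < 0.7
  tr <- data.frame(subject = rep_len(1:4, n), log_distance = d,
                   correct = correct,
                   confidence = ifelse(correct, rnorm(n, 0.7, 0.1),
                                       rnorm(n, 0.3, 0.1)))
  res <- confidence_by_correctness(tr)
  expect_true(res$passed)
  expect_lt(abs(res$contrast["estimate"] - 0.4), 0.05)
  expect_true(all(res$by_distance$mean_conf_correct >
                  res$by_distance$mean_conf_error, na.rm = TRUE))

  # label shuffling destroys the contrast
  tr$confidence <- sample(tr$confidence)
  res0 <- confidence_by_correctness(tr)
  expect_true(res0$contrast["ci_low"] < 0 && res0$contrast["ci_high"] > 0)

  # without error trials the check is not evaluable
  allc <- tr
  allc$correct <- TRUE
  expect_true(is.na(confidence_by_correctness(allc)$passed))
})

test_that("median splits assign ties to the low half and detect accuracy gaps", {
  tr <- data.frame(subject = 1, log_distance = rep(c(0.3, 0.9), each = 2),
                   correct = c(TRUE, FALSE, TRUE, FALSE),
                   confidence = c(0.2, 0.4, 0.6, 0.8))
  tr2 <- rbind(tr, tr)          # enough rows for the model
  split <- median_split_accuracy(tr2)
  expect_equal(sum(split$split_curve$n_high), 4)   # median 0.5: two above x2
  expect_equal(sum(split$split_curve$n_low), 4)

  res <- median_split_accuracy(make_proxy_trials(informative = TRUE))
  expect_true(res$passed)
  res0 <- median_split_accuracy(make_proxy_trials(informative = FALSE,
                                                  seed = 55))
  expect_lt(abs(res0$contrast["estimate"]), 0.1)
  flat <- make_proxy_trials()
  flat$confidence <- 1
  expect_error(median_split_accuracy(flat), "degenerate")
})

test_that("the normative illustration reproduces the three property shapes", {
  ill <- normative_illustration(n_trials = 5e4, percept_sd = 0.3, seed = 2)
  acc <- ill$accuracy_by_confidence$accuracy
  expect_true(all(diff(acc) > 0))
  cc <- ill$confidence_by_correctness
  expect_true(all(cc$conf_correct > cc$conf_error, na.rm = TRUE))
  ms <- ill$median_split
  expect_true(mean(ms$acc_high - ms$acc_low, na.rm = TRUE) > 0)
  # percepts near zero are maximally ambiguous
  near0 <- abs(ill$trials$percept) < 0.005
  expect_lt(abs(mean(ill$trials$confidence[near0]) - 0.5), 0.02)
  # noiseless limit: near-perfect accuracy and confidence
  sharp <- normative_illustration(n_trials = 1e4, percept_sd = 0.01, seed = 3)
  expect_gt(mean(sharp$trials$correct), 0.99)
  expect_gt(mean(sharp$trials$confidence), 0.99)
  expect_error(normative_illustration(1e4, percept_sd = 0), "percept_sd")
  expect_error(normative_illustration(100), "n_trials")
})

test_that("BIC comparison identifies the generating distance scale", {
  pairs <- canonical_pairs()
  wins_log <- 0
  wins_lin <- 0
  for (r in 1:10) {
    set.seed(300 + r)
    idx <- sample(nrow(pairs), 2000, replace = TRUE)
    tr <- pairs[idx, ]
    tr$subject <- rep_len(1:5, nrow(tr))
    tr$rt <- 1 - 0.2 * tr$log_distance + rnorm(nrow(tr), 0, 0.15)
    if (bic_distance_comparison(tr)$delta < 0) wins_log <- wins_log + 1
    tr$rt <- 1 - 0.05 * (tr$num_a - tr$num_b) + rnorm(nrow(tr), 0, 0.15)
    if (bic_distance_comparison(tr)$delta > 0) wins_lin <- wins_lin + 1
  }
  expect_gte(wins_log, 9)
  expect_gte(wins_lin, 9)
})

test_that("identical regressors give identical BICs", {
  tr <- make_proxy_trials(n = 400)
  tr$rt <- 0.9 - 0.1 * tr$log_distance + rnorm(400, 0, 0.1)
  tr$num_b <- 0
  tr$num_a <- tr$log_distance     # linear column equals the log column
  expect_equal(bic_distance_comparison(tr)$delta, 0)
  const <- tr
  const$log_distance <- 1
  const$num_a <- 2; const$num_b <- 1
  expect_error(bic_distance_comparison(const), "constant")
})
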