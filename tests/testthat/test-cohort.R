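test_that("participant parameters are truncated draws around the cohort means", {
  spec <- cohort_spec(n_subjects = 5, seed = 3)
  # zero spread degenerates to the exact means
  spec0 <- spec
  spec0$param_sds <- lapply(spec0$param_sds, function(s) s * 0)
  pars <- sample_participant_params(spec0, 1)
  ref <- ddm_reference_params("exp1", "negative")
  expect_equal(pars$negative$dr, ref$dr)
  expect_equal(pars$negative$ndt, ref$ndt)
  # determinism given (seed, subject index)
  expect_identical(sample_participant_params(spec, 4),
                   sample_participant_params(spec, 4))
  # truncation respected over many draws
  draws <- lapply(1:300, function(i) sample_participant_params(spec, i))
  syms <- vapply(draws, function(d) d$positive$sym, numeric(1))
  ics <- vapply(draws, function(d) d$positive$ic / d$positive$bo, numeric(1))
  expect_true(all(syms >= 0 & syms <= 1))
  expect_true(all(ics <= 0.95))
  # sample moments track the specified means
  drs <- vapply(draws, function(d) d$positive$dr, numeric(1))
  expect_lt(abs(mean(drs) - 2.46), 3 * 0.77 / sqrt(300) + 0.02)
  expect_error(cohort_spec(param_sds = list(
    positive = c(dr = -1, sym = 0, bo = 0, ic = 0, ndt = 0),
    negative = c(dr = 0, sym = 0, bo = 0, ic = 0, ndt = 0),
    one_over = c(dr = 0, sym = 0, bo = 0, ic = 0, ndt = 0))), "sds")
})

test_that("the confidence-to-pressure transfer is monotone and clipped", {
  spec <- cohort_spec(pressure_noise_sd = 0, seed = 1)
  conf <- seq(0.05, 0.95, by = 0.1)
  raw <- pressure_from_confidence(conf, spec)
  expect_true(all(diff(raw) > 0))
  expect_true(all(raw >= 0 & raw <= 1023))
  # zero gain: pressure carries no confidence signal
  spec0 <- cohort_spec(pressure_gain = 0, pressure_noise_sd = 0, seed = 1)
  raw0 <- pressure_from_confidence(conf, spec0)
  expect_equal(raw0, rep(spec0$pressure_intercept, length(conf)))
})

test_that("pressure normalization divides by the per-side session maximum", {
  raw <- c(492, 984, 300, 600)
  subject <- c(1, 1, 1, 1)
  side <- c("left", "left", "right", "right")
  norm <- normalize_pressure(raw, subject, side)
  expect_equal(norm, c(0.5, 1, 0.5, 1))
  # permutation leaves values attached to their trials
  ord <- c(3, 1, 4, 2)
  expect_equal(normalize_pressure(raw[ord], subject[ord], side[ord]),
               norm[ord])
  expect_error(normalize_pressure(c(0, 0), c(1, 1), c("l", "l")), "maximum")
})

test_that("slow-RT exclusion drops only the far right tail", {
  tt <- data.frame(rt = c(rep(0.5, 19), 10))
  ex <- exclude_slow_rts(tt)
  expect_equal(ex$n_excluded, 1)
  expect_equal(nrow(ex$trials), 19)
  expect_gt(ex$cutoff, max(ex$trials$rt))
  # no spread, nothing excluded
  flat <- exclude_slow_rts(data.frame(rt = rep(0.7, 10)))
  expect_equal(flat$n_excluded, 0)
  expect_error(exclude_slow_rts(data.frame(rt = 1)), ">= 2")
})

test_that("cohorts are reproducible and carry the full trial schema", {
  spec <- cohort_spec(n_subjects = 2, trials_per_pair_per_type = 2,
                      n_dummy = 10, seed = 99)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 2 * (3 * 20 + 10))
  expect_true(all(c("confidence", "pressure_raw", "pressure_norm",
                    "excluded", "exclusion_reason") %in% names(c1)))
  # dummies flagged, timeouts carry a reason, analyzable rows complete
  expect_true(all(c1$excluded[c1$is_dummy]))
  ok <- !c1$excluded
  expect_false(any(is.na(c1$confidence[ok])))
  expect_true(all(c1$pressure_norm[ok] > 0 & c1$pressure_norm[ok] <= 1))
  # every subject/side with responses has a maximal record at exactly 1
  resp <- c1[c1$choice != "timeout", ]
  mx <- tapply(resp$pressure_norm, interaction(resp$subject,
                                               resp$response_side), max)
  expect_true(all(abs(mx - 1) < 1e-12))
})

test_that("negative-numeral trials are slower than positive ones on average", {
  wins <- 0
  for (r in 1:5) {
    spec <- cohort_spec(n_subjects = 6, trials_per_pair_per_type = 3,
                        n_dummy = 0, seed = 500 + r)
    ch <- generate_cohort(spec)
    ch <- ch[!ch$excluded, ]
    mrt <- tapply(ch$rt, ch$numeral_type, mean)
    if (mrt["negative"] > mrt["positive"]) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("distance speeds responses and improves accuracy in cohorts", {
  spec <- cohort_spec(n_subjects = 8, trials_per_pair_per_type = 4,
                      n_dummy = 0, seed = 77)
  ch <- generate_cohort(spec)
  ch <- ch[!ch$excluded, ]
  rt_slope <- coef(lm(rt ~ log_distance + factor(subject), ch))["log_distance"]
  acc_slope <- coef(lm(correct ~ log_distance + factor(subject),
                       ch))["log_distance"]
  expect_lt(rt_slope, 0)
  expect_gt(acc_slope, 0)
})
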