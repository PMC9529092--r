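#' Accuracy by confidence bin
#'
#' First confidence signature: correct answers should be more likely in
#' trials with higher confidence. Trials are cut into equal-count quantile
#' bins of the proxy (model confidence or normalized button pressure), and
#' the slope comes from a linear probability model of correctness on the
#' proxy with per-subject intercepts. The signature passes when the slope's
#' 95% confidence interval lies above zero.
#'
#' @param trials Trial table with `correct`, the proxy column, and
#'   optionally `subject` (a single intercept is used without it).
#' @param proxy Name of the proxy column (default `"confidence"`).
#' @param n_bins Number of quantile bins (default 10).
#' @return List with `curve` (bin centers, accuracy, n), `slope`
#'   (`estimate`, `ci_low`, `ci_high`), `passed`.
#' @export
bin_accuracy_by_confidence <- function(trials, proxy = "confidence",
                                       n_bins = 10) {
  x <- trials[[proxy]]
  if (is.null(x)) stop("no column '", proxy, "' in trials")
  ok <- !is.na(x) & !is.na(trials$correct)
  trials <- trials[ok, , drop = FALSE]
  x <- x[ok]
  if (nrow(trials) < n_bins * 20)
    stop("need at least ", n_bins * 20, " trials for ", n_bins, " bins")
  if (length(unique(x)) < 2) stop("degenerate bins: proxy is constant")
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(x, qs, include.lowest = TRUE)
  curve <- data.frame(
    bin_center = as.numeric(tapply(x, bin, mean)),
    accuracy = as.numeric(tapply(trials$correct, bin, mean)),
    n = as.integer(tapply(x, bin, length)))
  slope <- .proxy_slope(trials, proxy, outcome = "correct")
  list(curve = curve, slope = slope, passed = unname(slope["ci_low"] > 0))
}

# OLS slope of outcome on predictor with subject-level intercepts
.proxy_slope <- function(trials, predictor, outcome,
                         covariate = NULL) {
  df <- data.frame(y = as.numeric(trials[[outcome]]),
                   x = as.numeric(trials[[predictor]]))
  form <- y ~ x
  if (!is.null(covariate)) {
    df$z <- as.numeric(trials[[covariate]])
    form <- y ~ x + z
  }
  if (!is.null(trials$subject) && length(unique(trials$subject)) > 1) {
    df$subject <- factor(trials$subject)
    form <- stats::update(form, . ~ . + subject)
  }
  fit <- lm(form, data = df)
  ci <- confint(fit, "x", level = 0.95)
  c(estimate = unname(coef(fit)["x"]), ci_low = ci[1], ci_high = ci[2])
}

#' Confidence on correct versus error trials
#'
#' Second confidence signature: at any given difficulty, confidence should
#' be higher on correct than on error trials. Returns per-distance proxy
#' means for correct and error trials and the overall correct-minus-error
#' contrast from an OLS model with subject intercepts, controlling for
#' logarithmic distance. Passes when the contrast's CI lies above zero;
#' when fewer than three distances carry error trials (very low error
#' rates) the check is flagged not evaluable.
#'
#' @inheritParams bin_accuracy_by_confidence
#' @return List with `by_distance` (distance, mean proxy for correct and
#'   error, counts), `contrast` (`estimate`, `ci_low`, `ci_high`), `passed`
#'   (NA when not evaluable).
#' @export
confidence_by_correctness <- function(trials, proxy = "confidence") {
  x <- trials[[proxy]]
  if (is.null(x)) stop("no column '", proxy, "' in trials")
  ok <- !is.na(x) & !is.na(trials$correct) & !is.na(trials$log_distance)
  trials <- trials[ok, , drop = FALSE]
  dists <- sort(unique(trials$log_distance))
  by_dist <- do.call(rbind, lapply(dists, function(d) {
    g <- trials[trials$log_distance == d, ]
    data.frame(log_distance = d,
               mean_conf_correct = mean(g[[proxy]][g$correct]),
               mean_conf_error = if (any(!g$correct))
                 mean(g[[proxy]][!g$correct]) else NA_real_,
               n_correct = sum(g$correct), n_error = sum(!g$correct))
  }))
  evaluable <- sum(by_dist$n_error > 0) >= 3
  if (!evaluable)
    return(list(by_distance = by_dist,
                contrast = c(estimate = NA_real_, ci_low = NA_real_,
                             ci_high = NA_real_),
                passed = NA))
  contrast <- .proxy_slope(trials, predictor = "correct", outcome = proxy,
                           covariate = "log_distance")
  list(by_distance = by_dist, contrast = contrast,
       passed = unname(contrast["ci_low"] > 0))
}

#' Accuracy after a within-subject median split of the proxy
#'
#' Third confidence signature: at fixed difficulty, trials above the
#' subject's median proxy should be more accurate than trials below it.
#' Ties go to the low half, so the split is deterministic. The contrast is
#' the high-minus-low accuracy difference from an OLS model with subject
#' intercepts controlling for distance; passes when its CI lies above zero.
#'
#' @inheritParams bin_accuracy_by_confidence
#' @return List with `split_curve` (distance, accuracy high/low, counts),
#'   `contrast`, `passed`.
#' @export
median_split_accuracy <- function(trials, proxy = "confidence") {
  x <- trials[[proxy]]
  if (is.null(x)) stop("no column '", proxy, "' in trials")
  ok <- !is.na(x) & !is.na(trials$correct) & !is.na(trials$log_distance)
  trials <- trials[ok, , drop = FALSE]
  subj <- if (is.null(trials$subject)) rep(1, nrow(trials)) else
    trials$subject
  med <- tapply(trials[[proxy]], subj, median)
  high <- trials[[proxy]] > med[as.character(subj)]
  if (all(!high) || all(high))
    stop("degenerate split: proxy does not vary around the median")
  trials$high_half <- high
  dists <- sort(unique(trials$log_distance))
  split_curve <- do.call(rbind, lapply(dists, function(d) {
    g <- trials[trials$log_distance == d, ]
    data.frame(log_distance = d,
               acc_high = mean(g$correct[g$high_half]),
               acc_low = mean(g$correct[!g$high_half]),
               n_high = sum(g$high_half), n_low = sum(!g$high_half))
  }))
  contrast <- .proxy_slope(trials, predictor = "high_half",
                           outcome = "correct", covariate = "log_distance")
  list(split_curve = split_curve, contrast = contrast,
       passed = unname(contrast["ci_low"] > 0))
}

#' The three confidence signatures in one report
#'
#' Runs [bin_accuracy_by_confidence()], [confidence_by_correctness()] and
#' [median_split_accuracy()] on a trial table with a confidence proxy and
#' collects the binned curves, effect estimates and pass flags.
#'
#' @inheritParams bin_accuracy_by_confidence
#' @return Object of class `property_report`.
#' @export
confidence_signatures <- function(trials, proxy = "confidence",
                                  n_bins = 10) {
  a <- bin_accuracy_by_confidence(trials, proxy, n_bins)
  b <- confidence_by_correctness(trials, proxy)
  c3 <- median_split_accuracy(trials, proxy)
  structure(list(
    proxy = proxy,
    binned_curve = a$curve,
    correct_vs_error = b$by_distance,
    split_curve = c3$split_curve,
    slopes = list(accuracy_by_proxy = a$slope,
                  correct_vs_error = b$contrast,
                  median_split = c3$contrast),
    passed = c(accuracy_by_proxy = a$passed,
               correct_vs_error = b$passed,
               median_split = c3$passed)
  ), class = "property_report")
}

#' @export
print.property_report <- function(x, ...) {
  cat("Confidence-signature report (proxy:", x$proxy, ")\n")
  for (nm in names(x$slopes)) {
    s <- x$slopes[[nm]]
    cat(sprintf("  %-20s est %7.4f  CI [%7.4f, %7.4f]  %s\n", nm,
                s["estimate"], s["ci_low"], s["ci_high"],
                if (is.na(x$passed[nm])) "not evaluable"
                else if (x$passed[nm]) "PASS" else "fail"))
  }
  invisible(x)
}

#' Normative illustration of the confidence properties
#'
#' A task-agnostic statistical-confidence simulation: trial discriminability
#' is uniform on (0, 1), the true side is +/-1 with equal probability, the
#' percept is the true signed discriminability plus Gaussian noise, the
#' choice follows the percept's sign, and confidence is the exact posterior
#' probability that the choice is correct under that generative model
#' (integrating discriminability out over its uniform prior, which reduces
#' to normal-CDF differences). Illustrates why any valid confidence proxy
#' must show the three signatures.
#'
#' @param n_trials Number of simulated trials (>= 1e4).
#' @param percept_sd Perceptual noise sd, > 0 (default 0.3).
#' @param seed Integer seed.
#' @param n_bins Bins for the summary curves.
#' @return List with `trials` and the three curves `accuracy_by_confidence`
#'   (deciles), `confidence_by_correctness` and `median_split` (by
#'   discriminability bins).
#' @export
normative_illustration <- function(n_trials = 1e5, percept_sd = 0.3,
                                   seed = 1, n_bins = 10) {
  if (percept_sd <= 0) stop("percept_sd must be > 0")
  if (n_trials < 1e4) stop("n_trials must be >= 1e4")
  set.seed(seed)
  d <- runif(n_trials)
  s <- sample(c(-1, 1), n_trials, replace = TRUE)
  x <- rnorm(n_trials, s * d, percept_sd)
  choice <- sign(x)
  choice[choice == 0] <- 1
  correct <- choice == s
  # posterior odds of the percept's side, discriminability integrated over
  # U(0,1): P(x | s = +1) = Phi(x/sd) - Phi((x-1)/sd) up to a constant
  like_pos <- pnorm(x / percept_sd) - pnorm((x - 1) / percept_sd)
  like_neg <- pnorm((x + 1) / percept_sd) - pnorm(x / percept_sd)
  post_pos <- like_pos / (like_pos + like_neg)
  confidence <- ifelse(choice > 0, post_pos, 1 - post_pos)
  trials <- data.frame(discriminability = d, percept = x, correct = correct,
                       confidence = confidence)

  cbin <- cut(confidence, unique(quantile(confidence,
              seq(0, 1, length.out = n_bins + 1))), include.lowest = TRUE)
  acc_by_conf <- data.frame(
    confidence = as.numeric(tapply(confidence, cbin, mean)),
    accuracy = as.numeric(tapply(correct, cbin, mean)))
  dbin <- cut(d, seq(0, 1, length.out = n_bins + 1), include.lowest = TRUE)
  conf_by_corr <- data.frame(
    discriminability = as.numeric(tapply(d, dbin, mean)),
    conf_correct = as.numeric(tapply(confidence[correct],
                                     dbin[correct], mean)),
    conf_error = as.numeric(tapply(confidence[!correct],
                                   dbin[!correct], mean)))
  high <- confidence > median(confidence)
  split <- data.frame(
    discriminability = as.numeric(tapply(d, dbin, mean)),
    acc_high = as.numeric(tapply(correct[high], dbin[high], mean)),
    acc_low = as.numeric(tapply(correct[!high], dbin[!high], mean)))
  list(trials = trials, accuracy_by_confidence = acc_by_conf,
       confidence_by_correctness = conf_by_corr, median_split = split)
}

#' Compare logarithmic against linear distance as a predictor
#'
#' Fits the same subject-intercept OLS model of an outcome (response time
#' or accuracy) twice - once with logarithmic numerical distance, once with
#' linear distance (`num_a - num_b`) - and compares Bayesian information
#' criteria. A negative delta (`BIC_log - BIC_linear`) favors the
#' logarithmic scaling of the mental number line.
#'
#' @param trials Trial table with `num_a`, `num_b`, `log_distance`, the
#'   outcome column, and optionally `subject`.
#' @param outcome Outcome column name (default `"rt"`).
#' @return List with `bic_log`, `bic_linear`, `delta`.
#' @export
bic_distance_comparison <- function(trials, outcome = "rt") {
  y <- trials[[outcome]]
  if (is.null(y)) stop("no column '", outcome, "' in trials")
  df <- data.frame(y = as.numeric(y),
                   dist_log = trials$log_distance,
                   dist_lin = trials$num_a - trials$num_b,
                   subject = if (is.null(trials$subject)) 1
                             else trials$subject)
  df <- df[complete.cases(df), ]
  if (sd(df$dist_log) == 0 || sd(df$dist_lin) == 0)
    stop("distance regressor is constant")
  form_log <- y ~ dist_log
  form_lin <- y ~ dist_lin
  if (length(unique(df$subject)) > 1) {
    df$subject <- factor(df$subject)
    form_log <- y ~ dist_log + subject
    form_lin <- y ~ dist_lin + subject
  }
  bic_log <- BIC(lm(form_log, data = df))
  bic_linear <- BIC(lm(form_lin, data = df))
  list(bic_log = bic_log, bic_linear = bic_linear,
       delta = bic_log - bic_linear)
}
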