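#' Specification of a synthetic cohort
#'
#' Describes a complete synthetic experiment: participants whose per-type
#' DDM parameters are drawn around the reference means with between-subject
#' spread, the trial design they run through, the inference-uncertainty
#' values used for the confidence readout, and a noisy monotone transfer
#' from confidence to button pressure (raw sensor units 0-1023). The
#' transfer function is an explicit modelling choice of this package: its
#' defaults (intercept 300, gain 400, noise sd 80) make normalized pressure
#' span roughly the 0.03-1 range seen on real force sensors.
#'
#' @param n_subjects Number of participants (default 50).
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`; selects the design and
#'   the reference parameter table.
#' @param un_mode `"equal"` or `"different"`, passed to [un_presets()].
#' @param param_means Named list (by numeral type) of [ddm_params()] used as
#'   population means; defaults to [ddm_reference_params()].
#' @param param_sds Named list (by numeral type) of named sd vectors over
#'   `dr, sym, bo, ic, ndt`; defaults to the reference between-subject sds.
#'   Set all sds to zero for a homogeneous cohort.
#' @param pressure_intercept,pressure_gain,pressure_noise_sd Confidence to
#'   raw-pressure transfer: `raw = clip(intercept + gain * confidence +
#'   N(0, noise_sd), 0, 1023)`. A gain of zero makes pressure uninformative,
#'   which is the null model against which the confidence signatures are
#'   falsified.
#' @param trials_per_pair_per_type,n_dummy Passed to [build_design()]
#'   (experiment defaults when `NULL`).
#' @param seed Root seed; everything downstream derives from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 50, experiment = "exp1",
                        un_mode = c("equal", "different"),
                        param_means = NULL, param_sds = NULL,
                        pressure_intercept = 300, pressure_gain = 400,
                        pressure_noise_sd = 80,
                        trials_per_pair_per_type = NULL, n_dummy = NULL,
                        seed = 1L) {
  un_mode <- match.arg(un_mode)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  types <- .numeral_types
  if (is.null(param_means))
    param_means <- setNames(lapply(types, function(tp)
      ddm_reference_params(experiment, tp)), types)
  if (is.null(param_sds))
    param_sds <- setNames(lapply(types, function(tp)
      ddm_reference_params(experiment, tp, what = "sd")), types)
  for (tp in types) {
    if (any(param_sds[[tp]] < 0)) stop("parameter sds must be >= 0")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 experiment = experiment, un_mode = un_mode,
                 un_by_type = un_presets(experiment, un_mode),
                 param_means = param_means, param_sds = param_sds,
                 pressure_intercept = pressure_intercept,
                 pressure_gain = pressure_gain,
                 pressure_noise_sd = pressure_noise_sd,
                 trials_per_pair_per_type = trials_per_pair_per_type,
                 n_dummy = n_dummy, seed = as.integer(seed)),
            class = "cohort_spec")
}

# inverse-CDF truncated normal; sd = 0 degenerates to the mean
.rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(1, plo, phi), mean, sd)
}

#' Draw one participant's parameters
#'
#' Independent truncated-normal draws per parameter and numeral type around
#' the cohort means, truncated to the fitting bounds (IC additionally to
#' `0.95 * BO` of the drawn bound). Deterministic given `(spec$seed,
#' subject_index)`.
#'
#' @param spec A [cohort_spec()].
#' @param subject_index Positive integer.
#' @param bounds A [fit_bounds()] giving the truncation box.
#' @return Named list mapping numeral types to [ddm_params()] with the
#'   cohort's `UN` attached.
#' @export
sample_participant_params <- function(spec, subject_index,
                                      bounds = fit_bounds()) {
  stopifnot(inherits(spec, "cohort_spec"), subject_index >= 1)
  set.seed((spec$seed * 97L + subject_index * 7919L) %% 2147483629L)
  out <- list()
  for (tp in names(spec$param_means)) {
    m <- spec$param_means[[tp]]
    s <- spec$param_sds[[tp]]
    dr <- .rtruncnorm1(m$dr, s[["dr"]], bounds$dr[1], bounds$dr[2])
    sym <- .rtruncnorm1(m$sym, s[["sym"]], bounds$sym[1], bounds$sym[2])
    bo <- .rtruncnorm1(m$bo, s[["bo"]], bounds$bo[1], bounds$bo[2])
    ic <- .rtruncnorm1(m$ic, s[["ic"]], 0, bounds$ic_frac[2] * bo)
    ndt <- .rtruncnorm1(m$ndt, s[["ndt"]], bounds$ndt[1], bounds$ndt[2])
    out[[tp]] <- ddm_params(dr = dr, sym = sym, bo = bo, ic = ic, ndt = ndt,
                            un = spec$un_by_type[[tp]])
  }
  out
}

#' Map confidence to raw button pressure
#'
#' Noisy affine transfer from confidence in (0, 1) to raw force-sensor units
#' on the 0-1023 scale: `clip(intercept + gain * confidence + noise, 0,
#' 1023)`.
#'
#' @param confidence Numeric vector in (0, 1).
#' @param spec A [cohort_spec()] supplying intercept, gain, noise sd.
#' @return Raw pressure values in [0, 1023].
#' @export
pressure_from_confidence <- function(confidence, spec) {
  raw <- spec$pressure_intercept + spec$pressure_gain * confidence +
    rnorm(length(confidence), 0, spec$pressure_noise_sd)
  pmin(pmax(raw, 0), 1023)
}

#' Normalize pressure to the session maximum
#'
#' Standardizes raw pressure peaks to each subject's maximum over the whole
#' session, separately per response side (sensor): a raw peak of 492 in a
#' session whose left-sensor maximum is 984 becomes 0.5, and the maximal
#' record maps to exactly 1.
#'
#' @param raw Raw pressure values.
#' @param subject Subject identifier per record.
#' @param side Response side (sensor) per record.
#' @return Normalized pressures in (0, 1].
#' @export
normalize_pressure <- function(raw, subject, side) {
  key <- interaction(subject, side, drop = TRUE)
  mx <- tapply(raw, key, max)
  if (any(mx <= 0)) stop("a session maximum is not positive")
  as.numeric(raw / mx[key])
}

#' Generate a full synthetic cohort
#'
#' Simulates every designed trial for every participant with that
#' participant's type-specific parameters, attaches confidence at choice
#' and button pressure, and normalizes pressure within subject and response
#' side. Dummy trials are simulated and kept but flagged; timeouts are kept
#' with an exclusion reason. The result is byte-for-byte reproducible from
#' the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param config A [sim_config()].
#' @return Trial table with columns `subject`, `trial_index`,
#'   `numeral_type`, `num_a`, `num_b`, `log_distance`, `is_dummy`,
#'   `correct_side`, `response_side`, `choice`, `correct`, `rt`, `n_steps`,
#'   `dv_mean`, `confidence`, `pressure_raw`, `pressure_norm`, `excluded`,
#'   `exclusion_reason`.
#' @examples
#' \donttest{
#' spec <- cohort_spec(n_subjects = 2, trials_per_pair_per_type = 2,
#'                     n_dummy = 10, seed = 42)
#' cohort <- generate_cohort(spec)
#' }
#' @export
generate_cohort <- function(spec, config = sim_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    pars <- sample_participant_params(spec, s)
    design <- build_design(spec$experiment,
                           trials_per_pair_per_type =
                             spec$trials_per_pair_per_type,
                           n_dummy = spec$n_dummy,
                           seed = (spec$seed * 131L + s) %% 2147483629L)
    rows <- vector("list", length(pars))
    for (k in seq_along(pars)) {
      tp <- names(pars)[k]
      sub <- design[design$numeral_type == tp, , drop = FALSE]
      rows[[k]] <- simulate_trials(pars[[tp]], sub, config)
    }
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$trial_index), , drop = FALSE]
    tab$subject <- s
    ok <- tab$choice != "timeout"
    tab$confidence <- NA_real_
    tab$confidence[ok] <- confidence_at_choice(
      tab$dv_mean[ok],
      un = spec$un_by_type[tab$numeral_type[ok]],
      n_steps = tab$n_steps[ok])
    # chosen side: the correct side when the upper bound was hit, else the
    # opposite; timeouts press nothing
    other <- ifelse(tab$correct_side == "left", "right", "left")
    tab$response_side <- ifelse(tab$choice == "upper", tab$correct_side,
                                ifelse(tab$choice == "lower", other,
                                       NA_character_))
    tab$pressure_raw <- NA_real_
    tab$pressure_raw[ok] <- pressure_from_confidence(tab$confidence[ok], spec)
    tab$pressure_norm <- NA_real_
    tab$pressure_norm[ok] <- normalize_pressure(tab$pressure_raw[ok],
                                                tab$subject[ok],
                                                tab$response_side[ok])
    tab$excluded <- !ok | tab$is_dummy
    tab$exclusion_reason <- ifelse(!ok, "timeout",
                                   ifelse(tab$is_dummy, "dummy", ""))
    subjects[[s]] <- tab
  }
  res <- do.call(rbind, subjects)
  rownames(res) <- NULL
  res[, c("subject", "trial_index", "numeral_type", "num_a", "num_b",
          "log_distance", "is_dummy", "correct_side", "response_side",
          "choice", "correct", "rt", "n_steps", "dv_mean", "confidence",
          "pressure_raw", "pressure_norm", "excluded", "exclusion_reason")]
}

#' Exclude slow response times
#'
#' One-sided outlier rule used before fitting and analysis: trials slower
#' than the pooled mean plus `k_sd` standard deviations are dropped (about
#' 8% of trials under realistic right-skewed RT distributions at the default
#' `k_sd = 2`).
#'
#' @param trials Trial table with an `rt` column (NA rts are ignored in the
#'   cutoff and kept out of the result).
#' @param k_sd Cutoff in pooled standard deviations above the pooled mean.
#' @return List with `trials` (the retained rows), `cutoff`, `n_excluded`
#'   and `fraction_kept`.
#' @examples
#' tt <- data.frame(rt = c(rep(0.5, 19), 10))
#' exclude_slow_rts(tt)$n_excluded  # 1
#' @export
exclude_slow_rts <- function(trials, k_sd = 2) {
  if (is.null(trials$rt) || nrow(trials) < 2)
    stop("need a trial table with >= 2 rt values")
  rts <- trials$rt
  keepable <- !is.na(rts)
  m <- mean(rts[keepable])
  s <- sd(rts[keepable])
  cutoff <- m + k_sd * s
  keep <- keepable & rts <= cutoff
  list(trials = trials[keep, , drop = FALSE], cutoff = cutoff,
       n_excluded = sum(keepable) - sum(keep),
       fraction_kept = sum(keep) / sum(keepable))
}
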