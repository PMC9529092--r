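#' Posterior over the mean decision variable
#'
#' With a normal likelihood for the decision-variable samples and a flat
#' prior on their mean, the posterior after `n` samples with running mean
#' `dv_mean` is Normal(`dv_mean`, `un / sqrt(n)`). Because positive values
#' of the decision variable code the correct option, the posterior
#' probability of being correct - the statistical confidence - is
#' `pnorm(dv_mean * sqrt(n) / un)`.
#'
#' @param dv_mean Mean of the decision-variable stream (vectorized).
#' @param n Number of samples, >= 1.
#' @param un Inference uncertainty `UN`, > 0.
#' @return A data frame with columns `dv_mean`, `n`, `un`, `post_sd`,
#'   `confidence`.
#' @examples
#' posterior_of_mean(0.5, 400, 2.5)  # post_sd 0.125, confidence ~0.99997
#' @export
posterior_of_mean <- function(dv_mean, n, un) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(un <= 0)) stop("un must be > 0")
  post_sd <- un / sqrt(n)
  data.frame(dv_mean = dv_mean, n = as.integer(n), un = un,
             post_sd = post_sd,
             confidence = pnorm(dv_mean / post_sd))
}

#' Confidence at the moment of choice
#'
#' Evaluates the posterior probability that the mean decision variable was
#' positive - i.e. the probability that the objectively correct option was
#' the better-supported one - at the moment the accumulator hit a threshold:
#' `pnorm(dv_mean * sqrt(n_steps) / un)`. Error trials typically have
#' `dv_mean < 0` and hence confidence below 0.5; confidence is always
#' relative to the objective correct side, not the chosen side.
#'
#' @param trials A trial table with columns `dv_mean`, `n_steps` and
#'   `choice` (as produced by [simulate_trials()]), or a numeric vector of
#'   `dv_mean` values if `n_steps` is given directly.
#' @param un Inference uncertainty `UN` (> 0).
#' @param n_steps Sample counts, only when `trials` is a numeric vector.
#' @return Numeric vector of confidences in (0, 1).
#' @examples
#' confidence_at_choice(0.5, un = 2.5, n_steps = 400)
#' @export
confidence_at_choice <- function(trials, un, n_steps = NULL) {
  if (any(un <= 0)) stop("un must be > 0")
  if (is.data.frame(trials)) {
    if (!is.null(trials$choice) && any(trials$choice == "timeout"))
      stop("confidence is undefined for timeout trials; drop them first")
    dv <- trials$dv_mean
    n <- trials$n_steps
  } else {
    dv <- trials
    n <- n_steps
  }
  if (is.null(n) || any(n < 1)) stop("n_steps must be >= 1")
  pnorm(dv * sqrt(n) / un)
}

#' Simulate a model-confidence table
#'
#' For each numeral type (with its own DDM parameters and `UN`) and each
#' distinct non-dummy logarithmic distance in the design, simulates
#' `sims_per_distance` decision trials and attaches confidence at choice.
#' Timeouts are dropped. This is the protocol used to compare confidence
#' across numeral types under equal versus different inference uncertainty.
#'
#' @param params_by_type Named list mapping numeral types to [ddm_params()].
#' @param design A `ddm_design` (only its distinct distances per type are
#'   used).
#' @param sims_per_distance Simulated trials per distance per type
#'   (default 150).
#' @param un_by_type Named numeric vector of `UN` values per type, e.g.
#'   from [un_presets()]; overrides any `un` stored in the parameter
#'   objects.
#' @param config A [sim_config()].
#' @param seed Optional seed.
#' @return Data frame with columns `numeral_type`, `log_distance`,
#'   `choice`, `correct`, `rt`, `n_steps`, `dv_mean`, `confidence`.
#' @examples
#' pars <- list(positive = ddm_reference_params("exp1", "positive"),
#'              negative = ddm_reference_params("exp1", "negative"))
#' d <- build_design("exp1", 1, n_dummy = 0, seed = 1)
#' ct <- simulate_confidence_table(pars, d, sims_per_distance = 20,
#'                                 un_by_type = un_presets("exp1", "equal"),
#'                                 seed = 1)
#' @export
simulate_confidence_table <- function(params_by_type, design,
                                      sims_per_distance = 150,
                                      un_by_type, config = sim_config(),
                                      seed = NULL) {
  if (sims_per_distance < 1) stop("sims_per_distance must be >= 1")
  if (nrow(design) == 0) stop("empty design")
  if (!is.null(seed)) set.seed(seed)
  nd <- design[!design$is_dummy, , drop = FALSE]
  if (nrow(nd) == 0) stop("design has no non-dummy trials")
  out <- list()
  for (tp in names(params_by_type)) {
    dists <- sort(unique(nd$log_distance[nd$numeral_type == tp]))
    if (length(dists) == 0) next
    un <- un_by_type[[tp]]
    if (is.null(un) || is.na(un)) stop("no UN value for type ", tp)
    grid <- data.frame(log_distance = rep(dists, each = sims_per_distance))
    sim <- simulate_trials(params_by_type[[tp]], grid, config)
    sim <- sim[sim$choice != "timeout", , drop = FALSE]
    sim$confidence <- confidence_at_choice(sim, un)
    sim$numeral_type <- tp
    out[[tp]] <- sim[, c("numeral_type", "log_distance", "choice", "correct",
                         "rt", "n_steps", "dv_mean", "confidence")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean-confidence ordering under equal versus different uncertainty
#'
#' Replicated cohort study of how the inference-uncertainty assignment
#' changes the confidence ordering between numeral types. For each
#' replicate, participants' decision parameters are drawn as in
#' [cohort_spec()]; each participant contributes `sims_per_distance`
#' simulated trials per canonical distance and type. Because `UN` affects
#' only the readout, never the decision process, every trial is simulated
#' once and its confidence computed under both presets: `"equal"` (one UN
#' for all types) and `"different"` (lower UN for positive numerals).
#'
#' Under equal UN, positive-numeral trials end with fewer accumulated
#' samples (they are faster), so their posterior is wider and mean
#' confidence is lower than for negative numerals; a sufficiently lower
#' positive UN reverses the ordering.
#'
#' @param experiment Experiment preset for parameters, sds and UN values.
#' @param n_subjects Participants per replicate cohort (default 50).
#' @param sims_per_distance Simulated trials per distance per type
#'   (default 150).
#' @param n_replicates Replicate cohorts (default 20).
#' @param seed Root seed.
#' @param types Numeral types to include (default positive and negative).
#' @param config A [sim_config()].
#' @return Data frame with one row per replicate x UN mode: mean confidence
#'   per type and `diff_positive_minus_negative`.
#' @export
confidence_ordering_study <- function(experiment = "exp1", n_subjects = 50,
                                      sims_per_distance = 150,
                                      n_replicates = 20, seed = 1L,
                                      types = c("positive", "negative"),
                                      config = sim_config()) {
  un <- list(equal = un_presets(experiment, "equal"),
             different = un_presets(experiment, "different"))
  dists <- canonical_pairs()$log_distance
  grid <- data.frame(log_distance = rep(dists, each = sims_per_distance))
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    spec <- cohort_spec(n_subjects = n_subjects, experiment = experiment,
                        seed = (seed + 7541L * r) %% 2147483629L)
    sums <- ns <- matrix(0, nrow = 2, ncol = length(types),
                         dimnames = list(c("equal", "different"), types))
    for (s in seq_len(n_subjects)) {
      pars <- sample_participant_params(spec, s)
      set.seed((spec$seed * 13L + s) %% 2147483629L)
      for (tp in types) {
        sim <- simulate_trials(pars[[tp]], grid, config)
        sim <- sim[sim$choice != "timeout", ]
        z <- sim$dv_mean * sqrt(sim$n_steps)
        for (mode in rownames(sums)) {
          sums[mode, tp] <- sums[mode, tp] + sum(pnorm(z / un[[mode]][[tp]]))
          ns[mode, tp] <- ns[mode, tp] + nrow(sim)
        }
      }
    }
    mc <- sums / ns
    out[[r]] <- data.frame(
      replicate = r, un_mode = rownames(mc),
      mean_conf_positive = mc[, "positive"],
      mean_conf_negative = mc[, "negative"],
      diff_positive_minus_negative = mc[, "positive"] - mc[, "negative"],
      row.names = NULL)
  }
  do.call(rbind, out)
}
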