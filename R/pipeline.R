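#' Run the full analysis pipeline
#'
#' Chains the stages end to end on a synthetic cohort: generate trials,
#' exclude slow response times, fit the DDM per participant and numeral
#' type, simulate model confidence under the configured
#' inference-uncertainty mode, and evaluate the three confidence signatures
#' on the cohort's button pressure. Every intermediate table is written as
#' CSV, and a JSON summary collects recovered parameter means, the property
#' pass flags and the positive-versus-negative mean-confidence contrast.
#' All outputs embed the seed and a hash of the configuration, and the run
#' is fully reproducible from (config, seed).
#'
#' @param config Named list (or path to a JSON file) with entries:
#'   `experiment`, `seed`, `n_subjects`, `trials_per_pair_per_type`,
#'   `n_dummy`, `un_mode` (`"equal"` or `"different"`), `sims_per_distance`,
#'   `n_bins` (confidence-signature quantile bins), `fit` (list of
#'   [fit_control()] overrides), `outdir`. Missing entries
#'   take the defaults shown in the function.
#' @return List with the per-stage objects and the `summary` list; written
#'   files are in `config$outdir`.
#' @examples
#' \donttest{
#' res <- run_pipeline(list(n_subjects = 2, trials_per_pair_per_type = 2,
#'                          n_dummy = 6, seed = 7, n_bins = 5,
#'                          fit = list(de_maxiter = 5, min_trials = 10),
#'                          outdir = tempfile("run")))
#' res$summary$properties_passed
#' }
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- list(experiment = "exp1", seed = 1L, n_subjects = 5L,
                   trials_per_pair_per_type = NULL, n_dummy = NULL,
                   un_mode = "equal", sims_per_distance = 150,
                   n_bins = 10, fit = list(),
                   outdir = file.path(tempdir(), "numddm_run"))
  config <- utils::modifyList(defaults, config)
  hash <- .config_hash(config[setdiff(names(config), "outdir")])
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  ctrl <- do.call(fit_control, config$fit)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out_path <- function(f) file.path(config$outdir, f)
  log_line <- function(...) message("[numddm] ", ...)

  spec <- cohort_spec(n_subjects = config$n_subjects,
                      experiment = config$experiment,
                      un_mode = config$un_mode,
                      trials_per_pair_per_type =
                        config$trials_per_pair_per_type,
                      n_dummy = config$n_dummy, seed = seed)

  cohort <- stage("synth", generate_cohort(spec))
  write_trials(cohort, out_path("trials.csv"), seed, hash)
  log_line("synth: ", nrow(cohort), " trials, ",
           sum(cohort$is_dummy), " dummies, ",
           sum(cohort$exclusion_reason == "timeout"), " timeouts")

  analyzable <- cohort[!cohort$is_dummy & cohort$choice != "timeout", ]
  excl <- stage("exclude", exclude_slow_rts(analyzable))
  write_trials(excl$trials, out_path("trials_filtered.csv"), seed, hash)
  log_line(sprintf("exclude: kept %.1f%% (%d slow trials dropped)",
                   100 * excl$fraction_kept, excl$n_excluded))

  fits <- stage("fit", fit_participants(excl$trials, seed = seed + 1000L,
                                        control = ctrl))
  write_trials(fits, out_path("fits.csv"), seed, hash)
  log_line("fit: ", sum(!fits$degenerate), " cells fitted, ",
           sum(fits$degenerate), " degenerate")

  pars <- setNames(lapply(.numeral_types, function(tp)
    ddm_reference_params(config$experiment, tp)), .numeral_types)
  design <- build_design(config$experiment,
                         trials_per_pair_per_type =
                           config$trials_per_pair_per_type,
                         n_dummy = 0, seed = seed)
  set.seed(seed + 2000L)
  conf <- stage("confidence", simulate_confidence_table(
    pars, design, sims_per_distance = config$sims_per_distance,
    un_by_type = un_presets(config$experiment, config$un_mode)))
  write_trials(conf, out_path("confidence.csv"), seed, hash)
  log_line("confidence: ", nrow(conf), " simulated trials (un_mode=",
           config$un_mode, ")")

  props <- stage("properties",
                 confidence_signatures(excl$trials, proxy = "pressure_norm",
                                       n_bins = config$n_bins))
  log_line("properties: ", paste(names(props$passed), props$passed,
                                 sep = "=", collapse = ", "))

  mean_conf <- tapply(conf$confidence, conf$numeral_type, mean)
  param_means <- stats::aggregate(
    fits[!fits$degenerate, c("dr", "sym", "bo", "ic", "ndt")],
    by = list(numeral_type = fits$numeral_type[!fits$degenerate]), FUN = mean)

  summary <- list(
    seed = seed, config_hash = hash,
    n_trials = nrow(cohort), fraction_kept = excl$fraction_kept,
    fitted_param_means = param_means,
    properties_passed = as.list(props$passed),
    mean_confidence_by_type = as.list(mean_conf),
    conf_positive_minus_negative =
      unname(mean_conf["positive"] - mean_conf["negative"]),
    un_mode = config$un_mode)
  jsonlite::write_json(summary, out_path("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(config = config, cohort = cohort, filtered = excl$trials,
                 fits = fits, confidence = conf, properties = props,
                 summary = summary))
}

#' Parameter-recovery study at the reference values
#'
#' Simulates a full single-type session (72 trials at each of the ten
#' canonical distances by default) from the reference mean parameters of an
#' experiment and numeral type, refits all five parameters by maximum
#' likelihood, and repeats over seeds. This is the package's
#' self-consistency check: generating values and refits share the same
#' simulator and likelihood conventions. Timeouts are dropped but the
#' slow-RT exclusion is deliberately not applied here: truncating the slow
#' tail of a dataset whose generating process is known biases the drift
#' estimate upward, whereas the exclusion rule belongs in pipelines for
#' empirical data with genuine outliers.
#'
#' @param experiment,numeral_type Select the generating
#'   [ddm_reference_params()].
#' @param trials_per_distance Simulated trials per distance (default 72).
#' @param n_seeds Number of replicate recoveries (default 3).
#' @param seed Root seed; replicate i uses `seed + 100 * i`.
#' @param control A [fit_control()].
#' @return List with `truth` (named generating vector), `fits` (one row per
#'   seed) and `median` (per-parameter medians across seeds).
#' @export
recovery_study <- function(experiment = "exp1", numeral_type = "positive",
                           trials_per_distance = 72, n_seeds = 3, seed = 1L,
                           control = fit_control()) {
  truth <- ddm_reference_params(experiment, numeral_type)
  pairs <- canonical_pairs()
  design <- data.frame(
    log_distance = rep(pairs$log_distance, each = trials_per_distance))
  rows <- lapply(seq_len(n_seeds), function(i) {
    s <- seed + 100L * i
    trials <- simulate_trials(truth, design, seed = s)
    trials <- trials[trials$choice != "timeout", ]
    fit <- ddm_fit(trials, seed = s, control = control)
    cbind(data.frame(seed = s, n_trials = fit$n_trials,
                     nll = fit$nll, converged = fit$converged),
          as.data.frame(as.list(coef(fit))))
  })
  fits <- do.call(rbind, rows)
  med <- apply(fits[, c("DR", "SYM", "BO", "IC", "NDT")], 2, median)
  list(truth = c(DR = truth$dr, SYM = truth$sym, BO = truth$bo,
                 IC = truth$ic, NDT = truth$ndt),
       fits = fits, median = med)
}
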