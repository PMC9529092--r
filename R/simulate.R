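#' Simulation settings
#'
#' @param dt Euler-Maruyama step, seconds (default 1 ms).
#' @param deadline_s Response deadline, seconds; the accumulator is cut off
#'   at `deadline_s - NDT` and the trial recorded as a timeout.
#' @param continuity_correction Apply Siegmund's continuity correction: the
#'   discrete-time walk is absorbed at `BO - 0.5826 * sigma * sqrt(dt)` so
#'   that its first-passage statistics match the continuous-time diffusion
#'   with bound `BO` (which is what the closed-form oracles and the
#'   Crank-Nicolson likelihood describe).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.001, deadline_s = 3.0,
                       continuity_correction = TRUE) {
  if (dt <= 0) stop("dt must be > 0")
  if (deadline_s <= 0) stop("deadline_s must be > 0")
  structure(list(dt = dt, deadline_s = deadline_s,
                 continuity_correction = continuity_correction),
            class = "sim_config")
}

.effective_bound <- function(params, config) {
  b <- params$bo
  if (isTRUE(config$continuity_correction))
    b <- b - 0.5826 * params$noise_sigma * sqrt(config$dt)
  if (b <= 0) stop("bound too small for this dt")
  b
}

#' Simulate decision trials
#'
#' Forward-simulates the diffusion decision process for every row of a trial
#' design: the decision variable starts at a Uniform(-IC, IC) draw, moves
#' with drift `DR * log_distance^SYM` and unit diffusion noise, and is
#' absorbed at the first crossing of the symmetric bounds. The upper bound
#' codes the objectively correct option, so `choice == "upper"` iff the
#' response is correct. Trials whose accumulation outlasts the deadline are
#' recorded as timeouts.
#'
#' @param params A [ddm_params()] object.
#' @param design A trial table with columns `log_distance` (and optionally
#'   `is_dummy` etc., carried through), e.g. from [build_design()].
#' @param config A [sim_config()].
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @return The design with columns `choice` (`"upper"`, `"lower"`,
#'   `"timeout"`), `correct`, `rt` (s), `n_steps` and `dv_mean` appended.
#'   `dv_mean` is the arithmetic mean of the decision-variable samples after
#'   each step, up to and including the crossing sample; `n_steps` counts
#'   those samples.
#' @examples
#' p <- ddm_params(dr = 2.46, sym = 0.09, bo = 0.77, ic = 0.22, ndt = 0.41)
#' d <- build_design("exp1", 2, n_dummy = 0, seed = 1)
#' head(simulate_trials(p, d, seed = 1))
#' @export
simulate_trials <- function(params, design, config = sim_config(),
                            seed = NULL) {
  stopifnot(inherits(params, "ddm_params"))
  if (!is.null(seed)) set.seed(seed)
  if (config$deadline_s <= params$ndt)
    stop("deadline must exceed the non-decision time")
  drift <- drift_for_distance(params, design$log_distance)
  out <- sim_ddm_cpp(drift, .effective_bound(params, config), params$ic,
                     params$ndt, params$noise_sigma, config$dt,
                     config$deadline_s)
  res <- as.data.frame(design)
  res$choice <- c("lower", "timeout", "upper")[out$choice + 2L]
  res$correct <- out$choice == 1L
  res$correct[out$choice == 0L] <- NA
  res$rt <- out$rt
  res$n_steps <- out$n_steps
  res$dv_mean <- out$dv_mean
  res
}

#' Closed-form accuracy of the diffusion process
#'
#' For a diffusion starting at 0 (no starting-point jitter) with drift `v`,
#' noise `sigma` and symmetric absorbing bounds at `+/-b`, the probability of
#' absorption at the upper (correct) bound is
#' `1 / (1 + exp(-2 v b / sigma^2))`. Used as an independent oracle for the
#' simulator and the first-passage solver.
#'
#' @param drift Drift rate (may be negative).
#' @param bound Bound magnitude, > 0.
#' @param noise Diffusion noise, > 0.
#' @return Hit probability of the upper bound.
#' @examples
#' analytic_accuracy(2.05, 0.77)  # ~0.959
#' @export
analytic_accuracy <- function(drift, bound, noise = 1) {
  if (any(bound <= 0) || any(noise <= 0)) stop("bound and noise must be > 0")
  1 / (1 + exp(-2 * drift * bound / noise^2))
}

#' Closed-form mean decision time
#'
#' Mean first-passage time of the symmetric-bound diffusion started at 0:
#' `(b / v) * tanh(v b / sigma^2)`, with the zero-drift limit `b^2 / sigma^2`.
#'
#' @inheritParams analytic_accuracy
#' @return Mean decision time in seconds (excludes non-decision time).
#' @examples
#' analytic_mean_dt(2, 0.77)  # ~0.351
#' @export
analytic_mean_dt <- function(drift, bound, noise = 1) {
  if (any(bound <= 0) || any(noise <= 0)) stop("bound and noise must be > 0")
  ifelse(drift == 0, bound^2 / noise^2,
         (bound / drift) * tanh(drift * bound / noise^2))
}
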