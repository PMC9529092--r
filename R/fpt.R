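#' First-passage time densities of the decision process
#'
#' Numeric (Crank-Nicolson) solution of the forward Fokker-Planck equation
#' for the diffusion with drift `DR * log_distance^SYM`, unit noise, and
#' absorbing bounds at `+/-BO`, starting from Uniform(-IC, IC). Returns the
#' two defective first-passage densities over decision time - upper bound
#' (correct) and lower bound (error) - which form the backbone of the
#' choice/RT likelihood used in fitting.
#'
#' The absorbed probability in each time step is taken from the discrete
#' mass balance, so upper mass + lower mass + surviving mass equals the
#' initial mass to machine precision; the split between bounds follows the
#' diffusive boundary fluxes. Densities are reported at time-step midpoints.
#'
#' @param params A [ddm_params()] object.
#' @param log_distance A single logarithmic distance, > 0.
#' @param dt Time step of the solver, seconds; must be <= 5 ms.
#' @param horizon Solution horizon, seconds (at least the task deadline).
#' @param nx Number of interior space nodes (forced odd so that 0 is a node).
#' @return An object of class `fpt_density`: list with `time`, `upper`,
#'   `lower` (densities, 1/s), `survivor` (probability still diffusing at the
#'   horizon), `dt`, `nx`.
#' @examples
#' p <- ddm_params(dr = 2.05, sym = 0, bo = 0.77)
#' fp <- first_passage_density(p, 1)
#' sum(fp$upper) * fp$dt  # ~ analytic_accuracy(2.05, 0.77)
#' @export
first_passage_density <- function(params, log_distance, dt = 0.005,
                                  horizon = 3.0, nx = 121) {
  stopifnot(inherits(params, "ddm_params"))
  if (length(log_distance) != 1L) stop("log_distance must be scalar")
  if (dt > 0.005 + 1e-12) stop("solver grid step must be <= 5 ms")
  if (dt <= 0) stop("dt must be > 0")
  if (horizon < dt) stop("horizon too short")
  drift <- drift_for_distance(params, log_distance)
  out <- fpt_cn_cpp(drift, params$bo, params$ic, params$noise_sigma,
                    dt, horizon, as.integer(nx))
  structure(out, class = "fpt_density")
}

#' @export
print.fpt_density <- function(x, ...) {
  up <- sum(x$upper) * x$dt
  lo <- sum(x$lower) * x$dt
  cat(sprintf(
    "First-passage densities on [0, %.3g s] (dt = %.3g s, %d nodes)\n",
    max(x$time) + x$dt / 2, x$dt, x$nx))
  cat(sprintf("  P(upper) = %.4f  P(lower) = %.4f  survivor = %.2e\n",
              up, lo, x$survivor))
  invisible(x)
}
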