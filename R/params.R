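#' DDM parameter set
#'
#' Bundles the six model parameters of the numeral-comparison drift-diffusion
#' model. Diffusion noise is fixed at 1 evidence unit per sqrt(second): the
#' DDM's scale is unidentified unless one parameter is pinned, and noise is
#' never fitted here, so all fitted magnitudes are expressed in that
#' convention.
#'
#' @param dr Drift rate `DR` (> 0), evidence units per second at unit distance.
#' @param sym Symbolic compression exponent `SYM` in `[0, 1]`; the trial drift
#'   is `DR * log_distance^SYM`, so 0 cancels the distance effect and 1 scales
#'   drift by raw (log) distance.
#' @param bo Bound `BO` (> 0): absorbing thresholds sit at `+BO` and `-BO`.
#' @param ic Starting-point jitter half-width `IC` (>= 0): the accumulator
#'   starts at a Uniform(-IC, IC) draw. Must satisfy `IC < BO`.
#' @param ndt Non-decision time `NDT` (>= 0), seconds.
#' @param un Inference uncertainty `UN` (> 0): base standard deviation of the
#'   Bayesian inference on the mean decision variable; the posterior sd after
#'   `n` samples is `UN / sqrt(n)`. Not used in fitting; may be `NA` until a
#'   confidence readout is needed.
#' @param noise_sigma Diffusion noise, fixed at 1.
#'
#' @return An object of class `ddm_params` (a named list).
#' @examples
#' ddm_params(dr = 2.46, sym = 0.09, bo = 0.77, ic = 0.22, ndt = 0.41)
#' @export
ddm_params <- function(dr, sym, bo, ic = 0, ndt = 0, un = NA_real_,
                       noise_sigma = 1) {
  stopifnot(is.numeric(dr), is.numeric(sym), is.numeric(bo),
            is.numeric(ic), is.numeric(ndt))
  if (dr <= 0) stop("drift rate DR must be > 0")
  if (sym < 0 || sym > 1) stop("SYM must lie in [0, 1]")
  if (bo <= 0) stop("bound BO must be > 0")
  if (ic < 0) stop("IC must be >= 0")
  if (ic >= bo) stop("IC must be strictly smaller than BO")
  if (ndt < 0) stop("NDT must be >= 0")
  if (!is.na(un) && un <= 0) stop("UN must be > 0")
  if (noise_sigma <= 0) stop("noise_sigma must be > 0")
  structure(list(dr = dr, sym = sym, bo = bo, ic = ic, ndt = ndt,
                 un = un, noise_sigma = noise_sigma),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("DDM parameters (noise fixed at", x$noise_sigma, "):\n")
  cat(sprintf("  DR = %.3f  SYM = %.3f  BO = %.3f  IC = %.3f  NDT = %.3f s",
              x$dr, x$sym, x$bo, x$ic, x$ndt))
  if (!is.na(x$un)) cat(sprintf("  UN = %.3f", x$un))
  cat("\n")
  invisible(x)
}

#' Trial drift rate under distance compression
#'
#' The drift rate on a trial with logarithmic numerical distance `d` is
#' `DR * d^SYM`: easy (distant) pairs accrue evidence faster, and the
#' compression exponent `SYM` controls how strongly distance matters.
#'
#' @param params A [ddm_params()] object.
#' @param log_distance Logarithmic numerical distance(s), > 0.
#' @return Numeric vector of trial drift rates.
#' @examples
#' p <- ddm_params(dr = 2.46, sym = 0.09, bo = 0.77)
#' drift_for_distance(p, 0.134)
#' @export
drift_for_distance <- function(params, log_distance) {
  stopifnot(inherits(params, "ddm_params"))
  if (any(!is.finite(log_distance)) || any(log_distance <= 0))
    stop("log_distance must be finite and > 0")
  params$dr * log_distance^params$sym
}

#' Reference DDM parameters by experiment and numeral type
#'
#' Average per-participant fitted parameters (and their between-subject
#' standard deviations) for the three numeral-comparison experiments the
#' package models. These serve as defaults for the synthetic-cohort generator
#' and as generating values in parameter-recovery studies.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param numeral_type `"positive"`, `"negative"` or `"one_over"`
#'   (pairs of 1/n numerals).
#' @param what `"mean"` for the mean parameter vector, `"sd"` for the
#'   between-subject standard deviations.
#' @return For `what = "mean"`, a [ddm_params()] object (UN unset); for
#'   `what = "sd"`, a named numeric vector over `dr, sym, bo, ic, ndt`.
#' @examples
#' ddm_reference_params("exp1", "positive")
#' ddm_reference_params("exp1", "negative", what = "sd")
#' @export
ddm_reference_params <- function(experiment = c("exp1", "exp2", "exp3"),
                                 numeral_type = c("positive", "negative",
                                                  "one_over"),
                                 what = c("mean", "sd")) {
  experiment <- match.arg(experiment)
  numeral_type <- match.arg(numeral_type)
  what <- match.arg(what)
  tab <- .reference_param_table[[experiment]][[numeral_type]]
  if (what == "sd") return(tab$sd)
  m <- tab$mean
  ddm_params(dr = m[["dr"]], sym = m[["sym"]], bo = m[["bo"]],
             ic = m[["ic"]], ndt = m[["ndt"]])
}

.ref_row <- function(mean, sd) {
  nm <- c("dr", "sym", "bo", "ic", "ndt")
  list(mean = setNames(mean, nm), sd = setNames(sd, nm))
}

.reference_param_table <- list(
  exp1 = list(
    one_over = .ref_row(c(3.01, 0.22, 1.03, 0.32, 0.43),
                        c(0.88, 0.11, 0.65, 0.21, 0.09)),
    negative = .ref_row(c(2.56, 0.19, 0.92, 0.33, 0.43),
                        c(0.71, 0.10, 0.20, 0.18, 0.07)),
    positive = .ref_row(c(2.46, 0.09, 0.77, 0.22, 0.41),
                        c(0.77, 0.12, 0.13, 0.09, 0.06))
  ),
  exp2 = list(
    one_over = .ref_row(c(3.00, 0.14, 1.59, 0.37, 0.69),
                        c(1.04, 0.13, 1.77, 0.27, 0.20)),
    negative = .ref_row(c(2.79, 0.14, 1.32, 0.45, 0.72),
                        c(0.85, 0.13, 0.77, 0.23, 0.16)),
    positive = .ref_row(c(2.65, 0.09, 1.20, 0.30, 0.67),
                        c(0.91, 0.14, 0.76, 0.18, 0.16))
  ),
  exp3 = list(
    one_over = .ref_row(c(2.93, 0.16, 1.27, 0.40, 0.67),
                        c(0.85, 0.12, 0.61, 0.27, 0.12)),
    negative = .ref_row(c(2.49, 0.14, 1.12, 0.49, 0.71),
                        c(0.61, 0.14, 0.26, 0.23, 0.14)),
    positive = .ref_row(c(2.31, 0.11, 0.88, 0.23, 0.66),
                        c(0.55, 0.12, 0.15, 0.10, 0.08))
  )
)

#' Inference-uncertainty (UN) presets
#'
#' The confidence readout divides `UN` by the square root of the number of
#' accumulated samples; a lower `UN` means each sample reduces uncertainty
#' faster. `UN` never enters the fitting procedure, so it is exposed as a
#' free configuration value with two presets per experiment: `"equal"` (one
#' value shared by all numeral types) and `"different"` (positive numerals
#' get a lower `UN`, i.e. more information per sample).
#'
#' @inheritParams ddm_reference_params
#' @param mode `"equal"` or `"different"`.
#' @return Named numeric vector with elements `positive`, `negative`,
#'   `one_over`.
#' @examples
#' un_presets("exp1", "equal")
#' un_presets("exp1", "different")
#' @export
un_presets <- function(experiment = c("exp1", "exp2", "exp3"),
                       mode = c("equal", "different")) {
  experiment <- match.arg(experiment)
  mode <- match.arg(mode)
  presets <- list(
    exp1 = list(equal = c(2.5, 2.5, 2.5), different = c(1.65, 2.4, 2.4)),
    exp2 = list(equal = c(4.5, 4.5, 4.5), different = c(3.5, 4.3, 4.3)),
    exp3 = list(equal = c(4.5, 4.5, 4.5), different = c(2.5, 4.0, 4.5))
  )
  setNames(presets[[experiment]][[mode]],
           c("positive", "negative", "one_over"))
}
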