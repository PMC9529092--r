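#' Parameter bounds for fitting
#'
#' Box constraints for the five fitted parameters. The starting-point jitter
#' is parameterized as a fraction of the bound (`IC = ic_frac * BO`) so that
#' the starting distribution always stays strictly inside the bounds; its
#' upper limit of 0.95 corresponds to `IC <= 0.95 * BO`.
#'
#' @param dr,sym,bo,ic_frac,ndt Length-2 numeric `(low, high)` pairs.
#' @return A list of class `fit_bounds`.
#' @export
fit_bounds <- function(dr = c(0.2, 8), sym = c(0, 1), bo = c(0.3, 4),
                       ic_frac = c(0, 0.95), ndt = c(0.05, 1.5)) {
  b <- list(dr = dr, sym = sym, bo = bo, ic_frac = ic_frac, ndt = ndt)
  for (nm in names(b)) {
    if (length(b[[nm]]) != 2 || b[[nm]][1] >= b[[nm]][2])
      stop("bounds for ", nm, " must be (low, high) with low < high")
  }
  if (sym[1] < 0 || sym[2] > 1) stop("SYM bounds must lie within [0, 1]")
  if (ic_frac[1] < 0 || ic_frac[2] >= 1)
    stop("ic_frac bounds must lie within [0, 1)")
  structure(b, class = "fit_bounds")
}

#' Fitting control settings
#'
#' @param de_popsize Differential-evolution population multiplier (population
#'   is `de_popsize * n_parameters`).
#' @param de_maxiter Maximum DE generations.
#' @param de_tol DE convergence tolerance on the spread of population
#'   objective values.
#' @param de_f,de_cr DE mutation weight and crossover probability.
#' @param polish Run a Nelder-Mead polish from the DE optimum.
#' @param fpt_dt,fpt_nx Grid of the Crank-Nicolson likelihood solver
#'   (seconds; interior nodes).
#' @param min_trials Minimum usable (non-timeout) trials required to fit.
#' @param density_floor Floor applied to first-passage densities so that
#'   infeasible response times (e.g. below the candidate non-decision time)
#'   contribute a large but finite penalty instead of an infinite one.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(de_popsize = 15, de_maxiter = 60, de_tol = 1e-6,
                        de_f = 0.8, de_cr = 0.9, polish = TRUE,
                        fpt_dt = 0.005, fpt_nx = 121, min_trials = 50,
                        density_floor = 1e-10) {
  structure(list(de_popsize = de_popsize, de_maxiter = de_maxiter,
                 de_tol = de_tol, de_f = de_f, de_cr = de_cr,
                 polish = polish, fpt_dt = fpt_dt, fpt_nx = fpt_nx,
                 min_trials = min_trials, density_floor = density_floor),
            class = "fit_control")
}

# group trials by distance once, so the likelihood loop touches no data frames
.split_trials <- function(trials) {
  dists <- sort(unique(trials$log_distance))
  horizon <- max(3.0, max(trials$rt))
  list(
    horizon = horizon,
    groups = lapply(dists, function(d) {
      g <- trials[trials$log_distance == d, , drop = FALSE]
      list(dist = d, rt_correct = g$rt[g$correct], rt_error = g$rt[!g$correct])
    })
  )
}

.negloglik_split <- function(theta, split, control) {
  dr <- theta[1]; sym <- theta[2]; bo <- theta[3]
  ic <- theta[4] * bo; ndt <- theta[5]
  floor_d <- control$density_floor
  nll <- 0
  for (g in split$groups) {
    v <- dr * g$dist^sym
    fp <- fpt_cn_cpp(v, bo, ic, 1.0, control$fpt_dt, split$horizon,
                     control$fpt_nx)
    for (side in c("rt_correct", "rt_error")) {
      rts <- g[[side]]
      if (length(rts) == 0) next
      dens_curve <- if (side == "rt_correct") fp$upper else fp$lower
      dens <- approx(fp$time, dens_curve, xout = rts - ndt, rule = 1)$y
      dens[is.na(dens)] <- 0
      nll <- nll - sum(log(pmax(dens, floor_d)))
    }
  }
  nll
}

.prepare_fit_trials <- function(trials) {
  if (is.null(trials$correct) && !is.null(trials$choice))
    trials$correct <- trials$choice == "upper"
  need <- c("rt", "correct", "log_distance")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trials lack column(s): ", paste(miss, collapse = ", "))
  if (!is.null(trials$is_dummy)) trials <- trials[!trials$is_dummy, ]
  if (!is.null(trials$choice)) trials <- trials[trials$choice != "timeout", ]
  trials <- trials[!is.na(trials$correct) & !is.na(trials$rt), ]
  trials
}

#' Joint choice/response-time negative log-likelihood
#'
#' Likelihood of observed choices and response times under the DDM, built
#' from the numeric first-passage densities: correct responses are scored
#' against the upper-bound density and errors against the lower-bound
#' density, each evaluated at `rt - NDT`. Densities below the floor (or
#' response times below the candidate non-decision time) contribute
#' `-log(density_floor)`.
#'
#' @param params A [ddm_params()] object.
#' @param trials Trial table with `rt`, `log_distance` and `correct` (or
#'   `choice`); timeouts and dummy trials are removed.
#' @param control A [fit_control()] (solver grid and density floor).
#' @return The negative log-likelihood (scalar).
#' @export
negloglik <- function(params, trials, control = fit_control()) {
  stopifnot(inherits(params, "ddm_params"))
  trials <- .prepare_fit_trials(trials)
  if (nrow(trials) == 0) stop("no usable trials")
  split <- .split_trials(trials)
  theta <- c(params$dr, params$sym, params$bo,
             if (params$bo > 0) params$ic / params$bo else 0, params$ndt)
  .negloglik_split(theta, split, control)
}

# seeded differential evolution (rand/1/bin) under box constraints
.de_optimize <- function(fn, lower, upper, popsize = 15, maxiter = 60,
                         tol = 1e-6, f = 0.8, cr = 0.9) {
  d <- length(lower)
  np <- popsize * d
  pop <- sapply(seq_len(d), function(j) runif(np, lower[j], upper[j]))
  fit <- apply(pop, 1, fn)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(maxiter)) {
    for (i in seq_len(np)) {
      r <- sample(setdiff(seq_len(np), i), 3)
      mutant <- pop[r[1], ] + f * (pop[r[2], ] - pop[r[3], ])
      mutant <- pmin(pmax(mutant, lower), upper)
      cross <- runif(d) < cr
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      ft <- fn(trial)
      if (ft <= fit[i]) {
        pop[i, ] <- trial
        fit[i] <- ft
      }
    }
    if (sd(fit) <= tol * abs(mean(fit)) + 1e-12) {
      converged <- TRUE
      break
    }
  }
  best <- which.min(fit)
  list(par = pop[best, ], value = fit[best], iterations = iter,
       converged = converged)
}

#' Fit the drift-diffusion model to one participant's trials
#'
#' Maximum-likelihood estimation of the five decision parameters (DR, SYM,
#' BO, IC, NDT) from trial-level choices and response times of a single
#' participant and numeral type, using the Crank-Nicolson first-passage
#' likelihood. Optimization is seeded differential evolution over the
#' [fit_bounds()] box followed by a Nelder-Mead polish, so fits are
#' reproducible given (data, bounds, seed). The inference uncertainty UN
#' does not enter the likelihood and is not fitted.
#'
#' Slow response times should be excluded beforehand (see
#' [exclude_slow_rts()]); timeout and dummy trials are dropped
#' automatically.
#'
#' @param trials Trial table with columns `rt` (seconds), `log_distance`,
#'   and `correct` or `choice`.
#' @param bounds A [fit_bounds()] object.
#' @param seed Integer seed for the optimizer.
#' @param control A [fit_control()] object.
#' @return An object of class `ddm_fit` with methods `print`, `summary`,
#'   `coef`, `logLik`, `predict`, `simulate`, `residuals` and `plot`.
#' @examples
#' \donttest{
#' truth <- ddm_reference_params("exp1", "positive")
#' d <- build_design("exp1", 8, n_dummy = 0, seed = 1)
#' trials <- simulate_trials(truth, d, seed = 1)
#' fit <- ddm_fit(trials, seed = 1,
#'                control = fit_control(de_maxiter = 20, min_trials = 20))
#' coef(fit)
#' }
#' @export
ddm_fit <- function(trials, bounds = fit_bounds(), seed = 1L,
                    control = fit_control()) {
  trials <- .prepare_fit_trials(trials)
  if (nrow(trials) == 0) stop("insufficient data: no usable trials")
  if (nrow(trials) < control$min_trials)
    stop("insufficient data: ", nrow(trials), " usable trials (need >= ",
         control$min_trials, ")")
  split <- .split_trials(trials)
  lower <- c(bounds$dr[1], bounds$sym[1], bounds$bo[1], bounds$ic_frac[1],
             bounds$ndt[1])
  upper <- c(bounds$dr[2], bounds$sym[2], bounds$bo[2], bounds$ic_frac[2],
             bounds$ndt[2])
  obj <- function(theta) .negloglik_split(theta, split, control)

  set.seed(seed)
  de <- .de_optimize(obj, lower, upper, popsize = control$de_popsize,
                     maxiter = control$de_maxiter, tol = control$de_tol,
                     f = control$de_f, cr = control$de_cr)
  theta <- de$par
  nll <- de$value
  converged <- de$converged
  if (isTRUE(control$polish)) {
    clamped <- function(th) obj(pmin(pmax(th, lower), upper))
    nm <- optim(theta, clamped, method = "Nelder-Mead",
                control = list(maxit = 400, reltol = 1e-8))
    if (nm$value <= nll) {
      theta <- pmin(pmax(nm$par, lower), upper)
      nll <- nm$value
      converged <- converged || nm$convergence == 0
    }
  }

  params <- ddm_params(dr = theta[1], sym = theta[2], bo = theta[3],
                       ic = theta[4] * theta[3], ndt = theta[5])
  structure(list(params = params, nll = nll, n_trials = nrow(trials),
                 converged = converged, seed = seed, bounds = bounds,
                 control = control, trials = trials,
                 de_iterations = de$iterations, call = match.call()),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("Drift-diffusion model fit (", x$n_trials, " trials)\n", sep = "")
  print(x$params)
  cat(sprintf("  -logLik = %.2f  converged = %s  seed = %d\n",
              x$nll, x$converged, x$seed))
  invisible(x)
}

#' @export
coef.ddm_fit <- function(object, ...) {
  with(object$params, c(DR = dr, SYM = sym, BO = bo, IC = ic, NDT = ndt))
}

#' @export
logLik.ddm_fit <- function(object, ...) {
  structure(-object$nll, df = 5L, nobs = object$n_trials, class = "logLik")
}

#' Model predictions by numerical distance
#'
#' Predicted response accuracy and mean response time at given logarithmic
#' distances, computed from the first-passage densities of the fitted
#' parameters (accuracy = upper-bound mass over total absorbed mass; mean
#' RT = NDT + mean decision time over both bounds).
#'
#' @param object A `ddm_fit`.
#' @param newdata Optional data frame with a `log_distance` column; defaults
#'   to the distances present in the fitted data.
#' @param ... Unused.
#' @return Data frame with `log_distance`, `accuracy`, `mean_rt`.
#' @export
predict.ddm_fit <- function(object, newdata = NULL, ...) {
  dists <- if (is.null(newdata)) sort(unique(object$trials$log_distance))
           else newdata$log_distance
  res <- lapply(dists, function(d) {
    fp <- first_passage_density(object$params, d,
                                dt = object$control$fpt_dt,
                                horizon = max(3, max(object$trials$rt)),
                                nx = object$control$fpt_nx)
    up <- sum(fp$upper) * fp$dt
    lo <- sum(fp$lower) * fp$dt
    mdt <- sum(fp$time * (fp$upper + fp$lower)) * fp$dt / (up + lo)
    data.frame(log_distance = d, accuracy = up / (up + lo),
               mean_rt = object$params$ndt + mdt)
  })
  do.call(rbind, res)
}

#' @export
residuals.ddm_fit <- function(object, ...) {
  pred <- predict(object)
  obs <- tapply(object$trials$correct, object$trials$log_distance, mean)
  pred$observed <- as.numeric(obs[as.character(pred$log_distance)])
  pred$residual <- pred$observed - pred$accuracy
  pred[, c("log_distance", "observed", "accuracy", "residual")]
}

#' Simulate trials from a fitted model
#'
#' @param object A `ddm_fit`.
#' @param nsim Number of simulated datasets.
#' @param seed Optional seed.
#' @param design Trial design to simulate (defaults to the fitted trials'
#'   distances, one trial per observed row).
#' @param ... Unused.
#' @return A data frame (`nsim = 1`) or list of data frames.
#' @export
simulate.ddm_fit <- function(object, nsim = 1, seed = NULL, design = NULL,
                             ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(design))
    design <- data.frame(log_distance = object$trials$log_distance)
  sims <- lapply(seq_len(nsim), function(i) simulate_trials(
    object$params, design, sim_config()))
  if (nsim == 1) sims[[1]] else sims
}

#' @export
summary.ddm_fit <- function(object, ...) {
  pred <- predict(object)
  obs_acc <- tapply(object$trials$correct, object$trials$log_distance, mean)
  obs_rt <- tapply(object$trials$rt, object$trials$log_distance, mean)
  n <- tapply(object$trials$rt, object$trials$log_distance, length)
  tab <- data.frame(log_distance = pred$log_distance,
                    n = as.integer(n[as.character(pred$log_distance)]),
                    obs_accuracy = as.numeric(obs_acc),
                    pred_accuracy = pred$accuracy,
                    obs_mean_rt = as.numeric(obs_rt),
                    pred_mean_rt = pred$mean_rt)
  structure(list(fit = object, by_distance = tab), class = "summary.ddm_fit")
}

#' @export
print.summary.ddm_fit <- function(x, ...) {
  print(x$fit)
  cat("\nBy numerical distance:\n")
  print(x$by_distance, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
plot.ddm_fit <- function(x, ...) {
  s <- summary(x)$by_distance
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(s$log_distance, s$obs_accuracy, ylim = range(c(s$obs_accuracy,
       s$pred_accuracy)), xlab = "log distance", ylab = "accuracy",
       pch = 19, ...)
  graphics::lines(s$log_distance, s$pred_accuracy, col = "red3")
  plot(s$log_distance, s$obs_mean_rt, ylim = range(c(s$obs_mean_rt,
       s$pred_mean_rt)), xlab = "log distance", ylab = "mean RT (s)",
       pch = 19, ...)
  graphics::lines(s$log_distance, s$pred_mean_rt, col = "red3")
  invisible(x)
}

#' Fit every participant-by-numeral-type cell of a trial table
#'
#' Applies [ddm_fit()] separately to each subject and numeral type, the way
#' the individual fits behind the reference parameter tables were obtained.
#' Degenerate cells - accuracy below 55% or more than 15% timeouts, the kind
#' of performance that gets a participant excluded from single-digit
#' comparison studies - are flagged and not fitted.
#'
#' @param trials Trial table with `subject`, `numeral_type`, `rt`,
#'   `log_distance`, `correct`/`choice` columns.
#' @param bounds,control Passed to [ddm_fit()].
#' @param seed Root seed; each cell gets a derived seed.
#' @return Data frame with one row per subject x type: parameter estimates,
#'   `nll`, `n_trials`, `converged`, `degenerate`.
#' @export
fit_participants <- function(trials, bounds = fit_bounds(), seed = 1L,
                             control = fit_control()) {
  stopifnot(all(c("subject", "numeral_type") %in% names(trials)))
  if (!is.null(trials$is_dummy)) trials <- trials[!trials$is_dummy, ]
  cells <- unique(trials[, c("subject", "numeral_type")])
  cells <- cells[order(cells$subject, cells$numeral_type), ]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    g <- trials[trials$subject == cells$subject[i] &
                trials$numeral_type == cells$numeral_type[i], ]
    n_timeout <- if (!is.null(g$choice)) sum(g$choice == "timeout") else 0
    usable <- .prepare_fit_trials(g)
    acc <- mean(usable$correct)
    degenerate <- (nrow(usable) > 0 && acc < 0.55) ||
      (nrow(g) > 0 && n_timeout / nrow(g) > 0.15)
    row <- data.frame(subject = cells$subject[i],
                      numeral_type = cells$numeral_type[i],
                      dr = NA_real_, sym = NA_real_, bo = NA_real_,
                      ic = NA_real_, ndt = NA_real_, nll = NA_real_,
                      n_trials = nrow(usable), converged = NA,
                      degenerate = degenerate)
    if (!degenerate) {
      fit <- ddm_fit(usable, bounds = bounds, seed = seed + i,
                     control = control)
      cf <- coef(fit)
      row[, c("dr", "sym", "bo", "ic", "ndt")] <- as.list(unname(cf))
      row$nll <- fit$nll
      row$converged <- fit$converged
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorts the raw p-values ascending and adjusts the i-th smallest as
#' `1 - (1 - p_(i))^(m - i + 1)`, enforcing monotone non-decreasing adjusted
#' values, where `m` is the total number of comparisons in the family.
#'
#' @param p Raw p-values.
#' @param m Family size (default `length(p)`; may be larger when the family
#'   spans more tests than supplied here).
#' @return Adjusted p-values in the original order.
#' @examples
#' holm_sidak(c(0.01, 0.03, 0.04))  # 0.0297 0.0591 0.0591
#' @export
holm_sidak <- function(p, m = length(p)) {
  if (m < length(p)) stop("family size m cannot be smaller than length(p)")
  ord <- order(p)
  ps <- p[ord]
  adj <- 1 - (1 - ps)^(m - seq_along(ps) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(length(p))
  out[ord] <- adj
  out
}

#' Compare fitted parameters between two conditions
#'
#' For paired per-subject fits from two numeral types, tests whether each
#' decision parameter changed by running a one-sample t-test of the absolute
#' within-subject difference `|theta_a - theta_b|` against zero, with
#' Holm-Sidak correction across parameters. Absolute differences are used
#' when no directional hypothesis is assumed.
#'
#' @param fits_a,fits_b Data frames as returned by [fit_participants()]
#'   (or any frames with `subject` and the parameter columns), paired by
#'   subject.
#' @param n_comparisons Family size for the correction (e.g. 15 when five
#'   parameters are compared across three type pairs); defaults to the
#'   number of parameters tested here.
#' @return Data frame with `parameter`, `mean_abs_diff`, `t`, `df`, `p`,
#'   `p_adjusted`, `degenerate` (TRUE when the differences are constant and
#'   the test is undefined).
#' @export
compare_params <- function(fits_a, fits_b, n_comparisons = NULL) {
  pars <- c("dr", "sym", "bo", "ic", "ndt")
  stopifnot(all(c("subject", pars) %in% names(fits_a)),
            all(c("subject", pars) %in% names(fits_b)))
  m <- merge(fits_a[, c("subject", pars)], fits_b[, c("subject", pars)],
             by = "subject", suffixes = c("_a", "_b"))
  if (nrow(m) != nrow(fits_a) || nrow(m) != nrow(fits_b))
    stop("fits are not paired by subject")
  rows <- lapply(pars, function(pp) {
    d <- abs(m[[paste0(pp, "_a")]] - m[[paste0(pp, "_b")]])
    d <- d[!is.na(d)]
    if (length(d) < 2 || sd(d) == 0) {
      data.frame(parameter = pp, mean_abs_diff = mean(d), t = NA_real_,
                 df = NA_real_, p = NA_real_, degenerate = TRUE)
    } else {
      tt <- t.test(d, mu = 0)
      data.frame(parameter = pp, mean_abs_diff = mean(d),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, degenerate = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  ok <- !is.na(res$p)
  if (is.null(n_comparisons)) n_comparisons <- sum(ok)
  res$p_adjusted <- NA_real_
  if (any(ok)) res$p_adjusted[ok] <- holm_sidak(res$p[ok], m = n_comparisons)
  res
}
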