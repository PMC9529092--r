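#' Logarithmic numerical distance
#'
#' Distance between two numerals on the logarithmic mental number line:
#' `log(num_a) - log(num_b)` (natural logs). This is the decision-relevant
#' difficulty of a comparison trial.
#'
#' @param num_a,num_b Positive integers (or vectors), `num_a >= num_b`.
#' @return `log(num_a) - log(num_b)`, always >= 0.
#' @examples
#' log_distance(8, 7)   # 0.134
#' log_distance(8, 2)   # 1.386
#' @export
log_distance <- function(num_a, num_b) {
  if (any(!is.finite(num_a)) || any(!is.finite(num_b)) ||
      any(num_a <= 0) || any(num_b <= 0))
    stop("numerals must be positive")
  if (any(num_a < num_b)) stop("num_a must be >= num_b")
  log(num_a) - log(num_b)
}

#' The ten canonical digit pairs
#'
#' Exp. 1 and 2 use ten exemplar pairs drawn from the digits {2, 3, 5, 7, 8},
#' one per distinct logarithmic distance (in log space every pair of these
#' digits has a unique distance; 4 and 6 are dropped for that reason, and 1
#' and 9 are excluded so the extreme digits cannot serve as trivial anchors).
#'
#' @return A data frame with columns `num_a`, `num_b`, `log_distance`,
#'   ordered by increasing distance.
#' @examples
#' canonical_pairs()
#' @export
canonical_pairs <- function() {
  pairs <- data.frame(
    num_a = c(8, 7, 3, 8, 5, 7, 5, 8, 7, 8),
    num_b = c(7, 5, 2, 5, 3, 3, 2, 3, 2, 2)
  )
  pairs$log_distance <- log_distance(pairs$num_a, pairs$num_b)
  pairs
}

.numeral_types <- c("positive", "negative", "one_over")

#' Build an experimental trial design
#'
#' Constructs the trial list for one participant-session: numeral pairs at
#' each logarithmic distance, crossed with the three numeral types (positive,
#' negative, 1/n), plus dummy filler trials that mask the design and are
#' flagged out of every analysis. The larger displayed value is placed left
#' or right with probability 0.5, and trial order is shuffled.
#'
#' For `exp1`/`exp2` the non-dummy pairs are exactly the ten
#' [canonical_pairs()]; defaults give 10 pairs x 3 types x 24 = 720 non-dummy
#' trials plus 150 dummies for `exp1` (i.e. 870 in total), and 12 repeats
#' plus 75 dummies for `exp2`. For `exp3` pairs are sampled uniformly from
#' distinct digits 2-8 (`10 * trials_per_pair_per_type` trials per type, so
#' counts line up with the other designs). Dummy trials use digits 2-15 and
#' may include 9 and double digits; non-dummy pairs never contain 1 or 9.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param trials_per_pair_per_type Repeats of each pair within each numeral
#'   type (>= 1).
#' @param n_dummy Number of dummy trials (default 150 for exp1, 75 for
#'   exp2/exp3).
#' @param seed Integer seed for side randomization, order shuffling and
#'   (exp3) pair sampling.
#' @param deadline_s Response deadline in seconds; trials slower than this
#'   time out.
#' @return A data frame of class `ddm_design` with columns `trial_index`,
#'   `numeral_type`, `num_a`, `num_b`, `log_distance`, `is_dummy`,
#'   `correct_side`; the deadline and experiment label are attached as
#'   attributes.
#' @examples
#' d <- build_design("exp1", seed = 1)
#' sum(!d$is_dummy)  # 720
#' @export
build_design <- function(experiment = c("exp1", "exp2", "exp3"),
                         trials_per_pair_per_type = NULL,
                         n_dummy = NULL, seed = 1, deadline_s = 3.0) {
  experiment <- match.arg(experiment)
  if (is.null(trials_per_pair_per_type))
    trials_per_pair_per_type <- switch(experiment, exp1 = 24, exp2 = 12,
                                       exp3 = 12)
  if (is.null(n_dummy))
    n_dummy <- switch(experiment, exp1 = 150, exp2 = 75, exp3 = 75)
  if (!is.numeric(trials_per_pair_per_type) || trials_per_pair_per_type < 1)
    stop("trials_per_pair_per_type must be >= 1")
  if (n_dummy < 0) stop("n_dummy must be >= 0")

  set.seed(seed)
  if (experiment %in% c("exp1", "exp2")) {
    base <- canonical_pairs()
    idx <- rep(seq_len(nrow(base)), each = trials_per_pair_per_type)
    per_type <- base[idx, , drop = FALSE]
  } else {
    n_per_type <- 10L * as.integer(trials_per_pair_per_type)
    a <- sample(2:8, n_per_type, replace = TRUE)
    b <- sample(2:8, n_per_type, replace = TRUE)
    while (any(a == b)) {            # no ties: resample equal digits
      eq <- a == b
      b[eq] <- sample(2:8, sum(eq), replace = TRUE)
    }
    per_type <- data.frame(num_a = pmax(a, b), num_b = pmin(a, b))
    per_type$log_distance <- log_distance(per_type$num_a, per_type$num_b)
  }

  main <- do.call(rbind, lapply(.numeral_types, function(tp) {
    cbind(data.frame(numeral_type = tp), per_type)
  }))
  main$is_dummy <- FALSE

  if (n_dummy > 0) {
    da <- sample(2:15, n_dummy, replace = TRUE)
    db <- sample(2:15, n_dummy, replace = TRUE)
    while (any(da == db)) {
      eq <- da == db
      db[eq] <- sample(2:15, sum(eq), replace = TRUE)
    }
    dummy <- data.frame(
      numeral_type = sample(.numeral_types, n_dummy, replace = TRUE),
      num_a = pmax(da, db), num_b = pmin(da, db),
      log_distance = log_distance(pmax(da, db), pmin(da, db)),
      is_dummy = TRUE
    )
    main <- rbind(main, dummy)
  }

  main <- main[sample.int(nrow(main)), , drop = FALSE]
  main$trial_index <- seq_len(nrow(main))
  main$correct_side <- sample(c("left", "right"), nrow(main), replace = TRUE)
  rownames(main) <- NULL
  main <- main[, c("trial_index", "numeral_type", "num_a", "num_b",
                   "log_distance", "is_dummy", "correct_side")]
  attr(main, "experiment") <- experiment
  attr(main, "deadline_s") <- deadline_s
  attr(main, "seed") <- seed
  class(main) <- c("ddm_design", "data.frame")
  main
}

#' Displayed numerals for a design row
#'
#' Maps a pair and numeral type to what the participant actually sees: for
#' positive pairs the larger displayed value is `num_a`; for negative and
#' 1/n pairs the inversion flips the order, so the numeral derived from
#' `num_b` (`-num_b` or `1/num_b`) is the larger displayed value.
#'
#' @param design A `ddm_design` data frame (or any trial table with
#'   `numeral_type`, `num_a`, `num_b`).
#' @return A data frame with character columns `shown_large`, `shown_small`.
#' @examples
#' displayed_numerals(build_design("exp1", 1, n_dummy = 0, seed = 1)[1:3, ])
#' @export
displayed_numerals <- function(design) {
  stopifnot(all(c("numeral_type", "num_a", "num_b") %in% names(design)))
  lab <- function(x, tp) switch(tp, positive = as.character(x),
                                negative = paste0("-", x),
                                one_over = paste0("1/", x),
                                stop("unknown numeral_type: ", tp))
  large <- character(nrow(design)); small <- character(nrow(design))
  for (i in seq_len(nrow(design))) {
    tp <- design$numeral_type[i]
    if (tp == "positive") {
      large[i] <- lab(design$num_a[i], tp); small[i] <- lab(design$num_b[i], tp)
    } else {
      large[i] <- lab(design$num_b[i], tp); small[i] <- lab(design$num_a[i], tp)
    }
  }
  data.frame(shown_large = large, shown_small = small)
}
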