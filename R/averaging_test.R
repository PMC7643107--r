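# The "averaging test": bisection refinement of a focusing threshold.
# A bracket (low, high) in um is known to contain the true threshold; the
# midpoint diameter is tested, its replicated highest particle-recovery
# rate (hPRR) is compared against a well-focused reference by a one-sided
# Welch t-test, and the bracket is narrowed accordingly until its width
# falls below a tolerance. This module works in micrometres, the natural
# unit of the measurements.

#' Replicated hPRR measurement at one test diameter
#'
#' @param test_diameter diameter tested (um).
#' @param replicate_hprrs numeric vector of highest particle-recovery
#'   rates (percent, in \[0, 100\]), one per independent experiment;
#'   triplicates are typical, two is the minimum for a statistical
#'   comparison.
#' @param outlet index of the outlet where the highest PRR was observed.
#' @return an object of class `prr_measurement`.
#' @export
prr_measurement <- function(test_diameter, replicate_hprrs, outlet = NA_integer_) {
  if (!is.numeric(replicate_hprrs) || length(replicate_hprrs) < 1L) {
    stop("replicate_hprrs must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(replicate_hprrs < 0 | replicate_hprrs > 100)) {
    stop("hPRR replicates must lie in [0, 100] percent", call. = FALSE)
  }
  structure(list(test_diameter = test_diameter,
                 replicate_hprrs = as.numeric(replicate_hprrs),
                 outlet = outlet),
            class = "prr_measurement")
}

#' @export
print.prr_measurement <- function(x, ...) {
  cat(sprintf("hPRR at %.1f um: %.1f +/- %.1f %% (n = %d%s)\n",
              x$test_diameter, mean(x$replicate_hprrs),
              stats::sd(x$replicate_hprrs), length(x$replicate_hprrs),
              if (is.na(x$outlet)) "" else sprintf(", outlet %d", x$outlet)))
  invisible(x)
}

#' Compare a test hPRR against a reference hPRR
#'
#' One-sided Welch two-sample t-test of H1: mean(test) < mean(reference).
#' p < alpha declares the test diameter significantly less focused
#' (`"lower"`); otherwise the two are statistically indistinguishable
#' (`"same"`). Identical replicate sets give p = 0.5. When both samples
#' are exactly constant the t statistic degenerates; the decision then
#' falls back to the sign of the mean difference (p reported as 0 or 0.5),
#' which makes deterministic oracles usable in the bisection.
#'
#' @param test a [prr_measurement()] at the candidate diameter.
#' @param reference a [prr_measurement()] at a diameter known to focus
#'   well.
#' @param alpha significance level, default 0.05.
#' @return list with `decision` (`"same"` or `"lower"`), `p_value`,
#'   `statistic` and `df`.
#' @export
compare_hprr <- function(test, reference, alpha = 0.05) {
  stopifnot(inherits(test, "prr_measurement"),
            inherits(reference, "prr_measurement"))
  x <- test$replicate_hprrs
  y <- reference$replicate_hprrs
  if (length(x) < 2L || length(y) < 2L) {
    stop("insufficient replicates: both measurements need >= 2", call. = FALSE)
  }
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  delta <- mean(x) - mean(y)
  if (vx + vy == 0) {
    # degenerate (zero-variance) samples: decide by the mean difference
    p <- if (delta < 0) 0 else 0.5
    res <- list(statistic = if (delta < 0) -Inf else 0, df = NA_real_,
                p_value = p)
  } else {
    tt <- stats::t.test(x, y, alternative = "less", var.equal = FALSE)
    res <- list(statistic = unname(tt$statistic),
                df = unname(tt$parameter), p_value = tt$p.value)
  }
  res$decision <- if (res$p_value < alpha) "lower" else "same"
  res[c("decision", "p_value", "statistic", "df")]
}

#' One bisection step of the averaging test
#'
#' Given the current bracket and the decision at its midpoint m:
#' `"same"` (the midpoint focuses as well as the reference) means the true
#' threshold is at or below m, so the bracket becomes (low, m);
#' `"lower"` means the threshold lies above m, giving (m, high).
#'
#' @param bracket numeric length-2, (low, high) in um with low < high.
#' @param decision `"same"` or `"lower"`.
#' @param midpoint midpoint actually tested; defaults to
#'   `(low + high) / 2`. Supplying it lets rounded test diameters carry
#'   into the next bracket.
#' @return the narrowed bracket, numeric length-2.
#' @export
averaging_test_step <- function(bracket, decision,
                                midpoint = mean(bracket)) {
  if (length(bracket) != 2L || bracket[1] >= bracket[2]) {
    stop("invalid bracket: need low < high", call. = FALSE)
  }
  decision <- match.arg(decision, c("same", "lower"))
  if (decision == "same") c(bracket[1], midpoint) else c(midpoint, bracket[2])
}

# truncate to 0.1 um, the reporting convention for test diameters
# (15.75 -> 15.7); epsilon guards against 16.1 * 10 = 160.999...
.trunc_um <- function(x) floor(x * 10 + 1e-9) / 10

#' Run the full averaging test
#'
#' Repeats midpoint-measure-compare-narrow until the bracket width is at
#' most `tol`. The proposed threshold is the final bracket's upper bound:
#' every diameter at or above it has been shown to focus like the
#' reference, and the residual overestimation is below `tol`.
#'
#' @param low,high initial bracket in um (e.g. the TM2 and TM1
#'   predictions); `low < high`.
#' @param oracle function taking a diameter (um) and returning a
#'   [prr_measurement()] for that diameter — replicated experiments, a
#'   simulator, or a lookup into recorded data.
#' @param reference a [prr_measurement()] at a well-focused diameter.
#' @param tol stopping tolerance on the bracket width (um), default 0.5.
#' @param alpha significance level for [compare_hprr()].
#' @param rounded_midpoints if `TRUE`, each midpoint is truncated to
#'   0.1 um before being tested and the truncated value is carried into
#'   the next bracket, mirroring how test diameters are specified at the
#'   bench ((16.5 + 15)/2 is tested as 15.7, and the next midpoint is then
#'   (15.7 + 16.5)/2 = 16.1). Default `FALSE`: full-precision midpoints.
#' @return an object of class `averaging_test_trace`: a list with
#'   `bracket_low`, `bracket_high` (initial), `steps` (data.frame of
#'   midpoint, decision, p_value, new_low, new_high) and
#'   `proposed_threshold` (um).
#' @export
run_averaging_test <- function(low, high, oracle, reference,
                               tol = 0.5, alpha = 0.05,
                               rounded_midpoints = FALSE) {
  if (!is.numeric(low) || !is.numeric(high) || low >= high) {
    stop("invalid bracket: need low < high", call. = FALSE)
  }
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  stopifnot(is.function(oracle), inherits(reference, "prr_measurement"))
  bracket <- c(low, high)
  steps <- list()
  while (bracket[2] - bracket[1] > tol) {
    m <- mean(bracket)
    if (rounded_midpoints) m <- .trunc_um(m)
    meas <- tryCatch(oracle(m), error = function(e) {
      stop(sprintf("averaging-test oracle failed at %.3f um (step %d): %s",
                   m, length(steps) + 1L, conditionMessage(e)),
           call. = FALSE)
    })
    cmp <- compare_hprr(meas, reference, alpha = alpha)
    bracket <- averaging_test_step(bracket, cmp$decision, midpoint = m)
    steps[[length(steps) + 1L]] <-
      data.frame(midpoint = m, decision = cmp$decision,
                 p_value = cmp$p_value,
                 new_low = bracket[1], new_high = bracket[2])
  }
  structure(list(bracket_low = low, bracket_high = high,
                 steps = if (length(steps)) do.call(rbind, steps) else
                   data.frame(midpoint = numeric(), decision = character(),
                              p_value = numeric(), new_low = numeric(),
                              new_high = numeric()),
                 proposed_threshold = bracket[2]),
            class = "averaging_test_trace")
}

#' @export
print.averaging_test_trace <- function(x, ...) {
  cat(sprintf("Averaging test on (%.2f, %.2f) um:\n",
              x$bracket_low, x$bracket_high))
  if (nrow(x$steps)) {
    for (i in seq_len(nrow(x$steps))) {
      s <- x$steps[i, ]
      cat(sprintf("  test %d: %.1f um -> %s (p = %.3g), bracket (%.2f, %.2f)\n",
                  i, s$midpoint, s$decision, s$p_value, s$new_low, s$new_high))
    }
  }
  cat(sprintf("  proposed threshold: %.2f um\n", x$proposed_threshold))
  invisible(x)
}
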