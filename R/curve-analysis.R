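# Learning-curve analysis: binned performance, 4-parameter logistic fits,
# and delay/learning phase durations.

#' Build a trial log
#'
#' @param stimulus Character vector of `"S_PLUS"` / `"S_MINUS"` labels.
#' @param response 0/1 lick responses, same length.
#' @return A `trial_log` data frame with columns `trial`, `stimulus`,
#'   `response`, `correct` (a lick is correct on S+ trials, withholding is
#'   correct on S- trials).
#' @export
trial_log <- function(stimulus, response) {
  stopifnot(length(stimulus) == length(response),
            all(stimulus %in% c("S_PLUS", "S_MINUS")),
            all(response %in% c(0L, 1L)))
  df <- data.frame(
    trial = seq_along(stimulus),
    stimulus = as.character(stimulus),
    response = as.integer(response),
    correct = ifelse(stimulus == "S_PLUS", as.integer(response),
                     1L - as.integer(response))
  )
  class(df) <- c("trial_log", "data.frame")
  df
}

#' Convert a stochastic trajectory to a trial log
#'
#' @param traj A stochastic `rw_trajectory`.
#' @return A [trial_log()].
#' @export
as_trial_log <- function(traj) {
  stopifnot(inherits(traj, "rw_trajectory"))
  if (traj$mode != "stochastic")
    stop("only stochastic trajectories carry trial-level responses")
  trial_log(traj$stimulus, traj$response)
}

#' Bin task performance over consecutive trial windows
#'
#' Performance is the mean of the hit rate (correct S+ trials) and the
#' correct-rejection rate (correct S- trials) per bin of `bin_size` trials;
#' a trailing partial bin is kept with its actual trial count. A bin missing
#' one stimulus class gets `NA` for that rate (never 0).
#'
#' @param x A [trial_log()] data frame, or an `rw_trajectory` (ergodic
#'   trajectories are binned on their per-step probabilities).
#' @param bin_size Trials per bin (>= 2); the study convention is 100.
#' @param ... Unused.
#' @return A `learning_curve` data frame with columns `bin`, `bin_center`,
#'   `n_trials`, `hit_rate`, `cr_rate`, `performance`.
#' @export
bin_performance <- function(x, bin_size = 100, ...) UseMethod("bin_performance")

#' @rdname bin_performance
#' @export
bin_performance.data.frame <- function(x, bin_size = 100, ...) {
  stopifnot(bin_size >= 2, nrow(x) >= 1,
            all(c("trial", "stimulus", "response") %in% names(x)))
  bin <- (seq_len(nrow(x)) - 1L) %/% as.integer(bin_size) + 1L
  correct <- ifelse(x$stimulus == "S_PLUS", x$response, 1L - x$response)
  out <- do.call(rbind, lapply(split(seq_len(nrow(x)), bin), function(i) {
    plus <- x$stimulus[i] == "S_PLUS"
    hit <- if (any(plus)) mean(correct[i][plus]) else NA_real_
    cr <- if (any(!plus)) mean(correct[i][!plus]) else NA_real_
    data.frame(n_trials = length(i), hit_rate = hit, cr_rate = cr,
               performance = (hit + cr) / 2)
  }))
  out <- cbind(bin = seq_len(nrow(out)), out)
  out$bin_center <- (out$bin - 1) * bin_size + out$n_trials / 2
  out <- out[, c("bin", "bin_center", "n_trials", "hit_rate", "cr_rate",
                 "performance")]
  rownames(out) <- NULL
  attr(out, "bin_size") <- bin_size
  class(out) <- c("learning_curve", "data.frame")
  out
}

#' @rdname bin_performance
#' @export
bin_performance.rw_trajectory <- function(x, bin_size = 100, ...) {
  if (x$mode == "stochastic") return(bin_performance(as_trial_log(x), bin_size))
  stopifnot(bin_size >= 2)
  bin <- (seq_len(x$n_steps) - 1L) %/% as.integer(bin_size) + 1L
  out <- do.call(rbind, lapply(split(seq_len(x$n_steps), bin), function(i) {
    data.frame(n_trials = length(i),
               hit_rate = mean(x$p_splus[i]),
               cr_rate = mean(1 - x$p_sminus[i]),
               performance = mean(x$performance[i]))
  }))
  out <- cbind(bin = seq_len(nrow(out)), out)
  out$bin_center <- (out$bin - 1) * bin_size + out$n_trials / 2
  out <- out[, c("bin", "bin_center", "n_trials", "hit_rate", "cr_rate",
                 "performance")]
  rownames(out) <- NULL
  attr(out, "bin_size") <- bin_size
  class(out) <- c("learning_curve", "data.frame")
  out
}

#' @export
plot.learning_curve <- function(x, ...) {
  graphics::plot(x$bin_center, x$performance, ylim = c(0, 1),
                 xlab = "trial", ylab = "fraction correct", pch = 16, ...)
  invisible(x)
}

logistic4 <- function(t, baseline, amplitude, midpoint, scale) {
  baseline + amplitude / (1 + exp(-(t - midpoint) / scale))
}

#' Fit a 4-parameter logistic to a learning curve
#'
#' Least-squares fit of `P(t) = baseline + amplitude / (1 + exp(-(t -
#' midpoint) / scale))` with multi-start initialization (several midpoint and
#' scale candidates, both signs of the amplitude), using Levenberg-Marquardt
#' via [minpack.lm::nlsLM]. Because performance is a probability, the
#' baseline is constrained to `[0, 1]` and the amplitude to `[-1, 1]`;
#' additionally the baseline may not sit more than a quarter of the observed
#' performance range below the observed minimum (curves sampled only through
#' their rising half leave the lower asymptote unidentifiable otherwise).
#' A flat or decreasing curve yields a fit flagged
#' as degenerate (amplitude <= 0, or below 0.05 performance units) rather
#' than an error.
#'
#' @param curve A `learning_curve` from [bin_performance()], or any data
#'   frame with `bin_center` and `performance` columns (>= 4 non-missing
#'   bins). Missing bins are dropped, not imputed.
#' @param degenerate_amplitude Amplitude (performance units) below which the
#'   fit is flagged degenerate.
#' @return An object of class `sigmoid_fit` with `coefficients` (baseline,
#'   amplitude, midpoint, scale), `goodness` (R-squared), `degenerate` flag,
#'   and the fitted data.
#' @examples
#' t <- seq(50, 2000, by = 100)
#' y <- 0.5 + 0.45 / (1 + exp(-(t - 800) / 120))
#' fit <- fit_sigmoid(data.frame(bin_center = t, performance = y))
#' coef(fit)
#' @export
fit_sigmoid <- function(curve, degenerate_amplitude = 0.05) {
  stopifnot(all(c("bin_center", "performance") %in% names(curve)))
  ok <- is.finite(curve$performance)
  t <- curve$bin_center[ok]
  y <- curve$performance[ok]
  if (length(t) < 4L) stop("at least 4 non-missing bins are required")

  span <- diff(range(t))
  rng <- max(y) - min(y)
  # identifiability: when a curve is sampled only through its rising half the
  # lower asymptote is unobserved; it cannot plausibly sit far below the
  # worst observed performance, so bound it relative to the data
  lo_baseline <- max(0, min(y) - 0.25 * rng)
  starts <- list()
  for (m in stats::quantile(t, c(0.25, 0.5, 0.75), names = FALSE))
    for (s in span * c(0.03, 0.1, 0.25))
      for (a in c(rng, -rng, 0.45))
        starts[[length(starts) + 1L]] <-
          c(baseline = if (a >= 0) min(y) else max(y),
            amplitude = a, midpoint = m, scale = s)

  best <- NULL
  best_sse <- Inf
  df <- data.frame(t = t, y = y)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ baseline + amplitude / (1 + exp(-(t - midpoint) / scale)),
        data = df, start = as.list(st),
        lower = c(lo_baseline, -1, -Inf, 1e-9), upper = c(1, 1, Inf, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.finite(sse) && sse < best_sse) {
      best_sse <- sse
      best <- fit
    }
  }
  if (is.null(best)) {
    # flat / pathological data: report a constant fit flagged degenerate
    cf <- c(baseline = mean(y), amplitude = 0,
            midpoint = stats::median(t), scale = span / 10)
    fitted_y <- rep(mean(y), length(y))
  } else {
    cf <- stats::coef(best)
    fitted_y <- as.numeric(stats::fitted(best))
  }
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - fitted_y)^2)
  goodness <- if (sst > 0) 1 - sse / sst else 1
  structure(list(
    coefficients = cf,
    goodness = goodness,
    degenerate = unname(cf["amplitude"] < degenerate_amplitude),
    data = df, fitted.values = fitted_y,
    residuals = y - fitted_y
  ), class = "sigmoid_fit")
}

#' @export
coef.sigmoid_fit <- function(object, ...) object$coefficients

#' @export
fitted.sigmoid_fit <- function(object, ...) object$fitted.values

#' @export
residuals.sigmoid_fit <- function(object, ...) object$residuals

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t
       else if (is.data.frame(newdata)) newdata$t else newdata
  cf <- object$coefficients
  logistic4(t, cf["baseline"], cf["amplitude"], cf["midpoint"], cf["scale"])
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("4-parameter logistic fit\n")
  print(round(x$coefficients, 4))
  cat(sprintf("R-squared: %.4f%s\n", x$goodness,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' @export
summary.sigmoid_fit <- function(object, ...) {
  print(object)
  if (!object$degenerate) {
    ph <- extract_phases(object)
    cat(sprintf("delay phase: %.1f trials, learning phase: %.1f trials\n",
                ph$delay_trials, ph$learning_trials))
  }
  invisible(object)
}

#' @export
plot.sigmoid_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$y, pch = 16, ylim = c(0, 1),
                 xlab = "trial", ylab = "fraction correct", ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 300)
  graphics::lines(tt, predict(x, tt), col = "red3")
  if (!x$degenerate) {
    ph <- extract_phases(x)
    graphics::abline(v = c(ph$delay_trials,
                           ph$delay_trials + ph$learning_trials),
                     lty = 2, col = "gray50")
  }
  invisible(x)
}

#' Delay and learning phase durations from a sigmoid fit
#'
#' The delay phase is the number of trials to reach 20% of maximal
#' performance (20% of the fitted amplitude above baseline) and the learning
#' phase the number of trials to go from 20% to 80%. For the logistic the
#' crossings are analytic: `t20 = midpoint - scale * log(4)`, `t80 =
#' midpoint + scale * log(4)`, so the learning phase equals
#' `2 * log(4) * scale`. The delay is clamped at zero, keeping
#' `delay + learning = t80`. With `relative = FALSE` the thresholds are the
#' absolute performance levels 0.2 and 0.8 instead.
#'
#' @param fit A non-degenerate `sigmoid_fit` with positive amplitude.
#' @param lower,upper Threshold fractions (defaults 0.2 and 0.8).
#' @param relative Interpret thresholds relative to the fitted amplitude
#'   (default) or as absolute performance levels.
#' @return An object of class `phase_durations` with `delay_trials` and
#'   `learning_trials`.
#' @export
extract_phases <- function(fit, lower = 0.2, upper = 0.8, relative = TRUE) {
  stopifnot(inherits(fit, "sigmoid_fit"), lower > 0, upper < 1, lower < upper)
  cf <- fit$coefficients
  if (fit$degenerate || cf["amplitude"] <= 0)
    stop("phases are undefined for a degenerate or non-increasing fit")
  crossing <- function(q) {
    # solve baseline + A / (1 + exp(-(t - m)/s)) = level
    frac <- if (relative) q
            else (q - cf["baseline"]) / cf["amplitude"]
    if (frac <= 0 || frac >= 1)
      stop("threshold outside the range of the fitted curve")
    unname(cf["midpoint"] + cf["scale"] * log(frac / (1 - frac)))
  }
  t_lo <- crossing(lower)
  t_hi <- crossing(upper)
  delay <- max(t_lo, 0)
  structure(list(delay_trials = delay, learning_trials = t_hi - delay),
            class = "phase_durations")
}

#' @export
print.phase_durations <- function(x, ...) {
  cat(sprintf("delay phase: %.1f trials\nlearning phase: %.1f trials\n",
              x$delay_trials, x$learning_trials))
  invisible(x)
}

#' Normalized-spread difference between two cohorts of learning phases
#'
#' Computes the difference of coefficient-of-variation-style normalized
#' standard deviations (SD divided by group mean) of learning-phase
#' durations, `group_a` minus `group_b`, expressed in percentage points.
#'
#' @param group_a,group_b Numeric vectors of learning-phase durations, or
#'   lists of `phase_durations` objects. Each group needs >= 2 members.
#' @return The normalized-SD difference in percent, with the normalization
#'   recorded in the `"normalization"` attribute.
#' @export
cohort_variability <- function(group_a, group_b) {
  pull <- function(g) {
    if (is.list(g) && !is.data.frame(g))
      g <- vapply(g, function(p) p$learning_trials, numeric(1))
    as.numeric(g)
  }
  a <- pull(group_a)
  b <- pull(group_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("variability is undefined for groups of size < 2")
  cv <- function(x) stats::sd(x) / mean(x)
  structure(100 * (cv(a) - cv(b)),
            normalization = "sd / mean (coefficient of variation), percent")
}
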