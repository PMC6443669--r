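# Circuit-level Rescorla-Wagner model of Go/NoGo discrimination.
#
# Three sensory populations -- C-hat (information common to both trial types),
# S-hat-minus and S-hat-plus (stimulus specific) -- project through excitatory
# and feed-forward inhibitory weights onto an all-or-none decision unit.
# Learning is a multiplicative Hebbian rule gated by an asymmetric reward
# prediction error. Input vectors are ordered (C, S-, S+) throughout.

#' Model parameters for the reinforcement-learning circuit
#'
#' @param alpha Learning rate (> 0).
#' @param sigma Noise-scale parameter setting asymptotic performance (> 0).
#'   At the learned fixed point the drive satisfies `dW.X = +/- 1/sigma`.
#' @param v Asymmetry of the prediction-error gain (>= 1): positive surprises
#'   are weighted `v` times more strongly than negative ones.
#' @param floor Weight floor applied after every update (>= 0). The
#'   multiplicative rule cannot change a weight's sign, but a large single
#'   step could; clamping preserves positivity.
#' @param seed Optional integer seed for stochastic simulations.
#' @return An object of class `rw_params`.
#' @examples
#' rw_params(alpha = 0.01, sigma = 0.6195, v = 6)
#' @export
rw_params <- function(alpha = 0.01, sigma = 0.6195, v = 6,
                      floor = 1e-6, seed = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(sigma), length(sigma) == 1L, sigma > 0,
            is.numeric(v), length(v) == 1L, v >= 1,
            is.numeric(floor), length(floor) == 1L, floor >= 0)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(is.finite(seed))
  }
  structure(list(alpha = alpha, sigma = sigma, v = v,
                 floor = floor, seed = seed),
            class = "rw_params")
}

#' Paired excitatory/inhibitory synaptic weights
#'
#' Weight vectors from the three sensory populations (C, S-, S+) onto the
#' decision unit (excitatory) and the feed-forward inhibitory path. A single
#' initial value `w_S` is shared by the four stimulus-specific weights.
#'
#' @param w_Ce,w_Ci Initial excitatory and inhibitory weights of the common
#'   population.
#' @param w_S Shared initial value for the four stimulus-specific weights.
#' @param excitatory,inhibitory Alternatively, full 3-vectors in (C, S-, S+)
#'   order; these override `w_Ce`/`w_Ci`/`w_S` when supplied.
#' @return An object of class `rw_weights` with components `E` and `I`.
#' @examples
#' rw_weights(w_Ce = 2, w_Ci = 1, w_S = 0.01)
#' @export
rw_weights <- function(w_Ce = 2, w_Ci = 1, w_S = 0.01,
                       excitatory = NULL, inhibitory = NULL) {
  if (is.null(excitatory)) excitatory <- c(w_Ce, w_S, w_S)
  if (is.null(inhibitory)) inhibitory <- c(w_Ci, w_S, w_S)
  # strip stray attributes picked up from input-vector arithmetic
  excitatory <- as.numeric(excitatory)
  inhibitory <- as.numeric(inhibitory)
  stopifnot(length(excitatory) == 3L, length(inhibitory) == 3L,
            all(is.finite(excitatory)), all(is.finite(inhibitory)),
            all(excitatory >= 0), all(inhibitory >= 0))
  names(excitatory) <- names(inhibitory) <- c("C", "Sminus", "Splus")
  structure(list(E = excitatory, I = inhibitory), class = "rw_weights")
}

#' @export
print.rw_weights <- function(x, ...) {
  cat("Synaptic weights (C, S-, S+):\n")
  m <- rbind(excitatory = x$E, inhibitory = x$I, drive = x$E - x$I)
  print(m, ...)
  invisible(x)
}

#' Effective drive of a weight pair
#'
#' @param weights An `rw_weights` object.
#' @return The 3-vector of excitatory minus inhibitory weights.
#' @export
delta_w <- function(weights) weights$E - weights$I

#' Recruitment scenario for a stimulus pair
#'
#' Cortical recruitment is modeled through the firing levels of the sound
#' units: the common population fires at `common` in both trial types, the
#' specific population of one stimulus fires at `strong` and the other at
#' `weak`.
#'
#' @param common Firing level of the common population (> 0).
#' @param weak,strong Firing levels of the two stimulus-specific populations;
#'   `strong` must be >= `weak` (equality gives the symmetric control).
#' @param larger Which stimulus gets the stronger specific population,
#'   `"S_PLUS"` or `"S_MINUS"`.
#' @return An object of class `recruitment_scenario`.
#' @examples
#' recruitment_scenario(common = 1, weak = 1, strong = 2, larger = "S_PLUS")
#' @export
recruitment_scenario <- function(common = 1, weak = 1, strong = 2,
                                 larger = c("S_PLUS", "S_MINUS")) {
  larger <- match.arg(larger)
  stopifnot(is.numeric(common), common > 0,
            is.numeric(weak), weak > 0,
            is.numeric(strong), strong > 0)
  if (strong < weak)
    stop("invalid scenario: strong_level must not be smaller than weak_level")
  structure(list(common = common, weak = weak, strong = strong,
                 larger = larger),
            class = "recruitment_scenario")
}

#' Sensory input vector
#'
#' @param activity Non-negative 3-vector of population activities in
#'   (C, S-, S+) order.
#' @param label One of `"S_PLUS"`, `"S_MINUS"`, `"PROBE"`.
#' @return A named numeric 3-vector with a `label` attribute.
#' @export
sensory_input <- function(activity, label = c("PROBE", "S_PLUS", "S_MINUS")) {
  label <- match.arg(label)
  stopifnot(length(activity) == 3L, all(is.finite(activity)),
            all(activity >= 0))
  if (label == "S_PLUS" && activity[2L] != 0)
    stop("S_PLUS input must have a silent S- component")
  if (label == "S_MINUS" && activity[3L] != 0)
    stop("S_MINUS input must have a silent S+ component")
  x <- as.numeric(activity)
  names(x) <- c("C", "Sminus", "Splus")
  attr(x, "label") <- label
  x
}

#' Build the S+ and S- input vectors of a recruitment scenario
#'
#' @param scenario A [recruitment_scenario()].
#' @return A list with components `x_plus` and `x_minus`, each a sensory
#'   input in (C, S-, S+) order. With `larger = "S_PLUS"` and levels
#'   (1, 1, 2) this yields `X_S+ = (1, 0, 2)` and `X_S- = (1, 1, 0)`.
#' @examples
#' make_inputs(recruitment_scenario(1, 1, 2, "S_PLUS"))
#' @export
make_inputs <- function(scenario) {
  stopifnot(inherits(scenario, "recruitment_scenario"))
  sp <- if (scenario$larger == "S_PLUS") scenario$strong else scenario$weak
  sm <- if (scenario$larger == "S_MINUS") scenario$strong else scenario$weak
  list(
    x_plus  = sensory_input(c(scenario$common, 0, sp), "S_PLUS"),
    x_minus = sensory_input(c(scenario$common, sm, 0), "S_MINUS")
  )
}

#' Binary lick decision of the circuit
#'
#' The decision unit thresholds the net drive against a standard-normal
#' noise realization: `y = theta((W_E - W_I).X - xi)` with a strict
#' threshold (`theta(0) = 0`).
#'
#' @param weights An `rw_weights` object.
#' @param input A sensory input 3-vector.
#' @param noise_draw A standard-normal realization.
#' @return 0 or 1.
#' @export
decide <- function(weights, input, noise_draw) {
  as.integer(sum(delta_w(weights) * input) - noise_draw > 0)
}

#' Asymmetric prediction-error gain
#'
#' `f(u) = u` for `u <= 0` and `f(u) = v * u` for `u > 0`: unexpected
#' rewards are weighted `v`-fold more than withheld rewards.
#'
#' @param u Prediction error (vectorized).
#' @param v Asymmetry factor (>= 1).
#' @return `f(u)`, same length as `u`.
#' @export
asymmetric_gain <- function(u, v) {
  stopifnot(v >= 1)
  ifelse(u > 0, v * u, u)
}

#' Lick probability under the ergodic approximation
#'
#' `p = (1 + erf(dW.X / sqrt(2))) / 2`, i.e. the standard-normal upper tail
#' of the drive -- exactly the probability that [decide()] returns 1 under
#' unit-variance Gaussian noise.
#'
#' @inheritParams decide
#' @return A probability in `[0, 1]`.
#' @export
lick_probability <- function(weights, input) {
  stats::pnorm(sum(delta_w(weights) * input))
}

#' One stochastic weight update
#'
#' Multiplicative delta-rule: on a licked trial with reward signal `R`,
#' `dW_E = alpha * W_E (*) f(R - sigma dW.X) * X` and the inhibitory weights
#' move with the opposite sign; `(*)` is the element-wise product. Without a
#' lick the Hebbian term vanishes and weights are unchanged. Components are
#' clamped at the weight floor afterwards.
#'
#' @param weights Current `rw_weights`.
#' @param input Sensory input of the trial.
#' @param response 0/1 lick response from [decide()].
#' @param reward +1 for a rewarded lick (S+ trial), -1 for a punished lick
#'   (S- trial). Ignored when `response = 0`.
#' @param params An [rw_params()] object.
#' @return Updated `rw_weights`.
#' @export
update_weights_stochastic <- function(weights, input, response, reward,
                                      params) {
  if (response == 0) return(weights)
  stopifnot(reward %in% c(-1, 1))
  gain <- asymmetric_gain(reward - params$sigma * sum(delta_w(weights) * input),
                          params$v)
  E <- pmax(weights$E + params$alpha * weights$E * gain * input, params$floor)
  I <- pmax(weights$I - params$alpha * weights$I * gain * input, params$floor)
  rw_weights(excitatory = unname(E), inhibitory = unname(I))
}

#' One ergodic (mean-field) weight update
#'
#' Deterministic expectation of the stochastic rule over the two trial types
#' (each presented with probability 1/2) and over the lick decision:
#' `dW_E = (alpha/2) W_E (*) (f(1 - sigma dW.X+) p+ X+ +
#' f(-1 - sigma dW.X-) p- X-)`, with lick probabilities from
#' [lick_probability()]; the inhibitory update has the opposite sign.
#'
#' @param weights Current `rw_weights`.
#' @param x_plus,x_minus The S+ and S- input vectors.
#' @param params An [rw_params()] object.
#' @return Updated `rw_weights`.
#' @export
update_weights_ergodic <- function(weights, x_plus, x_minus, params) {
  dw <- delta_w(weights)
  p_plus <- stats::pnorm(sum(dw * x_plus))
  p_minus <- stats::pnorm(sum(dw * x_minus))
  g_plus <- asymmetric_gain(1 - params$sigma * sum(dw * x_plus), params$v)
  g_minus <- asymmetric_gain(-1 - params$sigma * sum(dw * x_minus), params$v)
  drive <- g_plus * p_plus * x_plus + g_minus * p_minus * x_minus
  E <- pmax(weights$E + (params$alpha / 2) * weights$E * drive, params$floor)
  I <- pmax(weights$I - (params$alpha / 2) * weights$I * drive, params$floor)
  rw_weights(excitatory = unname(E), inhibitory = unname(I))
}

#' Simulate Go/NoGo discrimination learning
#'
#' Runs the circuit model either trial by trial (`mode = "stochastic"`,
#' stimuli interleaved pseudorandomly with exactly 4 S+ and 4 S- per block
#' of 8) or as the deterministic mean-field iteration (`mode = "ergodic"`,
#' one step per trial). In ergodic mode with `n_trials = NULL` the run stops
#' when the largest component-wise weight change falls below `converge_tol`
#' or after `max_steps` steps (a cap hit is flagged, not silent).
#'
#' @param scenario A [recruitment_scenario()].
#' @param init Initial [rw_weights()].
#' @param params An [rw_params()]; `params$seed` (if set) makes stochastic
#'   runs fully reproducible.
#' @param n_trials Number of trials/steps (>= 1); may be `NULL` in ergodic
#'   mode to run to convergence.
#' @param mode `"ergodic"` or `"stochastic"`.
#' @param converge_tol Ergodic convergence tolerance on `max |dW|`.
#' @param max_steps Step cap for convergence runs.
#' @return An object of class `rw_trajectory`: per-step lick probabilities
#'   `p_splus`, `p_sminus`, `performance = (p_S+ + 1 - p_S-) / 2`, weight
#'   history matrices `W_E` and `W_I`, and in stochastic mode the stimulus,
#'   response, and reward sequences.
#' @examples
#' traj <- simulate_learning(recruitment_scenario(1, 1, 2, "S_PLUS"),
#'                           rw_weights(2, 1, 0.01), rw_params(),
#'                           n_trials = 500, mode = "ergodic")
#' utils::tail(traj$performance, 1)
#' @export
simulate_learning <- function(scenario, init, params, n_trials = NULL,
                              mode = c("ergodic", "stochastic"),
                              converge_tol = 1e-8, max_steps = 1e5L) {
  mode <- match.arg(mode)
  stopifnot(inherits(init, "rw_weights"), inherits(params, "rw_params"))
  inputs <- make_inputs(scenario)
  xp <- inputs$x_plus
  xm <- inputs$x_minus

  if (mode == "stochastic") {
    if (is.null(n_trials) || n_trials < 1)
      stop("stochastic mode requires n_trials >= 1")
    n <- as.integer(n_trials)
    if (!is.null(params$seed)) set.seed(params$seed)
    stim <- generate_trial_sequence(n)
    xi <- stats::rnorm(n)
    E <- matrix(NA_real_, n, 3L)
    I <- matrix(NA_real_, n, 3L)
    pp <- pm <- numeric(n)
    y <- integer(n)
    R <- integer(n)
    w <- init
    for (t in seq_len(n)) {
      dw <- w$E - w$I
      pp[t] <- stats::pnorm(sum(dw * xp))
      pm[t] <- stats::pnorm(sum(dw * xm))
      is_plus <- stim[t] == "S_PLUS"
      x <- if (is_plus) xp else xm
      y[t] <- as.integer(sum(dw * x) - xi[t] > 0)
      R[t] <- if (y[t] == 0L) 0L else if (is_plus) 1L else -1L
      if (y[t] == 1L) {
        gain <- asymmetric_gain(R[t] - params$sigma * sum(dw * x), params$v)
        w <- list(E = pmax(w$E + params$alpha * w$E * gain * x, params$floor),
                  I = pmax(w$I - params$alpha * w$I * gain * x, params$floor))
      }
      if (!all(is.finite(w$E)) || !all(is.finite(w$I)))
        stop("non-finite weights at trial ", t)
      E[t, ] <- w$E
      I[t, ] <- w$I
    }
    w <- rw_weights(excitatory = unname(w$E), inhibitory = unname(w$I))
    out <- list(mode = "stochastic", scenario = scenario, params = params,
                stimulus = stim, response = y, reward = R,
                p_splus = pp, p_sminus = pm,
                performance = (pp + 1 - pm) / 2,
                W_E = E, W_I = I, final_weights = w,
                converged = NA, n_steps = n)
  } else {
    cap <- if (is.null(n_trials)) as.integer(max_steps) else as.integer(n_trials)
    check_tol <- is.null(n_trials)
    E <- matrix(NA_real_, cap, 3L)
    I <- matrix(NA_real_, cap, 3L)
    pp <- pm <- numeric(cap)
    w <- list(E = init$E, I = init$I)
    a2 <- params$alpha / 2
    converged <- FALSE
    t <- 0L
    while (t < cap) {
      t <- t + 1L
      dw <- w$E - w$I
      p_p <- stats::pnorm(sum(dw * xp))
      p_m <- stats::pnorm(sum(dw * xm))
      g_p <- asymmetric_gain(1 - params$sigma * sum(dw * xp), params$v)
      g_m <- asymmetric_gain(-1 - params$sigma * sum(dw * xm), params$v)
      drive <- g_p * p_p * xp + g_m * p_m * xm
      Enew <- pmax(w$E + a2 * w$E * drive, params$floor)
      Inew <- pmax(w$I - a2 * w$I * drive, params$floor)
      if (!all(is.finite(Enew)) || !all(is.finite(Inew)))
        stop("non-finite weights at step ", t)
      step_size <- max(abs(Enew - w$E), abs(Inew - w$I))
      w <- list(E = Enew, I = Inew)
      E[t, ] <- Enew
      I[t, ] <- Inew
      pp[t] <- p_p
      pm[t] <- p_m
      if (check_tol && step_size < converge_tol) {
        converged <- TRUE
        break
      }
    }
    keep <- seq_len(t)
    w <- rw_weights(excitatory = unname(w$E), inhibitory = unname(w$I))
    out <- list(mode = "ergodic", scenario = scenario, params = params,
                stimulus = NULL, response = NULL, reward = NULL,
                p_splus = pp[keep], p_sminus = pm[keep],
                performance = (pp[keep] + 1 - pm[keep]) / 2,
                W_E = E[keep, , drop = FALSE], W_I = I[keep, , drop = FALSE],
                final_weights = w,
                converged = if (check_tol) converged else NA,
                n_steps = t)
    if (check_tol && !converged)
      warning("ergodic run hit the step cap (", cap,
              ") before reaching tolerance ", converge_tol)
  }
  colnames(out$W_E) <- colnames(out$W_I) <- c("C", "Sminus", "Splus")
  class(out) <- "rw_trajectory"
  out
}

#' Probe the learned circuit with a stimulus component
#'
#' Returns the ergodic lick probability of the learned weights for a probe
#' input, e.g. the common population alone (a catch trial) or a blank.
#'
#' @param weights Learned `rw_weights`, or an `rw_trajectory` whose final
#'   weights are used.
#' @param probe A sensory input 3-vector, or one of `"C"`, `"S_PLUS"`,
#'   `"S_MINUS"`, `"blank"` to build the component probe from `scenario`.
#' @param scenario A [recruitment_scenario()]; required when `probe` is a
#'   character shorthand.
#' @return A lick probability in `[0, 1]`. A blank (zero) probe returns 0.5.
#' @export
probe_stimulus <- function(weights, probe, scenario = NULL) {
  if (inherits(weights, "rw_trajectory")) {
    if (is.null(scenario)) scenario <- weights$scenario
    weights <- weights$final_weights
  }
  if (is.character(probe)) {
    if (is.null(scenario))
      stop("a scenario is required for component-name probes")
    probe <- probe_vectors(scenario)[[match.arg(
      probe, c("C", "S_PLUS", "S_MINUS", "blank"))]]
  }
  stopifnot(length(probe) == 3L, all(is.finite(probe)))
  lick_probability(weights, probe)
}

#' Component probe vectors of a scenario
#'
#' @param scenario A [recruitment_scenario()].
#' @return Named list of probe 3-vectors: `C` (common population alone),
#'   `S_PLUS`, `S_MINUS` (specific populations alone), and `blank`.
#' @export
probe_vectors <- function(scenario) {
  inputs <- make_inputs(scenario)
  list(
    C = sensory_input(c(scenario$common, 0, 0), "PROBE"),
    S_PLUS = sensory_input(c(0, 0, inputs$x_plus[["Splus"]]), "PROBE"),
    S_MINUS = sensory_input(c(0, inputs$x_minus[["Sminus"]], 0), "PROBE"),
    blank = sensory_input(c(0, 0, 0), "PROBE")
  )
}

#' @export
print.rw_trajectory <- function(x, ...) {
  cat(sprintf("Go/NoGo learning trajectory (%s mode), %d steps\n",
              x$mode, x$n_steps))
  cat(sprintf("  final p(S+) = %.4f, p(S-) = %.4f, performance = %.4f\n",
              utils::tail(x$p_splus, 1), utils::tail(x$p_sminus, 1),
              utils::tail(x$performance, 1)))
  if (isTRUE(x$converged)) cat("  converged\n")
  if (isFALSE(x$converged)) cat("  step cap reached before convergence\n")
  invisible(x)
}

#' @export
summary.rw_trajectory <- function(object, ...) {
  dw <- object$final_weights$E - object$final_weights$I
  inputs <- make_inputs(object$scenario)
  out <- list(
    mode = object$mode, n_steps = object$n_steps,
    converged = object$converged,
    final_performance = utils::tail(object$performance, 1),
    dwx_plus = sum(dw * inputs$x_plus),
    dwx_minus = sum(dw * inputs$x_minus),
    final_weights = object$final_weights
  )
  class(out) <- "summary.rw_trajectory"
  out
}

#' @export
print.summary.rw_trajectory <- function(x, ...) {
  cat(sprintf("%s run, %d steps%s\n", x$mode, x$n_steps,
              if (isTRUE(x$converged)) " (converged)" else ""))
  cat(sprintf("  dW.X_S+ = %.6f   dW.X_S- = %.6f\n", x$dwx_plus, x$dwx_minus))
  cat(sprintf("  final performance = %.4f\n", x$final_performance))
  print(x$final_weights)
  invisible(x)
}

#' @export
as.data.frame.rw_trajectory <- function(x, ...) {
  df <- data.frame(
    step = seq_len(x$n_steps),
    p_splus = x$p_splus, p_sminus = x$p_sminus,
    performance = x$performance,
    wE_c = x$W_E[, 1L], wE_sm = x$W_E[, 2L], wE_sp = x$W_E[, 3L],
    wI_c = x$W_I[, 1L], wI_sm = x$W_I[, 2L], wI_sp = x$W_I[, 3L]
  )
  if (x$mode == "stochastic") {
    df$stimulus <- x$stimulus
    df$response <- x$response
    df$reward <- x$reward
  }
  df
}

#' @export
plot.rw_trajectory <- function(x, ...) {
  t <- seq_len(x$n_steps)
  graphics::plot(t, x$performance, type = "l", ylim = c(0, 1),
                 xlab = "trial", ylab = "probability", ...)
  graphics::lines(t, x$p_splus, col = "red3")
  graphics::lines(t, 1 - x$p_sminus, col = "steelblue")
  graphics::legend("bottomright", bty = "n", lty = 1,
                   col = c("black", "red3", "steelblue"),
                   legend = c("performance", "p(lick | S+)",
                              "p(no lick | S-)"))
  invisible(x)
}
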