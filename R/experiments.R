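# Figure-level experiment drivers: recruitment sweeps, phase comparisons,
# weight correlations, strategy probes, and asymptote checks. Each driver
# returns an experiment_report that fully determines a re-run.

new_report <- function(id, config, seed, tables, stats = list()) {
  structure(list(id = id, config = config, seed = seed,
                 tables = tables, stats = stats),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report:", x$id, "\n")
  for (nm in names(x$tables))
    cat(sprintf("  table %s: %d rows\n", nm, nrow(x$tables[[nm]])))
  if (length(x$stats)) {
    cat("  stats:\n")
    for (nm in names(x$stats)) {
      v <- x$stats[[nm]]
      if (is.numeric(v) && length(v) == 1L)
        cat(sprintf("    %s = %.4g\n", nm, v))
    }
  }
  invisible(x)
}

# simulate one subject under one recruitment assignment and extract phases;
# a fixed training budget (like an experimental schedule) rather than a run
# to numerical convergence, whose long saturation tail would skew the fits
subject_phases <- function(subject, ratio, larger, bin_size = 100,
                           n_trials = 4000L) {
  scen <- recruitment_scenario(common = 1, weak = 1, strong = ratio,
                               larger = larger)
  traj <- simulate_learning(scen, subject$weights, subject$params,
                            n_trials = n_trials, mode = "ergodic")
  curve <- bin_performance(traj, bin_size = bin_size)
  fit <- fit_sigmoid(curve)
  ph <- tryCatch(extract_phases(fit), error = function(e) NULL)
  data.frame(
    subject = subject$id, ratio = ratio, larger = larger,
    assignment = if (larger == "S_PLUS") "sminus_smaller" else "sminus_larger",
    w_Ce = subject$w_Ce, w_Ci = subject$w_Ci, w_S = subject$w_S,
    delay = if (is.null(ph)) NA_real_ else ph$delay_trials,
    learning = if (is.null(ph)) NA_real_ else ph$learning_trials,
    goodness = fit$goodness,
    final_performance = utils::tail(traj$performance, 1)
  )
}

#' Learning-phase duration versus recruitment difference
#'
#' For each simulated subject and recruitment ratio, runs the ergodic model
#' under both assignments of the larger input (to S+ or to S-) and tabulates
#' the per-subject difference in learning-phase duration (S- smaller minus
#' S- larger) against the recruitment ratio.
#'
#' @param cohort A [cohort_spec()].
#' @param ratios Recruitment ratios (> 0; 1 is the symmetric control).
#' @param bin_size Trials per performance bin.
#' @param n_trials Ergodic training budget per run (trials).
#' @return An `experiment_report` with a per-subject `phases` table and a
#'   per-ratio `summary` table (mean and SD of the duration difference).
#' @export
run_recruitment_sweep <- function(cohort, ratios = c(1, 1.5, 2, 3),
                                  bin_size = 100, n_trials = 4000L) {
  stopifnot(all(ratios > 0))
  subjects <- generate_cohort(cohort)
  rows <- list()
  for (r in ratios)
    for (s in subjects)
      for (side in c("S_PLUS", "S_MINUS"))
        rows[[length(rows) + 1L]] <-
          subject_phases(s, r, side, bin_size, n_trials)
  phases <- do.call(rbind, rows)
  diffs <- do.call(rbind, lapply(split(phases, phases$ratio), function(d) {
    wide <- merge(d[d$assignment == "sminus_smaller",
                    c("subject", "learning")],
                  d[d$assignment == "sminus_larger",
                    c("subject", "learning")],
                  by = "subject", suffixes = c("_smaller", "_larger"))
    dd <- wide$learning_smaller - wide$learning_larger
    data.frame(ratio = d$ratio[1L], mean_diff = mean(dd, na.rm = TRUE),
               sd_diff = stats::sd(dd, na.rm = TRUE), n = sum(!is.na(dd)))
  }))
  diffs <- diffs[order(diffs$ratio), ]
  rownames(diffs) <- NULL
  new_report("recruitment_sweep",
             config = list(cohort = unclass(cohort), ratios = ratios,
                           bin_size = bin_size, n_trials = n_trials),
             seed = cohort$seed,
             tables = list(phases = phases, summary = diffs))
}

#' Delay/learning phase comparison at a fixed recruitment ratio
#'
#' Runs every cohort subject under both recruitment assignments at the given
#' ratio and compares delay and learning phase durations between the
#' assignments with two-sided rank-sum tests, mirroring the nonparametric
#' analyses standard in this field.
#'
#' @inheritParams run_recruitment_sweep
#' @param ratio Recruitment ratio (default 2).
#' @return An `experiment_report`; `stats` carries the rank-sum p-values and
#'   group SDs of the learning phase.
#' @export
run_phase_comparison <- function(cohort, ratio = 2, bin_size = 100,
                                 n_trials = 4000L) {
  subjects <- generate_cohort(cohort)
  rows <- list()
  for (s in subjects)
    for (side in c("S_PLUS", "S_MINUS"))
      rows[[length(rows) + 1L]] <-
        subject_phases(s, ratio, side, bin_size, n_trials)
  phases <- do.call(rbind, rows)
  smaller <- phases[phases$assignment == "sminus_smaller", ]
  larger <- phases[phases$assignment == "sminus_larger", ]
  wl <- stats::wilcox.test(smaller$learning, larger$learning,
                           alternative = "greater", exact = FALSE)
  wd <- stats::wilcox.test(smaller$delay, larger$delay, exact = FALSE)
  new_report("phase_comparison",
             config = list(cohort = unclass(cohort), ratio = ratio,
                           bin_size = bin_size),
             seed = cohort$seed,
             tables = list(phases = phases),
             stats = list(
               p_learning = wl$p.value, p_delay = wd$p.value,
               mean_learning_smaller = mean(smaller$learning, na.rm = TRUE),
               mean_learning_larger = mean(larger$learning, na.rm = TRUE),
               sd_learning_smaller = stats::sd(smaller$learning, na.rm = TRUE),
               sd_learning_larger = stats::sd(larger$learning, na.rm = TRUE),
               variability_difference = cohort_variability(
                 smaller$learning[!is.na(smaller$learning)],
                 larger$learning[!is.na(larger$learning)])))
}

#' Rank correlations of learning speed with initial weights
#'
#' Spearman correlations of learning-phase duration with the initial weights
#' `w_S`, `w_Ce`, `w_Ci`, split by recruitment assignment.
#'
#' @inheritParams run_phase_comparison
#' @return An `experiment_report` with a `correlations` table (rho and
#'   p-value per weight and assignment) and the underlying `phases` table.
#' @export
run_weight_correlations <- function(cohort, ratio = 2, bin_size = 100,
                                    n_trials = 4000L) {
  rep0 <- run_phase_comparison(cohort, ratio, bin_size, n_trials)
  phases <- rep0$tables$phases
  rows <- list()
  for (asg in unique(phases$assignment)) {
    d <- phases[phases$assignment == asg & !is.na(phases$learning), ]
    for (w in c("w_S", "w_Ce", "w_Ci")) {
      ct <- suppressWarnings(
        stats::cor.test(d[[w]], d$learning, method = "spearman"))
      rows[[length(rows) + 1L]] <- data.frame(
        assignment = asg, weight = w,
        rho = unname(ct$estimate), p = ct$p.value, n = nrow(d))
    }
  }
  new_report("weight_correlations",
             config = rep0$config, seed = cohort$seed,
             tables = list(correlations = do.call(rbind, rows),
                           phases = phases))
}

#' Default parameter panels for the strategy-probe experiment
#'
#' Four panels crossing the recruitment assignment (larger S+ at levels
#' (1, 1, 2), or larger S- at (1, 2, 1)) with strong (`w_Ce = 2`,
#' `w_Ci = 1`) or weak (`w_Ce = 0.2`, `w_Ci = 0.1`) initial common weights;
#' `w_S = 0.01`, `alpha = 0.01`, `sigma = 0.6195`, `v = 6` throughout.
#'
#' @return A named list of panel configurations.
#' @export
default_strategy_panels <- function() {
  base <- list(alpha = 0.01, sigma = 0.6195, v = 6, w_S = 0.01)
  list(
    a = c(base, list(larger = "S_PLUS", w_Ce = 2, w_Ci = 1)),
    b = c(base, list(larger = "S_PLUS", w_Ce = 0.2, w_Ci = 0.1)),
    c = c(base, list(larger = "S_MINUS", w_Ce = 2, w_Ci = 1)),
    d = c(base, list(larger = "S_MINUS", w_Ce = 0.2, w_Ci = 0.1))
  )
}

#' Post-learning catch-trial probe probabilities
#'
#' Runs each parameter panel to convergence in ergodic mode and reports the
#' lick probability for the common population alone, each specific
#' population alone, and a blank, read out from the learned weights.
#'
#' @param panels A list of panel configurations as produced by
#'   [default_strategy_panels()].
#' @param max_steps Ergodic step cap.
#' @return An `experiment_report` with a `probes` table (one row per panel
#'   and probe) and a `weights` table of learned weights.
#' @export
run_strategy_probe <- function(panels = default_strategy_panels(),
                               max_steps = 1e5L) {
  probe_rows <- list()
  weight_rows <- list()
  for (nm in names(panels)) {
    p <- panels[[nm]]
    scen <- recruitment_scenario(common = 1, weak = 1, strong = 2,
                                 larger = p$larger)
    traj <- simulate_learning(
      scen, rw_weights(w_Ce = p$w_Ce, w_Ci = p$w_Ci, w_S = p$w_S),
      rw_params(alpha = p$alpha, sigma = p$sigma, v = p$v),
      n_trials = NULL, mode = "ergodic", max_steps = max_steps)
    for (pr in c("C", "S_PLUS", "S_MINUS", "blank"))
      probe_rows[[length(probe_rows) + 1L]] <- data.frame(
        panel = nm, larger = p$larger, probe = pr,
        probability = probe_stimulus(traj, pr))
    w <- traj$final_weights
    weight_rows[[length(weight_rows) + 1L]] <- data.frame(
      panel = nm, t(c(E = w$E, I = w$I)))
  }
  new_report("strategy_probe",
             config = list(panels = panels, max_steps = max_steps),
             seed = NA_integer_,
             tables = list(probes = do.call(rbind, probe_rows),
                           weights = do.call(rbind, weight_rows)))
}

#' Converged drive and asymptotic performance of the ergodic model
#'
#' Runs the ergodic model to convergence and reports the drives
#' `dW.X_S+` and `dW.X_S-` against their fixed-point values `+/- 1/sigma`,
#' together with the implied percent-correct
#' `100 * (p_S+ + 1 - p_S-) / 2`.
#'
#' @param params An [rw_params()].
#' @param scenario A [recruitment_scenario()].
#' @param init Initial [rw_weights()].
#' @param converge_tol,max_steps Convergence control.
#' @return An `experiment_report`; `stats` carries `dwx_plus`, `dwx_minus`,
#'   `target_drive = 1/sigma`, and `percent_correct`.
#' @export
run_asymptote_check <- function(params = rw_params(),
                                scenario = recruitment_scenario(1, 1, 2,
                                                                "S_PLUS"),
                                init = rw_weights(2, 1, 0.01),
                                converge_tol = 1e-8, max_steps = 1e5L) {
  traj <- simulate_learning(scenario, init, params, n_trials = NULL,
                            mode = "ergodic", converge_tol = converge_tol,
                            max_steps = max_steps)
  s <- summary(traj)
  stats <- list(dwx_plus = s$dwx_plus, dwx_minus = s$dwx_minus,
                target_drive = 1 / params$sigma,
                p_splus = utils::tail(traj$p_splus, 1),
                p_sminus = utils::tail(traj$p_sminus, 1),
                percent_correct = 100 * s$final_performance,
                converged = isTRUE(traj$converged),
                n_steps = traj$n_steps)
  new_report("asymptote_check",
             config = list(params = unclass(params),
                           scenario = unclass(scenario),
                           init = unclass(init),
                           converge_tol = converge_tol),
             seed = params$seed,
             tables = list(summary = data.frame(
               dwx_plus = stats$dwx_plus, dwx_minus = stats$dwx_minus,
               target_drive = stats$target_drive,
               percent_correct = stats$percent_correct)),
             stats = stats)
}

#' Probability that independent binary experiments all agree by chance
#'
#' For `n` independent experiments whose outcome direction is a fair coin
#' flip, the chance that all agree with a prespecified direction is
#' `p ^ n`; with five experiments this is `2^-5`, about 3%.
#'
#' @param n_experiments Number of independent experiments.
#' @param p Per-experiment probability of agreeing (default 0.5).
#' @return The all-agree probability.
#' @examples
#' consistent_direction_probability(5)
#' @export
consistent_direction_probability <- function(n_experiments, p = 0.5) {
  stopifnot(n_experiments >= 1, p >= 0, p <= 1)
  p^n_experiments
}

#' Write an experiment report to a flat directory
#'
#' Creates `config.yaml`, `tables/<name>.csv`, and `report.json` (id, seed,
#' stats) under `dir`; no binary state.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(file.path(dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(report$config, file.path(dir, "config.yaml"))
  for (nm in names(report$tables))
    utils::write.csv(report$tables[[nm]],
                     file.path(dir, "tables", paste0(nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(list(id = report$id, seed = report$seed,
                            stats = report$stats),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
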