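# Synthetic-data generators with known ground truth: balanced Go/NoGo trial
# sequences, GCaMP-like calcium movies, and cohorts of simulated learners.

#' Pseudorandom Go/NoGo trial sequence
#'
#' Every complete block of 8 trials contains exactly 4 S+ and 4 S- trials in
#' a uniformly random within-block order; a trailing partial block is the
#' head of a random balanced block.
#'
#' @param n_trials Sequence length (>= 1).
#' @param seed Optional integer seed.
#' @return Character vector of `"S_PLUS"` / `"S_MINUS"` labels.
#' @export
generate_trial_sequence <- function(n_trials, seed = NULL) {
  stopifnot(n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- ceiling(n_trials / 8)
  block <- c(rep("S_PLUS", 4L), rep("S_MINUS", 4L))
  seq <- unlist(lapply(seq_len(n_blocks), function(b) sample(block)))
  seq[seq_len(n_trials)]
}

#' Specification of a synthetic calcium-imaging dataset
#'
#' Defaults emulate GCaMP6s imaging of mouse auditory cortex: 31.5 Hz
#' acquisition, a 2 s indicator decay constant, a quarter of neurons
#' responsive, and 0.7 neuropil contamination.
#'
#' @param n_neurons,n_trials,duration_s Dataset dimensions (trials are split
#'   evenly between `n_stimuli` stimuli).
#' @param frame_rate Hz (default 31.5).
#' @param tau_s Indicator decay constant in seconds (default 2).
#' @param responsive_fraction_true Fraction of truly responsive neurons.
#' @param response_amplitude Added firing rate (spikes/s) of a responsive
#'   neuron during the stimulus, before per-neuron scaling.
#' @param baseline_rate Spontaneous rate in spikes/s.
#' @param noise_sd Additive Gaussian noise SD in fluorescence units.
#' @param neuropil_gain Contamination gain applied to the shared neuropil
#'   signal (default 0.7).
#' @param pattern_correlation Correlation between the per-neuron response
#'   amplitude patterns of the stimuli.
#' @param recruitment_ratio Population response of stimulus 2 relative to
#'   stimulus 1.
#' @param n_stimuli Number of stimuli (default 2).
#' @param onset_s,stim_dur_s Stimulus onset and duration in seconds.
#' @param f0 Baseline fluorescence level.
#' @param unit_amplitude Fluorescence per unit calcium (per spike at the
#'   kernel peak).
#' @return An object of class `calcium_spec`.
#' @export
calcium_spec <- function(n_neurons = 60, n_trials = 30, duration_s = 4,
                         frame_rate = 31.5, tau_s = 2,
                         responsive_fraction_true = 0.25,
                         response_amplitude = 4, baseline_rate = 0.2,
                         noise_sd = 0.5, neuropil_gain = 0.7,
                         pattern_correlation = 0.5, recruitment_ratio = 1,
                         n_stimuli = 2, onset_s = 1, stim_dur_s = 0.5,
                         f0 = 100, unit_amplitude = 10) {
  stopifnot(responsive_fraction_true >= 0, responsive_fraction_true <= 1,
            recruitment_ratio > 0, pattern_correlation >= 0,
            pattern_correlation <= 1, n_stimuli >= 1,
            onset_s + stim_dur_s <= duration_s)
  structure(as.list(environment()), class = "calcium_spec")
}

#' Generate a synthetic calcium-imaging dataset with ground truth
#'
#' Forward model: Poisson spikes at stimulus-dependent rates, convolved with
#' the exponential indicator kernel `exp(-t / tau)`, scaled and offset into
#' fluorescence, plus additive Gaussian noise and a shared low-frequency
#' neuropil signal scaled by `neuropil_gain`. Responsive neurons share one
#' responsive set across stimuli; their per-stimulus amplitude patterns are
#' positive linear mixtures of a common and a stimulus-specific uniform
#' component, giving exactly the requested pattern correlation in
#' expectation, and stimulus 2's amplitudes are scaled by
#' `recruitment_ratio`.
#'
#' @param spec A [calcium_spec()].
#' @param seed Optional integer seed.
#' @return A list with `dataset` (a [fluorescence_dataset()] of measured
#'   traces plus neuropil traces) and `truth` (true per-frame rates, spike
#'   counts, amplitude matrix, responsive mask, clean cell fluorescence).
#' @export
generate_calcium <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "calcium_spec"))
  if (!is.null(seed)) set.seed(seed)
  nt <- round(spec$duration_s * spec$frame_rate)
  n <- spec$n_neurons
  labels <- rep(paste0("stim", seq_len(spec$n_stimuli)),
                length.out = spec$n_trials)
  labels <- sample(labels)

  n_resp <- round(spec$responsive_fraction_true * n)
  responsive <- rep(FALSE, n)
  if (n_resp > 0) responsive[sample(n, n_resp)] <- TRUE

  # correlated positive amplitude patterns across stimuli
  rho <- spec$pattern_correlation
  u0 <- stats::runif(n, 0.5, 1.5)
  amplitudes <- sapply(seq_len(spec$n_stimuli), function(s) {
    us <- stats::runif(n, 0.5, 1.5)
    a <- spec$response_amplitude * (sqrt(rho) * u0 + sqrt(1 - rho) * us)
    a * responsive
  })
  scale_s <- c(1, rep(spec$recruitment_ratio, spec$n_stimuli - 1L))
  amplitudes <- sweep(amplitudes, 2L, scale_s, `*`)

  t_frames <- (seq_len(nt) - 1L) / spec$frame_rate
  stim_on <- t_frames >= spec$onset_s &
    t_frames < spec$onset_s + spec$stim_dur_s
  decay <- exp(-1 / (spec$tau_s * spec$frame_rate))

  rates <- array(spec$baseline_rate, c(n, spec$n_trials, nt))
  spikes <- array(0L, c(n, spec$n_trials, nt))
  f_cell <- array(0, c(n, spec$n_trials, nt))
  f_np <- array(0, c(n, spec$n_trials, nt))
  for (tr in seq_len(spec$n_trials)) {
    s <- match(labels[tr], paste0("stim", seq_len(spec$n_stimuli)))
    r <- matrix(spec$baseline_rate, n, nt)
    r[, stim_on] <- r[, stim_on] + amplitudes[, s]
    rates[, tr, ] <- r
    sp <- matrix(stats::rpois(n * nt, r / spec$frame_rate), n, nt)
    spikes[, tr, ] <- sp
    # recursive exponential-kernel convolution: c_t = decay c_{t-1} + sp_t
    ca <- t(apply(sp, 1L, function(z)
      stats::filter(z, decay, method = "recursive")))
    f_cell[, tr, ] <- spec$f0 + spec$unit_amplitude * ca
    # shared slow neuropil signal: smoothed random walk, positive offset
    walk <- cumsum(stats::rnorm(nt, sd = 0.5))
    walk <- moving_average(walk, max(1L, round(spec$frame_rate)))
    f_np[, tr, ] <- matrix(20 + walk - min(walk), n, nt, byrow = TRUE)
  }
  noise <- array(stats::rnorm(length(f_cell), sd = spec$noise_sd), dim(f_cell))
  traces <- f_cell + spec$neuropil_gain * f_np + noise

  dataset <- fluorescence_dataset(
    traces, frame_rate = spec$frame_rate, stimulus_labels = labels,
    neuropil_traces = f_np, onset_s = spec$onset_s,
    offset_s = spec$onset_s + spec$stim_dur_s)
  list(dataset = dataset,
       truth = list(rates = rates, spikes = spikes,
                    amplitudes = amplitudes, responsive = responsive,
                    labels = labels, f_cell = f_cell))
}

#' Specification of a simulated learner cohort
#'
#' Stands in for a panel of per-animal initial conditions: shared core
#' parameters and per-subject initial weights drawn from wide distributions
#' (`w_S` log-uniform, `w_Ce` uniform, `w_Ci = w_Ce / 2`).
#'
#' @param n_subjects Cohort size (default 15).
#' @param w_s_range Range of the stimulus-specific initial weight, sampled
#'   log-uniformly (default `[1e-3, 1e-1]`).
#' @param w_ce_range Range of the common excitatory weight, sampled
#'   uniformly (default `[0.1, 2]`).
#' @param alpha,sigma,v Core model parameters shared by all subjects.
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 15, w_s_range = c(1e-3, 1e-1),
                        w_ce_range = c(0.1, 2), alpha = 0.01,
                        sigma = 0.6195, v = 6, seed = 1L) {
  stopifnot(n_subjects >= 1, all(w_s_range > 0), all(w_ce_range > 0),
            w_s_range[1L] <= w_s_range[2L], w_ce_range[1L] <= w_ce_range[2L])
  structure(list(n_subjects = as.integer(n_subjects),
                 w_s_range = w_s_range, w_ce_range = w_ce_range,
                 alpha = alpha, sigma = sigma, v = v,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a cohort of simulated learners
#'
#' @param spec A [cohort_spec()].
#' @return A list of subjects, each with an `id`, initial [rw_weights()],
#'   sampled `w_Ce`, `w_Ci`, `w_S`, and shared [rw_params()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  w_s <- 10^stats::runif(spec$n_subjects, log10(spec$w_s_range[1L]),
                         log10(spec$w_s_range[2L]))
  w_ce <- stats::runif(spec$n_subjects, spec$w_ce_range[1L],
                       spec$w_ce_range[2L])
  lapply(seq_len(spec$n_subjects), function(i) {
    list(id = i,
         w_Ce = w_ce[i], w_Ci = w_ce[i] / 2, w_S = w_s[i],
         weights = rw_weights(w_Ce = w_ce[i], w_Ci = w_ce[i] / 2,
                              w_S = w_s[i]),
         params = rw_params(alpha = spec$alpha, sigma = spec$sigma,
                            v = spec$v))
  })
}
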