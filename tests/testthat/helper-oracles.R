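# Shared helpers for the test suite.

# four-parameter logistic used as ground truth in recovery tests
logistic_curve <- function(t, baseline, amplitude, midpoint, scale) {
  baseline + amplitude / (1 + exp(-(t - midpoint) / scale))
}

# closed-form phase durations of a logistic with positive amplitude,
# 20%/80% relative thresholds, delay clamped at zero
logistic_phases <- function(midpoint, scale) {
  midpoint <- unname(midpoint)
  scale <- unname(scale)
  t20 <- midpoint - scale * log(4)
  t80 <- midpoint + scale * log(4)
  delay <- max(t20, 0)
  list(delay = delay, learning = t80 - delay)
}

# deterministic fluorescence dataset builder for the metric tests:
# trace_fun(neuron, trial) returns a numeric vector of n_frames values
make_dataset <- function(trace_fun, n_neurons, n_trials, n_frames,
                         frame_rate = 10, labels = rep("A", n_trials),
                         onset_s = 0, offset_s = 0) {
  tr <- array(0, c(n_neurons, n_trials, n_frames))
  for (n in seq_len(n_neurons))
    for (k in seq_len(n_trials))
      tr[n, k, ] <- trace_fun(n, k)
  fluorescence_dataset(tr, frame_rate = frame_rate, stimulus_labels = labels,
                       onset_s = onset_s, offset_s = offset_s)
}

# wrap a rates array directly in a deconvolved container (unit of analysis
# for population_response / responsive_fraction / similarity / decoding)
make_deconvolved <- function(rates, frame_rate = 10, labels, onset_s = 0,
                             offset_s = 0) {
  structure(list(rates = rates, tau = 2, frame_rate = frame_rate,
                 stimulus_labels = as.character(labels),
                 onset_s = onset_s, offset_s = offset_s),
            class = "deconvolved_dataset")
}
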