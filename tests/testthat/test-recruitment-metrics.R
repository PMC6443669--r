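# Imaging metrics: neuropil correction, dF/F0, deconvolution, population
# responses, responsiveness, similarity, decoding, grid integrals, overlap.

test_that("neuropil_correct subtracts 0.7 of the neuropil signal", {
  cell <- function(n, k) rep(10, 8)
  ds <- make_dataset(cell, 1, 1, 8)
  ds$neuropil_traces <- array(10, dim(ds$traces))
  out <- neuropil_correct(ds)
  expect_equal(as.numeric(out$traces), rep(10 - 0.7 * 10, 8))
  expect_null(out$neuropil_traces)
  # exact recovery of the true signal when contamination is additive
  true_sig <- array(seq_len(8), c(1, 1, 8))
  np <- array(runif(8), c(1, 1, 8))
  ds2 <- fluorescence_dataset(true_sig + 0.7 * np, frame_rate = 10,
                              stimulus_labels = "A", neuropil_traces = np)
  expect_equal(neuropil_correct(ds2)$traces, true_sig)
  expect_error(neuropil_correct(make_dataset(cell, 1, 1, 8)), "no neuropil")
})

test_that("compute_dff is zero on a constant trace and exact on a transient", {
  n_frames <- 100
  ds <- make_dataset(function(n, k) rep(100, n_frames), 1, 2, n_frames,
                     frame_rate = 2)
  out <- compute_dff(ds, window_s = 40, smooth_s = 0)
  expect_equal(as.numeric(out$traces), rep(0, 2 * n_frames))
  # a brief 100 -> 150 transient on a flat 100 baseline: peak dF/F0 = 0.5
  tr <- rep(100, n_frames)
  tr[50] <- 150
  ds2 <- make_dataset(function(n, k) tr, 1, 1, n_frames, frame_rate = 2)
  out2 <- compute_dff(ds2, window_s = 40, smooth_s = 0)
  expect_equal(out2$traces[1, 1, 50], 0.5)
  expect_equal(out2$traces[1, 1, 10], 0)
})

test_that("compute_dff excludes neurons with a non-positive baseline", {
  tr <- function(n, k) if (n == 1) rep(0, 100) else rep(100, 100)
  ds <- make_dataset(tr, 2, 1, 100, frame_rate = 2)
  out <- compute_dff(ds, window_s = 40, smooth_s = 0)
  expect_equal(attr(out$traces, "excluded_neurons"), 1L)
  expect_true(all(is.na(out$traces[1, , ])))
  expect_true(all(out$traces[2, , ] == 0))
})

test_that("deconvolve returns c/tau for a constant trace", {
  ds <- make_dataset(function(n, k) rep(3, 20), 1, 1, 20, frame_rate = 10)
  out <- deconvolve(ds, tau_s = 2)
  expect_equal(as.numeric(out$rates), rep(3 / 2, 20))
})

test_that("deconvolve is linear to machine precision", {
  set.seed(3)
  n_frames <- 50
  f1 <- array(rnorm(2 * 3 * n_frames), c(2, 3, n_frames))
  f2 <- array(rnorm(2 * 3 * n_frames), c(2, 3, n_frames))
  wrap <- function(f) fluorescence_dataset(f, frame_rate = 10,
                                           stimulus_labels = rep("A", 3))
  r1 <- deconvolve(wrap(f1))$rates
  r2 <- deconvolve(wrap(f2))$rates
  r12 <- deconvolve(wrap(2.5 * f1 - 0.7 * f2))$rates
  expect_lt(max(abs(r12 - (2.5 * r1 - 0.7 * r2))), 1e-12)
})

test_that("deconvolve annihilates the discrete indicator kernel", {
  # the discrete null space of r_t = (f_{t+1} - f_t) fr + f_t / tau is the
  # geometric decay with ratio 1 - 1/(tau * fr)
  fr <- 10
  tau <- 2
  k <- 1 - 1 / (tau * fr)
  f <- array(5 * k^(0:39), c(1, 1, 40))
  ds <- fluorescence_dataset(f, frame_rate = fr, stimulus_labels = "A")
  r <- as.numeric(deconvolve(ds, tau_s = tau)$rates)
  # the final sample replicates the previous forward difference (documented
  # edge handling), so exact annihilation holds everywhere before it
  expect_lt(max(abs(r[-40])), 1e-12)
})

test_that("population_response averages the window and subtracts baselines", {
  # rates identically 1: the grand mean is 1 for any window
  rates <- array(1, c(5, 4, 30))
  ds <- make_deconvolved(rates, frame_rate = 10, labels = rep(c("A", "B"), 2),
                         onset_s = 1, offset_s = 1.5)
  pr <- population_response(ds, "A")
  expect_equal(pr$mean, 1)
  expect_equal(unname(pr$per_neuron), rep(1, 5))
  pr2 <- population_response(ds, "A", window = c(0.05, 2.95))
  expect_equal(pr2$mean, 1)
  # baseline 1, response 3: baseline-subtracted response is 2
  rates2 <- array(1, c(2, 2, 30))
  rates2[, , 11:20] <- 3
  ds2 <- make_deconvolved(rates2, frame_rate = 10, labels = c("A", "A"),
                          onset_s = 1, offset_s = 1.5)
  pr3 <- population_response(ds2, "A", window = c(1, 2),
                             baseline_window = c(0, 1))
  expect_equal(pr3$mean, 2)
  expect_error(population_response(ds2, "Z"), "not found")
  expect_error(population_response(ds2, "A", window = c(5, 6)), "window")
})

test_that("response windows are half-open in time", {
  rates <- array(0, c(1, 1, 10))
  rates[1, 1, 6] <- 10  # frame 6 is t = 0.5 s at 10 Hz
  ds <- make_deconvolved(rates, frame_rate = 10, labels = "A")
  # [0, 0.5) excludes the spike frame; [0.5, 0.6) contains exactly it
  expect_equal(population_response(ds, "A", window = c(0, 0.5))$mean, 0)
  expect_equal(population_response(ds, "A", window = c(0.5, 0.6))$mean, 10)
})

test_that("responsive_fraction detects consistent responders via sign test", {
  n_frames <- 40
  rates <- array(0, c(3, 20, n_frames))
  # neuron 1 responds on every trial; neurons 2-3 are flat (all-zero
  # differences are not evidence of a response)
  rates[1, , 21:30] <- 5
  ds <- make_deconvolved(rates, frame_rate = 10, labels = rep("A", 20),
                         onset_s = 2, offset_s = 2.5)
  expect_equal(responsive_fraction(ds, "A", n_reps = 20), 1 / 3)
  expect_error(responsive_fraction(ds, "A", n_reps = 30), "at least 30")
})

test_that("split-half similarity is 1 for perfectly reliable patterns", {
  pattern_a <- c(1, 5, 2, 8)
  pattern_b <- c(8, 2, 5, 1)
  rates <- array(0, c(4, 8, 10))
  labels <- rep(c("A", "B"), 4)
  for (tr in 1:8)
    rates[, tr, ] <- if (labels[tr] == "A") pattern_a else pattern_b
  ds <- make_deconvolved(rates, frame_rate = 10, labels = labels,
                         onset_s = 0, offset_s = 0.5)
  m <- similarity_matrix(ds, window = c(0, 1))
  expect_equal(unname(diag(m)), c(1, 1))
  expect_true(isSymmetric(m))
  expect_equal(m["A", "B"], cor(pattern_a, pattern_b))
})

test_that("decode_pair separates disjoint patterns perfectly", {
  set.seed(5)
  rates <- array(rnorm(6 * 60 * 10, sd = 0.05), c(6, 60, 10))
  labels <- rep(c("A", "B"), 30)
  for (tr in 1:60) {
    if (labels[tr] == "A") rates[1:3, tr, ] <- rates[1:3, tr, ] + 2
    else rates[4:6, tr, ] <- rates[4:6, tr, ] + 2
  }
  ds <- make_deconvolved(rates, frame_rate = 10, labels = labels,
                         onset_s = 0, offset_s = 0.5)
  acc <- decode_pair(ds, "A", "B", n_train = 20, n_test = 10, seed = 1)
  expect_equal(as.numeric(acc), 1)
  expect_error(decode_pair(ds, "A", "B", n_train = 55), ">= 65")
})

test_that("grid metrics follow their defining arithmetic", {
  rec <- grid_recording(c(1, 2, 3), dx = 180, dy = 180,
                        responsive_counts = c(2, 3, 5), n_cells = 10)
  expect_equal(grid_integrated_rate(rec), 6 * 180 * 180 / 360^2)
  expect_equal(responsive_cell_fraction_grid(rec), 10 / (3 * 10))
  expect_equal(grid_integrated_rate(grid_recording(4, dx = 360, dy = 360)), 4)
  expect_error(responsive_cell_fraction_grid(grid_recording(1, 1, 1)),
               "required")
})

test_that("overlap_fraction is the common share of activated cells", {
  expect_equal(overlap_fraction(1, 1, 2.5), 1 / 4.5)
  expect_equal(overlap_fraction(1, 1, 1), 1 / 3)
  expect_equal(overlap_fraction(2, 1, 1), 1 / 2)
  expect_error(overlap_fraction(0, 1, 1), "positive")
})
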