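# Cortical-recruitment metrics for calcium-imaging and electrode-grid data:
# neuropil correction, dF/F0, exponential-kernel deconvolution, population
# responses, responsive fractions, split-half similarity, linear decoding,
# and grid-integrated population rates.

#' Fluorescence dataset container
#'
#' @param traces Numeric array, neurons x trials x timepoints.
#' @param frame_rate Acquisition rate in Hz (> 0).
#' @param stimulus_labels Per-trial stimulus identifiers (length = trials).
#' @param neuropil_traces Optional neuropil array of the same shape.
#' @param onset_s,offset_s Stimulus onset/offset in seconds from trial start.
#' @return An object of class `fluorescence_dataset`.
#' @export
fluorescence_dataset <- function(traces, frame_rate, stimulus_labels,
                                 neuropil_traces = NULL,
                                 onset_s = 0, offset_s = onset_s) {
  stopifnot(is.array(traces), length(dim(traces)) == 3L,
            is.numeric(frame_rate), frame_rate > 0,
            length(stimulus_labels) == dim(traces)[2L],
            offset_s >= onset_s)
  if (!is.null(neuropil_traces))
    stopifnot(identical(dim(neuropil_traces), dim(traces)))
  structure(list(traces = traces, neuropil_traces = neuropil_traces,
                 frame_rate = frame_rate,
                 stimulus_labels = as.character(stimulus_labels),
                 onset_s = onset_s, offset_s = offset_s),
            class = "fluorescence_dataset")
}

#' @export
print.fluorescence_dataset <- function(x, ...) {
  d <- dim(x$traces)
  cat(sprintf("Fluorescence dataset: %d neurons x %d trials x %d frames @ %.1f Hz\n",
              d[1L], d[2L], d[3L], x$frame_rate))
  cat("stimuli:", paste(names(table(x$stimulus_labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Subtract neuropil contamination
#'
#' `F_true(t) = F_measured(t) - factor * F_neuropil(t)` element-wise, with
#' the standard contamination factor 0.7.
#'
#' @param dataset A [fluorescence_dataset()] carrying `neuropil_traces`.
#' @param factor Contamination factor (default 0.7).
#' @return The dataset with corrected traces; the neuropil array is dropped.
#' @export
neuropil_correct <- function(dataset, factor = 0.7) {
  stopifnot(inherits(dataset, "fluorescence_dataset"))
  if (is.null(dataset$neuropil_traces))
    stop("dataset has no neuropil traces")
  dataset$traces <- dataset$traces - factor * dataset$neuropil_traces
  dataset$neuropil_traces <- NULL
  dataset
}

moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  k <- rep(1 / width, width)
  sm <- stats::filter(x, k, sides = 2)
  # zero-phase edges: fall back to the raw signal where the window is partial
  sm[is.na(sm)] <- x[is.na(sm)]
  as.numeric(sm)
}

#' Normalized fluorescence change dF/F0
#'
#' The baseline `F0(t)` is the rolling minimum, over windows of about
#' `window_s` seconds, of the low-pass filtered (zero-phase moving average of
#' width `smooth_s`) fluorescence of each neuron's concatenated trace; the
#' output is `(F - F0) / F0`. Neurons whose baseline is not strictly positive
#' are excluded (set to `NA`) and listed in the `"excluded_neurons"`
#' attribute of the traces.
#'
#' @param dataset A [fluorescence_dataset()].
#' @param window_s Rolling-minimum window in seconds (default 40).
#' @param smooth_s Moving-average width in seconds (default 1).
#' @return The dataset with dF/F0 traces.
#' @export
compute_dff <- function(dataset, window_s = 40, smooth_s = 1) {
  stopifnot(inherits(dataset, "fluorescence_dataset"))
  d <- dim(dataset$traces)
  n_time_total <- d[2L] * d[3L]
  w_min <- max(2L, round(window_s * dataset$frame_rate))
  w_sm <- max(1L, round(smooth_s * dataset$frame_rate))
  if (n_time_total < w_min)
    stop("trace shorter than one baseline window")
  excluded <- integer(0)
  out <- dataset$traces
  for (n in seq_len(d[1L])) {
    f <- as.numeric(aperm(dataset$traces[n, , , drop = FALSE], c(1, 3, 2)))
    sm <- moving_average(f, w_sm)
    f0 <- zoo::rollapply(zoo::zoo(sm), width = w_min, FUN = min,
                         align = "center", partial = TRUE)
    f0 <- as.numeric(f0)
    if (any(f0 <= 0)) {
      excluded <- c(excluded, n)
      out[n, , ] <- NA_real_
    } else {
      out[n, , ] <- matrix((f - f0) / f0, nrow = d[2L], ncol = d[3L],
                           byrow = TRUE)
    }
  }
  dataset$traces <- out
  attr(dataset$traces, "excluded_neurons") <- excluded
  dataset
}

#' Deconvolve calcium traces into firing-rate estimates
#'
#' Inverts the single-exponential indicator kernel via
#' `r(t) = f'(t) + f(t) / tau`, with the derivative taken as the forward
#' difference scaled by the frame rate (the last sample repeats the previous
#' derivative). The operator is linear, so additivity holds exactly.
#'
#' @param dataset A [fluorescence_dataset()] (typically dF/F0 traces).
#' @param tau_s Indicator decay constant in seconds (2 for GCaMP6s).
#' @return An object of class `deconvolved_dataset` with a `rates` array of
#'   the same shape.
#' @export
deconvolve <- function(dataset, tau_s = 2) {
  stopifnot(inherits(dataset, "fluorescence_dataset"), tau_s > 0)
  f <- dataset$traces
  d <- dim(f)
  nt <- d[3L]
  fd <- (f[, , c(2:nt, nt), drop = FALSE] - f) * dataset$frame_rate
  fd[, , nt] <- fd[, , nt - 1L]  # replicate last forward difference
  rates <- fd + f / tau_s
  structure(list(rates = rates, tau = tau_s,
                 frame_rate = dataset$frame_rate,
                 stimulus_labels = dataset$stimulus_labels,
                 onset_s = dataset$onset_s, offset_s = dataset$offset_s),
            class = "deconvolved_dataset")
}

# frame indices for a half-open time window [start, end) in seconds
window_frames <- function(window, frame_rate, n_frames) {
  stopifnot(length(window) == 2L, window[1L] < window[2L])
  t <- (seq_len(n_frames) - 1L) / frame_rate
  idx <- which(t >= window[1L] & t < window[2L])
  if (length(idx) == 0L)
    stop("empty window: [", window[1L], ", ", window[2L],
         ") contains no frames")
  if (window[1L] < 0 || window[1L] >= n_frames / frame_rate)
    stop("window outside the data extent")
  idx
}

#' Population response to a stimulus
#'
#' Mean deconvolved signal per neuron, averaged over trials of the stimulus
#' and over a response window (default: sound onset to 500 ms after offset).
#' The grand mean over neurons is the recruitment scalar. An optional
#' baseline window is subtracted per neuron before averaging.
#'
#' @param dataset A `deconvolved_dataset`.
#' @param stimulus Stimulus label.
#' @param window Response window `c(start, end)` in seconds from trial
#'   start, half-open.
#' @param baseline_window Optional baseline window to subtract (per neuron).
#' @return A list with `per_neuron` responses, the grand `mean`, and the
#'   window used.
#' @export
population_response <- function(dataset, stimulus,
                                window = c(dataset$onset_s,
                                           dataset$offset_s + 0.5),
                                baseline_window = NULL) {
  stopifnot(inherits(dataset, "deconvolved_dataset"))
  trials <- which(dataset$stimulus_labels == stimulus)
  if (length(trials) == 0L) stop("stimulus not found: ", stimulus)
  nt <- dim(dataset$rates)[3L]
  idx <- window_frames(window, dataset$frame_rate, nt)
  resp <- apply(dataset$rates[, trials, idx, drop = FALSE], 1L, mean)
  if (!is.null(baseline_window)) {
    bidx <- window_frames(baseline_window, dataset$frame_rate, nt)
    resp <- resp - apply(dataset$rates[, trials, bidx, drop = FALSE], 1L, mean)
  }
  list(per_neuron = resp, mean = mean(resp, na.rm = TRUE), window = window)
}

#' Fraction of stimulus-responsive neurons
#'
#' A neuron is responsive if its single-trial response-window means differ
#' from its baseline-window means by a two-sided sign test at level `alpha`
#' across `n_reps` stimulus repetitions. The default baseline is an
#' equal-length window immediately before stimulus onset.
#'
#' @param dataset A `deconvolved_dataset`.
#' @param stimulus Stimulus label (>= `n_reps` trials required).
#' @param n_reps Number of repetitions entering the test (default 20).
#' @param alpha Test level (default 0.05).
#' @param window Response window in seconds; defaults to onset to 500 ms
#'   after offset.
#' @param baseline_window Baseline window; defaults to the mirror-image
#'   window before onset.
#' @return The responsive fraction in `[0, 1]`.
#' @export
responsive_fraction <- function(dataset, stimulus, n_reps = 20, alpha = 0.05,
                                window = c(dataset$onset_s,
                                           dataset$offset_s + 0.5),
                                baseline_window = NULL) {
  stopifnot(inherits(dataset, "deconvolved_dataset"))
  trials <- which(dataset$stimulus_labels == stimulus)
  if (length(trials) < n_reps)
    stop("need at least ", n_reps, " trials of stimulus ", stimulus)
  trials <- trials[seq_len(n_reps)]
  if (is.null(baseline_window)) {
    len <- window[2L] - window[1L]
    baseline_window <- c(window[1L] - len, window[1L])
  }
  nt <- dim(dataset$rates)[3L]
  idx <- window_frames(window, dataset$frame_rate, nt)
  bidx <- window_frames(baseline_window, dataset$frame_rate, nt)
  n_neurons <- dim(dataset$rates)[1L]
  responsive <- vapply(seq_len(n_neurons), function(n) {
    r <- apply(dataset$rates[n, trials, idx, drop = FALSE], 2L, mean)
    b <- apply(dataset$rates[n, trials, bidx, drop = FALSE], 2L, mean)
    d <- r - b
    d <- d[d != 0]
    if (length(d) == 0L) return(FALSE)
    stats::binom.test(sum(d > 0), length(d))$p.value < alpha
  }, logical(1))
  mean(responsive)
}

trial_vectors <- function(dataset, trials, window) {
  nt <- dim(dataset$rates)[3L]
  idx <- window_frames(window, dataset$frame_rate, nt)
  t(apply(dataset$rates[, trials, idx, drop = FALSE], c(1, 2), mean))
}

#' Split-half population similarity matrix
#'
#' Pearson correlations between mean population response vectors computed
#' from disjoint trial halves (odd/even split). The diagonal correlates the
#' two halves of the same stimulus (reliability); off-diagonal entries
#' average the two cross-half, cross-stimulus correlations. Zero-variance
#' vectors yield `NA` entries.
#'
#' @param dataset A `deconvolved_dataset`.
#' @param stimuli Stimulus labels (default: all, in first-appearance order);
#'   each needs >= 2 trials.
#' @param window Response window in seconds.
#' @return A symmetric correlation matrix over stimuli.
#' @export
similarity_matrix <- function(dataset, stimuli = NULL,
                              window = c(dataset$onset_s,
                                         dataset$offset_s + 0.5)) {
  stopifnot(inherits(dataset, "deconvolved_dataset"))
  if (is.null(stimuli)) stimuli <- unique(dataset$stimulus_labels)
  halves <- lapply(stimuli, function(s) {
    trials <- which(dataset$stimulus_labels == s)
    if (length(trials) < 2L) stop("stimulus ", s, " needs >= 2 trials")
    odd <- trials[seq_along(trials) %% 2L == 1L]
    even <- trials[seq_along(trials) %% 2L == 0L]
    list(h1 = colMeans(trial_vectors(dataset, odd, window)),
         h2 = colMeans(trial_vectors(dataset, even, window)))
  })
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  k <- length(stimuli)
  m <- matrix(NA_real_, k, k, dimnames = list(stimuli, stimuli))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    m[i, j] <- mean(c(safe_cor(halves[[i]]$h1, halves[[j]]$h2),
                      safe_cor(halves[[i]]$h2, halves[[j]]$h1)))
  }
  (m + t(m)) / 2
}

#' Pairwise stimulus decoding with a linear classifier
#'
#' Trains a linear maximum-margin classifier (support vector machine) on
#' `n_train` single-trial population vectors per stimulus and reports its
#' accuracy on `n_test` held-out trials per stimulus, optionally averaged
#' over repeated random splits.
#'
#' @param dataset A `deconvolved_dataset`.
#' @param stim_a,stim_b Stimulus labels (each with >= `n_train + n_test`
#'   trials).
#' @param n_train,n_test Training/test trials per stimulus (defaults 20/10).
#' @param n_repeats Number of random splits to average (default 1).
#' @param seed Optional seed making the splits reproducible.
#' @param cost Regularization constant of the classifier (default 1,
#'   recorded in the `"cost"` attribute of the result).
#' @param window Response window in seconds.
#' @return Mean held-out accuracy in `[0, 1]`.
#' @export
decode_pair <- function(dataset, stim_a, stim_b, n_train = 20, n_test = 10,
                        n_repeats = 1, seed = NULL, cost = 1,
                        window = c(dataset$onset_s, dataset$offset_s + 0.5)) {
  stopifnot(inherits(dataset, "deconvolved_dataset"))
  if (!is.null(seed)) set.seed(seed)
  get_trials <- function(s) {
    tr <- which(dataset$stimulus_labels == s)
    if (length(tr) < n_train + n_test)
      stop("stimulus ", s, " needs >= ", n_train + n_test, " trials")
    tr
  }
  ta <- get_trials(stim_a)
  tb <- get_trials(stim_b)
  va <- trial_vectors(dataset, ta, window)
  vb <- trial_vectors(dataset, tb, window)
  acc <- vapply(seq_len(n_repeats), function(r) {
    ia <- sample(nrow(va), n_train + n_test)
    ib <- sample(nrow(vb), n_train + n_test)
    xtr <- rbind(va[ia[seq_len(n_train)], , drop = FALSE],
                 vb[ib[seq_len(n_train)], , drop = FALSE])
    xte <- rbind(va[ia[n_train + seq_len(n_test)], , drop = FALSE],
                 vb[ib[n_train + seq_len(n_test)], , drop = FALSE])
    ytr <- factor(rep(c("a", "b"), each = n_train))
    yte <- factor(rep(c("a", "b"), each = n_test))
    fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = cost,
                      scale = FALSE)
    mean(stats::predict(fit, xte) == yte)
  }, numeric(1))
  structure(mean(acc), cost = cost)
}

#' Electrode-grid recording of optogenetically evoked responses
#'
#' @param rates Population response `r_{x,y}` at each grid location (one
#'   value per location).
#' @param dx,dy Grid spacings in micrometers.
#' @param responsive_counts Optional per-location responsive-cell counts.
#' @param n_cells Total number of recorded cells (for the responsive
#'   fraction).
#' @return An object of class `grid_recording`.
#' @export
grid_recording <- function(rates, dx, dy, responsive_counts = NULL,
                           n_cells = NULL) {
  stopifnot(is.numeric(rates), length(rates) >= 1L,
            all(is.finite(rates)), dx > 0, dy > 0)
  if (!is.null(responsive_counts))
    stopifnot(length(responsive_counts) == length(rates),
              all(responsive_counts >= 0))
  structure(list(rates = as.numeric(rates), dx = dx, dy = dy,
                 responsive_counts = responsive_counts,
                 n_locations = length(rates), n_cells = n_cells),
            class = "grid_recording")
}

#' Grid-integrated population firing rate
#'
#' The population rate elicited by a single optogenetic disk, estimated as
#' the integral `sum r_{x,y} dx dy` over grid locations, normalized by the
#' reference cell area `360 x 360 um^2`.
#'
#' @param rec A [grid_recording()].
#' @param ref_area Normalization area in um^2 (default `360^2`).
#' @return The normalized integrated rate.
#' @export
grid_integrated_rate <- function(rec, ref_area = 360^2) {
  stopifnot(inherits(rec, "grid_recording"))
  sum(rec$rates) * rec$dx * rec$dy / ref_area
}

#' Overall responsive-cell fraction over a stimulation grid
#'
#' `sum_{x,y} N_responsive(x,y) / (N_locations * N_cells)`.
#'
#' @param rec A [grid_recording()] with `responsive_counts` and `n_cells`.
#' @return The fraction in `[0, 1]`.
#' @export
responsive_cell_fraction_grid <- function(rec) {
  stopifnot(inherits(rec, "grid_recording"))
  if (is.null(rec$responsive_counts) || is.null(rec$n_cells))
    stop("responsive counts and total cell number are required")
  if (rec$n_cells == 0) stop("n_cells must be positive")
  sum(rec$responsive_counts) / (rec$n_locations * rec$n_cells)
}

#' Fraction of commonly activated cells in a compound stimulus
#'
#' For a compound whose common, small specific and large specific components
#' activate neurons in given proportions, the overlap fraction is
#' `common / (common + small_specific + large_specific)`; with proportions
#' 1 : 1 : 2.5 this is about 22%.
#'
#' @param common,small_specific,large_specific Positive activation
#'   proportions.
#' @return The overlap fraction in `(0, 1)`.
#' @examples
#' overlap_fraction(1, 1, 2.5)
#' @export
overlap_fraction <- function(common, small_specific, large_specific) {
  if (any(c(common, small_specific, large_specific) <= 0))
    stop("all activation proportions must be positive")
  common / (common + small_specific + large_specific)
}
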