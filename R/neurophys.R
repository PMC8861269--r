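#' Default sample spacing of the simulated recordings
#'
#' One movement occupies `step_duration` seconds (default 0.25 s), so with
#' 16 gradient-descent iterations per step each iteration is a 15.625 ms
#' sample (64 Hz): one belief-update cycle per move is a 4 Hz rhythm.
#'
#' @param iterations_per_step iterations per movement.
#' @param step_duration seconds per movement.
#' @return sample spacing in seconds.
#' @export
ephys_dt <- function(iterations_per_step = 16, step_duration = 0.25) {
  step_duration / iterations_per_step
}

#' Firing-rate raster of hidden-state units
#'
#' One unit per (location, represented time point): unit `(j, tau)` at
#' global iteration `k` holds the Bayesian-model-average state expectation
#' `s_bar_tau[j]` recorded at that iteration. For the 10x10 navigation
#' scenario with 10 moves this yields 100 x 11 = 1,100 units over 160
#' iterations. Columns of units belonging to one represented time point sum
#' to 1 at every iteration.
#'
#' @param belief_trace a `sim_record` (its stored model-average trace is
#'   used), or an array `n_states x n_policies x n_timepoints x iterations`
#'   as recorded by [infer_states()].
#' @param policy_posterior_trace required when `belief_trace` is a raw
#'   per-policy array: probability vector over policies (or a matrix with
#'   one column per iteration).
#' @return matrix `n_units x n_iterations`; attribute `n_states` and
#'   `n_timepoints` give the unit layout (time point varies slowest).
#' @export
firing_rate_raster <- function(belief_trace, policy_posterior_trace = NULL) {
  if (inherits(belief_trace, "sim_record")) {
    tr <- belief_trace$belief_trace
    if (is.null(tr)) stop("record was run with record_trace = FALSE")
    n <- dim(tr)[1]; T1 <- dim(tr)[2]; n_it <- dim(tr)[3]
    raster <- matrix(tr, n * T1, n_it)  # time point varies slowest
  } else {
    d <- dim(belief_trace)  # n, npol, T1, iter
    if (is.null(policy_posterior_trace))
      stop("policy_posterior_trace needed for a per-policy trace")
    q <- policy_posterior_trace
    if (is.matrix(q)) stopifnot(ncol(q) == d[4]) else q <- matrix(q, d[2], d[4])
    raster <- matrix(NA_real_, d[1] * d[3], d[4])
    for (it in seq_len(d[4])) {
      bma <- apply(belief_trace[, , , it, drop = FALSE], 3,
                   function(S) matrix(S, d[1], d[2]) %*% q[, it])
      raster[, it] <- as.vector(bma)
    }
    n <- d[1]; T1 <- d[3]
  }
  structure(raster, n_states = n, n_timepoints = T1)
}

#' Local field potentials from a firing-rate raster
#'
#' Per-unit LFP is the rate of change of the firing rate (first difference
#' divided by the sample spacing); the average trace is the plain mean over
#' units. Because the model-average rates are normalized within each
#' represented time point, this plain average cancels; the depolarization
#' average of [ephys_traces()] is the broadband signal used for spectra.
#'
#' @param raster `n_units x n_iterations` matrix.
#' @param dt sample spacing in seconds.
#' @return list with `lfp` (`n_units x (n_iterations - 1)`) and `average`
#'   (length `n_iterations - 1`).
#' @export
local_field_potentials <- function(raster, dt = ephys_dt()) {
  if (dt <= 0) stop("dt must be > 0")
  lfp <- t(diff(t(raster))) / dt
  list(lfp = lfp, average = colMeans(lfp))
}

#' Simulated dopamine traces from the precision record
#'
#' Tonic dopamine is the precision gamma itself; phasic dopamine is the
#' positive part of its rate of change. Precision is updated once per
#' movement, landing on the last iteration of each 16-iteration block, so
#' phasic events occur only at global iteration indices that are multiples
#' of `iterations_per_step`.
#'
#' @param precision_trace numeric vector of gamma per global iteration, or
#'   a `sim_record` (its `gamma_trace` is used).
#' @param dt sample spacing in seconds.
#' @return list with `tonic` (gamma), `phasic` (aligned with iterations
#'   2..N; index i holds the change landing at iteration i + 1) and
#'   `event_iterations` (1-based global iteration indices of positive
#'   phasic events).
#' @export
dopamine_trace <- function(precision_trace, dt = ephys_dt()) {
  g <- if (inherits(precision_trace, "sim_record")) precision_trace$gamma_trace
       else precision_trace
  dg <- diff(g)
  phasic <- pmax(dg, 0) / dt
  list(tonic = g, phasic = phasic,
       event_iterations = which(phasic > 0) + 1L)
}

#' Zero-phase theta band-pass filter
#'
#' Second-order Butterworth band-pass (default 2-6 Hz around a 4 Hz
#' centre), applied forward and backward so the output is phase-neutral. A
#' sinusoid at the centre frequency passes with less than 10% attenuation;
#' constant input maps to ~0.
#'
#' @param trace numeric signal.
#' @param dt sample spacing in seconds.
#' @param center_hz centre frequency (default 4).
#' @param band band edges in Hz (default `center_hz * c(0.5, 1.5)`).
#' @param order filter order (default 2).
#' @return filtered signal, same length.
#' @export
bandpass_theta <- function(trace, dt = ephys_dt(), center_hz = 4,
                           band = center_hz * c(0.5, 1.5), order = 2) {
  fs <- 1 / dt
  if (band[2] >= fs / 2) stop("band edge at or above the Nyquist frequency")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, trace - mean(trace)))
}

#' Short-time spectral decomposition
#'
#' Windowed Fourier power of a trace (Hanning window, default 1 s with 75%
#' overlap), as a time x frequency power map plus its time average.
#' Frequencies completing fewer than `min_cycles` cycles per window are
#' excluded: they cannot be distinguished from within-window trend at the
#' chosen resolution.
#'
#' @param trace numeric signal (demeaned internally).
#' @param dt sample spacing in seconds.
#' @param window_s window length in seconds (default 1).
#' @param overlap fraction of window overlap (default 0.75).
#' @param min_cycles lowest reported frequency, in cycles per window
#'   (default 2).
#' @return list with `time` (s), `frequency` (Hz), `power`
#'   (`n_freq x n_time`), and `mean_spectrum` (time-averaged power per
#'   frequency).
#' @export
time_frequency <- function(trace, dt = ephys_dt(), window_s = 1,
                           overlap = 0.75, min_cycles = 2) {
  fs <- 1 / dt
  win <- round(window_s * fs)
  if (length(trace) < win) stop("trace shorter than one analysis window")
  sg <- signal::specgram(trace - mean(trace), n = win, Fs = fs,
                         overlap = floor(overlap * win))
  keep <- as.numeric(sg$f) >= min_cycles / window_s
  power <- Mod(sg$S[keep, , drop = FALSE])^2
  list(time = as.numeric(sg$t), frequency = as.numeric(sg$f)[keep],
       power = power, mean_spectrum = rowMeans(power))
}

#' Assemble the simulated electrophysiology of a trial
#'
#' Computes, from a trial record with a belief trace: the firing-rate
#' raster; per-unit LFPs (rate of change of firing rates) and their mean;
#' the depolarization LFP (mean rate of change of log firing rates, the
#' broadband signal that is not cancelled by normalization) raw and
#' theta-filtered; its time-frequency decomposition; and tonic/phasic
#' dopamine.
#'
#' @param record a `sim_record` run with `record_trace = TRUE`.
#' @param dt sample spacing in seconds.
#' @return object of class `ephys_traces`: list with `time`, `raster`,
#'   `lfp`, `lfp_average`, `depolarization_lfp`, `lfp_theta`,
#'   `spectrogram`, `dopamine`, `dt`.
#' @export
ephys_traces <- function(record, dt = ephys_dt(record$iterations_per_step)) {
  raster <- firing_rate_raster(record)
  lfps <- local_field_potentials(raster, dt)
  depol <- log_stable(raster)
  depol_lfp <- colMeans(t(diff(t(depol))) / dt)
  long_enough <- length(depol_lfp) >= round(1 / dt)  # one analysis window
  structure(list(
    time = dt * seq_len(ncol(raster)),
    raster = raster,
    lfp = lfps$lfp,
    lfp_average = lfps$average,
    depolarization_lfp = depol_lfp,
    lfp_theta = if (long_enough) bandpass_theta(depol_lfp, dt),
    spectrogram = if (long_enough) time_frequency(depol_lfp, dt),
    dopamine = dopamine_trace(record, dt),
    dt = dt
  ), class = "ephys_traces")
}

#' @export
print.ephys_traces <- function(x, ...) {
  cat(sprintf("<ephys_traces> %d units x %d iterations (dt = %.4g s)\n",
              nrow(x$raster), ncol(x$raster), x$dt))
  invisible(x)
}

#' Long-format export of electrophysiology traces
#'
#' @param ephys an [ephys_traces()] result.
#' @param path optional CSV path; when given the data frame is also
#'   written.
#' @return data.frame with columns `time_s`, `channel`, `signal_type`
#'   (`lfp_avg`, `da_tonic`, `da_phasic`, `lfp_theta`, `depol_lfp`),
#'   `value`. Unit-level traces are omitted from the long export for size;
#'   use the `raster`/`lfp` matrices directly.
#' @export
ephys_long <- function(ephys, path = NULL) {
  tt <- ephys$time
  out <- rbind(
    data.frame(time_s = tt, channel = "avg", signal_type = "da_tonic",
               value = ephys$dopamine$tonic),
    data.frame(time_s = tt[-1], channel = "avg", signal_type = "da_phasic",
               value = ephys$dopamine$phasic),
    data.frame(time_s = tt[-1], channel = "avg", signal_type = "lfp_avg",
               value = ephys$lfp_average),
    data.frame(time_s = tt[-1], channel = "avg", signal_type = "depol_lfp",
               value = ephys$depolarization_lfp)
  )
  if (!is.null(ephys$lfp_theta))
    out <- rbind(out, data.frame(time_s = tt[-1], channel = "avg",
                                 signal_type = "lfp_theta",
                                 value = ephys$lfp_theta))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
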