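#' Specification of synthetic evoked field-potential sweeps
#'
#' Describes extracellular sweeps containing a truncated stimulus artifact,
#' a presynaptic volley burst (VB), a monosynaptic field potential (FP1,
#' latency 4-6 ms) and a polysynaptic field potential (FP2, latency 6-10 ms).
#' Component amplitudes follow a saturating input-output function of the
#' stimulus current,
#' \deqn{A(I) = A_{max} / (1 + \exp(-k (I - I_{1/2}))),}
#' with \code{io_slope} k (1/uA) and \code{io_half_current} \eqn{I_{1/2}}
#' (uA). \code{potentiation_factor} scales the FP1/FP2 saturation amplitude
#' (> 1 emulates post-hypoxic potentiation of glutamatergic transmission);
#' \code{facilitation_factor} sets the second-response/first-response
#' amplitude ratio for paired pulses. Blockade flags emulate pharmacology:
#' \code{cnqx} (AMPA-receptor blockade) silences FP1 and FP2 only;
#' \code{ttx} (axonal conduction blockade) silences VB, FP1 and FP2.
#'
#' Components are rendered as negative raised-cosine (Hann) pulses with
#' compact support, so noiseless components do not overlap and the trough
#' equals the nominal amplitude exactly at the nominal latency.
#'
#' @param sampling_rate samples per ms (default 20, i.e. 20 kHz).
#' @param sweep_length_ms sweep duration, ms.
#' @param stim_time_ms time of the (first) stimulus, ms.
#' @param vb_latency,fp1_latency,fp2_latency component trough latencies, ms
#'   after the stimulus. FP1 must lie in [4, 6], FP2 in (6, 10].
#' @param vb_amp,fp1_amp,fp2_amp saturation amplitudes of the negative
#'   deflections, mV (positive magnitudes).
#' @param vb_width,fp1_width,fp2_width pulse half-support, ms.
#' @param io_half_current,io_slope input-output sigmoid parameters.
#' @param potentiation_factor multiplicative scaling (>= 1 emulates hLTP) of
#'   FP1/FP2 saturation amplitude.
#' @param facilitation_factor paired-pulse amplitude ratio (> 0).
#' @param cnqx,ttx logical blockade flags.
#' @param artifact_amp stimulus-artifact peak, mV.
#' @param noise_sd additive Gaussian noise, mV.
#' @param seed integer RNG seed.
#' @return An object of class \code{ephys_spec}.
#' @export
ephys_spec <- function(sampling_rate = 20,
                       sweep_length_ms = 120,
                       stim_time_ms = 10,
                       vb_latency = 2.5, fp1_latency = 5, fp2_latency = 8,
                       vb_amp = 0.3, fp1_amp = 1.2, fp2_amp = 0.8,
                       vb_width = 1, fp1_width = 1, fp2_width = 1.5,
                       io_half_current = 200, io_slope = 0.015,
                       potentiation_factor = 1,
                       facilitation_factor = 1.3,
                       cnqx = FALSE, ttx = FALSE,
                       artifact_amp = 5,
                       noise_sd = 0.02,
                       seed = 1L) {
  stopifnot(sampling_rate > 0, sweep_length_ms > 0,
            stim_time_ms > 5, stim_time_ms < sweep_length_ms,
            facilitation_factor > 0, potentiation_factor > 0, noise_sd >= 0)
  if (fp1_latency < 4 || fp1_latency > 6) {
    stop("fp1_latency must lie in the monosynaptic window [4, 6] ms")
  }
  if (fp2_latency <= 6 || fp2_latency > 10) {
    stop("fp2_latency must lie in the polysynaptic window (6, 10] ms")
  }
  # each component must span >= 5 samples
  if (sampling_rate * 2 * min(vb_width, fp1_width, fp2_width) < 5) {
    stop("sampling_rate too low: components must span at least 5 samples")
  }
  structure(list(sampling_rate = sampling_rate,
                 sweep_length_ms = sweep_length_ms,
                 stim_time_ms = stim_time_ms,
                 vb_latency = vb_latency, fp1_latency = fp1_latency,
                 fp2_latency = fp2_latency,
                 vb_amp = vb_amp, fp1_amp = fp1_amp, fp2_amp = fp2_amp,
                 vb_width = vb_width, fp1_width = fp1_width,
                 fp2_width = fp2_width,
                 io_half_current = io_half_current, io_slope = io_slope,
                 potentiation_factor = potentiation_factor,
                 facilitation_factor = facilitation_factor,
                 cnqx = cnqx, ttx = ttx,
                 artifact_amp = artifact_amp, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ephys_spec")
}

#' Input-output amplitude sigmoid
#'
#' The saturating amplitude-recruitment function used by the sweep
#' generator: \code{amp_max / (1 + exp(-io_slope * (I - io_half_current)))}.
#'
#' @param current_ua stimulus current, uA.
#' @param amp_max saturation amplitude, mV.
#' @param io_half_current half-recruitment current, uA.
#' @param io_slope sigmoid steepness, 1/uA.
#' @return Amplitude in mV.
#' @export
io_sigmoid <- function(current_ua, amp_max, io_half_current, io_slope) {
  amp_max / (1 + exp(-io_slope * (current_ua - io_half_current)))
}

# negative Hann pulse: trough -amp at t0, support (t0 - w, t0 + w)
hann_pulse <- function(time_ms, t0, w, amp) {
  u <- (time_ms - t0) / w
  v <- numeric(length(time_ms))
  inside <- abs(u) < 1
  v[inside] <- -amp * 0.5 * (1 + cos(pi * u[inside]))
  v
}

# deterministic sweep body (no RNG); stim_scale scales FP1/FP2 only
render_sweep <- function(spec, time_ms, stim_time, stim_current,
                         fp_scale = 1) {
  s <- io_sigmoid(stim_current, 1, spec$io_half_current, spec$io_slope)
  v <- numeric(length(time_ms))
  # truncated biphasic stimulus artifact, 0.4 ms
  au <- (time_ms - stim_time) / 0.4
  ain <- au >= 0 & au < 1
  v[ain] <- v[ain] + spec$artifact_amp * sin(2 * pi * au[ain]) *
    (1 - au[ain])
  if (!spec$ttx) {
    v <- v + hann_pulse(time_ms, stim_time + spec$vb_latency,
                        spec$vb_width, spec$vb_amp * s)
    if (!spec$cnqx) {
      pot <- spec$potentiation_factor * fp_scale
      v <- v + hann_pulse(time_ms, stim_time + spec$fp1_latency,
                          spec$fp1_width, spec$fp1_amp * pot * s)
      v <- v + hann_pulse(time_ms, stim_time + spec$fp2_latency,
                          spec$fp2_width, spec$fp2_amp * pot * s)
    }
  }
  v
}

new_field_trace <- function(time_ms, voltage_mv, sampling_rate,
                            stim_times_ms, stim_current_ua) {
  structure(list(time_ms = time_ms, voltage_mv = voltage_mv,
                 sampling_rate = sampling_rate,
                 stim_times_ms = stim_times_ms,
                 stim_current_ua = stim_current_ua),
            class = "field_trace")
}

# shared by the public generators; assumes RNG already seeded
make_sweep_core <- function(spec, stim_current, stim_times, fp_scales) {
  n <- round(spec$sweep_length_ms * spec$sampling_rate) + 1L
  time_ms <- (seq_len(n) - 1L) / spec$sampling_rate
  v <- numeric(n)
  for (k in seq_along(stim_times)) {
    v <- v + render_sweep(spec, time_ms, stim_times[k], stim_current,
                          fp_scale = fp_scales[k])
  }
  if (spec$noise_sd > 0) v <- v + stats::rnorm(n, 0, spec$noise_sd)
  new_field_trace(time_ms, v, spec$sampling_rate, stim_times, stim_current)
}

#' Generate one evoked sweep
#'
#' @param spec an [ephys_spec()].
#' @param stim_current stimulus current, uA (>= 0).
#' @return A \code{field_trace}: \code{time_ms}, \code{voltage_mv},
#'   \code{sampling_rate}, \code{stim_times_ms}, \code{stim_current_ua}.
#' @export
make_fepsp_sweep <- function(spec, stim_current) {
  stopifnot(inherits(spec, "ephys_spec"), stim_current >= 0)
  set.seed(spec$seed)
  make_sweep_core(spec, stim_current, spec$stim_time_ms, 1)
}

#' Generate an input-output sweep series
#'
#' One sweep per stimulus current from a shared seeded noise stream. The
#' default grid is the standard recruitment protocol: 0 to 650 uA in 50 uA
#' increments (14 levels).
#'
#' @param spec an [ephys_spec()].
#' @param currents stimulus currents, uA; non-empty, non-negative, unique.
#' @return List of \code{field_trace}.
#' @export
make_io_series <- function(spec, currents = seq(0, 650, by = 50)) {
  stopifnot(inherits(spec, "ephys_spec"), length(currents) >= 1,
            all(currents >= 0))
  if (anyDuplicated(currents)) stop("duplicate stimulus currents")
  set.seed(spec$seed)
  lapply(currents, function(i) {
    make_sweep_core(spec, i, spec$stim_time_ms, 1)
  })
}

#' Generate a paired-pulse sweep
#'
#' Two identical stimuli; the second response's FP1/FP2 amplitudes are
#' scaled by \code{facilitation_factor}. The default protocol is a pair of
#' 50 uA stimuli separated by 75 ms.
#'
#' @param spec an [ephys_spec()].
#' @param stim_current stimulus current, uA.
#' @param interval_ms inter-stimulus interval; must exceed the full span of
#'   the first response (FP2 latency plus pulse width).
#' @return A \code{field_trace} with two entries in \code{stim_times_ms}.
#' @export
make_paired_pulse <- function(spec, stim_current = 50, interval_ms = 75) {
  stopifnot(inherits(spec, "ephys_spec"), stim_current >= 0)
  if (interval_ms <= spec$fp2_latency + spec$fp2_width) {
    stop("interval_ms too short: paired responses would overlap")
  }
  t2 <- spec$stim_time_ms + interval_ms
  if (t2 + spec$fp2_latency + spec$fp2_width > spec$sweep_length_ms) {
    stop("second response extends beyond the sweep")
  }
  set.seed(spec$seed)
  make_sweep_core(spec, stim_current,
                  c(spec$stim_time_ms, t2),
                  c(1, spec$facilitation_factor))
}
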