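#' Default component latency windows
#'
#' Post-stimulus latency windows (ms): volley burst [1, 4), monosynaptic
#' FP1 [4, 6], polysynaptic FP2 (6, 10].
#' @return Named list of length-2 numeric vectors.
#' @export
default_windows <- function() {
  list(vb = c(1, 4), fp1 = c(4, 6), fp2 = c(6, 10))
}

window_samples <- function(trace, stim, win, component) {
  t_rel <- trace$time_ms - stim
  if (component == "vb") {
    t_rel >= win[1L] & t_rel < win[2L]
  } else if (component == "fp1") {
    t_rel >= win[1L] & t_rel <= win[2L]
  } else {
    t_rel > win[1L] & t_rel <= win[2L]
  }
}

#' Measure evoked field-potential components
#'
#' Baseline is the mean voltage over the 5 ms preceding the stimulus.
#' Samples within \code{blank_ms} after every stimulus are blanked (the
#' truncated stimulus artifact) before measurement. Each component's
#' amplitude is baseline minus the minimum voltage inside its latency
#' window (negative deflection, clamped at 0); its latency is the time of
#' that minimum relative to the stimulus. With \code{mode = "peak_to_peak"}
#' the amplitude is instead the window maximum minus minimum.
#'
#' @param trace a \code{field_trace}.
#' @param stim_index which stimulus of the sweep to measure (1 or 2).
#' @param windows named list of latency windows, ms ([default_windows()]).
#' @param blank_ms post-stimulus artifact blanking span, ms.
#' @param mode \code{"trough"} (baseline-to-trough, default) or
#'   \code{"peak_to_peak"}.
#' @return List: \code{vb_amp_mv}, \code{fp1_amp_mv}, \code{fp2_amp_mv},
#'   \code{fp1_latency_ms}, \code{fp2_latency_ms}, \code{baseline_mv}.
#'   Latencies are \code{NA} when the component amplitude is 0 (absent).
#' @export
measure_components <- function(trace, stim_index = 1L,
                               windows = default_windows(),
                               blank_ms = 0.5,
                               mode = c("trough", "peak_to_peak")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "field_trace"))
  if (stim_index > length(trace$stim_times_ms)) {
    stop("trace has no stimulus #", stim_index)
  }
  for (w in windows) {
    if (w[1L] < blank_ms) stop("window overlaps the artifact blanking span")
  }
  stim <- trace$stim_times_ms[stim_index]
  tmax <- max(trace$time_ms)
  if (stim + max(vapply(windows, `[`, numeric(1), 2L)) > tmax) {
    stop("component window extends beyond the trace")
  }
  v <- trace$voltage_mv
  # blank after every stimulus so a preceding response's artifact never
  # leaks into a measurement
  for (s in trace$stim_times_ms) {
    v[trace$time_ms >= s & trace$time_ms < s + blank_ms] <- NA_real_
  }
  base_sel <- trace$time_ms >= stim - 5 & trace$time_ms < stim
  baseline <- mean(v[base_sel], na.rm = TRUE)
  if (!is.finite(baseline)) baseline <- 0

  one <- function(name) {
    sel <- window_samples(trace, stim, windows[[name]], name) & !is.na(v)
    if (!any(sel)) return(c(amp = 0, lat = NA_real_))
    if (mode == "trough") {
      i <- which(sel)[which.min(v[sel])]
      amp <- max(0, baseline - v[i])
    } else {
      i <- which(sel)[which.min(v[sel])]
      amp <- max(v[sel]) - min(v[sel])
    }
    lat <- trace$time_ms[i] - stim
    if (amp <= 0) c(amp = 0, lat = NA_real_) else c(amp = amp, lat = lat)
  }
  vb <- one("vb"); fp1 <- one("fp1"); fp2 <- one("fp2")
  list(vb_amp_mv = unname(vb["amp"]),
       fp1_amp_mv = unname(fp1["amp"]),
       fp2_amp_mv = unname(fp2["amp"]),
       fp1_latency_ms = unname(fp1["lat"]),
       fp2_latency_ms = unname(fp2["lat"]),
       baseline_mv = baseline)
}

#' Build an input-output curve from a sweep series
#'
#' Measures FP1/FP2 amplitudes in every sweep, orders points by stimulus
#' current, and attaches trapezoidal areas under both curves.
#'
#' @param traces list of \code{field_trace}, one per stimulus current; at
#'   least 2 distinct currents, no duplicates.
#' @param ... passed to [measure_components()].
#' @return An \code{io_curve}: \code{currents_ua}, \code{fp1_amps_mv},
#'   \code{fp2_amps_mv}, \code{vb_amps_mv}, \code{auc_fp1}, \code{auc_fp2}
#'   (mV.uA).
#' @export
build_io_curve <- function(traces, ...) {
  stopifnot(length(traces) >= 2L)
  currents <- vapply(traces, `[[`, numeric(1), "stim_current_ua")
  if (anyDuplicated(currents)) stop("duplicate stimulus currents")
  ord <- order(currents)
  meas <- lapply(traces[ord], measure_components, ...)
  curve <- structure(list(
    currents_ua = currents[ord],
    fp1_amps_mv = vapply(meas, `[[`, numeric(1), "fp1_amp_mv"),
    fp2_amps_mv = vapply(meas, `[[`, numeric(1), "fp2_amp_mv"),
    vb_amps_mv = vapply(meas, `[[`, numeric(1), "vb_amp_mv")),
    class = "io_curve")
  curve$auc_fp1 <- io_auc(curve, "fp1")
  curve$auc_fp2 <- io_auc(curve, "fp2")
  curve
}

#' Area under an input-output curve
#'
#' Trapezoidal integration of component amplitude over stimulus current
#' across the recorded range — the scalar summary of synaptic strength and
#' excitability used downstream.
#'
#' @param curve an \code{io_curve} (or any list with \code{currents_ua} and
#'   the component amplitude vector).
#' @param component \code{"fp1"} or \code{"fp2"}.
#' @return Area in mV.uA.
#' @export
io_auc <- function(curve, component = c("fp1", "fp2")) {
  component <- match.arg(component)
  y <- curve[[paste0(component, "_amps_mv")]]
  x <- curve$currents_ua
  stopifnot(length(x) >= 2L, length(x) == length(y))
  pracma::trapz(x, y)
}

#' Paired-pulse facilitation
#'
#' FP1 amplitude after each of the two stimuli of a paired sweep;
#' facilitation is the percentage increase of the second response over the
#' first, \code{100 * (A2 - A1) / A1}. When the first response is absent
#' (A1 = 0) the ratio is undefined and reported as \code{NA} with a
#' diagnostic message, not an error.
#'
#' @param trace a \code{field_trace} with exactly two stimulus times.
#' @param component component to measure (\code{"fp1"}, the monosynaptic
#'   response, by default; \code{"fp2"} switchable).
#' @param ... passed to [measure_components()].
#' @return List: \code{first_amp_mv}, \code{second_amp_mv},
#'   \code{ppf_percent}.
#' @export
paired_pulse_facilitation <- function(trace, component = c("fp1", "fp2"),
                                      ...) {
  component <- match.arg(component)
  stopifnot(inherits(trace, "field_trace"))
  if (length(trace$stim_times_ms) != 2L) {
    stop("paired-pulse sweep must contain exactly 2 stimuli")
  }
  m1 <- measure_components(trace, 1L, ...)
  m2 <- measure_components(trace, 2L, ...)
  a1 <- m1[[paste0(component, "_amp_mv")]]
  a2 <- m2[[paste0(component, "_amp_mv")]]
  ppf <- if (a1 > 0) 100 * (a2 - a1) / a1 else {
    message("first response absent (amplitude 0); PPF undefined")
    NA_real_
  }
  list(first_amp_mv = a1, second_amp_mv = a2, ppf_percent = ppf)
}

#' Border-versus-contralateral excitability contrast
#'
#' Descriptive summary of post-hypoxic potentiation: mean area under the
#' input-output curve on each side and their ratio
#' (border / contralateral). This is the statistic that feeds an external
#' ANOVA; no test is run here.
#'
#' @param border_curves,contralateral_curves non-empty lists of
#'   \code{io_curve}.
#' @param component \code{"fp1"} or \code{"fp2"}.
#' @return List: \code{mean_auc_border}, \code{mean_auc_contralateral},
#'   \code{auc_ratio}, \code{n_border}, \code{n_contralateral}.
#' @export
hltp_contrast <- function(border_curves, contralateral_curves,
                          component = c("fp1", "fp2")) {
  component <- match.arg(component)
  if (!length(border_curves) || !length(contralateral_curves)) {
    stop("both recording sides need at least one curve")
  }
  auc <- function(curves) {
    vapply(curves, function(cv) cv[[paste0("auc_", component)]], numeric(1))
  }
  b <- mean(auc(border_curves))
  ct <- mean(auc(contralateral_curves))
  list(mean_auc_border = b, mean_auc_contralateral = ct,
       auc_ratio = b / ct,
       n_border = length(border_curves),
       n_contralateral = length(contralateral_curves))
}
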