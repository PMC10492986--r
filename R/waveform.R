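# Synthetic aortic flow/area waveforms for the QA-method pulse wave velocity.
#
# During reflection-free early systole the lumen area tracks flow as
# A(t) = A0 + Q(t) / PWV, so the generator enforces that identity exactly up
# to `reflection_onset` (as a fraction of systole) and then adds a reflected
# late-systolic area bump that breaks the Q-A linearity. Units follow the
# field's convention: Q in mL/s, A in mm2, PWV in m/s -- with those units the
# slope dQ/dA is numerically the PWV in m/s (1 mL/s per mm2 = 1 m/s).

#' Specify a flow/area waveform
#'
#' @param true_pwv pulse wave velocity of the simulated segment, m/s.
#' @param baseline_area diastolic lumen area A0, mm2.
#' @param peak_flow peak systolic flow, mL/s.
#' @param sample_interval sampling interval, ms.
#' @param cycle_ms cardiac cycle length, ms.
#' @param systole_ms systolic ejection duration, ms.
#' @param onset_ms delay from R-wave to flow upstroke, ms.
#' @param reflection_onset fraction of systole after which the reflected wave
#'   distorts the Q-A relation; 1 means reflection-free throughout.
#' @param reflection_amp amplitude of the reflected area bump as a fraction of
#'   the systolic area excursion.
#' @param noise_sd length-2 noise sd `c(q, a)` in mL/s and mm2; see
#'   [waveform_noise_frac()] for the "percent of peak" convenience form.
#' @param seed integer RNG seed.
#' @return object of class `waveform_spec`.
#' @export
waveform_spec <- function(true_pwv = 4, baseline_area = 450, peak_flow = 400,
                          sample_interval = 9.6, cycle_ms = 800, systole_ms = 300,
                          onset_ms = 20, reflection_onset = 0.5,
                          reflection_amp = 0.35, noise_sd = c(0, 0), seed = 1L) {
  check_positive(true_pwv, "true_pwv")
  check_positive(sample_interval, "sample_interval")
  check_positive(baseline_area, "baseline_area")
  check_positive(peak_flow, "peak_flow")
  if (reflection_onset <= 0 || reflection_onset > 1) {
    stop_validation("reflection_onset must lie in (0, 1]")
  }
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, 2L)
  check_nonnegative(noise_sd, "noise_sd")
  structure(class = "waveform_spec", list(
    true_pwv = true_pwv, baseline_area = baseline_area, peak_flow = peak_flow,
    sample_interval = sample_interval, cycle_ms = cycle_ms,
    systole_ms = systole_ms, onset_ms = onset_ms,
    reflection_onset = reflection_onset, reflection_amp = reflection_amp,
    noise_sd = noise_sd, seed = as.integer(seed)))
}

#' Noise sd as a fraction of peak excursion in both channels
#'
#' @param spec a [waveform_spec()].
#' @param frac fraction of the peak flow (Q channel) and of the systolic area
#'   excursion (A channel), e.g. `0.02` for 2 percent noise.
#' @return the spec with `noise_sd` set accordingly.
#' @export
waveform_noise_frac <- function(spec, frac) {
  check_nonnegative(frac, "frac")
  spec$noise_sd <- c(frac * spec$peak_flow, frac * spec$peak_flow / spec$true_pwv)
  spec
}

#' Generate one cardiac cycle of aortic flow and area
#'
#' @param spec a [waveform_spec()].
#' @return data.frame of class `flow_area_waveform` with columns `t_ms`,
#'   `q_ml_s`, `a_mm2`; attributes `true_pwv`, `reflection_end_ms` (last time
#'   at which the exact A = A0 + Q/PWV relation still holds) and `spec`.
#' @export
generate_waveform <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  t <- seq(0, spec$cycle_ms, by = spec$sample_interval)
  phase <- (t - spec$onset_ms) / spec$systole_ms
  q <- ifelse(phase >= 0 & phase <= 1, spec$peak_flow * sin(pi * phase), 0)
  a <- spec$baseline_area + q / spec$true_pwv
  refl_t <- spec$onset_ms + spec$reflection_onset * spec$systole_ms
  if (spec$reflection_onset < 1) {
    # additive late-systolic bump: raised-cosine from reflection onset to
    # end-diastole, peaking mid-way; breaks A = A0 + Q/PWV after the window
    bump_span <- spec$cycle_ms - refl_t
    u <- (t - refl_t) / bump_span
    bump <- ifelse(u > 0 & u < 1,
                   spec$reflection_amp * (spec$peak_flow / spec$true_pwv) *
                     sin(pi * u)^2, 0)
    a <- a + bump
  }
  if (any(spec$noise_sd > 0)) {
    set.seed(spec$seed)
    q <- q + stats::rnorm(length(t), 0, spec$noise_sd[1])
    a <- a + stats::rnorm(length(t), 0, spec$noise_sd[2])
  }
  wf <- data.frame(t_ms = t, q_ml_s = q, a_mm2 = a)
  class(wf) <- c("flow_area_waveform", "data.frame")
  attr(wf, "true_pwv") <- spec$true_pwv
  attr(wf, "reflection_end_ms") <- if (spec$reflection_onset < 1) refl_t else Inf
  attr(wf, "spec") <- spec
  validate_waveform(wf)
  wf
}

validate_waveform <- function(wf) {
  need <- c("t_ms", "q_ml_s", "a_mm2")
  if (!all(need %in% names(wf))) {
    stop_validation("waveform needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(wf) < 10L) stop_validation("waveform needs >= 10 samples")
  if (any(diff(wf$t_ms) <= 0)) stop_validation("t_ms must be strictly increasing")
  invisible(wf)
}

#' Write / read a waveform as CSV (columns t_ms, q_ml_s, a_mm2)
#' @param wf a waveform data.frame.
#' @param path CSV path.
#' @return `path` / the waveform.
#' @export
write_waveform <- function(wf, path) {
  utils::write.csv(as.data.frame(wf)[c("t_ms", "q_ml_s", "a_mm2")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  if (!file.exists(path)) stop_validation("waveform CSV not found: ", path)
  wf <- utils::read.csv(path)
  class(wf) <- c("flow_area_waveform", "data.frame")
  validate_waveform(wf)
  wf
}
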