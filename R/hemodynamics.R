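# Derived cardiovascular indices: QA-method pulse wave velocity, stroke
# volume, ejection fraction, cardiac output, LV mass, total arterial
# compliance, systemic vascular resistance.

#' Find the reflection-free early-systolic window of a flow/area waveform
#'
#' Locates the foot of the systolic flow upstroke (first sample at or above
#' `foot_frac` of peak flow) and grows a window from it while both Q(t) and
#' A(t) stay jointly linear: the ordinary-least-squares fits of Q on t and A
#' on t must each keep R-squared at or above `r2_min`. The window is at least
#' `min_len` samples (that minimum is used even when noise pushes R-squared
#' below the criterion; the result then carries `low_linearity = TRUE`) and
#' at most `max_frac` of systole (foot to the end-systolic return of Q below
#' `foot_frac` of peak).
#'
#' @param wf waveform with columns `t_ms`, `q_ml_s`, `a_mm2`.
#' @param foot_frac upstroke-foot threshold as a fraction of peak flow.
#' @param r2_min linearity criterion for both channels.
#' @param min_len minimum window length, samples.
#' @param max_frac maximum window length as a fraction of systole.
#' @return integer vector of row indices (the window), with attributes `foot`
#'   and `low_linearity`.
#' @export
early_systolic_window <- function(wf, foot_frac = 0.05, r2_min = 0.98,
                                  min_len = 4L, max_frac = 0.4) {
  validate_waveform(wf)
  q <- wf$q_ml_s; t <- wf$t_ms; a <- wf$a_mm2
  qmax <- max(q)
  if (!is.finite(qmax) || qmax <= 0 || stats::sd(q) == 0) {
    stop_estimation("no systolic upstroke detected (flat or non-positive flow)")
  }
  ipeak <- which.max(q)
  foot <- which(q[seq_len(ipeak)] >= foot_frac * qmax)[1]
  if (is.na(foot)) stop_estimation("no upstroke foot found")
  # end of systole: first return below the foot threshold after the peak
  after <- which(q[ipeak:length(q)] < foot_frac * qmax)
  sys_end <- if (length(after)) ipeak + after[1] - 1L else length(q)
  max_len <- max(min_len, floor(max_frac * (sys_end - foot + 1L)))
  max_len <- min(max_len, length(q) - foot + 1L)
  if (max_len < min_len) stop_estimation("systolic upstroke too short for a window")

  r2 <- function(yy, tt) {
    f <- stats::lm.fit(cbind(1, tt), yy)
    tss <- sum((yy - mean(yy))^2)
    if (tss == 0) return(0)
    1 - sum(f$residuals^2) / tss
  }
  # the minimum window is always used; it is extended while both channels
  # stay jointly linear
  best <- seq.int(foot, foot + min_len - 1L)
  low_linearity <- r2(q[best], t[best]) < r2_min || r2(a[best], t[best]) < r2_min
  if (max_len > min_len) {
    for (len in seq.int(min_len + 1L, max_len)) {
      idx <- seq.int(foot, foot + len - 1L)
      if (r2(q[idx], t[idx]) >= r2_min && r2(a[idx], t[idx]) >= r2_min) {
        best <- idx
      } else {
        break
      }
    }
  }
  attr(best, "foot") <- foot
  attr(best, "low_linearity") <- low_linearity
  best
}

# Huber-loss slope (tuning constant 1.345) via MASS::rlm; OLS fallback/option.
robust_slope <- function(y, x, method = c("huber", "ols")) {
  method <- match.arg(method)
  if (method == "ols") {
    return(unname(stats::lm.fit(cbind(1, x), y)$coefficients[2]))
  }
  fit <- suppressWarnings(
    MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345, maxit = 100))
  unname(stats::coef(fit)[2])
}

#' QA-method pulse wave velocity
#'
#' PWV = (gradient of Q over the early-systolic window) / (gradient of A over
#' the same window), each gradient from a robust (Huber) linear regression on
#' time. With Q in mL/s and A in mm2 the ratio is numerically in m/s
#' (1 mL = 1000 mm3, 1000 mm = 1 m).
#'
#' @param wf waveform with columns `t_ms`, `q_ml_s`, `a_mm2`.
#' @param window row indices from [early_systolic_window()]; computed from
#'   `wf` when `NULL`.
#' @param method `"huber"` (default) or `"ols"` slope estimator.
#' @param min_delta_a minimum area excursion (mm2) over the window below which
#'   the segment is treated as incompressible.
#' @param ... passed to [early_systolic_window()] when `window` is `NULL`.
#' @return PWV in m/s, with attribute `window`.
#' @export
pwv_qa <- function(wf, window = NULL, method = c("huber", "ols"),
                   min_delta_a = 1e-6, ...) {
  validate_waveform(wf)
  method <- match.arg(method)
  if (is.null(window)) window <- early_systolic_window(wf, ...)
  if (length(window) < 3L) stop_validation("window must have >= 3 samples")
  t <- wf$t_ms[window]; q <- wf$q_ml_s[window]; a <- wf$a_mm2[window]
  if (diff(range(a)) < min_delta_a) {
    stop_estimation("incompressible segment: area excursion ",
                    format(diff(range(a))), " mm2 below tolerance")
  }
  grad_q <- robust_slope(q, t, method)   # mL/s per ms
  grad_a <- robust_slope(a, t, method)   # mm2 per ms
  if (abs(grad_a) < .Machine$double.eps) {
    stop_estimation("area gradient is zero over the window")
  }
  pwv <- grad_q / grad_a                 # (mL/s)/mm2 == m/s numerically
  attr(pwv, "window") <- window
  pwv
}

#' Ventricular volumetric indices
#'
#' `stroke_volume()` is LVEDV - LVESV (mL); `ejection_fraction()` is
#' 100 * SV / LVEDV (percent); `lv_mass()` converts myocardial volume to mass
#' with the standard myocardial density 1.05 g/mL.
#'
#' @param edv,esv end-diastolic and end-systolic LV volumes, mL.
#' @param myocardial_volume epicardial minus endocardial LV volume, mL.
#' @return numeric scalar (mL, percent, or g).
#' @export
stroke_volume <- function(edv, esv) {
  check_nonnegative(edv, "edv"); check_nonnegative(esv, "esv")
  if (any(esv > edv)) stop_validation("esv must not exceed edv")
  edv - esv
}

#' @rdname stroke_volume
#' @export
ejection_fraction <- function(edv, esv) {
  sv <- stroke_volume(edv, esv)
  if (any(edv == 0)) stop_validation("ejection fraction undefined for edv = 0")
  100 * sv / edv
}

#' @rdname stroke_volume
#' @export
lv_mass <- function(myocardial_volume) {
  check_nonnegative(myocardial_volume, "myocardial_volume")
  1.05 * myocardial_volume
}

#' Pressure-derived indices
#'
#' `cardiac_output()` = SV x HR / 1000 (L/min); `tac()` = SV / pulse pressure
#' (mL/mm Hg); `svr()` = mean BP / CO (Wood units, mm Hg.min/L).
#'
#' @param sv stroke volume, mL.
#' @param heart_rate beats per minute.
#' @param sbp,dbp,mbp systolic / diastolic / mean blood pressure, mm Hg.
#'   `mbp = NULL` derives it as `dbp + (sbp - dbp) / 3` (flagged by attribute
#'   `mbp_derived`).
#' @param co cardiac output, L/min.
#' @return numeric scalar.
#' @export
cardiac_output <- function(sv, heart_rate) {
  check_nonnegative(sv, "sv"); check_positive(heart_rate, "heart_rate")
  sv * heart_rate / 1000
}

#' @rdname cardiac_output
#' @export
tac <- function(sv, sbp, dbp) {
  check_nonnegative(sv, "sv")
  if (any(sbp <= dbp)) stop_estimation("zero or negative pulse pressure: sbp must exceed dbp")
  sv / (sbp - dbp)
}

#' @rdname cardiac_output
#' @export
svr <- function(sbp, dbp, co, mbp = NULL) {
  if (any(co <= 0)) stop_estimation("svr undefined for non-positive cardiac output")
  derived <- is.null(mbp)
  if (derived) mbp <- dbp + (sbp - dbp) / 3
  if (any(mbp < dbp | mbp > sbp)) stop_validation("mbp must lie between dbp and sbp")
  out <- mbp / co
  attr(out, "mbp_derived") <- derived
  out
}

#' One-call hemodynamic summary
#'
#' Combines a flow/area waveform, ventricular volumes and cuff pressures into
#' the derived index set.
#'
#' @param wf flow/area waveform (or `NULL` to skip PWV).
#' @param edv,esv,myocardial_volume LV volumes, mL.
#' @param sbp,dbp,heart_rate cuff pressures (mm Hg) and heart rate (bpm).
#' @param mbp measured mean pressure, or `NULL` to derive it.
#' @return data.frame of class `hemodynamic_summary` (one row).
#' @export
hemodynamic_summary <- function(wf, edv, esv, myocardial_volume,
                                sbp, dbp, heart_rate, mbp = NULL) {
  sv <- stroke_volume(edv, esv)
  co <- cardiac_output(sv, heart_rate)
  svr_v <- svr(sbp, dbp, co, mbp)
  out <- data.frame(
    pwv_m_s = if (is.null(wf)) NA_real_ else as.numeric(pwv_qa(wf)),
    sv_ml = sv,
    ef_pct = ejection_fraction(edv, esv),
    co_l_min = co,
    lv_mass_g = lv_mass(myocardial_volume),
    mass_to_edv = lv_mass(myocardial_volume) / edv,
    tac_ml_mmhg = tac(sv, sbp, dbp),
    svr_wu = as.numeric(svr_v),
    pulse_pressure_mmhg = sbp - dbp,
    mbp_derived = isTRUE(attr(svr_v, "mbp_derived")))
  class(out) <- c("hemodynamic_summary", "data.frame")
  out
}
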