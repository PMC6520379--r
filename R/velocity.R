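#' Velocity waveform over one cardiac cycle
#'
#' T velocity samples in cm/s (positive = cranial, negative = caudal),
#' together with the RR interval and the phase-drift bookkeeping. Created
#' by [grey_to_velocity()]; [correct_phase_drift()] returns a corrected
#' copy whose mean is zero.
#'
#' @param values Numeric vector of T velocities in cm/s.
#' @param rr_interval_s RR interval in seconds.
#' @param venc Velocity encoding of the originating series, cm/s.
#' @param corrected Logical: has phase drift been subtracted?
#' @param drift_estimate The subtracted mean, cm/s (0 when uncorrected).
#' @param saturated Logical: did any source grey value sit at full scale?
#' @return An object of class `velocity_waveform`.
#' @export
velocity_waveform <- function(values, rr_interval_s, venc = 2,
                              corrected = FALSE, drift_estimate = 0,
                              saturated = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 2)
    cm_stop("waveform needs >= 2 samples", "cordmotion_structure_error")
  if (rr_interval_s <= 0)
    cm_stop("rr_interval_s must be positive", "cordmotion_metadata_error")
  if (corrected && abs(mean(values)) > 1e-12 * max(1, max(abs(values))))
    cm_stop("corrected waveform must have zero mean", "cordmotion_state_error")
  if (max(abs(values)) > venc + abs(drift_estimate) + 1e-9)
    cm_stop("velocities exceed the encodable range venc + |drift|",
            "cordmotion_range_error")
  structure(list(values = values, rr_interval_s = as.numeric(rr_interval_s),
                 venc = as.numeric(venc), corrected = isTRUE(corrected),
                 drift_estimate = as.numeric(drift_estimate),
                 saturated = isTRUE(saturated)),
            class = "velocity_waveform")
}

#' @export
print.velocity_waveform <- function(x, ...) {
  cat(sprintf("<velocity_waveform> T=%d, RR %.3f s, %s, drift %.4f cm/s%s\n",
              length(x$values), x$rr_interval_s,
              if (x$corrected) "corrected" else "uncorrected",
              x$drift_estimate, if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Convert ROI mean grey values to velocities
#'
#' The linear phase-contrast map: each mean grey value is divided by the
#' grey full scale (4096) and multiplied by the velocity encoding
#' (2 cm/s), so full-scale grey corresponds to venc. Positive grey
#' encodes cranial motion by convention; set `polarity = -1` for vendors
#' with the opposite sign convention.
#'
#' @param grey_means Numeric vector of T ROI mean grey values.
#' @param venc Velocity encoding, cm/s (> 0).
#' @param grey_full_scale Grey value corresponding to venc.
#' @param rr_interval_s RR interval in seconds.
#' @param polarity `+1` (default) or `-1`.
#' @return An uncorrected [velocity_waveform].
#' @examples
#' w <- grey_to_velocity(c(4096, 0, -2048), venc = 2, rr_interval_s = 1)
#' w$values  # 2, 0, -1 cm/s
#' @export
grey_to_velocity <- function(grey_means, venc = 2, grey_full_scale = 4096,
                             rr_interval_s = 1, polarity = 1) {
  if (venc <= 0)
    cm_stop("venc must be positive", "cordmotion_metadata_error")
  if (any(abs(grey_means) > grey_full_scale))
    cm_stop("grey values beyond full scale: velocity aliasing/saturation",
            "cordmotion_range_error")
  velocity_waveform(polarity * grey_means / grey_full_scale * venc,
                    rr_interval_s, venc = venc, corrected = FALSE,
                    drift_estimate = 0,
                    saturated = any(abs(grey_means) == grey_full_scale))
}

#' Phase-drift correction by the zero-net-motion assumption
#'
#' Phase-contrast velocities carry a scanner-dependent baseline offset
#' ("phase drift"). Because the cord starts and ends one cardiac cycle at
#' the same position, its net motion — hence its mean velocity — must be
#' zero, so the drift equals the mean of the T velocity samples and is
#' subtracted from each sample. Correcting twice is refused: the second
#' subtraction would be a silent no-op masquerading as a correction.
#'
#' @param w An uncorrected [velocity_waveform].
#' @return A corrected [velocity_waveform] with `drift_estimate` set to
#'   the subtracted mean and `mean(values) == 0`.
#' @export
correct_phase_drift <- function(w) {
  stopifnot(inherits(w, "velocity_waveform"))
  if (w$corrected)
    cm_stop("waveform is already drift-corrected", "cordmotion_state_error")
  d <- mean(w$values)
  velocity_waveform(w$values - d, w$rr_interval_s, venc = w$venc,
                    corrected = TRUE, drift_estimate = d,
                    saturated = w$saturated)
}

#' Motion readouts of one segment
#'
#' The four standardized readouts of one corrected velocity waveform:
#' maximum cranial velocity (the waveform maximum, cm/s), maximum caudal
#' velocity (the minimum, cm/s, negative), amplitude (their difference,
#' cm/s) and displacement (cm): the rectified area under the velocity
#' curve by the left rectangle rule with uniform step RR/T — each sample's
#' absolute velocity times one T-th of the cardiac cycle, summed.
#'
#' @param w A corrected [velocity_waveform] (see `allow_uncorrected`).
#' @param allow_uncorrected Permit readouts of a raw, uncorrected
#'   waveform. Raw displacement is systematically biased by phase drift;
#'   this is only useful for quantifying that bias (e.g. raw vs corrected
#'   reliability).
#' @return An object of class `motion_readouts`: a list with fields
#'   `amplitude`, `max_cranial`, `max_caudal`, `displacement`.
#' @examples
#' w <- velocity_waveform(c(0.1, -0.2, 0.3, -0.2), rr_interval_s = 1,
#'                        corrected = TRUE)
#' compute_readouts(w)$displacement  # 0.2 cm
#' @export
compute_readouts <- function(w, allow_uncorrected = FALSE) {
  stopifnot(inherits(w, "velocity_waveform"))
  if (!w$corrected && !allow_uncorrected)
    cm_stop("readouts require a drift-corrected waveform (or allow_uncorrected = TRUE)",
            "cordmotion_state_error")
  v <- w$values
  mx <- max(v); mn <- min(v)
  structure(list(amplitude = mx - mn,
                 max_cranial = mx,
                 max_caudal = mn,
                 displacement = sum(abs(v)) * w$rr_interval_s / length(v)),
            class = "motion_readouts")
}

#' @export
print.motion_readouts <- function(x, ...) {
  cat(sprintf("<motion_readouts> amplitude %.3f, max cranial %.3f, max caudal %.3f cm/s; displacement %.4f cm\n",
              x$amplitude, x$max_cranial, x$max_caudal, x$displacement))
  invisible(x)
}

#' Full per-segment evaluation of one phase series
#'
#' Composition of the evaluation steps: ROI grey-value averaging, venc
#' conversion, phase-drift correction, readout computation.
#'
#' @param series A [phase_series].
#' @param roi A cord-labelled [ellipse_roi].
#' @param correct Apply phase-drift correction (default). With
#'   `correct = FALSE` readouts are computed on the raw waveform.
#' @param polarity Grey-to-velocity sign convention, see
#'   [grey_to_velocity()].
#' @return List with elements `waveform` (a [velocity_waveform]) and
#'   `readouts` (a [motion_readouts]).
#' @export
process_series <- function(series, roi, correct = TRUE, polarity = 1) {
  if (roi$label != "cord")
    cm_stop("process_series expects a cord-labelled ROI",
            "cordmotion_geometry_error")
  g <- roi_mean_greyvalues(series, roi)
  w <- grey_to_velocity(g, venc = series$venc,
                        grey_full_scale = series$grey_full_scale,
                        rr_interval_s = series$rr_interval / 1000,
                        polarity = polarity)
  if (correct) w <- correct_phase_drift(w)
  list(waveform = w, readouts = compute_readouts(w, allow_uncorrected = !correct))
}
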