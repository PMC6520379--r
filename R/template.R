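#' Biphasic spinal cord motion template
#'
#' Parametric model of the pulse-synchronous motion pattern: nearly no
#' motion during the first half of the cardiac cycle, then a caudal
#' (negative) lobe followed by a cranial (positive) lobe. Lobes are
#' compact-support raised-cosine bumps `cos(pi*(t-c)/(2W))^(2p)` in
#' cycle-fraction time, zero outside `|t - c| < W`, so the quiescent first
#' half is exactly zero rather than carrying Gaussian tails. The shape
#' exponent `p` controls lobe mass (hence displacement) without moving the
#' peaks; [fit_template_exponent()] exploits this.
#'
#' Peak phases are snapped to the nearest of the T sample points so that
#' the gridded extrema equal the requested peak velocities exactly, and
#' the waveform is forced to zero mean by redistributing the lobe mass
#' over the post-quiescent samples (so injected drift is identifiable as
#' the unique waveform mean).
#'
#' @param n_timepoints Samples per cardiac cycle (T, nominally 20).
#' @param quiescent_fraction Fraction of the cycle with no motion
#'   (nominal 0.5).
#' @param caudal_peak_phase,cranial_peak_phase Cycle fractions of the two
#'   lobe peaks (nominal 0.65 and 0.85); must satisfy
#'   `0 < quiescent_fraction < caudal < cranial < 1`.
#' @param lobe_half_width Half-support of each lobe in cycle fractions;
#'   capped so lobes cannot spill into the quiescent half.
#' @param shape_exponent Raised-cosine exponent p (> 0); larger = spikier
#'   lobes = smaller displacement at fixed peaks.
#' @return Object of class `motion_template`.
#' @export
motion_template <- function(n_timepoints = 20, quiescent_fraction = 0.5,
                            caudal_peak_phase = 0.65,
                            cranial_peak_phase = 0.85,
                            lobe_half_width = 0.12, shape_exponent = 1) {
  if (!(0 < quiescent_fraction && quiescent_fraction < caudal_peak_phase &&
        caudal_peak_phase < cranial_peak_phase && cranial_peak_phase < 1))
    cm_stop("need 0 < quiescent < caudal peak < cranial peak < 1",
            "cordmotion_config_error")
  if (lobe_half_width <= 0 || shape_exponent <= 0)
    cm_stop("lobe_half_width and shape_exponent must be positive",
            "cordmotion_config_error")
  ## cap the half-width so lobes cannot spill into the quiescent half or
  ## past the end of the cycle; mild lobe overlap is allowed (the exact
  ## 2x2 peak solve accounts for it, and the extrema are re-verified)
  w_max <- min(caudal_peak_phase - quiescent_fraction, 1 - cranial_peak_phase,
               lobe_half_width)
  structure(list(n_timepoints = as.integer(n_timepoints),
                 quiescent_fraction = quiescent_fraction,
                 caudal_peak_phase = caudal_peak_phase,
                 cranial_peak_phase = cranial_peak_phase,
                 lobe_half_width = w_max,
                 shape_exponent = shape_exponent),
            class = "motion_template")
}

## Raised-cosine bump, peak 1 at center, support |t - center| < width.
rc_bump <- function(t, center, width, p) {
  u <- abs(t - center) / width
  ifelse(u < 1, cos(pi * u / 2)^(2 * p), 0)
}

#' Evaluate the template at requested peak velocities
#'
#' Returns the zero-mean T-sample velocity sequence whose gridded minimum
#' equals `max_caudal` and gridded maximum equals `max_cranial` exactly.
#' The two lobe scales are obtained by solving the 2x2 linear system at
#' the snapped peak samples (mean-redistribution included), so the
#' contract is exact, not approximate.
#'
#' @param template A [motion_template].
#' @param max_cranial Requested positive peak, cm/s (> 0).
#' @param max_caudal Requested negative peak, cm/s (< 0).
#' @return Numeric vector of length T with `max(v) == max_cranial`,
#'   `min(v) == max_caudal`, `mean(v) == 0` (to machine precision).
#' @examples
#' v <- evaluate_template(motion_template(), 0.186, -0.259)
#' c(max(v), min(v), mean(v))
#' @export
evaluate_template <- function(template, max_cranial, max_caudal) {
  stopifnot(inherits(template, "motion_template"))
  if (!(max_cranial > 0 && max_caudal < 0))
    cm_stop("need max_cranial > 0 > max_caudal", "cordmotion_config_error")
  T <- template$n_timepoints
  t <- (seq_len(T) - 1) / T
  ic <- which.min(abs(t - template$cranial_peak_phase))
  id <- which.min(abs(t - template$caudal_peak_phase))
  if (ic == id)
    cm_stop("peak phases collide on the sample grid",
            "cordmotion_config_error")
  active <- t >= template$quiescent_fraction
  n_act <- sum(active)
  u_raw <- rc_bump(t, template$cranial_peak_phase, template$lobe_half_width,
                   template$shape_exponent)
  v_raw <- -rc_bump(t, template$caudal_peak_phase, template$lobe_half_width,
                    template$shape_exponent)
  u <- u_raw - (sum(u_raw) / n_act) * active
  v <- v_raw - (sum(v_raw) / n_act) * active
  M <- rbind(c(u[ic], v[ic]), c(u[id], v[id]))
  ab <- solve(M, c(max_cranial, max_caudal))
  vals <- ab[1] * u + ab[2] * v
  vals <- vals - mean(vals)               # exact zero mean despite rounding
  if (which.max(vals) != ic || which.min(vals) != id ||
      abs(vals[ic] - max_cranial) > 1e-9 || abs(vals[id] - max_caudal) > 1e-9)
    cm_stop("template parameters do not realize the requested peaks (lobes overlap too strongly)",
            "cordmotion_config_error")
  vals
}

## Displacement (cm) of the exact template waveform at exponent p.
template_displacement <- function(template, max_cranial, max_caudal,
                                  rr_interval_s, p) {
  template$shape_exponent <- p
  v <- evaluate_template(template, max_cranial, max_caudal)
  sum(abs(v)) * rr_interval_s / length(v)
}

#' Tune the lobe shape so displacement matches a target
#'
#' Displacement at fixed peaks is a monotone function of the
#' raised-cosine exponent (spikier lobes sweep less area), so the
#' exponent realizing a target displacement is found by root bracketing.
#' If the target lies outside the attainable range for the given peaks
#' and RR, the nearest attainable exponent is returned with a warning.
#'
#' @param template A [motion_template].
#' @param max_cranial,max_caudal Peak velocities, cm/s.
#' @param rr_interval_s RR interval, s.
#' @param target_displacement_cm Desired rectified AUC, cm.
#' @param p_range Search interval for the exponent.
#' @return The fitted exponent (scalar).
#' @export
fit_template_exponent <- function(template, max_cranial, max_caudal,
                                  rr_interval_s, target_displacement_cm,
                                  p_range = c(0.1, 16)) {
  f <- function(p) template_displacement(template, max_cranial, max_caudal,
                                         rr_interval_s, p) -
                   target_displacement_cm
  ## very flat lobes (small p) can violate the snapped-extrema contract;
  ## walk the lower bracket up to the flattest admissible exponent
  lo <- NA
  for (i in 0:12) {
    lo <- tryCatch(f(p_range[1]), cordmotion_config_error = function(e) NA)
    if (!is.na(lo)) break
    p_range[1] <- p_range[1] * 1.5
    if (p_range[1] >= p_range[2])
      cm_stop("no admissible shape exponent for these template parameters",
              "cordmotion_config_error")
  }
  hi <- f(p_range[2])
  ## targets outside the attainable band are clamped to its edge; the
  ## realized displacement is what lands in the ground-truth table, so a
  ## clamp is only worth a warning when the miss is substantial
  if (lo <= 0) {                          # target above attainable maximum
    if (-lo > 0.1 * target_displacement_cm)
      cm_warn(sprintf("displacement target %.4f cm above attainable %.4f; clamped",
                      target_displacement_cm, lo + target_displacement_cm),
              "cordmotion_clamp_warning")
    return(p_range[1])
  }
  if (hi >= 0) {                          # target below attainable minimum
    if (hi > 0.1 * target_displacement_cm)
      cm_warn(sprintf("displacement target %.4f cm below attainable %.4f; clamped",
                      target_displacement_cm, hi + target_displacement_cm),
              "cordmotion_clamp_warning")
    return(p_range[2])
  }
  stats::uniroot(f, interval = p_range, tol = 1e-10)$root
}
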