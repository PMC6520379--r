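#' Nominal per-segment peak velocity and displacement distributions
#'
#' Normative healthy-cohort group means and SDs per cervical segment for
#' maximum cranial velocity, maximum caudal velocity (cm/s) and
#' displacement (cm), used as the generator's default sampling
#' distributions.
#'
#' @return data.frame with one row per segment C2..C7.
#' @export
segment_reference_values <- function() {
  data.frame(
    segment = cervical_segments(),
    cranial_mean = c(0.115, 0.132, 0.161, 0.186, 0.161, 0.168),
    cranial_sd   = c(0.041, 0.042, 0.052, 0.078, 0.050, 0.053),
    caudal_mean  = c(-0.182, -0.204, -0.226, -0.259, -0.197, -0.169),
    caudal_sd    = c(0.060, 0.072, 0.096, 0.094, 0.061, 0.055),
    disp_mean    = c(0.036, 0.042, 0.048, 0.054, 0.049, 0.051),
    disp_sd      = c(0.009, 0.011, 0.013, 0.016, 0.010, 0.015),
    stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' The stated world of the generator: cohort size and segment list,
#' per-segment peak/displacement distributions, phase-drift distribution,
#' pixel noise, RR distribution, imaging geometry, ROI and template.
#'
#' @param seed Integer seed; mandatory — the whole cohort is a pure
#'   function of the config including the seed.
#' @param n_subjects Retained (non-flagged) cohort size.
#' @param segments Character vector of segments to image.
#' @param peak_table Per-segment distribution table in the format of
#'   [segment_reference_values()].
#' @param drift_mean,drift_sd Phase-drift distribution, cm/s. The default
#'   0.25 +/- 0.025 keeps the injected positive drift within the
#'   0.2-0.3 cm/s band seen on clinical scanners.
#' @param pixel_noise_sd Per-pixel Gaussian noise SD in grey-value units
#'   (rounded to integers before adding).
#' @param rr_mean,rr_sd RR interval distribution, ms (draws rounded to
#'   whole ms).
#' @param venc,grey_full_scale Velocity encoding (cm/s) and grey full
#'   scale.
#' @param image_size `c(H, W)` pixels; `pixel_spacing` mm per pixel.
#' @param roi Cord [ellipse_roi]; default: the predefined 30.52 mm^2
#'   ellipse centred in the image.
#' @param template A [motion_template].
#' @param peak_cor Correlation between the standardized subject deviates
#'   of the two peaks and the displacement target (shared motion
#'   magnitude).
#' @param displacement_match If TRUE (default) the template shape
#'   exponent is tuned per subject so the exact waveform's rectified AUC
#'   equals the subject's displacement draw.
#' @param scans Scan labels; use `c("baseline", "retest")` for
#'   test-retest designs.
#' @param retest_sd_frac Within-subject between-scan SD of the true
#'   peaks, as a fraction of the between-subject SD.
#' @param cov_motion_rho Strength of the (negative) association between
#'   motion magnitude and canal size / body size in the metadata table.
#' @param n_flagged Additional subjects flagged for exclusion
#'   (incidental stenosis) on top of `n_subjects`.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(seed, n_subjects = 18,
                          segments = cervical_segments(),
                          peak_table = segment_reference_values(),
                          drift_mean = 0.25, drift_sd = 0.025,
                          pixel_noise_sd = 50,
                          rr_mean = 1000, rr_sd = 100,
                          venc = 2, grey_full_scale = 4096L,
                          image_size = c(64, 64),
                          pixel_spacing = c(0.5, 0.5),
                          roi = NULL, template = motion_template(),
                          peak_cor = 0.8, displacement_match = TRUE,
                          scans = "baseline", retest_sd_frac = 0.4,
                          cov_motion_rho = 0.3, n_flagged = 0) {
  if (missing(seed) || !is.numeric(seed))
    cm_stop("cohort_config requires an integer seed", "cordmotion_config_error")
  if (n_subjects < 1 || drift_sd < 0 || pixel_noise_sd < 0 || rr_sd < 0)
    cm_stop("invalid cohort_config: n_subjects >= 1 and SDs >= 0 required",
            "cordmotion_config_error")
  if (!all(segments %in% cervical_segments()))
    cm_stop("unknown segment label", "cordmotion_config_error")
  if (any(peak_table$cranial_mean <= 0) || any(peak_table$caudal_mean >= 0))
    cm_stop("peak means must be positive (cranial) / negative (caudal)",
            "cordmotion_config_error")
  if (is.null(roi))
    roi <- default_cord_roi((image_size[1] - 1) / 2, (image_size[2] - 1) / 2)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 segments = segments, peak_table = peak_table,
                 drift_mean = drift_mean, drift_sd = drift_sd,
                 pixel_noise_sd = pixel_noise_sd,
                 rr_mean = rr_mean, rr_sd = rr_sd, venc = venc,
                 grey_full_scale = as.integer(grey_full_scale),
                 image_size = image_size, pixel_spacing = pixel_spacing,
                 roi = roi, template = template, peak_cor = peak_cor,
                 displacement_match = isTRUE(displacement_match),
                 scans = scans, retest_sd_frac = retest_sd_frac,
                 cov_motion_rho = cov_motion_rho,
                 n_flagged = as.integer(n_flagged)),
            class = "cohort_config")
}

## Correlated standard normal deviates sharing a latent motion factor.
draw_motion_deviates <- function(rho) {
  z0 <- stats::rnorm(1)
  r <- sqrt(rho)
  e <- stats::rnorm(3)
  list(z = r * z0 + sqrt(1 - rho) * e, z_latent = z0)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Draw the subject x segment ground truth (peaks, displacement target,
## drift, rr) from the configured distributions; uses the current RNG.
draw_truth <- function(config, subject_id, segment, scan_id = "baseline",
                       base = NULL) {
  pt <- config$peak_table[config$peak_table$segment == segment, ]
  if (nrow(pt) != 1)
    cm_stop(paste("segment missing from peak_table:", segment),
            "cordmotion_config_error")
  if (is.null(base)) {
    dz <- draw_motion_deviates(config$peak_cor)
    cran <- clamp(pt$cranial_mean + pt$cranial_sd * dz$z[1], 0.02, Inf)
    caud <- clamp(pt$caudal_mean + pt$caudal_sd * dz$z[2], -Inf, -0.02)
    disp <- pt$disp_mean + pt$disp_sd * dz$z[3]
    z_lat <- dz$z_latent
  } else {
    ## retest: same subject-level truth perturbed by the within-subject SD
    f <- config$retest_sd_frac
    cran <- clamp(base$true_cranial + stats::rnorm(1, 0, f * pt$cranial_sd),
                  0.02, Inf)
    caud <- clamp(base$true_caudal + stats::rnorm(1, 0, f * pt$caudal_sd),
                  -Inf, -0.02)
    disp <- base$disp_target + stats::rnorm(1, 0, f * pt$disp_sd)
    z_lat <- base$z_latent
  }
  ## physiological feasibility: with zero net motion and a quiescent half
  ## cycle, one lobe's area must balance the other's, which bounds how
  ## asymmetric the two peaks can be; rein in rare extreme draws
  if (cran < 0.35 * abs(caud)) cran <- 0.35 * abs(caud)
  if (abs(caud) < 0.35 * cran) caud <- -0.35 * cran
  rr <- round(clamp(stats::rnorm(1, config$rr_mean, config$rr_sd), 600, 1400))
  drift <- stats::rnorm(1, config$drift_mean, config$drift_sd)
  list(subject_id = subject_id, scan_id = scan_id, segment = segment,
       true_cranial = cran, true_caudal = caud, disp_target = disp,
       drift = drift, rr = rr, z_latent = z_lat)
}

#' Synthesize one phase series with known ground truth
#'
#' Forward model of the acquisition: the biphasic zero-mean template is
#' evaluated at the subject's true peaks (shape exponent tuned to the
#' displacement target when `displacement_match` is set), the phase drift
#' is added, velocities are encoded to grey values
#' `round((v + drift) / venc * full_scale)`, and integer-rounded Gaussian
#' pixel noise is added per pixel. In-ROI pixels carry the motion signal;
#' all other (static-tissue) pixels carry the drift-only signal. Encoding
#' beyond full scale raises a saturation error — the generator never
#' clips.
#'
#' @param config A [cohort_config].
#' @param subject_id,segment,scan_id Identifiers for the series.
#' @param truth Optional pre-drawn truth record (internal use); when NULL
#'   the truth is drawn from the configured distributions using the
#'   current RNG state.
#' @param seed Optional seed fixing both the truth draw and the noise.
#' @return List with `series` (a [phase_series]) and `truth` (one-row
#'   data.frame: true peaks, true amplitude, true displacement of the
#'   exact waveform, injected drift, RR).
#' @export
synthesize_series <- function(config, subject_id = "S01", segment = "C5",
                              scan_id = "baseline", truth = NULL,
                              seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed,
    synthesize_series(config, subject_id, segment, scan_id, truth)))
  if (is.null(truth))
    truth <- draw_truth(config, subject_id, segment, scan_id)
  tpl <- config$template
  if (config$displacement_match)
    tpl$shape_exponent <- fit_template_exponent(
      tpl, truth$true_cranial, truth$true_caudal, truth$rr / 1000,
      truth$disp_target)
  v <- evaluate_template(tpl, truth$true_cranial, truth$true_caudal)
  T <- length(v)
  if (max(abs(v + truth$drift)) > config$venc)
    cm_stop("velocity plus drift exceeds venc: saturation (adjust config)",
            "cordmotion_saturation_error")
  scale <- config$grey_full_scale / config$venc
  enc_cord <- as.integer(round((v + truth$drift) * scale))
  enc_static <- as.integer(round(truth$drift * scale))
  H <- config$image_size[1]; W <- config$image_size[2]
  mask <- roi_pixel_mask(config$roi, H, W, config$pixel_spacing)
  frames <- array(0L, dim = c(T, H, W))
  for (tt in seq_len(T)) {
    fr <- matrix(enc_static, H, W)
    fr[mask] <- enc_cord[tt]
    if (config$pixel_noise_sd > 0)
      fr <- fr + matrix(as.integer(round(stats::rnorm(H * W, 0,
                                                      config$pixel_noise_sd))),
                        H, W)
    frames[tt, , ] <- fr
  }
  if (max(abs(frames)) > config$grey_full_scale)
    cm_stop("noise pushed grey values beyond full scale: saturation",
            "cordmotion_saturation_error")
  series <- phase_series(frames, venc = config$venc,
                         rr_interval = truth$rr,
                         grey_full_scale = config$grey_full_scale,
                         pixel_spacing = config$pixel_spacing,
                         subject_id = subject_id, scan_id = scan_id,
                         segment = segment)
  truth_df <- data.frame(
    subject_id = subject_id, scan_id = scan_id, segment = segment,
    true_cranial = truth$true_cranial, true_caudal = truth$true_caudal,
    true_amplitude = truth$true_cranial - truth$true_caudal,
    true_displacement = sum(abs(v)) * (truth$rr / 1000) / T,
    drift = truth$drift, rr_interval = truth$rr,
    stringsAsFactors = FALSE)
  list(series = series, truth = truth_df, truth_draw = truth)
}

#' Synthesize a full cohort
#'
#' One series per subject x segment (x scan for test-retest designs;
#' retest truths are the baseline truths perturbed by the within-subject
#' SD, with fresh drift and RR per scan), plus a ground-truth table and a
#' subject metadata table (blood pressures before/after, body size and
#' weight, sex, age, per-segment canal cross-sectional area) whose
#' association with motion magnitude is controlled by `cov_motion_rho`.
#' Flagged subjects (incidental stenosis) are generated like the others
#' but carry `excluded = TRUE`. The entire cohort is a pure function of
#' the config (including its seed).
#'
#' @param config A [cohort_config].
#' @return Object of class `synthetic_cohort`: list with `series` (named
#'   list of [phase_series]), `truth` (data.frame) and `subjects`
#'   (metadata data.frame).
#' @export
synthesize_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n_all <- config$n_subjects + config$n_flagged
    ids <- sprintf("S%02d", seq_len(n_all))
    flagged <- rep(c(FALSE, TRUE), c(config$n_subjects, config$n_flagged))
    series <- list()
    truth <- list()
    subj_lat <- numeric(n_all)
    canal <- list()
    for (i in seq_len(n_all)) {
      lat_acc <- 0
      for (seg in config$segments) {
        base_draw <- NULL
        for (sc in config$scans) {
          tr <- draw_truth(config, ids[i], seg, sc, base = base_draw)
          if (sc == config$scans[1]) base_draw <- tr
          out <- synthesize_series(config, ids[i], seg, sc, truth = tr)
          key <- paste(ids[i], sc, seg, sep = "_")
          series[[key]] <- out$series
          truth[[key]] <- out$truth
        }
        lat_acc <- lat_acc + base_draw$z_latent
        ## canal CSA (cm^2): negatively associated with motion magnitude
        rho <- config$cov_motion_rho
        canal[[paste(ids[i], seg, sep = "_")]] <- data.frame(
          subject_id = ids[i], segment = seg,
          canal_csa_cm2 = 2.7 + 0.25 * (-rho * base_draw$z_latent +
                                        sqrt(1 - rho^2) * stats::rnorm(1)),
          stringsAsFactors = FALSE)
      }
      subj_lat[i] <- lat_acc / length(config$segments)
    }
    rho <- config$cov_motion_rho
    subjects <- data.frame(
      subject_id = ids,
      sex = rep_len(c("m", "f"), n_all),
      age = round(stats::rnorm(n_all, 62.2, 6.5), 1),
      body_size_cm = round(172 + 9 * (-rho * subj_lat +
                                      sqrt(1 - rho^2) * stats::rnorm(n_all)), 1),
      body_weight_kg = round(stats::rnorm(n_all, 75, 12), 1),
      sys_before = round(stats::rnorm(n_all, 129.7, 13.7), 1),
      dia_before = round(stats::rnorm(n_all, 80.0, 7.3), 1),
      sys_after = round(stats::rnorm(n_all, 122.7, 10.5), 1),
      dia_after = round(stats::rnorm(n_all, 77.0, 7.7), 1),
      excluded = flagged,
      exclusion_reason = ifelse(flagged, "incidental stenosis", ""),
      stringsAsFactors = FALSE)
    structure(list(series = series,
                   truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                   subjects = subjects,
                   anatomy = do.call(rbind, c(canal, make.row.names = FALSE)),
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d flagged) x %d segments x %d scan(s): %d series\n",
              nrow(x$subjects), sum(x$subjects$excluded),
              length(x$config$segments), length(x$config$scans),
              length(x$series)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits one series file (or DICOM directory) per subject/scan/segment
#' plus `truth.csv`, `subjects.csv` and `anatomy.csv`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param format `"fixture"` or `"dicom"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("fixture", "dicom")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (key in names(cohort$series)) {
    path <- file.path(dir, if (format == "fixture") paste0(key, ".txt") else key)
    write_phase_series(cohort$series[[key]], path, format = format)
  }
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$anatomy, file.path(dir, "anatomy.csv"),
                   row.names = FALSE)
  invisible(dir)
}
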