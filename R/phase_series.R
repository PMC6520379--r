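#' Cardiac-gated phase-contrast image series
#'
#' One phase image stack for one cervical segment of one subject/scan:
#' T frames (cardiac phases, nominally 20) of H x W signed grey values.
#' Grey values encode velocity linearly: full scale (nominally 4096)
#' corresponds to the velocity encoding limit venc (nominally 2 cm/s).
#'
#' @param frames Integer array `T x H x W` of signed grey values, ordered
#'   by cardiac phase (trigger time ascending).
#' @param venc Velocity encoding in cm/s (> 0).
#' @param rr_interval RR interval (cardiac cycle duration) in ms, stored as
#'   an integer.
#' @param grey_full_scale Grey value corresponding to venc (default 4096).
#' @param pixel_spacing Length-2 numeric, mm per pixel (row, col).
#' @param subject_id,scan_id,segment Identifiers; `segment` must be one of
#'   `C2..C7`.
#' @return An object of class `phase_series`.
#' @export
phase_series <- function(frames, venc = 2, rr_interval = 1000,
                         grey_full_scale = 4096L,
                         pixel_spacing = c(0.5, 0.5),
                         subject_id = "S00", scan_id = "baseline",
                         segment = "C5") {
  if (length(dim(frames)) != 3)
    cm_stop("frames must be a T x H x W array", "cordmotion_structure_error")
  storage.mode(frames) <- "integer"
  s <- structure(
    list(subject_id = as.character(subject_id),
         scan_id = as.character(scan_id),
         segment = as.character(segment),
         frames = frames,
         n_timepoints = dim(frames)[1],
         venc = as.numeric(venc),
         grey_full_scale = as.integer(grey_full_scale),
         rr_interval = as.integer(round(rr_interval)),
         pixel_spacing = as.numeric(pixel_spacing)),
    class = "phase_series")
  validate_phase_series(s)
}

validate_phase_series <- function(s) {
  if (!s$segment %in% cervical_segments())
    cm_stop(paste("unknown segment:", s$segment), "cordmotion_metadata_error")
  if (is.na(s$venc) || s$venc <= 0)
    cm_stop("missing or non-positive venc", "cordmotion_metadata_error")
  if (is.na(s$rr_interval) || s$rr_interval <= 0)
    cm_stop("missing or non-positive rr_interval", "cordmotion_metadata_error")
  if (length(s$pixel_spacing) != 2 || any(s$pixel_spacing <= 0))
    cm_stop("pixel_spacing must be two positive values",
            "cordmotion_metadata_error")
  if (s$n_timepoints < 2 || dim(s$frames)[1] != s$n_timepoints)
    cm_stop(sprintf("frame count %d does not match n_timepoints %d (need >= 2)",
                    dim(s$frames)[1], s$n_timepoints),
            "cordmotion_structure_error")
  rng <- range(s$frames)
  if (max(abs(rng)) > s$grey_full_scale)
    cm_stop(sprintf("grey values in [%d, %d] exceed full scale %d",
                    rng[1], rng[2], s$grey_full_scale),
            "cordmotion_range_error")
  s
}

#' @export
print.phase_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<phase_series> %s/%s %s: %d frames of %dx%d, venc %g cm/s, RR %d ms\n",
              x$subject_id, x$scan_id, x$segment, d[1], d[2], d[3],
              x$venc, x$rr_interval))
  invisible(x)
}

#' ROI mean grey value per timepoint
#'
#' Averages the grey values of the pixels whose centers fall inside the
#' ellipse (pixel-center inclusion test in mm coordinates), separately for
#' each of the T cardiac phases. This is the quantity the clinical
#' workflow exports from the DICOM viewer before velocity conversion.
#'
#' @param series A [phase_series].
#' @param roi An [ellipse_roi]; must lie fully inside the image grid and
#'   cover at least one pixel center.
#' @return Numeric vector of length T.
#' @export
roi_mean_greyvalues <- function(series, roi) {
  d <- dim(series$frames)
  check_roi_inside(roi, d[2], d[3], series$pixel_spacing)
  mask <- roi_pixel_mask(roi, d[2], d[3], series$pixel_spacing)
  n_in <- sum(mask)
  if (n_in == 0)
    cm_stop("ROI covers no pixel centers", "cordmotion_geometry_error")
  idx <- which(mask)                      # column-major over H x W
  vapply(seq_len(d[1]), function(t) {
    fr <- series$frames[t, , ]
    mean(fr[idx])
  }, numeric(1))
}
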