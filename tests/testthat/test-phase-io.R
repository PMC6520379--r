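test_that("phase_series enforces its invariants", {
  s <- flat_series(0L, T = 20)
  expect_s3_class(s, "phase_series")
  expect_identical(s$n_timepoints, 20L)

  expect_error(phase_series(array(0L, c(1, 4, 4))),
               class = "cordmotion_structure_error")
  expect_error(phase_series(array(5000L, c(3, 4, 4))),
               class = "cordmotion_range_error")
  expect_error(phase_series(array(0L, c(3, 4, 4)), venc = 0),
               class = "cordmotion_metadata_error")
  expect_error(phase_series(array(0L, c(3, 4, 4)), rr_interval = -1),
               class = "cordmotion_metadata_error")
  expect_error(phase_series(array(0L, c(3, 4, 4)), segment = "T1"),
               class = "cordmotion_metadata_error")
})

test_that("ROI mean: constant and partition cases", {
  roi <- default_cord_roi(11.5, 11.5)
  s <- flat_series(1024L)
  expect_equal(roi_mean_greyvalues(s, roi), rep(1024, 20))

  # pixels inside the ellipse hold +full scale, outside -full scale
  mask <- cordmotion:::roi_pixel_mask(roi, 24, 24, c(0.5, 0.5))
  fr <- array(-4096L, c(5, 24, 24))
  for (t in 1:5) { m <- fr[t, , ]; m[mask] <- 4096L; fr[t, , ] <- m }
  s2 <- phase_series(fr)
  expect_equal(roi_mean_greyvalues(s2, roi), rep(4096, 5))
})

test_that("ROI mean equals the exhaustive pixel-enumeration oracle", {
  set.seed(41)
  roi <- ellipse_roi(7, 8, 2.5, 1.5)   # 5x3-pixel-ish ellipse at 1 mm spacing
  fr <- array(sample.int(8193, 4 * 16 * 16, replace = TRUE) - 4097L,
              c(4, 16, 16))
  s <- phase_series(fr, pixel_spacing = c(1, 1))
  got <- roi_mean_greyvalues(s, roi)

  # brute force: enumerate every pixel center and test the inequality
  for (t in 1:4) {
    vals <- c()
    for (r in 0:15) for (cc in 0:15)
      if (((r - 7) / 2.5)^2 + ((cc - 8) / 1.5)^2 <= 1)
        vals <- c(vals, fr[t, r + 1, cc + 1])
    expect_equal(got[t], mean(vals))
  }
})

test_that("ROI mean ignores pixels outside the ellipse", {
  set.seed(42)
  roi <- default_cord_roi(11.5, 11.5)
  mask <- cordmotion:::roi_pixel_mask(roi, 24, 24, c(0.5, 0.5))
  fr <- array(sample.int(2001, 3 * 576, replace = TRUE) - 1001L, c(3, 24, 24))
  s <- phase_series(fr)
  base <- roi_mean_greyvalues(s, roi)
  # permute every outside pixel, per frame
  fr2 <- fr
  for (t in 1:3) {
    m <- fr2[t, , ]
    m[!mask] <- sample(m[!mask])
    fr2[t, , ] <- m
  }
  expect_equal(roi_mean_greyvalues(phase_series(fr2), roi), base)
})

test_that("ROI pixel count approximates the ellipse area", {
  for (ab in list(c(2.2, 3.5), c(3, 3), c(1.5, 4))) {
    roi <- ellipse_roi(15.5, 15.5, ab[1], ab[2])
    mask <- cordmotion:::roi_pixel_mask(roi, 32, 32, c(0.5, 0.5))
    px_area <- 0.25
    # boundary pixels: in-mask pixels 4-adjacent to an out-of-mask pixel
    shift <- function(m, dr, dc) {
      out <- matrix(FALSE, nrow(m), ncol(m))
      rs <- pmin(pmax(row(m) + dr, 1), nrow(m))
      cs <- pmin(pmax(col(m) + dc, 1), ncol(m))
      out[] <- m[cbind(as.vector(rs), as.vector(cs))]
      out
    }
    interior <- mask & shift(mask, 1, 0) & shift(mask, -1, 0) &
                shift(mask, 0, 1) & shift(mask, 0, -1)
    n_boundary <- sum(mask & !interior)
    expect_lt(abs(sum(mask) * px_area - roi$area_mm2),
              (n_boundary + 1) * px_area)
  }
})

test_that("geometry errors: out-of-bounds and empty ROIs", {
  s <- flat_series(0L)
  expect_error(roi_mean_greyvalues(s, default_cord_roi(1, 1)),
               class = "cordmotion_geometry_error")
  expect_error(ellipse_roi(8, 8, -1, 2), class = "cordmotion_geometry_error")
  # legal bounding box but no pixel center inside: sub-pixel ellipse
  # between centers at 2 mm spacing
  tiny <- ellipse_roi(3.25, 3.25, 0.4, 0.4)
  s2 <- phase_series(array(0L, c(3, 8, 8)), pixel_spacing = c(2, 2))
  expect_error(roi_mean_greyvalues(s2, tiny),
               class = "cordmotion_geometry_error")
})

test_that("fixture format round-trips exactly and validates structure", {
  set.seed(7)
  fr <- array(sample.int(8193, 20 * 12 * 10, replace = TRUE) - 4097L,
              c(20, 12, 10))
  s <- phase_series(fr, venc = 2, rr_interval = 937,
                    pixel_spacing = c(0.47, 0.53),
                    subject_id = "S09", scan_id = "retest", segment = "C3")
  p <- tempfile(fileext = ".txt")
  write_phase_series(s, p, format = "fixture")
  s2 <- read_phase_series(p, format = "fixture")
  expect_identical(s2$frames, s$frames)
  for (f in c("subject_id", "scan_id", "segment", "n_timepoints", "venc",
              "grey_full_scale", "rr_interval", "pixel_spacing"))
    expect_identical(s2[[f]], s[[f]])

  # header advertising 20 frames over a 19-frame body -> structural error
  lines <- readLines(p)
  h <- 12  # image height
  truncated <- lines[seq_len(length(lines) - h)]
  p2 <- tempfile(fileext = ".txt")
  writeLines(truncated, p2)
  expect_error(read_phase_series(p2), class = "cordmotion_structure_error")

  # missing venc -> metadata error naming the field
  p3 <- tempfile(fileext = ".txt")
  writeLines(lines[!grepl("^venc_cm_s:", lines)], p3)
  expect_error(read_phase_series(p3), regexp = "venc",
               class = "cordmotion_metadata_error")
})

test_that("DICOM series round-trips bit-identically", {
  set.seed(8)
  fr <- array(sample.int(8193, 20 * 10 * 14, replace = TRUE) - 4097L,
              c(20, 10, 14))
  s <- phase_series(fr, venc = 2, rr_interval = 1042,
                    pixel_spacing = c(0.5, 0.625),
                    subject_id = "S03", scan_id = "baseline", segment = "C6")
  d <- tempfile()
  write_phase_series(s, d, format = "dicom")
  expect_length(list.files(d), 20)
  s2 <- read_phase_series(d, format = "dicom")
  expect_identical(s2$frames, s$frames)
  for (f in c("subject_id", "scan_id", "segment", "venc", "rr_interval",
              "pixel_spacing", "grey_full_scale"))
    expect_identical(s2[[f]], s[[f]])
})

test_that("DICOM frames are ordered by trigger time, not file name", {
  s <- synthesize_series(tiny_config(3, pixel_noise_sd = 0), seed = 3)$series
  d <- tempfile(); dir.create(d)
  # write frames under shuffled names
  set.seed(9)
  for (t in sample(seq_len(s$n_timepoints)))
    cordmotion:::write_dicom_frame(s, t, file.path(d, sprintf("z%02d.dcm",
                                                   sample.int(1000, 1))))
  s2 <- read_phase_series(d, format = "dicom")
  expect_identical(s2$frames, s$frames)
})

test_that("ROI config files round-trip", {
  rois <- list(cord = default_cord_roi(15.5, 15.5),
               static_tissue = ellipse_roi(4, 4, 1.5, 1.5,
                                           label = "static_tissue"))
  p <- tempfile()
  write_roi_file(rois, p)
  back <- read_roi_file(p)
  expect_named(back, c("cord", "static_tissue"))
  expect_equal(back$cord$area_mm2, 30.52)
  expect_identical(back$cord$semi_axis_col, rois$cord$semi_axis_col)
})
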