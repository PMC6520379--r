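#' Ellipsoid region of interest
#'
#' An elliptical ROI placed mid-centred in the spinal cord on the axial
#' phase image. The protocol's predefined cord ROI has an area of
#' 30.52 mm^2; [default_cord_roi()] reproduces it. Semi-axes are in mm so
#' the same ROI is valid across acquisitions with different pixel spacing;
#' the center is in 0-based pixel coordinates (row, col), pixel centers at
#' integer coordinates.
#'
#' @param center_row,center_col ROI center, 0-based pixel coordinates.
#' @param semi_axis_row,semi_axis_col Semi-axes in mm along the row and
#'   column directions. Must be positive.
#' @param label ROI label: `"cord"`, `"static_tissue"` or `"csf"`.
#' @return An object of class `ellipse_roi` with an `area_mm2` field
#'   (pi * a * b).
#' @examples
#' roi <- ellipse_roi(32, 32, 2.2, 3.5)
#' roi$area_mm2
#' @export
ellipse_roi <- function(center_row, center_col, semi_axis_row, semi_axis_col,
                        label = c("cord", "static_tissue", "csf")) {
  label <- match.arg(label)
  if (!is.numeric(semi_axis_row) || !is.numeric(semi_axis_col) ||
      semi_axis_row <= 0 || semi_axis_col <= 0)
    cm_stop("ROI semi-axes must be positive", "cordmotion_geometry_error")
  structure(
    list(center = c(row = as.numeric(center_row), col = as.numeric(center_col)),
         semi_axis_row = as.numeric(semi_axis_row),
         semi_axis_col = as.numeric(semi_axis_col),
         label = label,
         area_mm2 = pi * semi_axis_row * semi_axis_col),
    class = "ellipse_roi")
}

#' @export
print.ellipse_roi <- function(x, ...) {
  cat(sprintf("<ellipse_roi '%s'> center (%.2f, %.2f) px, semi-axes (%.3f, %.3f) mm, area %.2f mm^2\n",
              x$label, x$center["row"], x$center["col"],
              x$semi_axis_row, x$semi_axis_col, x$area_mm2))
  invisible(x)
}

#' Predefined cord ROI (30.52 mm^2)
#'
#' The protocol's predefined ellipsoid cord ROI. The published area is
#' 30.52 mm^2; the aspect ratio is not published, so the default uses a
#' right-left / anterior-posterior semi-axis ratio of 1.6, matching the
#' typical axial cord silhouette (wider right-left than
#' anterior-posterior). Semi-axes are solved from area and ratio, so the
#' area is exact by construction.
#'
#' @param center_row,center_col ROI center in 0-based pixel coordinates.
#' @param area_mm2 ROI area in mm^2.
#' @param aspect Ratio of the column (right-left) to the row
#'   (anterior-posterior) semi-axis.
#' @return An `ellipse_roi` with `area_mm2 == area_mm2`.
#' @export
default_cord_roi <- function(center_row, center_col,
                             area_mm2 = 30.52, aspect = 1.6) {
  a <- sqrt(area_mm2 / (pi * aspect))   # row (AP) semi-axis
  ellipse_roi(center_row, center_col, a, aspect * a, label = "cord")
}

## Logical H x W mask of pixels whose centers (in mm) fall inside the
## ellipse. Pixel (r, c) (0-based) has its center at (r * sp_r, c * sp_c).
roi_pixel_mask <- function(roi, height, width, pixel_spacing) {
  sp <- as.numeric(pixel_spacing)
  r_mm <- (seq_len(height) - 1) * sp[1]
  c_mm <- (seq_len(width) - 1) * sp[2]
  cr <- roi$center["row"] * sp[1]
  cc <- roi$center["col"] * sp[2]
  du <- (r_mm - cr) / roi$semi_axis_row
  dv <- (c_mm - cc) / roi$semi_axis_col
  outer(du^2, dv^2, `+`) <= 1
}

## Error unless the ROI bounding box lies inside the pixel-center grid.
check_roi_inside <- function(roi, height, width, pixel_spacing) {
  sp <- as.numeric(pixel_spacing)
  cr <- roi$center["row"] * sp[1]
  cc <- roi$center["col"] * sp[2]
  if (cr - roi$semi_axis_row < 0 || cr + roi$semi_axis_row > (height - 1) * sp[1] ||
      cc - roi$semi_axis_col < 0 || cc + roi$semi_axis_col > (width - 1) * sp[2])
    cm_stop(sprintf("ROI '%s' exceeds the %dx%d image grid", roi$label,
                    height, width),
            "cordmotion_geometry_error")
  invisible(TRUE)
}

#' Read and write ROI definition files
#'
#' Plain-text ROI config: one ROI per line,
#' `label center_row center_col semi_axis_row_mm semi_axis_col_mm`,
#' whitespace-separated, `#` comments allowed.
#'
#' @param path File path.
#' @return `read_roi_file()`: a named list of [ellipse_roi] objects (named
#'   by label). `write_roi_file()`: the path, invisibly.
#' @export
read_roi_file <- function(path) {
  if (!file.exists(path))
    cm_stop(paste("ROI file not found:", path), "cordmotion_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  rois <- lapply(lines, function(ln) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) != 5)
      cm_stop(paste("malformed ROI line:", ln), "cordmotion_io_error")
    ellipse_roi(as.numeric(f[2]), as.numeric(f[3]),
                as.numeric(f[4]), as.numeric(f[5]), label = f[1])
  })
  names(rois) <- vapply(rois, `[[`, "", "label")
  rois
}

#' @rdname read_roi_file
#' @param rois A list of [ellipse_roi] objects.
#' @export
write_roi_file <- function(rois, path) {
  if (inherits(rois, "ellipse_roi")) rois <- list(rois)
  lines <- vapply(rois, function(r) {
    paste(r$label, num_chr(r$center["row"]), num_chr(r$center["col"]),
          num_chr(r$semi_axis_row), num_chr(r$semi_axis_col))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
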