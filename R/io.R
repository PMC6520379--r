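#' Read and write a cardiac-gated phase series
#'
#' Two on-disk representations are supported. `"fixture"` is the package's
#' portable single-file plain-text container (explicit header with every
#' scalar field, then the integer frame block); `"dicom"` is a directory
#' of single-frame Explicit-VR-little-endian DICOM files, one per cardiac
#' phase, ordered by per-frame TriggerTime (ties broken by
#' InstanceNumber), with the RR interval taken from NominalInterval and
#' rescale slope/intercept applied at read time. For both formats
#' `read_phase_series(write_phase_series(s))` is the identity on frames
#' and all scalar metadata.
#'
#' @param path File path (fixture) or directory (dicom).
#' @param format `"fixture"` or `"dicom"`; `read_phase_series()` guesses
#'   from `path` when omitted (directory implies dicom).
#' @return `read_phase_series()`: a [phase_series]. `write_phase_series()`:
#'   `path`, invisibly.
#' @examples
#' s <- phase_series(array(0L, c(20, 8, 8)))
#' p <- tempfile(fileext = ".txt")
#' write_phase_series(s, p)
#' identical(read_phase_series(p)$frames, s$frames)
#' @export
read_phase_series <- function(path, format = c("auto", "fixture", "dicom")) {
  format <- match.arg(format)
  if (!file.exists(path))
    cm_stop(paste("no such path:", path), "cordmotion_io_error")
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom" else "fixture"
  switch(format,
         fixture = read_phase_fixture(path),
         dicom = read_dicom_series(path))
}

#' @rdname read_phase_series
#' @param series A [phase_series].
#' @export
write_phase_series <- function(series, path,
                               format = c("auto", "fixture", "dicom")) {
  format <- match.arg(format)
  stopifnot(inherits(series, "phase_series"))
  if (format == "auto")
    format <- if (grepl("\\.(txt|fix)$", path)) "fixture" else "dicom"
  switch(format,
         fixture = write_phase_fixture(series, path),
         dicom = write_dicom_series(series, path))
  invisible(path)
}
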