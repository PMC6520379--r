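## Portable single-file fixture format for a phase series: a plain-text
## header (every phase_series scalar field) followed by the frame block,
## one image row of whitespace-separated integers per line, frames in
## cardiac-phase order. Deterministic, diffable, and independent of any
## DICOM machinery.

FIXTURE_MAGIC <- "cordmotion-phase-series v1"

write_phase_fixture <- function(series, path) {
  d <- dim(series$frames)
  con <- tryCatch(file(path, "w"), error = function(e)
    cm_stop(paste("cannot open for writing:", path), "cordmotion_io_error"))
  on.exit(close(con))
  writeLines(c(
    FIXTURE_MAGIC,
    paste("subject_id:", series$subject_id),
    paste("scan_id:", series$scan_id),
    paste("segment:", series$segment),
    paste("n_timepoints:", d[1]),
    paste("height:", d[2]),
    paste("width:", d[3]),
    paste("venc_cm_s:", num_chr(series$venc)),
    paste("grey_full_scale:", series$grey_full_scale),
    paste("rr_interval_ms:", series$rr_interval),
    paste("pixel_spacing_mm:", num_chr(series$pixel_spacing[1]),
          num_chr(series$pixel_spacing[2])),
    "frames:"), con)
  for (t in seq_len(d[1]))
    writeLines(apply(series$frames[t, , , drop = FALSE], 2, function(row)
      paste(row, collapse = " ")), con)
  invisible(path)
}

read_phase_fixture <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 12 || lines[1] != FIXTURE_MAGIC)
    cm_stop(paste("not a cordmotion fixture file:", path),
            "cordmotion_structure_error")
  hdr_end <- match("frames:", lines)
  if (is.na(hdr_end))
    cm_stop("fixture header missing 'frames:' marker",
            "cordmotion_structure_error")
  hdr <- lines[2:(hdr_end - 1)]
  kv <- strsplit(hdr, ":[[:space:]]*")
  keys <- vapply(kv, `[[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ":"), "")
  names(vals) <- keys
  need <- function(k) {
    if (!k %in% keys)
      cm_stop(paste("fixture header missing field:", k),
              "cordmotion_metadata_error")
    vals[[k]]
  }
  nt <- as.integer(need("n_timepoints"))
  h  <- as.integer(need("height"))
  w  <- as.integer(need("width"))
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nt * h)
    cm_stop(sprintf("fixture advertises %d frames of %d rows but holds %d rows",
                    nt, h, length(body)),
            "cordmotion_structure_error")
  vals_int <- scan(text = body, what = integer(), quiet = TRUE)
  if (length(vals_int) != nt * h * w)
    cm_stop("fixture frame block has wrong pixel count",
            "cordmotion_structure_error")
  ## rows were written per (frame, image-row); rebuild T x H x W
  frames <- aperm(array(vals_int, dim = c(w, h, nt)), c(3, 2, 1))
  sp <- as.numeric(strsplit(need("pixel_spacing_mm"), "[[:space:]]+")[[1]])
  phase_series(frames,
               venc = as.numeric(need("venc_cm_s")),
               rr_interval = as.integer(need("rr_interval_ms")),
               grey_full_scale = as.integer(need("grey_full_scale")),
               pixel_spacing = sp,
               subject_id = need("subject_id"),
               scan_id = need("scan_id"),
               segment = need("segment"))
}
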