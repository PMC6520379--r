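## Minimal DICOM Part-10 support for cardiac-gated phase series.
##
## No DICOM library is available in the target environment, so this module
## implements the small subset the pipeline needs: Explicit VR Little
## Endian only, one single-frame MR image file per cardiac phase, with
## per-frame TriggerTime, NominalInterval (RR, ms), PixelSpacing, signed
## 16-bit pixel data and rescale slope/intercept. It is a faithful but
## deliberately narrow implementation; it is not a general DICOM parser.

TRANSFER_SYNTAX_EVLE <- "1.2.840.10008.1.2.1"
UID_ROOT <- "1.2.826.0.1.3680043.9.7434"   # generic org root for synthetic UIDs

even_pad <- function(x, pad = as.raw(0x20)) {
  if (length(x) %% 2 == 1) c(x, pad) else x
}

## One data element in Explicit VR LE.
dcm_element <- function(group, element, vr, value) {
  tag <- writeBin(as.integer(c(group, element)), raw(), size = 2,
                  endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    body <- value
    len <- writeBin(length(body), raw(), size = 4, endian = "little")
    c(tag, charToRaw(vr), as.raw(c(0, 0)), len, body)
  } else {
    body <- if (is.raw(value)) value else {
      pad <- if (vr == "UI") as.raw(0) else as.raw(0x20)
      even_pad(charToRaw(as.character(value)), pad)
    }
    len <- writeBin(length(body), raw(), size = 2, endian = "little")
    c(tag, charToRaw(vr), len, body)
  }
}

dcm_us <- function(group, element, value)
  dcm_element(group, element, "US",
              writeBin(as.integer(value), raw(), size = 2, endian = "little"))
dcm_ss <- function(group, element, value)
  dcm_element(group, element, "SS",
              writeBin(as.integer(value), raw(), size = 2, endian = "little"))
dcm_fd <- function(group, element, value)
  dcm_element(group, element, "FD",
              writeBin(as.numeric(value), raw(), size = 8, endian = "little"))

## Write one single-frame file for cardiac phase t of a series.
write_dicom_frame <- function(series, t, path) {
  d <- dim(series$frames)
  sop_uid <- paste(UID_ROOT, abs(sum(utf8ToInt(series$subject_id))),
                   match(series$segment, cervical_segments()), t, sep = ".")
  trigger <- (t - 1) / d[1] * series$rr_interval
  pix <- t(series$frames[t, , ])          # row-major pixel order
  pixel_bytes <- writeBin(as.integer(as.vector(pix)), raw(), size = 2,
                          endian = "little")
  dataset <- c(
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "MR"),
    dcm_element(0x0008, 0x1030, "LO", series$scan_id),
    dcm_element(0x0008, 0x103E, "LO", series$segment),
    dcm_element(0x0010, 0x0020, "LO", series$subject_id),
    dcm_element(0x0018, 0x1060, "DS", num_chr(trigger)),
    dcm_element(0x0018, 0x1062, "IS", as.character(series$rr_interval)),
    dcm_fd(0x0018, 0x9217, series$venc),
    dcm_element(0x0020, 0x0013, "IS", as.character(t)),
    dcm_us(0x0028, 0x0002, 1),
    dcm_us(0x0028, 0x0010, d[2]),
    dcm_us(0x0028, 0x0011, d[3]),
    dcm_element(0x0028, 0x0030, "DS",
                paste(num_chr(series$pixel_spacing[1]),
                      num_chr(series$pixel_spacing[2]), sep = "\\")),
    dcm_us(0x0028, 0x0100, 16),
    dcm_us(0x0028, 0x0101, 16),
    dcm_us(0x0028, 0x0102, 15),
    dcm_us(0x0028, 0x0103, 1),            # signed
    dcm_ss(0x0028, 0x0107, series$grey_full_scale),
    dcm_element(0x0028, 0x1052, "DS", "0"),
    dcm_element(0x0028, 0x1053, "DS", "1"),
    dcm_element(0x7FE0, 0x0010, "OW", pixel_bytes))
  meta_body <- c(
    dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.4"),
    dcm_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_element(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_EVLE))
  meta <- c(dcm_element(0x0002, 0x0000, "UL",
                        writeBin(length(meta_body), raw(), size = 4,
                                 endian = "little")),
            meta_body)
  con <- tryCatch(file(path, "wb"), error = function(e)
    cm_stop(paste("cannot open for writing:", path), "cordmotion_io_error"))
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, dataset), con)
  invisible(path)
}

## --- reader -----------------------------------------------------------

dcm_parse_file <- function(path) {
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    cm_stop(paste("not a DICOM file:", path), "cordmotion_structure_error")
  pos <- 133L
  n <- length(bytes)
  elems <- list()
  u16 <- function(i) readBin(bytes[i:(i + 1)], "integer", size = 2,
                             signed = FALSE, endian = "little")
  u32 <- function(i) readBin(bytes[i:(i + 3)], "integer", size = 4,
                             endian = "little")
  while (pos + 7 <= n) {
    group <- u16(pos); element <- u16(pos + 2)
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8)
      data_start <- pos + 12
    } else {
      len <- u16(pos + 6)
      data_start <- pos + 8
    }
    if (len < 0 || data_start + len - 1 > n)
      cm_stop(paste("truncated DICOM element in", path),
              "cordmotion_structure_error")
    key <- sprintf("%04X,%04X", group, element)
    elems[[key]] <- list(vr = vr,
                         raw = if (len > 0) bytes[data_start:(data_start + len - 1)]
                               else raw(0))
    pos <- data_start + len
  }
  elems
}

dcm_str <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) return(NULL)
  trimws(rawToChar(e$raw[e$raw != as.raw(0)]))
}
dcm_num <- function(elems, key) {
  s <- dcm_str(elems, key)
  if (is.null(s)) NULL else as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_u16 <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) NULL
  else readBin(e$raw, "integer", size = 2, signed = FALSE, endian = "little")
}
dcm_s16 <- function(elems, key, n = 1) {
  e <- elems[[key]]
  if (is.null(e)) NULL
  else readBin(e$raw, "integer", n = n, size = 2, signed = TRUE,
               endian = "little")
}
dcm_f64 <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) NULL
  else readBin(e$raw, "double", size = 8, endian = "little")
}

## Read a directory of single-frame DICOM files as one phase series.
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2)
    cm_stop(paste("DICOM series directory holds fewer than 2 files:", dir),
            "cordmotion_structure_error")
  frames_raw <- lapply(files, dcm_parse_file)
  meta_of <- function(e, key, what) {
    v <- what(e, key)
    if (is.null(v))
      cm_stop(paste("DICOM file missing required field", key),
              "cordmotion_metadata_error")
    v
  }
  trigger <- vapply(frames_raw, meta_of, numeric(1), "0018,1060", dcm_num)
  instance <- vapply(frames_raw, meta_of, numeric(1), "0020,0013", dcm_num)
  ord <- order(trigger, instance)         # cardiac phase; ties by instance
  frames_raw <- frames_raw[ord]
  e1 <- frames_raw[[1]]
  rows <- meta_of(e1, "0028,0010", dcm_u16)
  cols <- meta_of(e1, "0028,0011", dcm_u16)
  venc <- meta_of(e1, "0018,9217", dcm_f64)
  rr <- meta_of(e1, "0018,1062", dcm_num)
  spacing <- meta_of(e1, "0028,0030", dcm_num)
  full_scale <- dcm_s16(e1, "0028,0107")
  if (is.null(full_scale)) full_scale <- 4096L
  nt <- length(frames_raw)
  frames <- array(0L, dim = c(nt, rows, cols))
  for (t in seq_len(nt)) {
    e <- frames_raw[[t]]
    slope <- dcm_num(e, "0028,1053"); intercept <- dcm_num(e, "0028,1052")
    if (is.null(slope)) slope <- 1
    if (is.null(intercept)) intercept <- 0
    pix <- dcm_s16(e, "7FE0,0010", n = rows * cols)
    if (is.null(pix) || length(pix) != rows * cols)
      cm_stop("DICOM pixel data missing or wrong length",
              "cordmotion_structure_error")
    frames[t, , ] <- matrix(as.integer(round(pix * slope + intercept)),
                            nrow = rows, byrow = TRUE)
  }
  phase_series(frames, venc = venc, rr_interval = rr,
               grey_full_scale = full_scale, pixel_spacing = spacing,
               subject_id = dcm_str(e1, "0010,0020"),
               scan_id = dcm_str(e1, "0008,1030"),
               segment = dcm_str(e1, "0008,103E"))
}

write_dicom_series <- function(series, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (t in seq_len(series$n_timepoints))
    write_dicom_frame(series, t, file.path(dir, sprintf("frame%03d.dcm", t)))
  invisible(dir)
}
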