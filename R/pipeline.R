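#' Read a pipeline run configuration
#'
#' Plain-text config in DCF (`key: value`) format. Recognized fields:
#' `mode` (simulate | fixture-dir | dicom-dir), `seed` (required for
#' simulate), `input_dir`, `output_dir`, `roi_file`, `n_subjects`,
#' `segments` (comma-separated), `scans` (comma-separated),
#' `use_correction` (true/false), `reliability` (none | inter_rater |
#' test_retest), `rater_jitter_px` (re-placement jitter of the second
#' rater's ROI center, pixels). Explicit arguments to [run_pipeline()]
#' override file values.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    cm_stop(paste("config file not found:", path), "cordmotion_io_error")
  dcf <- read.dcf(path)
  cfg <- as.list(dcf[1, ])
  for (f in c("seed", "n_subjects"))
    if (!is.null(cfg[[f]])) cfg[[f]] <- as.integer(cfg[[f]])
  for (f in c("rater_jitter_px"))
    if (!is.null(cfg[[f]])) cfg[[f]] <- as.numeric(cfg[[f]])
  for (f in c("segments", "scans"))
    if (!is.null(cfg[[f]]))
      cfg[[f]] <- trimws(strsplit(cfg[[f]], ",")[[1]])
  if (!is.null(cfg$use_correction))
    cfg$use_correction <- tolower(cfg$use_correction) %in% c("true", "yes", "1")
  cfg
}

#' Run the pipeline end-to-end
#'
#' Orchestrates simulate -> quantify -> report. In `simulate` mode a
#' synthetic cohort is generated from the seed; in `fixture-dir` /
#' `dicom-dir` mode every series found under `input_dir` is read (one
#' fixture file or one DICOM directory per series). Outputs, all CSV:
#' per-series waveforms (`waveforms.csv`), per-series readouts
#' (`readouts.csv`), the per-segment summary (`summary.csv`), optional
#' reliability and correlation tables, and `manifest.csv` listing every
#' artifact with its md5 checksum. Identical config + seed gives
#' identical checksums. On any module error, partial outputs are removed
#' and the error is rethrown.
#'
#' @param config Path to a DCF config file, or a named list as returned
#'   by [read_run_config()].
#' @param ... Overrides of individual config fields.
#' @return Invisibly, the manifest data.frame (`file`, `md5`).
#' @export
run_pipeline <- function(config, ...) {
  if (is.character(config)) config <- read_run_config(config)
  over <- list(...)
  config[names(over)] <- over
  mode <- config$mode %||% "simulate"
  out_dir <- config$output_dir %||%
    cm_stop("config must name an output_dir", "cordmotion_config_error")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  tryCatch({
    if (mode == "simulate") {
      if (is.null(config$seed))
        cm_stop("simulate mode requires a seed", "cordmotion_config_error")
      cc_args <- list(seed = config$seed)
      for (f in c("n_subjects", "segments", "scans"))
        if (!is.null(config[[f]])) cc_args[[f]] <- config[[f]]
      cohort <- synthesize_cohort(do.call(cohort_config, cc_args))
      series <- cohort$series
      subjects <- cohort$subjects
      anatomy <- cohort$anatomy
      roi <- cohort$config$roi
    } else if (mode %in% c("fixture-dir", "dicom-dir")) {
      input_dir <- config$input_dir %||%
        cm_stop("directory modes require input_dir", "cordmotion_config_error")
      fmt <- if (mode == "fixture-dir") "fixture" else "dicom"
      paths <- if (fmt == "fixture")
        list.files(input_dir, pattern = "\\.(txt|fix)$", full.names = TRUE)
      else
        list.dirs(input_dir, recursive = FALSE)
      if (length(paths) == 0)
        cm_stop(paste("no series found under", input_dir),
                "cordmotion_io_error")
      series <- lapply(paths, read_phase_series, format = fmt)
      names(series) <- vapply(series, function(s)
        paste(s$subject_id, s$scan_id, s$segment, sep = "_"), "")
      subj_csv <- file.path(input_dir, "subjects.csv")
      subjects <- if (file.exists(subj_csv))
        utils::read.csv(subj_csv, stringsAsFactors = FALSE)
      else data.frame(subject_id = unique(vapply(series, `[[`, "", "subject_id")),
                      excluded = FALSE, exclusion_reason = "",
                      stringsAsFactors = FALSE)
      anat_csv <- file.path(input_dir, "anatomy.csv")
      anatomy <- if (file.exists(anat_csv))
        utils::read.csv(anat_csv, stringsAsFactors = FALSE) else NULL
      roi <- if (!is.null(config$roi_file))
        read_roi_file(config$roi_file)[["cord"]]
      else default_cord_roi((dim(series[[1]]$frames)[2] - 1) / 2,
                            (dim(series[[1]]$frames)[3] - 1) / 2)
    } else {
      cm_stop(paste("unknown mode:", mode), "cordmotion_config_error")
    }
    rois <- list(R1 = roi)
    reliability <- config$reliability %||% "none"
    if (reliability == "inter_rater") {
      j <- config$rater_jitter_px %||% 0.5
      rois$R2 <- ellipse_roi(roi$center["row"] + j, roi$center["col"] + j,
                             roi$semi_axis_row, roi$semi_axis_col,
                             label = "cord")
    }
    use_corr <- config$use_correction %||% TRUE

    ## quantify
    readouts <- quantify_cohort(series, rois)
    waveforms <- do.call(rbind, c(lapply(series, function(s) {
      pr <- process_series(s, roi)
      data.frame(subject_id = s$subject_id, scan_id = s$scan_id,
                 segment = s$segment,
                 timepoint = seq_along(pr$waveform$values),
                 velocity = pr$waveform$values,
                 stringsAsFactors = FALSE)
    }), make.row.names = FALSE))
    emit(waveforms, "waveforms.csv")
    emit(readouts, "readouts.csv")

    ## report
    cohort_tab <- apply_exclusions(
      cohort_table(readouts, derive_biometrics_if_present(subjects), anatomy))
    summary_tab <- do.call(rbind, c(lapply(READOUT_NAMES, function(ro) {
      s <- segment_summary(cohort_tab, ro)
      s$readout <- ro
      s
    }), make.row.names = FALSE))
    emit(summary_tab, "summary.csv")
    if (reliability %in% c("inter_rater", "test_retest"))
      emit(reliability_report(cohort_tab, reliability,
                              use_correction = use_corr),
           paste0("reliability_", reliability, ".csv"))
    if (length(unique(cohort_tab$readouts$segment)) >= 3 &&
        nrow(cohort_tab$subjects) >= 2) {
      fr <- friedman_intersegment(cohort_tab, "amplitude")
      emit(fr$pairwise, "friedman_pairwise_amplitude.csv")
    }
    covs <- intersect(c("body_size_cm", "map", "canal_csa_cm2"),
                      c(names(cohort_tab$subjects),
                        names(cohort_tab$anatomy %||% data.frame())))
    if (length(covs) > 0 && nrow(cohort_tab$subjects) >= 4) {
      cors <- do.call(rbind, c(lapply(covs, function(cv) {
        r <- spearman_correlations(cohort_tab, "displacement", cv,
                                   scope = "pooled_all_segments")
        r$covariate <- cv
        r
      }), make.row.names = FALSE))
      emit(cors, "correlations.csv")
    }
    manifest <- data.frame(file = basename(written),
                           md5 = unname(tools::md5sum(written)),
                           stringsAsFactors = FALSE)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    invisible(manifest)
  }, cordmotion_error = function(e) {
    unlink(written)                       # no partial outputs on failure
    stop(e)
  })
}

derive_biometrics_if_present <- function(subjects) {
  if (all(c("sys_before", "sys_after", "dia_before", "dia_after") %in%
          names(subjects)))
    derive_biometrics(subjects)
  else subjects
}
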