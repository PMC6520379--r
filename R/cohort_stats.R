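READOUT_NAMES <- c("amplitude", "max_cranial", "max_caudal", "displacement")

#' Quantify every series of a cohort
#'
#' Runs the full evaluation ([process_series()]) over a set of phase
#' series, once per rater ROI. Supplying two rater ROIs (e.g. the
#' predefined ROI and a jittered re-placement) yields the substrate for
#' inter-rater reliability. Raw (uncorrected) readouts are carried along
#' for drift-sensitivity analyses.
#'
#' @param series A `synthetic_cohort` or a (named) list of [phase_series].
#' @param rois Either one cord [ellipse_roi] used for a single rater
#'   `"R1"`, or a named list of ROIs, one per rater.
#' @return data.frame with one row per series x rater: identifiers, the
#'   four corrected readouts, `drift_estimate`, `rr_interval` (ms), and
#'   `raw_*` counterparts computed without drift correction.
#' @export
quantify_cohort <- function(series, rois = NULL) {
  if (inherits(series, "synthetic_cohort")) {
    if (is.null(rois)) rois <- series$config$roi
    series <- series$series
  }
  if (is.null(rois))
    cm_stop("quantify_cohort needs at least one cord ROI",
            "cordmotion_config_error")
  if (inherits(rois, "ellipse_roi")) rois <- list(R1 = rois)
  rows <- list()
  for (s in series) {
    for (rater in names(rois)) {
      corr <- process_series(s, rois[[rater]], correct = TRUE)
      raw <- compute_readouts(
        grey_to_velocity(roi_mean_greyvalues(s, rois[[rater]]),
                         venc = s$venc, grey_full_scale = s$grey_full_scale,
                         rr_interval_s = s$rr_interval / 1000),
        allow_uncorrected = TRUE)
      r <- corr$readouts
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = s$subject_id, scan_id = s$scan_id, rater_id = rater,
        segment = s$segment,
        amplitude = r$amplitude, max_cranial = r$max_cranial,
        max_caudal = r$max_caudal, displacement = r$displacement,
        drift_estimate = corr$waveform$drift_estimate,
        rr_interval = s$rr_interval,
        raw_amplitude = raw$amplitude, raw_max_cranial = raw$max_cranial,
        raw_max_caudal = raw$max_caudal, raw_displacement = raw$displacement,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Cohort table: readouts joined with subject covariates
#'
#' The substrate for all cohort statistics. `readouts` holds one row per
#' (subject, scan, rater, segment) — the unique key — with the four
#' readouts as columns; `subjects` holds one row per subject with the
#' exclusion flag and covariates; `anatomy` optionally holds per
#' subject x segment anatomical measures.
#'
#' @param readouts data.frame as produced by [quantify_cohort()].
#' @param subjects Subject metadata; must carry `subject_id` and a
#'   logical `excluded` column (with `exclusion_reason` for flagged
#'   subjects).
#' @param anatomy Optional per subject x segment covariates.
#' @return Object of class `cohort_table`.
#' @export
cohort_table <- function(readouts, subjects, anatomy = NULL) {
  need <- c("subject_id", "scan_id", "rater_id", "segment", READOUT_NAMES)
  if (!all(need %in% names(readouts)))
    cm_stop(paste("readouts missing columns:",
                  paste(setdiff(need, names(readouts)), collapse = ", ")),
            "cordmotion_structure_error")
  key <- interaction(readouts$subject_id, readouts$scan_id,
                     readouts$rater_id, readouts$segment, drop = TRUE)
  if (anyDuplicated(key))
    cm_stop("(subject, scan, rater, segment) key is not unique",
            "cordmotion_structure_error")
  if (!"excluded" %in% names(subjects))
    cm_stop("subjects table must carry an 'excluded' flag",
            "cordmotion_structure_error")
  if (any(subjects$excluded &
          !nzchar(trimws(subjects$exclusion_reason %||% ""))))
    cm_stop("excluded subjects must carry a non-empty exclusion_reason",
            "cordmotion_structure_error")
  structure(list(readouts = readouts, subjects = subjects, anatomy = anatomy),
            class = "cohort_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d readout rows, %d subjects (%d excluded)%s\n",
              nrow(x$readouts), nrow(x$subjects), sum(x$subjects$excluded),
              if (!is.null(x$anatomy)) ", with anatomy" else ""))
  invisible(x)
}

#' Remove subjects flagged for exclusion
#'
#' Subjects flagged at structural imaging review (e.g. incidental
#' stenosis) are removed from the readouts, subjects and anatomy tables;
#' the before/after counts are reported via `message()`.
#'
#' @param cohort A [cohort_table].
#' @return A [cohort_table] holding retained subjects only.
#' @export
apply_exclusions <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  keep <- cohort$subjects$subject_id[!cohort$subjects$excluded]
  n0 <- nrow(cohort$subjects)
  message(sprintf("exclusion filter: %d of %d subjects retained",
                  length(keep), n0))
  if (length(keep) == 0)
    cm_warn("all subjects excluded: empty cohort", "cordmotion_empty_warning")
  out <- cohort
  out$subjects <- cohort$subjects[!cohort$subjects$excluded, , drop = FALSE]
  out$readouts <- cohort$readouts[cohort$readouts$subject_id %in% keep, ,
                                  drop = FALSE]
  if (!is.null(cohort$anatomy))
    out$anatomy <- cohort$anatomy[cohort$anatomy$subject_id %in% keep, ,
                                  drop = FALSE]
  out
}

#' Derived biometric covariates
#'
#' Blood pressure is taken before and after the scan; the derived values
#' are the before/after means and the mean arterial pressure
#' `MAP = diastolic + (systolic - diastolic) / 3` computed on those
#' means. Missing pressures propagate as `NA` (pairwise deletion happens
#' per downstream analysis).
#'
#' @param subjects Subject table with `sys_before`, `sys_after`,
#'   `dia_before`, `dia_after` (mmHg).
#' @return The table with `mean_systolic`, `mean_diastolic` and `map`
#'   columns appended.
#' @examples
#' derive_biometrics(data.frame(sys_before = 129.7, sys_after = 122.7,
#'                              dia_before = 80, dia_after = 77))
#' @export
derive_biometrics <- function(subjects) {
  need <- c("sys_before", "sys_after", "dia_before", "dia_after")
  if (!all(need %in% names(subjects)))
    cm_stop(paste("subjects missing columns:",
                  paste(setdiff(need, names(subjects)), collapse = ", ")),
            "cordmotion_structure_error")
  subjects$mean_systolic <- (subjects$sys_before + subjects$sys_after) / 2
  subjects$mean_diastolic <- (subjects$dia_before + subjects$dia_after) / 2
  subjects$map <- subjects$mean_diastolic +
    (subjects$mean_systolic - subjects$mean_diastolic) / 3
  subjects
}

## One value per subject for a readout, restricted to one scan/rater.
readout_by_subject <- function(cohort, readout, scan_id = NULL,
                               rater_id = NULL, raw = FALSE) {
  rd <- cohort$readouts
  if (is.null(scan_id)) scan_id <- rd$scan_id[1]
  if (is.null(rater_id)) rater_id <- rd$rater_id[1]
  col <- if (raw) paste0("raw_", readout) else readout
  if (!col %in% names(rd))
    cm_stop(paste("unknown readout:", readout), "cordmotion_structure_error")
  rd <- rd[rd$scan_id == scan_id & rd$rater_id == rater_id, , drop = FALSE]
  rd[, c("subject_id", "segment", col)]
}

#' Per-segment summary of a readout
#'
#' Group mean, sample SD (n-1 denominator) and n per segment.
#'
#' @param cohort A [cohort_table] (post-exclusion).
#' @param readout One of `"amplitude"`, `"max_cranial"`, `"max_caudal"`,
#'   `"displacement"`.
#' @param scan_id,rater_id Restrict to one scan/rater (defaults: the
#'   first present).
#' @return data.frame with columns `segment`, `mean`, `sd`, `n`.
#' @export
segment_summary <- function(cohort, readout = READOUT_NAMES,
                            scan_id = NULL, rater_id = NULL) {
  readout <- match.arg(readout)
  d <- readout_by_subject(cohort, readout, scan_id, rater_id)
  if (length(unique(d$subject_id)) < 2)
    cm_stop("segment_summary needs >= 2 subjects", "cordmotion_data_error")
  segs <- intersect(cervical_segments(), unique(d$segment))
  out <- do.call(rbind, lapply(segs, function(sg) {
    v <- d[d$segment == sg, 3]
    data.frame(segment = sg, mean = mean(v), sd = stats::sd(v),
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Friedman intersegment comparison with Dunn post-hoc tests
#'
#' Omnibus Friedman test of the readout across segments (subjects as
#' blocks; a complete block design — subjects missing any segment are
#' dropped with a warning), followed by pairwise Dunn tests on the
#' within-subject mean ranks with Bonferroni adjustment over all segment
#' pairs.
#'
#' @inheritParams segment_summary
#' @return List with `statistic` (Friedman chi-square), `df`, `p_value`,
#'   `n_subjects`, and `pairwise`: a data.frame of segment pairs with
#'   `z`, `p_raw` and Bonferroni-adjusted `p_adj`.
#' @export
friedman_intersegment <- function(cohort, readout = READOUT_NAMES,
                                  scan_id = NULL, rater_id = NULL) {
  readout <- match.arg(readout)
  d <- readout_by_subject(cohort, readout, scan_id, rater_id)
  segs <- intersect(cervical_segments(), unique(d$segment))
  if (length(segs) < 3)
    cm_stop("Friedman test needs >= 3 segments", "cordmotion_data_error")
  m <- stats::reshape(d, idvar = "subject_id", timevar = "segment",
                      direction = "wide")
  mat <- as.matrix(m[, -1])
  colnames(mat) <- sub("^[^.]*\\.", "", colnames(m)[-1])
  mat <- mat[, segs, drop = FALSE]
  complete <- stats::complete.cases(mat)
  if (any(!complete))
    cm_warn(sprintf("%d subject(s) dropped from Friedman test (incomplete segments)",
                    sum(!complete)), "cordmotion_dropped_warning")
  mat <- mat[complete, , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2)
    cm_stop("Friedman test needs >= 2 complete subjects",
            "cordmotion_data_error")
  ft <- stats::friedman.test(mat)
  stat <- unname(ft$statistic); pval <- ft$p.value
  if (is.nan(stat)) {                     # every ranking fully tied
    stat <- 0; pval <- 1
  }
  ranks <- t(apply(mat, 1, rank))
  rbar <- colMeans(ranks)
  pairs <- utils::combn(seq_len(k), 2)
  se <- sqrt(k * (k + 1) / (6 * n))
  z <- (rbar[pairs[1, ]] - rbar[pairs[2, ]]) / se
  p_raw <- 2 * stats::pnorm(-abs(z))
  pairwise <- data.frame(
    segment_a = segs[pairs[1, ]], segment_b = segs[pairs[2, ]],
    z = as.numeric(z), p_raw = p_raw,
    p_adj = pmin(1, p_raw * ncol(pairs)),
    stringsAsFactors = FALSE)
  list(statistic = stat, df = unname(ft$parameter),
       p_value = pval, n_subjects = n, pairwise = pairwise)
}

#' Two-way mixed, absolute-agreement, average-measures ICC
#'
#' The intraclass correlation ICC(A,k) of McGraw & Wong for a two-way
#' model with absolute agreement on the average of k measurements:
#' `(MS_R - MS_E) / (MS_R + (MS_C - MS_E) / n)`, where MS_R, MS_C and
#' MS_E are the rows (subjects), columns (raters/scans) and error mean
#' squares of the two-way ANOVA decomposition. The p-value is the F test
#' of `MS_R / MS_E` on `(n - 1, (n - 1)(k - 1))` degrees of freedom.
#'
#' @param mat Numeric matrix, subjects in rows, the k raters or scans in
#'   columns; no missing cells.
#' @param type,unit Fixed to `"absolute_agreement"` / `"average"`; other
#'   conventions are out of scope.
#' @return Object of class `icc_result`: list with `icc`, `p_value`,
#'   `n_subjects`, `k`, `model`, `f_value`, `df1`, `df2`.
#' @export
icc_two_way <- function(mat, type = "absolute_agreement", unit = "average") {
  type <- match.arg(type); unit <- match.arg(unit)
  mat <- as.matrix(mat)
  if (anyNA(mat))
    cm_stop("ICC input must have no missing cells", "cordmotion_data_error")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2)
    cm_stop("ICC needs >= 2 subjects and >= 2 measurements",
            "cordmotion_data_error")
  gm <- mean(mat)
  ssr <- k * sum((rowMeans(mat) - gm)^2)
  ssc <- n * sum((colMeans(mat) - gm)^2)
  sst <- sum((mat - gm)^2)
  sse <- max(0, sst - ssr - ssc)   # guard fp cancellation when fit is exact
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (msc - mse) / n
  if (msr <= mse)
    cm_warn("no between-subject variance beyond error: ICC <= 0",
            "cordmotion_degenerate_warning")
  icc <- if (denom == 0) 0 else (msr - mse) / denom
  f <- if (mse == 0) Inf else msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  structure(list(icc = icc,
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 n_subjects = n, k = k,
                 model = "two-way mixed, absolute agreement, average measures",
                 f_value = f, df1 = df1, df2 = df2),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,%d) = %.3f (n = %d, p = %.4g)\n%s\n",
              x$k, x$icc, x$n_subjects, x$p_value, x$model))
  invisible(x)
}

#' Reliability report: ICC per segment and readout
#'
#' Inter-rater mode pairs the two raters' measurements of the same scan;
#' test-retest mode pairs the two scans measured by the same rater.
#' Subjects missing either member of the pair are dropped with a
#' warning. `use_correction = FALSE` evaluates the raw (uncorrected)
#' readouts — phase drift differs between sessions, so raw test-retest
#' reliability is expected to be inferior, which is the point of
#' exposing it.
#'
#' @param cohort A [cohort_table] (post-exclusion).
#' @param mode `"inter_rater"` or `"test_retest"`.
#' @param use_correction Use drift-corrected (default) or raw readouts.
#' @return data.frame: one row per segment x readout with `icc`,
#'   `p_value`, `n`, `k`.
#' @export
reliability_report <- function(cohort, mode = c("inter_rater", "test_retest"),
                               use_correction = TRUE) {
  mode <- match.arg(mode)
  rd <- cohort$readouts
  unit_col <- if (mode == "inter_rater") "rater_id" else "scan_id"
  fix_col <- if (mode == "inter_rater") "scan_id" else "rater_id"
  units <- unique(rd[[unit_col]])
  if (length(units) != 2)
    cm_stop(sprintf("%s reliability needs exactly 2 %ss (found %d)",
                    mode, sub("_id$", "", unit_col), length(units)),
            "cordmotion_data_error")
  rd <- rd[rd[[fix_col]] == rd[[fix_col]][1], , drop = FALSE]
  segs <- intersect(cervical_segments(), unique(rd$segment))
  out <- list()
  for (sg in segs) {
    for (ro in READOUT_NAMES) {
      col <- if (use_correction) ro else paste0("raw_", ro)
      sub <- rd[rd$segment == sg, c("subject_id", unit_col, col)]
      wide <- stats::reshape(sub, idvar = "subject_id", timevar = unit_col,
                             direction = "wide")
      mat <- as.matrix(wide[, -1])
      ok <- stats::complete.cases(mat)
      if (any(!ok))
        cm_warn(sprintf("%s/%s: %d subject(s) without a complete pair dropped",
                        sg, ro, sum(!ok)), "cordmotion_dropped_warning")
      res <- suppressWarnings(icc_two_way(mat[ok, , drop = FALSE]))
      out[[length(out) + 1]] <- data.frame(
        segment = sg, readout = ro, icc = res$icc, p_value = res$p_value,
        n = res$n_subjects, k = res$k, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Spearman correlation of a readout with a covariate
#'
#' Spearman rank correlation (mid-ranks for ties) between a motion
#' readout and a subject- or segment-level covariate, either per segment
#' (one coefficient per segment, n = subjects) or pooled across all
#' segments (segment-level observations stacked, n ~ subjects x
#' segments; within-subject correlation is ignored by design — the
#' pooled n treats observations as independent). Incomplete pairs are
#' dropped per analysis; a constant covariate yields `NA` with a reason.
#'
#' @param cohort A [cohort_table] (post-exclusion).
#' @param readout Readout name.
#' @param covariate Column name in the subjects table (subject-level,
#'   e.g. `"body_size_cm"`, `"map"`) or the anatomy table
#'   (segment-level, e.g. `"canal_csa_cm2"`).
#' @param scope `"per_segment"` or `"pooled_all_segments"`.
#' @param scan_id,rater_id Restrict to one scan/rater.
#' @return data.frame with `scope`/`segment`, `rho`, `p_value`, `n`,
#'   `note`.
#' @export
spearman_correlations <- function(cohort, readout = READOUT_NAMES, covariate,
                                  scope = c("per_segment",
                                            "pooled_all_segments"),
                                  scan_id = NULL, rater_id = NULL) {
  readout <- match.arg(readout)
  scope <- match.arg(scope)
  d <- readout_by_subject(cohort, readout, scan_id, rater_id)
  names(d)[3] <- "value"
  if (covariate %in% names(cohort$subjects)) {
    d <- merge(d, cohort$subjects[, c("subject_id", covariate)],
               by = "subject_id")
  } else if (!is.null(cohort$anatomy) &&
             covariate %in% names(cohort$anatomy)) {
    d <- merge(d, cohort$anatomy[, c("subject_id", "segment", covariate)],
               by = c("subject_id", "segment"))
  } else {
    cm_stop(paste("unknown covariate:", covariate),
            "cordmotion_structure_error")
  }
  one <- function(x, y, label) {
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 4)
      return(data.frame(segment = label, rho = NA_real_, p_value = NA_real_,
                        n = length(x), note = "fewer than 4 complete pairs",
                        stringsAsFactors = FALSE))
    if (stats::sd(y) == 0 || stats::sd(x) == 0)
      return(data.frame(segment = label, rho = NA_real_, p_value = NA_real_,
                        n = length(x), note = "constant variable",
                        stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    data.frame(segment = label, rho = unname(ct$estimate),
               p_value = ct$p.value, n = length(x), note = "",
               stringsAsFactors = FALSE)
  }
  if (scope == "pooled_all_segments")
    return(one(d$value, d[[covariate]], "all"))
  segs <- intersect(cervical_segments(), unique(d$segment))
  do.call(rbind, c(lapply(segs, function(sg) {
    sub <- d[d$segment == sg, ]
    one(sub$value, sub[[covariate]], sg)
  }), make.row.names = FALSE))
}
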