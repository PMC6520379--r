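# shared fixtures: everything is generated in code, no stored data

# tiny imaging geometry to keep tests fast
tiny_config <- function(seed, roi = default_cord_roi(15.5, 15.5), ...) {
  cohort_config(seed = seed, image_size = c(32, 32), roi = roi, ...)
}

# generate a cohort silently (clamp warnings and progress messages are
# expected generator behaviour, not test failures)
quiet_cohort <- function(config) {
  suppressWarnings(suppressMessages(synthesize_cohort(config)))
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# a phase series with identical cord/static encoding, no noise; 24x24 at
# 0.5 mm spacing comfortably holds the 30.52 mm^2 default ROI
flat_series <- function(value = 0L, T = 20, H = 24, W = 24, ...) {
  phase_series(array(as.integer(value), c(T, H, W)), ...)
}

# independent two-way ANOVA mean squares via lm(), used as the ICC oracle
aov_mean_squares <- function(mat) {
  d <- data.frame(y = as.vector(mat),
                  subject = factor(rep(seq_len(nrow(mat)), ncol(mat))),
                  rater = factor(rep(seq_len(ncol(mat)), each = nrow(mat))))
  an <- stats::anova(stats::lm(y ~ subject + rater, data = d))
  list(msr = an["subject", "Mean Sq"], msc = an["rater", "Mean Sq"],
       mse = an["Residuals", "Mean Sq"])
}

# ICC(A,k) computed from the lm() route only
icc_ak_oracle <- function(mat) {
  ms <- aov_mean_squares(mat)
  (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / nrow(mat))
}

# consistency-type average-measures ICC(C,k), for the bias-penalty check
icc_ck_oracle <- function(mat) {
  ms <- aov_mean_squares(mat)
  (ms$msr - ms$mse) / ms$msr
}
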