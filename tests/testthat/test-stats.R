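# a minimal readouts table for stats tests, built without imaging
fake_readouts <- function(values, segments = "C5", scans = "baseline",
                          raters = "R1") {
  g <- expand.grid(subject_id = names(values), scan_id = scans,
                   rater_id = raters, segment = segments,
                   stringsAsFactors = FALSE)
  g$amplitude <- g$max_cranial <- g$max_caudal <- g$displacement <-
    unlist(values)[g$subject_id]
  for (ro in c("amplitude", "max_cranial", "max_caudal", "displacement"))
    g[[paste0("raw_", ro)]] <- g[[ro]]
  g$drift_estimate <- 0
  g$rr_interval <- 1000
  g
}

fake_subjects <- function(ids, excluded = rep(FALSE, length(ids))) {
  data.frame(subject_id = ids, excluded = excluded,
             exclusion_reason = ifelse(excluded, "incidental stenosis", ""),
             stringsAsFactors = FALSE)
}

test_that("exclusion filter retains exactly the unflagged subjects", {
  ids <- sprintf("S%02d", 1:22)
  vals <- stats::setNames(as.list(seq(0.3, 0.5, length.out = 22)), ids)
  ct <- cohort_table(fake_readouts(vals),
                     fake_subjects(ids, excluded = c(rep(TRUE, 4),
                                                     rep(FALSE, 18))))
  out <- suppressMessages(apply_exclusions(ct))
  expect_equal(nrow(out$subjects), 18)
  expect_equal(length(unique(out$readouts$subject_id)), 18)

  # no flags: identity
  ct0 <- cohort_table(fake_readouts(vals), fake_subjects(ids))
  out0 <- suppressMessages(apply_exclusions(ct0))
  expect_identical(out0$readouts, ct0$readouts)

  # all flagged: empty cohort with a warning
  ct1 <- cohort_table(fake_readouts(vals),
                      fake_subjects(ids, excluded = rep(TRUE, 22)))
  expect_warning(suppressMessages(apply_exclusions(ct1)),
                 class = "cordmotion_empty_warning")

  # flagged subject without a reason is rejected at construction
  bad <- fake_subjects(ids, excluded = c(TRUE, rep(FALSE, 21)))
  bad$exclusion_reason <- ""
  expect_error(cohort_table(fake_readouts(vals), bad),
               class = "cordmotion_structure_error")
})

test_that("cohort table enforces the unique key", {
  ids <- c("S01", "S02")
  rd <- fake_readouts(stats::setNames(list(1, 2), ids))
  expect_error(cohort_table(rbind(rd, rd), fake_subjects(ids)),
               class = "cordmotion_structure_error")
})

test_that("biometric derivations: means and MAP", {
  d <- derive_biometrics(data.frame(sys_before = 129.7, sys_after = 122.7,
                                    dia_before = 80.0, dia_after = 77.0))
  expect_equal(d$mean_systolic, 126.2)
  expect_equal(d$mean_diastolic, 78.5)
  expect_equal(round(d$map, 1), 94.4)

  # equal pressures: MAP collapses to the common value
  e <- derive_biometrics(data.frame(sys_before = 100, sys_after = 100,
                                    dia_before = 100, dia_after = 100))
  expect_equal(e$map, 100)

  # algebraic identity: dia + (sys - dia)/3 == (2 dia + sys)/3
  set.seed(51)
  sys <- stats::runif(20, 100, 160); dia <- stats::runif(20, 60, 95)
  f <- derive_biometrics(data.frame(sys_before = sys, sys_after = sys,
                                    dia_before = dia, dia_after = dia))
  expect_equal(f$map, (2 * dia + sys) / 3)

  # missing propagates
  g <- derive_biometrics(data.frame(sys_before = NA, sys_after = 120,
                                    dia_before = 80, dia_after = 78))
  expect_true(is.na(g$map))
})

test_that("segment summary uses the sample SD", {
  ids <- c("S01", "S02")
  ct <- cohort_table(fake_readouts(stats::setNames(list(0, 1), ids)),
                     fake_subjects(ids))
  s <- segment_summary(ct, "amplitude")
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, sqrt(0.5))
  expect_equal(s$n, 2)

  # constant cohort: sd 0
  ids3 <- sprintf("S%02d", 1:5)
  ct3 <- cohort_table(fake_readouts(stats::setNames(as.list(rep(0.445, 5)),
                                                    ids3)),
                      fake_subjects(ids3))
  s3 <- segment_summary(ct3, "amplitude")
  expect_equal(s3$mean, 0.445)
  expect_equal(s3$sd, 0)
})

test_that("summary and correlations are invariant to subject order", {
  ids <- sprintf("S%02d", 1:8)
  set.seed(52)
  rd <- fake_readouts(stats::setNames(as.list(stats::runif(8, 0.2, 0.6)),
                                      ids),
                      segments = c("C2", "C5"))
  sub <- fake_subjects(ids)
  sub$body_size_cm <- stats::rnorm(8, 172, 9)
  ct_a <- cohort_table(rd, sub)
  perm <- sample(nrow(rd))
  ct_b <- cohort_table(rd[perm, ], sub[sample(8), ])
  expect_equal(segment_summary(ct_a, "amplitude"),
               segment_summary(ct_b, "amplitude"))
  expect_equal(
    spearman_correlations(ct_a, "displacement", "body_size_cm",
                          "pooled_all_segments")$rho,
    spearman_correlations(ct_b, "displacement", "body_size_cm",
                          "pooled_all_segments")$rho)
})

make_block_cohort <- function(mat, segments = colnames(mat)) {
  ids <- sprintf("S%02d", seq_len(nrow(mat)))
  rows <- do.call(rbind, lapply(seq_len(nrow(mat)), function(i)
    data.frame(subject_id = ids[i], scan_id = "baseline", rater_id = "R1",
               segment = segments, amplitude = mat[i, ],
               max_cranial = mat[i, ], max_caudal = mat[i, ],
               displacement = mat[i, ], raw_amplitude = mat[i, ],
               raw_max_cranial = mat[i, ], raw_max_caudal = mat[i, ],
               raw_displacement = mat[i, ], drift_estimate = 0,
               rr_interval = 1000, stringsAsFactors = FALSE)))
  cohort_table(rows, fake_subjects(ids))
}

test_that("Friedman: null case, constructed separation, formula oracle", {
  segs <- cervical_segments()
  # identical across segments: statistic 0 (rank ties everywhere)
  m0 <- matrix(rep(stats::runif(6, 0.2, 0.6), each = 6), nrow = 6,
               byrow = FALSE, dimnames = list(NULL, segs))
  m0[] <- rep(seq(0.2, 0.7, length.out = 6), times = 6)  # constant rows
  f0 <- friedman_intersegment(make_block_cohort(m0), "amplitude")
  expect_equal(f0$statistic, 0, tolerance = 1e-12)
  expect_gte(f0$p_value, 0.99)

  # C5 = C2 + 0.15 for every subject, others intermediate: C2-C5 pairwise
  # significant at alpha 0.05
  set.seed(53)
  base <- stats::runif(6, 0.2, 0.3)
  m1 <- cbind(C2 = base, C3 = base + 0.03, C4 = base + 0.07,
              C5 = base + 0.15, C6 = base + 0.11, C7 = base + 0.05)
  f1 <- friedman_intersegment(make_block_cohort(m1), "amplitude")
  pw <- f1$pairwise
  p_c2c5 <- pw$p_adj[pw$segment_a == "C2" & pw$segment_b == "C5"]
  expect_lt(p_c2c5, 0.05)

  # omnibus statistic equals the rank-sum formula on a 5-subject toy
  set.seed(54)
  m2 <- matrix(stats::rnorm(30), nrow = 5, dimnames = list(NULL, segs))
  f2 <- friedman_intersegment(make_block_cohort(m2), "amplitude")
  ranks <- t(apply(m2, 1, rank))
  n <- 5; k <- 6
  chi <- 12 / (n * k * (k + 1)) * sum(colSums(ranks)^2) - 3 * n * (k + 1)
  expect_equal(f2$statistic, chi, tolerance = 1e-10)

  # adding a per-subject constant leaves the statistic unchanged
  m3 <- m2 + stats::rnorm(5)
  f3 <- friedman_intersegment(make_block_cohort(m3), "amplitude")
  expect_equal(f3$statistic, f2$statistic, tolerance = 1e-10)
})

test_that("Friedman drops incomplete subjects and validates sizes", {
  segs <- c("C2", "C3", "C4")
  m <- matrix(stats::runif(12), nrow = 4, dimnames = list(NULL, segs))
  ct <- make_block_cohort(m)
  ct$readouts <- ct$readouts[-1, ]  # S01 loses C2
  expect_warning(f <- friedman_intersegment(ct, "amplitude"),
                 class = "cordmotion_dropped_warning")
  expect_equal(f$n_subjects, 3)

  ct2 <- make_block_cohort(m[, 1:2, drop = FALSE])
  expect_error(friedman_intersegment(ct2, "amplitude"),
               class = "cordmotion_data_error")
})

test_that("ICC(A,k): perfect agreement, bias penalty, ANOVA oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(icc_two_way(cbind(x, x))$icc, 1)

  # constant inter-rater bias: absolute agreement < consistency
  set.seed(55)
  a <- stats::rnorm(12, sd = 2)
  mat <- cbind(a, a + 3)
  res <- icc_two_way(mat)
  # (anova() warns about the essentially perfect fit of the oracle lm)
  expect_lt(res$icc, suppressWarnings(icc_ck_oracle(mat)))
  expect_equal(res$icc, suppressWarnings(icc_ak_oracle(mat)),
               tolerance = 1e-10)

  # property: matches the independent lm()-based oracle across sizes
  # (pure-noise matrices legitimately trigger the degenerate-ICC warning)
  for (i in 1:30) {
    n <- sample(3:20, 1); k <- sample(2:3, 1)
    m <- matrix(stats::rnorm(n * k), n, k)
    r <- suppressWarnings(icc_two_way(m))
    expect_equal(r$icc, icc_ak_oracle(m), tolerance = 1e-10)
    ms <- aov_mean_squares(m)
    expect_equal(r$p_value,
                 stats::pf(ms$msr / ms$mse, n - 1, (n - 1) * (k - 1),
                           lower.tail = FALSE),
                 tolerance = 1e-10)
  }

  # zero between-subject variance: warning, not an exception
  flat <- cbind(rep(1, 3), rep(1.2, 3))   # rater bias only, no subject spread
  expect_warning(r0 <- icc_two_way(flat),
                 class = "cordmotion_degenerate_warning")
  expect_lte(r0$icc, 0)

  expect_error(icc_two_way(matrix(c(1, NA, 2, 3), 2)),
               class = "cordmotion_data_error")
  expect_error(icc_two_way(matrix(1:2, ncol = 1)),
               class = "cordmotion_data_error")
})

test_that("reliability report: duplicate scans, pairs, correction flag", {
  cfg <- tiny_config(56, n_subjects = 5, segments = "C5",
                     scans = c("baseline", "retest"))
  co <- quiet_cohort(cfg)
  rd <- quantify_cohort(co)
  ct <- cohort_table(rd, co$subjects)

  # duplicate-scan cohort: all ICCs 1
  dup <- rd[rd$scan_id == "baseline", ]
  dup2 <- dup; dup2$scan_id <- "retest"
  ctd <- cohort_table(rbind(dup, dup2), co$subjects)
  rel <- reliability_report(ctd, "test_retest")
  expect_true(all(abs(rel$icc - 1) < 1e-12))

  # amplitude ICC identical with or without drift correction
  rel_c <- reliability_report(ct, "test_retest", use_correction = TRUE)
  rel_r <- reliability_report(ct, "test_retest", use_correction = FALSE)
  expect_equal(rel_c$icc[rel_c$readout == "amplitude"],
               rel_r$icc[rel_r$readout == "amplitude"], tolerance = 1e-10)

  # missing pair: subject dropped with warning (one per segment x readout)
  ct_miss <- cohort_table(rd[-1, ], co$subjects)
  ws <- testthat::capture_warnings(
    rel_m <- reliability_report(ct_miss, "test_retest"))
  expect_true(any(grepl("without a complete pair", ws)))
  expect_true(all(rel_m$n == 4))

  # wrong design: only one scan
  ct1 <- cohort_table(rd[rd$scan_id == "baseline", ], co$subjects)
  expect_error(reliability_report(ct1, "test_retest"),
               class = "cordmotion_data_error")
})

test_that("Spearman: exact cases, hand oracle, degenerate inputs", {
  ids <- sprintf("S%02d", 1:6)
  vals <- c(0.31, 0.45, 0.28, 0.52, 0.40, 0.36)
  rd <- fake_readouts(stats::setNames(as.list(vals), ids))
  sub <- fake_subjects(ids)
  sub$cov_same <- vals
  sub$cov_neg <- -vals
  sub$cov_free <- c(170, 181, 166, 159, 175, 178)
  sub$cov_const <- 5
  ct <- cohort_table(rd, sub)

  expect_equal(spearman_correlations(ct, "amplitude", "cov_same",
                                     "per_segment")$rho, 1)
  expect_equal(spearman_correlations(ct, "amplitude", "cov_neg",
                                     "per_segment")$rho, -1)

  # 6-pair toy: rho from rank arithmetic (no ties -> 1 - 6*sum(d^2)/(n^3-n))
  r <- spearman_correlations(ct, "amplitude", "cov_free", "per_segment")
  d2 <- sum((rank(vals) - rank(sub$cov_free))^2)
  expect_equal(r$rho, 1 - 6 * d2 / (6^3 - 6), tolerance = 1e-12)

  cst <- spearman_correlations(ct, "amplitude", "cov_const", "per_segment")
  expect_true(is.na(cst$rho))
  expect_match(cst$note, "constant")

  expect_error(spearman_correlations(ct, "amplitude", "no_such_cov"),
               class = "cordmotion_structure_error")
})

test_that("pooled Spearman stacks segments and is near zero under the null", {
  ids <- sprintf("S%02d", 1:10)
  set.seed(57)
  rd <- fake_readouts(stats::setNames(as.list(stats::runif(10)), ids),
                      segments = cervical_segments())
  # give each (subject, segment) cell its own value
  rd$displacement <- stats::rnorm(nrow(rd))
  sub <- fake_subjects(ids)
  ps <- numeric(200)
  for (i in 1:200) {
    rd$displacement <- stats::rnorm(nrow(rd))   # fresh null draw both sides
    sub$noise_cov <- stats::rnorm(10)
    ct <- cohort_table(rd, sub)
    ps[i] <- spearman_correlations(ct, "displacement", "noise_cov",
                                   "pooled_all_segments")$p_value
  }
  expect_gt(min(ps), 0)          # well-defined
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.075)  # roughly uniform null rate
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.15)
  ct <- cohort_table(rd, sub)
  pooled <- spearman_correlations(ct, "displacement", "noise_cov",
                                  "pooled_all_segments")
  expect_equal(pooled$n, 60)     # subjects x segments observations
})
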