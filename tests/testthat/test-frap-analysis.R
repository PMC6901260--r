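test_that("double normalization matches the worked example and its contracts", {
  # 4-frame trace, 2 pre-bleach: quotient (0.5,0.5,0.1,0.3), pre mean 0.5
  tr <- raw_frap_trace(times = 0:3, roi = c(10, 10, 2, 6), whole = rep(20, 4),
                       background = rep(0, 4), n_prebleach = 2)
  cv <- normalize_frap(tr)
  expect_equal(cv$mean, c(1, 1, 0.2, 0.6))
  expect_equal(cv$time_s, c(-2, -1, 0, 1))

  # constant roi == whole: everything normalizes to 1
  tr1 <- raw_frap_trace(0:5, rep(7, 6), rep(7, 6), rep(0, 6), 2)
  expect_equal(normalize_frap(tr1)$mean, rep(1, 6))

  # pure acquisition bleaching decays roi and whole equally: fully corrected
  decay <- 0.97^(0:9)
  tr2 <- raw_frap_trace(0:9, 100 * decay, 400 * decay, rep(0, 10), 3)
  expect_equal(normalize_frap(tr2)$mean, rep(1, 10))

  # pre-bleach mean is exactly 1 on arbitrary valid input
  tr3 <- raw_frap_trace(0:9, 30 + sin(1:10), 100 + cos(1:10), rep(5, 10), 4)
  expect_equal(mean(normalize_frap(tr3)$mean[1:4]), 1, tolerance = 1e-12)
})

test_that("normalize_frap rejects corrupt traces with frame-level messages", {
  expect_error(normalize_frap(raw_frap_trace(0:3, c(5, 5, 1, 2), c(10, 10, 2, 10),
                                             c(1, 1, 2, 1), 2)),
               "frame\\(s\\) 3")
  expect_error(raw_frap_trace(0:3, 1:4, 1:4, rep(0, 4), 4), "n_prebleach")
  expect_warning(raw_frap_trace(0:3, c(1, 5, 5, 5), c(9, 9, 9, 9), rep(2, 4), 2),
                 "background exceeds")
})

test_that("exponential fits recover noiseless generating parameters exactly", {
  cv1 <- biexp_curve(0.1, 0.8, 0.05)
  f1 <- fit_recovery(cv1, 1)
  expect_equal(f1$y0, 0.1, tolerance = 1e-6)
  expect_equal(f1$amplitudes, 0.8, tolerance = 1e-6)
  expect_equal(f1$rates, 0.05, tolerance = 1e-6)
  expect_lt(f1$sse, 1e-12)

  cv2 <- biexp_curve(0.05, c(0.45, 0.35), c(0.5, 0.02))
  f2 <- fit_recovery(cv2, 2)
  expect_lt(f2$sse, 1e-12)
  expect_equal(f2$rates, c(0.5, 0.02), tolerance = 1e-5)
  expect_equal(f2$amplitudes, c(0.45, 0.35), tolerance = 1e-5)
  expect_equal(f2$fractions, c(0.45, 0.35) / 0.8, tolerance = 1e-5)
  expect_equal(f2$immobile_fraction, 1 - 0.85, tolerance = 1e-5)
})

test_that("a flat post-bleach curve fits as pure immobile fraction", {
  ft <- schedule_frame_times(frap_schedule("mrna-frap"))
  flat <- recovery_curve(ft, c(rep(1, 6), rep(0.4, sum(ft >= 0))))
  f <- select_model(flat)
  expect_identical(f$n_components, 1)
  expect_equal(sum(abs(f$amplitudes)), 0, tolerance = 1e-6)
  expect_equal(f$immobile_fraction, 0.6, tolerance = 1e-6)
})

test_that("model selection identifies the generating component count", {
  # 100 seeded noisy curves, half mono-, half bi-exponential
  n_each <- 50
  correct <- 0
  for (i in seq_len(n_each)) {
    c1 <- biexp_curve(0.1, 0.8, 0.05, noise_sd = 0.02, seed = i)
    if (select_model(c1)$n_components == 1) correct <- correct + 1
    c2 <- biexp_curve(0.05, c(0.45, 0.35), c(0.5, 0.02), noise_sd = 0.02,
                      seed = 1000 + i)
    if (select_model(c2)$n_components == 2) correct <- correct + 1
  }
  expect_gte(correct / (2 * n_each), 0.9)
})

test_that("fit_recovery demands enough post-bleach frames and flags plateaus above 1", {
  short <- recovery_curve(seq(-1, 8), c(1, seq(0.2, 1, length.out = 9)))
  expect_error(fit_recovery(short, 2), "post-bleach frames")
  high <- biexp_curve(0.2, 1.1, 0.05)
  expect_warning(fit_recovery(high, 1), "plateau")
})

test_that("identical replicate sets compare as indistinguishable", {
  reps <- lapply(1:4, function(i) {
    biexp_curve(0.1, 0.8, 0.05, noise_sd = 0.02, seed = i,
                schedule = coarse_schedule())
  })
  cc <- compare_curves(reps, reps, n_permutations = 199, seed = 7)
  expect_equal(cc$statistic, 0)
  expect_equal(cc$p_value, 1)
  expect_error(compare_curves(reps[1:2], reps, 99, 1), "at least 3 replicates")
})

test_that("permutation comparison is seeded and separates distinct kinetics", {
  fast <- lapply(1:6, function(i) biexp_curve(0.1, 0.8, 0.1, noise_sd = 0.03,
                                              seed = i, schedule = coarse_schedule()))
  slow <- lapply(1:6, function(i) biexp_curve(0.1, 0.8, 0.01, noise_sd = 0.03,
                                              seed = 100 + i, schedule = coarse_schedule()))
  a <- compare_curves(fast, slow, n_permutations = 499, seed = 3)
  b <- compare_curves(fast, slow, n_permutations = 499, seed = 3)
  expect_identical(a, b)
  expect_lte(a$p_value, 0.05)
  expect_gt(a$statistic, 0.1)
})

test_that("curve comparison has near-nominal type-I error under the null", {
  # both conditions drawn from the same generator; 60 datasets here keep the
  # unit test quick, the acceptance suite runs the full calibration
  rej <- 0
  n_data <- 60
  for (d in seq_len(n_data)) {
    reps <- lapply(1:10, function(i) {
      biexp_curve(0.1, 0.7, 0.05, noise_sd = 0.05, seed = d * 100 + i,
                  schedule = coarse_schedule())
    })
    cc <- compare_curves(reps[1:5], reps[6:10], n_permutations = 199, seed = d)
    if (cc$p_value <= 0.05) rej <- rej + 1
  }
  expect_lte(rej / n_data, 0.12)
})

test_that("BH adjustment matches hand-computed values and its invariants", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  # p * m / rank with step-up monotonicity, by hand
  p <- c(0.001, 0.01, 0.04, 0.8)
  expect_equal(fdr_adjust(p), c(0.004, 0.02, 4 * 0.04 / 3, 0.8))
  expect_error(fdr_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
  # adjusted values never fall below the raw ones
  q <- c(0.03, 0.2, 0.011, 0.9, 0.05)
  expect_true(all(fdr_adjust(q) >= q))
})

test_that("curves round-trip through CSV and readers reject malformed files", {
  cv <- biexp_curve(0.1, 0.8, 0.05, schedule = coarse_schedule())
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cv, path)
  cv2 <- read_curve_csv(path)
  expect_s3_class(cv2, "recovery_curve")
  expect_equal(cv2$time_s, cv$time_s)
  expect_equal(cv2$mean, cv$mean)

  tr <- raw_frap_trace(0:5, 6:11, rep(20, 6), rep(1, 6), 2)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(tr, path2)
  tr2 <- read_curve_csv(path2)
  expect_s3_class(tr2, "raw_frap_trace")
  expect_equal(tr2$roi, tr$roi)
  expect_identical(tr2$n_prebleach, 2L)

  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(t = 1:3, mean = 1:3), bad, row.names = FALSE)
  expect_error(read_curve_csv(bad), "time_s")
  dup <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = c(0, 1, 1), mean = 1:3), dup, row.names = FALSE)
  expect_error(read_curve_csv(dup), "duplicated")
})
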