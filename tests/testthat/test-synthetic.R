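test_that("noiseless synthetic traces invert exactly under double normalization", {
  truth <- list(y0 = 0.1, amplitudes = c(0.5, 0.3), rates = c(0.3, 0.02))
  spec <- synth_frap_spec("biexp", truth, noise_sd = 0, acq_bleach_rate = 0,
                          n_cells = 3, day_sd = 0, seed = 2)
  ds <- gen_frap_dataset(spec)
  ft <- schedule_frame_times(spec$schedule)
  expected <- biexp_curve(truth$y0, truth$amplitudes, truth$rates)
  for (tr in ds$traces) {
    cv <- normalize_frap(tr)
    expect_lt(max(abs(cv$mean - expected$mean)), 1e-9)
  }
  # acquisition bleaching alone is fully corrected by the normalization
  spec_b <- synth_frap_spec("biexp", truth, noise_sd = 0, acq_bleach_rate = 0.01,
                            n_cells = 2, day_sd = 0, seed = 2)
  for (tr in gen_frap_dataset(spec_b)$traces) {
    expect_lt(max(abs(normalize_frap(tr)$mean - expected$mean)), 1e-9)
  }
})

test_that("generators are seed-deterministic and emit their ground truth", {
  truth <- list(y0 = 0.05, amplitudes = c(0.45, 0.35), rates = c(0.5, 0.02))
  spec <- synth_frap_spec("biexp", truth, n_cells = 6, n_days = 3, seed = 9)
  a <- gen_frap_dataset(spec)
  b <- gen_frap_dataset(spec)
  expect_identical(a, b)
  expect_identical(nrow(a$truth), 6L)
  expect_setequal(unique(a$truth$day), 1:3)
  # day effect multiplies the amplitudes in the recorded truth
  expect_equal(a$truth$A1, 0.45 * a$truth$day_multiplier)

  fspec <- synth_fish_spec("E3", kinetic_params(), n_sites = 30, seed = 4)
  expect_identical(gen_fish_table(fspec), gen_fish_table(fspec))
})

test_that("generated noise magnitude matches the requested sd", {
  truth <- list(y0 = 0.1, amplitudes = 0.8, rates = 0.05)
  spec <- synth_frap_spec("biexp", truth, noise_sd = 0.05, acq_bleach_rate = 0,
                          n_cells = 8, day_sd = 0, seed = 31)
  ds <- gen_frap_dataset(spec)
  expected <- biexp_curve(truth$y0, truth$amplitudes, truth$rates)
  resid <- unlist(lapply(ds$traces, function(tr) normalize_frap(tr)$mean - expected$mean))
  expect_gt(length(resid), 1000)
  expect_equal(sd(resid), 0.05, tolerance = 0.1)
})

test_that("the full synthetic pipeline recovers bi-exponential truth", {
  truth <- list(y0 = 0.05, amplitudes = c(0.45, 0.35), rates = c(0.5, 0.02))
  spec <- synth_frap_spec("biexp", truth, noise_sd = 0.02, acq_bleach_rate = 0.005,
                          n_cells = 10, n_days = 3, day_sd = 0.02, seed = 11)
  ds <- gen_frap_dataset(spec)
  curves <- lapply(ds$traces, normalize_frap)
  mean_curve <- recovery_curve(curves[[1]]$time_s,
                               rowMeans(vapply(curves, `[[`, numeric(nrow(curves[[1]])), "mean")))
  f <- select_model(mean_curve)
  expect_identical(f$n_components, 2)
  expect_equal(f$rates, truth$rates, tolerance = 0.1)
  expect_equal(f$amplitudes, truth$amplitudes, tolerance = 0.1)
  expect_equal(f$y0, truth$y0, tolerance = 0.1)
})

test_that("fish tables carry noiseless truth and preserve the median ratio", {
  g <- toy_gene(n_copies = 10L)
  p <- no_pause_params(elong_rate = 40, retention_mean = 20, splice_depletion_bp = 800)
  spec0 <- synth_fish_spec(g, p, n_sites = 40, lognormal_noise_sd = 0, seed = 6)
  tab0 <- gen_fish_table(spec0)
  expect_equal(tab0$intron_channel, tab0$intron_true)
  expect_equal(tab0$exon_channel, tab0$exon_true)

  spec <- synth_fish_spec(g, p, n_sites = 400, lognormal_noise_sd = 0.2, seed = 6)
  tab <- gen_fish_table(spec)
  expect_false(isTRUE(all.equal(tab$intron_channel, tab$intron_true)))
  # lognormal noise has median multiplier 1: median ratio tracks the oracle
  expect_equal(median(tab$ratio), expected_fish_ratio(g, p), tolerance = 0.1)
})

test_that("simulator-backed synthetic traces mirror the simulated kinetics", {
  g <- build_gene("E3", overrides = list(n_copies = 10L))
  p <- kinetic_params()
  spec <- synth_frap_spec("simulator", list(gene = g, params = p),
                          schedule = coarse_schedule(), noise_sd = 0.01,
                          n_cells = 3, sites_per_cell = 5, seed = 21)
  ds <- gen_frap_dataset(spec)
  expect_length(ds$traces, 3)
  expect_true(all(c("retention_mean", "sim_seed") %in% names(ds$truth)))
  cv <- normalize_frap(ds$traces[[1]])
  # post-bleach signal recovers from near zero toward the pre-bleach level
  post <- cv$mean[cv$time_s >= 0]
  expect_lt(post[1], 0.3)
  expect_gt(mean(tail(post, 5)), 0.5)
})
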