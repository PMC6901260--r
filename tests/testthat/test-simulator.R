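test_that("no initiation leaves the site empty forever", {
  g <- toy_gene()
  p <- no_pause_params(init_rate = 0)
  st <- new_site_state(g, 1)
  st <- advance_site(st, g, p, 200)
  expect_identical(nrow(st$pols), 0L)
  expect_identical(nrow(st$retained), 0L)
  expect_equal(unname(site_signals(st, g, p)), rep(0, 5))
})

test_that("a lone polymerase advances deterministically without pausing", {
  g <- toy_gene()
  p <- no_pause_params(init_rate = 0)
  st <- new_site_state(g, 1)
  st$pols <- rbind(c(copy = 1, position = 500, paused = 0, at_end = 0, bleached = 0))
  colnames(st$pols) <- c("copy", "position", "paused", "at_end", "bleached")
  st1 <- step_site(st, g, p)
  expect_equal(unname(st1$pols[1, "position"]), 500 + p$elong_rate * p$dt)
  expect_equal(st1$clock, p$dt)
  # many steps: position is clock * v until the gene end
  st2 <- advance_site(st, g, p, 10)
  expect_equal(unname(st2$pols[1, "position"]), 500 + p$elong_rate * 10)
})

test_that("intron signal lives for splice_depletion_bp / elong_rate seconds", {
  # oracle: hand-computed boundary-crossing times of a single polymerase
  g <- toy_gene()
  p <- no_pause_params(init_rate = 0, splice_depletion_bp = 400)
  st <- new_site_state(g, 1)
  st$pols <- matrix(c(1, 0, 0, 0, 0), 1, 5,
                    dimnames = list(NULL, c("copy", "position", "paused", "at_end", "bleached")))
  res <- simulate_trajectory(st, g, p, duration = 2000 / p$elong_rate, record_dt = p$dt)
  tr <- res$trajectory
  v <- p$elong_rate
  for (i in 1:2) {
    onset <- g$introns[i, 2] / v            # crossing of the intron 3' end
    offset <- (g$introns[i, 2] + 400) / v   # depletion point
    on <- tr$time_s >= onset + p$dt & tr$time_s <= offset - p$dt
    off <- tr$time_s < onset - p$dt | tr$time_s > offset + p$dt
    other <- sum(g$introns[-i, 2] / v <= tr$time_s &
                   tr$time_s < (g$introns[-i, 2] + 400) / v)
    expect_true(all(tr$intron_signal[on] >= 1))
    # intron i contributes nothing outside [onset, offset)
    expect_true(all(tr$intron_signal[tr$time_s > offset + p$dt] <= 1))
  }
  # total lifetime of each intron's signal: depletion_bp / v seconds
  one_intron <- tr$intron_signal
  lifetime_steps <- sum(one_intron) * p$dt  # integral of the 0/1/2 signal
  expect_equal(lifetime_steps, 2 * 400 / v, tolerance = 2 * p$dt / (400 / v))
})

test_that("same seed gives bit-identical states and curves", {
  g <- build_gene("E6", overrides = list(n_copies = 5L))
  p <- kinetic_params()
  a <- advance_site(new_site_state(g, 33), g, p, 300)
  b <- advance_site(new_site_state(g, 33), g, p, 300)
  expect_identical(a, b)
  ca <- simulate_frap(g, p, coarse_schedule(), n_sites = 4, seed = 5)
  cb <- simulate_frap(g, p, coarse_schedule(), n_sites = 4, seed = 5)
  expect_identical(ca, cb)
  expect_false(identical(
    simulate_frap(g, p, coarse_schedule(), n_sites = 4, seed = 6)$mean, ca$mean))
})

test_that("transcript conservation: counts change only by initiation and release", {
  g <- toy_gene(n_copies = 3L)
  p <- kinetic_params(retention_mean = 30)
  st <- new_site_state(g, 8)
  prev <- 0
  for (i in 1:300) {
    st <- step_site(st, g, p)
    n <- nrow(st$pols) + nrow(st$retained)
    # at most one initiation per copy per step; releases only shrink
    expect_lte(n - prev, g$n_copies)
    prev <- n
  }
  expect_gt(prev, 0)  # something was transcribed in 300 steps
})

test_that("polymerases never overlap closer than the footprint", {
  g <- toy_gene(n_copies = 2L)
  p <- kinetic_params(init_rate = 0.5, elong_rate = 20, dt = 0.1,
                      pause_on_rate = 0.05, pause_off_rate = 0.1)
  st <- new_site_state(g, 13)
  for (i in 1:500) {
    st <- step_site(st, g, p)
    for (cp in unique(st$pols[, "copy"])) {
      pos <- sort(st$pols[st$pols[, "copy"] == cp, "position"])
      if (length(pos) > 1) expect_true(all(diff(pos) >= g$footprint_bp - 1e-9))
    }
  }
})

test_that("run_to_steady_state converges, is seeded, and reports non-convergence", {
  g <- oracle_gene()
  p <- no_pause_params(init_rate = 0.1, elong_rate = 50)
  a <- run_to_steady_state(g, p, seed = 4)
  b <- run_to_steady_state(g, p, seed = 4)
  expect_identical(unclass(a), unclass(b))
  wm <- attr(a, "window_means")
  expect_length(wm, 2)
  expect_lt(abs(diff(wm)), 0.05 * max(wm))

  # empty system converges immediately (both windows are exactly zero)
  empty <- run_to_steady_state(g, no_pause_params(init_rate = 0), seed = 1)
  expect_identical(nrow(empty$pols), 0L)

  # an unattainable tolerance exhausts the window budget with a clear error
  expect_error(run_to_steady_state(g, p, seed = 1, rel_tol = 1e-12, max_windows = 2),
               "window means")
})

test_that("bleaching zeroes the unbleached signal, is idempotent, and recovers", {
  g <- build_gene("E6", overrides = list(n_copies = 5L))
  p <- kinetic_params()
  st <- run_to_steady_state(g, p, seed = 21)
  sig <- site_signals(st, g, p)
  expect_gt(sig["total_ms2"], 0)
  bl <- apply_bleach(st, g)
  sigb <- site_signals(bl, g, p)
  expect_equal(unname(sigb["total_ms2"]), 0)
  expect_equal(unname(sigb["total_bleached"]),
               unname(sig["total_ms2"] + sig["total_bleached"]))
  expect_identical(apply_bleach(bl, g), bl)
  # conservation of the other channels
  expect_equal(sigb[c("intron_signal", "exon_signal", "n_transcripts")],
               sig[c("intron_signal", "exon_signal", "n_transcripts")])
  # empty state is untouched
  e <- new_site_state(g, 1)
  expect_identical(apply_bleach(e, g), e)
})

test_that("post-bleach recovery is zero without initiation and non-decreasing on average", {
  g <- oracle_gene(n_copies = 2L)
  p0 <- no_pause_params(init_rate = 0, elong_rate = 50)
  expect_error(simulate_frap(g, p0, coarse_schedule(), n_sites = 3, seed = 1),
               "no site had pre-bleach signal")
  p <- no_pause_params(init_rate = 0.1, elong_rate = 50)
  cv <- simulate_frap(g, p, coarse_schedule(), n_sites = 200, seed = 17)
  post <- cv$mean[cv$time_s >= 0]
  # monotone in expectation: allow small Monte-Carlo wiggles
  expect_true(all(diff(post) > -3 * cv$sem[cv$time_s >= 0][-1] - 1e-9))
  expect_equal(post[1], 0, tolerance = 1e-12)
  # pre-bleach level is 1 by construction of the per-site normalization
  expect_equal(mean(cv$mean[cv$time_s < 0]), 1, tolerance = 1e-9)
})

test_that("mean transcript occupancy matches the Little's-law closed form", {
  g <- oracle_gene()
  p <- no_pause_params(init_rate = 0.1, elong_rate = 50)  # L/v = 80 s, retention 50 s
  st <- run_to_steady_state(g, p, seed = 42)
  res <- simulate_trajectory(st, g, p, duration = 50 * 135, record_dt = 1)
  counts <- res$trajectory$n_transcripts
  batches <- split(counts, cut(seq_along(counts), 10))
  bm <- vapply(batches, mean, numeric(1))
  se <- sd(bm) / sqrt(length(bm))
  expect_equal(expected_site_occupancy(g, p), 13)
  expect_lt(abs(mean(counts) - 13), 3 * se + 0.6)
})
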