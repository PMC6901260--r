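# Shared fixtures: small geometries and parameter sets used across tests.

# deterministic "conveyor-belt" regime: no pausing, fast termination so the
# post-termination wait is negligible against retention and transit times
no_pause_params <- function(...) {
  kinetic_params(pause_on_rate = 0, termination_rate = 2, dt = 0.05, ...)
}

# single-copy gene with length/elong_rate = 80 s and an MS2 region whose
# start is 1000 bp from the gene end (used by the closed-form FRAP oracles)
oracle_gene <- function(n_copies = 1L) {
  build_gene("E3", overrides = list(
    length_bp = 4000,
    exons = rbind(c(0, 200), c(500, 700), c(1000, 1300)),
    introns = rbind(c(200, 500), c(700, 1000)),
    ms2_region = c(3000, 3800),
    n_copies = n_copies
  ))
}

# two-intron toy geometry with round numbers for hand computations
toy_gene <- function(...) {
  build_gene("E3", overrides = list(
    length_bp = 2000,
    exons = rbind(c(0, 100), c(300, 400), c(600, 1000)),
    introns = rbind(c(100, 300), c(400, 600)),
    ms2_region = c(1200, 1800),
    exon_probe = c(0, 100),
    n_copies = 1L,
    ...
  ))
}

# coarse short schedule for cheap FRAP simulations
coarse_schedule <- function(duration = 90, interval = 2, n_prebleach = 3) {
  acquisition_schedule(n_prebleach, rbind(c(duration, interval)))
}

# mono/bi-exponential recovery curve on a schedule's frame grid
biexp_curve <- function(y0, A, k, noise_sd = 0, seed = NULL,
                        schedule = frap_schedule("mrna-frap")) {
  ft <- schedule_frame_times(schedule)
  post <- ft >= 0
  m <- rep(1, length(ft))
  val <- rep(y0, sum(post))
  for (j in seq_along(A)) val <- val + A[j] * (1 - exp(-k[j] * ft[post]))
  if (noise_sd > 0) {
    stopifnot(!is.null(seed))
    val <- val + withr::with_seed(seed, rnorm(length(val), sd = noise_sd))
  }
  m[post] <- val
  recovery_curve(ft, m, schedule = schedule)
}
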