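#' Create an empty transcription-site state
#'
#' A `site_state` is the full Monte-Carlo state of one transcription site
#' (a tandem array of `gene$n_copies` gene copies): the clock, every engaged
#' polymerase, every completed-but-retained transcript, and the RNG state.
#' All randomness is drawn from a self-contained 64-bit stream stored in the
#' state, so every operation is bit-reproducible from the seed.
#'
#' @param gene a [build_gene()] model.
#' @param seed integer seed.
#' @return A `site_state` with no polymerases and no retained transcripts.
#' @export
new_site_state <- function(gene, seed = 1) {
  structure(list(
    clock = 0,
    pols = matrix(numeric(), 0, 5,
                  dimnames = list(NULL, c("copy", "position", "paused", "at_end", "bleached"))),
    retained = matrix(numeric(), 0, 2,
                      dimnames = list(NULL, c("release_deadline", "bleached"))),
    rng_state = rng_state_from_seed_cpp(as.numeric(seed))
  ), class = "site_state")
}

#' @export
print.site_state <- function(x, ...) {
  cat(sprintf("<site_state>  t = %.2f s, %d polymerase(s), %d retained transcript(s)\n",
              x$clock, nrow(x$pols), nrow(x$retained)))
  invisible(x)
}

check_sim_inputs <- function(state, gene, params) {
  stopifnot(inherits(state, "site_state"))
  v <- validate_gene(gene)
  if (length(v)) stop("invalid gene model: ", paste(v, collapse = "; "))
  v <- validate_params(params)
  if (length(v)) stop("invalid kinetic parameters: ", paste(v, collapse = "; "))
}

#' Advance a site by one step or a fixed duration
#'
#' One step of duration `params$dt`: per gene copy, a polymerase initiates
#' with probability `init_rate * dt` if the promoter-proximal footprint is
#' clear; elongating polymerases enter the paused state with probability
#' `pause_on_rate * dt` and paused ones exit with `pause_off_rate * dt`;
#' non-paused polymerases advance `elong_rate * dt` bp, clamped so they never
#' come within `footprint_bp` of the polymerase ahead and stop at the gene
#' end. A polymerase at the gene end converts to a retained transcript with
#' probability `termination_rate * dt`; retained transcripts leave the site
#' once their release deadline (creation time + retention draw) passes.
#'
#' @param state a [new_site_state()].
#' @param gene a [build_gene()] model.
#' @param params a [kinetic_params()] object.
#' @param duration seconds to advance (rounded to whole steps).
#' @return The advanced `site_state`.
#' @export
step_site <- function(state, gene, params) {
  check_sim_inputs(state, gene, params)
  res <- sim_advance_cpp(gene, params, state, 1L, 0L)
  structure(res$state, class = "site_state")
}

#' @rdname step_site
#' @export
advance_site <- function(state, gene, params, duration) {
  check_sim_inputs(state, gene, params)
  n <- as.integer(round(duration / params$dt))
  if (n < 1) return(state)
  res <- sim_advance_cpp(gene, params, state, n, 0L)
  structure(res$state, class = "site_state")
}

#' Channel totals of a site state
#'
#' @inheritParams step_site
#' @return Named numeric vector: `total_ms2` (unbleached MS2 signal, in
#'   units of fully tagged transcripts), `total_bleached`, `intron_signal`
#'   (probe-intron count over all transcripts), `exon_signal` (transcripts
#'   past the exon-probe target) and `n_transcripts`.
#' @export
site_signals <- function(state, gene, params) {
  check_sim_inputs(state, gene, params)
  sim_record_cpp(gene, params, state)
}

#' Record a trajectory of channel signals
#'
#' Advances the state while recording the site's channel totals every
#' `record_dt` seconds.
#'
#' @inheritParams step_site
#' @param duration seconds to simulate.
#' @param record_dt seconds between recorded points (snapped to the step grid).
#' @return A list with the advanced `state` and `trajectory`, a data.frame
#'   with columns `time_s`, `total_ms2`, `total_bleached`, `intron_signal`,
#'   `exon_signal`, `n_transcripts`.
#' @export
simulate_trajectory <- function(state, gene, params, duration, record_dt = params$dt) {
  check_sim_inputs(state, gene, params)
  every <- max(1L, as.integer(round(record_dt / params$dt)))
  n <- as.integer(round(duration / params$dt))
  res <- sim_advance_cpp(gene, params, state, n, every)
  list(state = structure(res$state, class = "site_state"),
       trajectory = as.data.frame(res$record))
}

# expected transcript dwell time at the site: elongation (inflated by the
# expected pausing overhead), mean termination wait, then retention
expected_dwell <- function(gene, params) {
  transit <- gene$length_bp / params$elong_rate
  if (params$pause_off_rate > 0) {
    transit <- transit * (1 + params$pause_on_rate / params$pause_off_rate)
  }
  wait <- if (params$termination_rate > 0) 1 / params$termination_rate else 0
  transit + wait + params$retention_mean
}

#' Run a site to steady state
#'
#' Advances a fresh site until the windowed mean of the total MS2 signal
#' stabilizes: two consecutive windows, each `window_dwell` expected
#' transcript dwell times long, must agree to a relative tolerance
#' (default 5%). Deterministic given the seed.
#'
#' @inheritParams step_site
#' @param seed integer seed.
#' @param rel_tol relative tolerance between consecutive window means.
#' @param window_dwell window length in units of the expected dwell time
#'   (elongation + termination wait + retention); minimum 5.
#' @param max_windows step budget: error if the means have not stabilized
#'   after this many windows.
#' @return The converged `site_state`, with the two final window means in
#'   attribute `"window_means"`.
#' @export
run_to_steady_state <- function(gene, params, seed = 1, rel_tol = 0.05,
                                window_dwell = 5, max_windows = 40) {
  state <- new_site_state(gene, seed)
  check_sim_inputs(state, gene, params)
  stopifnot(rel_tol > 0, max_windows >= 2)
  window_dwell <- max(window_dwell, 5)
  window_s <- window_dwell * expected_dwell(gene, params)
  n_steps <- max(2L, as.integer(round(window_s / params$dt)))
  every <- max(1L, n_steps %/% 200L)
  prev <- NULL
  for (w in seq_len(max_windows)) {
    res <- sim_advance_cpp(gene, params, state, n_steps, every)
    state <- structure(res$state, class = "site_state")
    cur <- mean(res$record[, "total_ms2"])
    if (!is.null(prev)) {
      if ((prev < 1e-12 && cur < 1e-12) ||
          abs(cur - prev) < rel_tol * max(prev, cur)) {
        attr(state, "window_means") <- c(prev, cur)
        return(state)
      }
    }
    prev <- cur
  }
  stop(sprintf(paste0("site did not reach steady state within %d windows of %.0f s ",
                      "(last window means %.4g and %.4g, relative tolerance %g)"),
               max_windows, window_s, prev, cur, rel_tol))
}

#' Photobleach a site
#'
#' Instantaneous, total bleach of the transcription-site spot: for every
#' transcript (nascent and retained) the bleached fraction is set to its
#' current MS2 signal, so the unbleached total is exactly 0 immediately
#' after. The free MS2 coat-protein pool is assumed unbleached and in
#' excess, so subsequently synthesized stem-loops are fluorescent.
#' Idempotent.
#'
#' @inheritParams step_site
#' @return The bleached `site_state`.
#' @export
apply_bleach <- function(state, gene) {
  stopifnot(inherits(state, "site_state"))
  if (nrow(state$pols)) {
    f <- (state$pols[, "position"] - gene$ms2_region[1]) / diff(gene$ms2_region)
    state$pols[, "bleached"] <- pmin(pmax(f, 0), 1)
  }
  if (nrow(state$retained)) state$retained[, "bleached"] <- 1
  state
}

#' Simulate a FRAP experiment on transcription sites
#'
#' Runs `n_sites` independent sites to stationarity, bleaches each at t = 0,
#' and samples the unbleached MS2 signal at the schedule's frame times. Each
#' site's intensity is normalized by its own pre-bleach mean; the returned
#' curve is the across-site mean with its standard error. For fixed
#' retention the occupancy process is exactly stationary once the simulated
#' time exceeds one transcript dwell time, so each site is burned in for
#' `burnin_dwell` expected dwell times before the bleach.
#'
#' @inheritParams step_site
#' @param schedule an [acquisition_schedule()].
#' @param n_sites number of independent sites (cells).
#' @param seed integer seed; site `i` uses an independent substream.
#' @param burnin_dwell pre-bleach burn-in, in expected dwell times.
#' @return A `recovery_curve` data.frame with columns `time_s`, `mean`,
#'   `sem` and `bleached_mean` (the mean normalized bleached signal, useful
#'   to locate the exit of the last bleached transcript), with attributes
#'   `n` (sites used) and `schedule`.
#' @export
simulate_frap <- function(gene, params, schedule = frap_schedule("mrna-frap"),
                          n_sites = 100, seed = 1, burnin_dwell = 2) {
  check_sim_inputs(new_site_state(gene, 1), gene, params)
  stopifnot(inherits(schedule, "acquisition_schedule"))
  if (n_sites < 1) stop("n_sites must be >= 1")
  ft <- schedule_frame_times(schedule)
  if (length(ft) < 2) stop("schedule must contain at least 2 frames")
  if (schedule$n_prebleach < 1) stop("FRAP simulation needs at least 1 pre-bleach frame")
  burnin <- max(burnin_dwell * expected_dwell(gene, params), 50 * params$dt)
  res <- sim_frap_cpp(gene, params, burnin, ft, as.integer(n_sites), as.numeric(seed))
  pre <- ft < 0
  pre_mean <- rowMeans(res$unbleached[, pre, drop = FALSE])
  keep <- pre_mean > 0
  if (!any(keep)) stop("no site had pre-bleach signal; raise init_rate or n_copies")
  if (any(!keep)) {
    message(sum(!keep), " site(s) with zero pre-bleach signal dropped")
  }
  norm <- res$unbleached[keep, , drop = FALSE] / pre_mean[keep]
  normb <- res$bleached[keep, , drop = FALSE] / pre_mean[keep]
  n <- sum(keep)
  recovery_curve(
    time_s = ft,
    mean = colMeans(norm),
    sem = if (n > 1) apply(norm, 2, sd) / sqrt(n) else rep(NA_real_, length(ft)),
    n = n,
    schedule = schedule,
    bleached_mean = colMeans(normb)
  )
}

#' Steady-state intron/exon FISH snapshots
#'
#' Each site is an independent stationary snapshot. The intron channel
#' counts, over every transcript at the site, the probe-carrying introns
#' that have been synthesized (polymerase past the intron 3' end) and not
#' yet depleted (polymerase not yet `splice_depletion_bp` further); the exon
#' channel counts transcripts whose polymerase has passed the exon-probe
#' target. Sites with zero exon signal have an undefined ratio and are
#' dropped (reported via a message and the `"n_dropped"` attribute).
#'
#' @inheritParams simulate_frap
#' @param control_mean_ratio optional mean ratio of a designated control
#'   condition; when given, a `ratio_norm` column (ratio divided by the
#'   control mean, the E3-control normalization convention) is added.
#' @return A data.frame with columns `site`, `intron_signal`, `exon_signal`,
#'   `ratio` (and optionally `ratio_norm`).
#' @export
simulate_fish_snapshot <- function(gene, params, n_sites = 100, seed = 1,
                                   burnin_dwell = 2, control_mean_ratio = NULL) {
  check_sim_inputs(new_site_state(gene, 1), gene, params)
  if (n_sites < 1) stop("n_sites must be >= 1")
  burnin <- max(burnin_dwell * expected_dwell(gene, params), 50 * params$dt)
  m <- sim_fish_cpp(gene, params, burnin, as.integer(n_sites), as.numeric(seed))
  out <- data.frame(site = seq_len(n_sites),
                    intron_signal = m[, "intron_signal"],
                    exon_signal = m[, "exon_signal"])
  drop <- out$exon_signal == 0
  if (any(drop)) message(sum(drop), " site(s) with zero exon signal dropped")
  out <- out[!drop, , drop = FALSE]
  out$ratio <- out$intron_signal / out$exon_signal
  if (!is.null(control_mean_ratio)) {
    stopifnot(is.numeric(control_mean_ratio), control_mean_ratio > 0)
    out$ratio_norm <- out$ratio / control_mean_ratio
  }
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Analytic steady-state intron/exon ratio (no-pause limit)
#'
#' Independent closed-form oracle for [simulate_fish_snapshot()], valid in
#' the no-pause, deterministic-elongation regime. By stationarity the
#' expected channel signal is proportional to the arrival rate times the
#' signal's lifetime per transcript (Little's law), and the arrival rate is
#' common to both channels, so the expected ratio is a ratio of lifetimes.
#'
#' With the simulator's event-based (binary) accrual, a probe intron's
#' signal lives from the crossing of its 3' end until depletion
#' `splice_depletion_bp` downstream — `depletion/elong_rate` seconds — or,
#' when the depletion point lies beyond the gene end, until the transcript
#' leaves the site (remaining elongation + mean termination wait +
#' retention). The exon probe's signal lives from the crossing of its
#' target's 3' boundary until transcript departure. `accrual = "gradual"`
#' adds the half-length synthesis terms that approximate length-proportional
#' probe hybridization; the two variants differ by a bounded amount that the
#' package's tests quantify on toy geometries.
#'
#' @inheritParams simulate_frap
#' @param accrual `"binary"` (matches the simulator's signal model; default)
#'   or `"gradual"` (half-length synthesis approximation).
#' @return The expected intron/exon signal ratio (0 when no intron carries a
#'   probe).
#' @export
expected_fish_ratio <- function(gene, params, accrual = c("binary", "gradual")) {
  accrual <- match.arg(accrual)
  v <- validate_gene(gene)
  if (length(v)) stop("invalid gene model: ", paste(v, collapse = "; "))
  v <- validate_params(params)
  if (length(v)) stop("invalid kinetic parameters: ", paste(v, collapse = "; "))
  if (params$pause_on_rate > 0) {
    stop("expected_fish_ratio is defined only in the no-pause regime ",
         "(pause_on_rate = 0); got pause_on_rate = ", params$pause_on_rate)
  }
  vel <- params$elong_rate
  wait <- if (params$termination_rate > 0) 1 / params$termination_rate else 0
  depart_after_end <- wait + params$retention_mean

  intron_life <- 0
  for (i in gene$intron_probe_indices) {
    end_i <- gene$introns[i, 2]
    life <- if (end_i + params$splice_depletion_bp <= gene$length_bp) {
      params$splice_depletion_bp / vel
    } else {
      (gene$length_bp - end_i) / vel + depart_after_end
    }
    if (accrual == "gradual") {
      life <- life + (gene$introns[i, 2] - gene$introns[i, 1]) / 2 / vel
    }
    intron_life <- intron_life + life
  }
  exon_life <- (gene$length_bp - gene$exon_probe[2]) / vel + depart_after_end
  if (accrual == "gradual") {
    exon_life <- exon_life + (gene$exon_probe[2] - gene$exon_probe[1]) / 2 / vel
  }
  unname(intron_life / exon_life)
}

#' Expected steady-state transcript occupancy (no-pause limit)
#'
#' Little's-law closed form for the mean number of transcripts (nascent +
#' retained) at a site: arrival rate times mean dwell,
#' `n_copies * init_rate * (length_bp/elong_rate + retention_mean)`.
#' The mean termination wait `1/termination_rate` is excluded to match the
#' bare closed form; choose a fast termination rate when using this as an
#' oracle.
#'
#' @inheritParams simulate_frap
#' @return Expected transcript count.
#' @export
expected_site_occupancy <- function(gene, params) {
  gene$n_copies * params$init_rate *
    (gene$length_bp / params$elong_rate + params$retention_mean)
}
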