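#' Specification for a synthetic FRAP dataset
#'
#' Describes how to fabricate a set of raw FRAP traces with known ground
#' truth: the true normalized recovery comes either from a closed-form
#' bi-exponential (`model = "biexp"`) or from the Monte-Carlo simulator
#' (`model = "simulator"`); replicate structure follows the experimental
#' design of repeated cells measured on several independent days (day
#' effects are Gaussian multipliers on the recovery amplitudes); raw counts
#' acquire per-frame acquisition photobleaching and additive Gaussian noise.
#'
#' @param model `"biexp"` or `"simulator"`.
#' @param model_params for `"biexp"`, a list with `y0`, `amplitudes`,
#'   `rates`; for `"simulator"`, a list with `gene` and `params`.
#' @param schedule an [acquisition_schedule()].
#' @param noise_sd Gaussian noise sd on the normalized intensity scale.
#' @param acq_bleach_rate per-frame multiplicative acquisition-bleaching
#'   decay applied to the roi and whole-cell channels, in [0, 1).
#' @param n_cells number of traces (cells).
#' @param n_days number of acquisition days the cells are spread over.
#' @param day_sd sd of the Gaussian day multiplier on amplitudes.
#' @param sites_per_cell sites averaged per cell for the simulator model.
#' @param seed integer seed.
#' @return A validated `synth_frap_spec`.
#' @export
synth_frap_spec <- function(model = c("biexp", "simulator"), model_params,
                            schedule = frap_schedule("mrna-frap"),
                            noise_sd = 0.02, acq_bleach_rate = 0.01,
                            n_cells = 10, n_days = 3, day_sd = 0.05,
                            sites_per_cell = 1, seed = 1) {
  model <- match.arg(model)
  stopifnot(inherits(schedule, "acquisition_schedule"),
            noise_sd >= 0, acq_bleach_rate >= 0, acq_bleach_rate < 1,
            n_cells >= 1, n_days >= 1, day_sd >= 0, sites_per_cell >= 1)
  if (model == "biexp") {
    need <- c("y0", "amplitudes", "rates")
    if (!all(need %in% names(model_params))) {
      stop("biexp model_params needs fields: ", paste(need, collapse = ", "))
    }
    stopifnot(length(model_params$amplitudes) == length(model_params$rates),
              all(model_params$rates > 0))
  } else {
    if (!all(c("gene", "params") %in% names(model_params))) {
      stop("simulator model_params needs fields: gene, params")
    }
  }
  structure(list(model = model, model_params = model_params, schedule = schedule,
                 noise_sd = noise_sd, acq_bleach_rate = acq_bleach_rate,
                 n_cells = as.integer(n_cells), n_days = as.integer(n_days),
                 day_sd = day_sd, sites_per_cell = as.integer(sites_per_cell),
                 seed = as.integer(seed)),
            class = "synth_frap_spec")
}

#' Generate a synthetic FRAP dataset with ground truth
#'
#' For each cell the true normalized curve is evaluated on the schedule's
#' frame grid (1 before the bleach), multiplied into a raw trace
#' `roi = background + m(t) * W(t)` with `W(t) = 1000 * (1 -
#' acq_bleach_rate)^frame` and `whole = background + W(t)`, and Gaussian
#' noise of sd `noise_sd * W(t)` is added to the roi channel. Because the
#' whole-cell channel carries the same acquisition-bleaching decay, double
#' normalization recovers the true curve exactly in the noiseless case.
#' Day effects multiply the post-bleach recovery amplitudes.
#'
#' @param spec a [synth_frap_spec()].
#' @return A list with `traces` (list of [raw_frap_trace()]) and `truth`, a
#'   data.frame of per-cell generating parameters and day assignments.
#' @export
gen_frap_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_frap_spec"))
  ft <- schedule_frame_times(spec$schedule)
  npre <- spec$schedule$n_prebleach
  post <- ft >= 0
  days <- rep(seq_len(spec$n_days), length.out = spec$n_cells)

  with_local_seed(spec$seed, {
    day_mult <- rnorm(spec$n_days, mean = 1, sd = spec$day_sd)
    cell_seeds <- sample.int(.Machine$integer.max, spec$n_cells)
    traces <- vector("list", spec$n_cells)
    truth <- vector("list", spec$n_cells)
    for (i in seq_len(spec$n_cells)) {
      g <- day_mult[days[i]]
      m <- rep(1, length(ft))
      if (spec$model == "biexp") {
        mp <- spec$model_params
        A <- mp$amplitudes * g
        m[post] <- exp_model(ft[post], mp$y0, A, mp$rates)
        truth[[i]] <- data.frame(cell = i, day = days[i], day_multiplier = g,
                                 y0 = mp$y0,
                                 t(stats::setNames(A, paste0("A", seq_along(A)))),
                                 t(stats::setNames(mp$rates,
                                                   paste0("k", seq_along(mp$rates)))))
      } else {
        mp <- spec$model_params
        sim <- simulate_frap(mp$gene, mp$params, spec$schedule,
                             n_sites = spec$sites_per_cell, seed = cell_seeds[i])
        mm <- sim$mean
        m0 <- mm[post][1]
        m[post] <- m0 + g * (mm[post] - m0)
        truth[[i]] <- data.frame(cell = i, day = days[i], day_multiplier = g,
                                 retention_mean = mp$params$retention_mean,
                                 sim_seed = cell_seeds[i])
      }
      frame <- seq_along(ft) - 1
      W <- 1000 * (1 - spec$acq_bleach_rate)^frame
      background <- rep(50, length(ft))
      roi <- background + m * W
      if (spec$noise_sd > 0) roi <- roi + rnorm(length(ft), sd = spec$noise_sd * W)
      traces[[i]] <- raw_frap_trace(times = ft - ft[1], roi = roi,
                                    whole = background + W,
                                    background = background, n_prebleach = npre)
    }
    list(traces = traces, truth = do.call(rbind, truth))
  })
}

#' Specification for a synthetic FISH intensity table
#'
#' @param gene a [build_gene()] model (or preset label).
#' @param params a [kinetic_params()] object.
#' @param n_sites number of transcription sites.
#' @param lognormal_noise_sd sdlog of the independent multiplicative
#'   lognormal noise applied to each channel (median multiplier 1, so
#'   median ratios are preserved). Lognormal keeps intensities positive.
#' @param seed integer seed.
#' @return A validated `synth_fish_spec`.
#' @export
synth_fish_spec <- function(gene, params, n_sites = 300,
                            lognormal_noise_sd = 0.2, seed = 1) {
  if (is.character(gene)) gene <- build_gene(gene)
  v <- c(validate_gene(gene), validate_params(params))
  if (length(v)) stop("invalid spec: ", paste(v, collapse = "; "))
  stopifnot(n_sites >= 1, lognormal_noise_sd >= 0)
  structure(list(gene = gene, params = params, n_sites = as.integer(n_sites),
                 lognormal_noise_sd = lognormal_noise_sd, seed = as.integer(seed)),
            class = "synth_fish_spec")
}

#' Generate a synthetic per-site FISH intensity table
#'
#' Site signals come from [simulate_fish_snapshot()]; each channel is then
#' multiplied by independent lognormal noise. The noiseless simulator values
#' are carried alongside as ground truth.
#'
#' @param spec a [synth_fish_spec()].
#' @return A data.frame with columns `site`, `intron_true`, `exon_true`,
#'   `intron_channel`, `exon_channel`, `ratio`.
#' @export
gen_fish_table <- function(spec) {
  stopifnot(inherits(spec, "synth_fish_spec"))
  snap <- simulate_fish_snapshot(spec$gene, spec$params, n_sites = spec$n_sites,
                                 seed = spec$seed)
  n <- nrow(snap)
  noise <- with_local_seed(spec$seed + 1L, {
    matrix(exp(rnorm(2 * n, mean = 0, sd = spec$lognormal_noise_sd)), ncol = 2)
  })
  out <- data.frame(site = snap$site,
                    intron_true = snap$intron_signal,
                    exon_true = snap$exon_signal,
                    intron_channel = snap$intron_signal * noise[, 1],
                    exon_channel = snap$exon_signal * noise[, 2])
  out$ratio <- out$intron_channel / out$exon_channel
  out
}
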