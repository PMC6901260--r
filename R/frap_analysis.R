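#' Normalized FRAP recovery curves
#'
#' A `recovery_curve` is a data.frame of frame times (seconds relative to
#' the bleach; pre-bleach frames negative, first post-bleach frame at 0),
#' the normalized mean intensity and its standard error, with the replicate
#' count and (optionally) the acquisition schedule carried as attributes.
#'
#' @param time_s frame times (strictly increasing).
#' @param mean normalized intensity.
#' @param sem standard error (NA for single traces).
#' @param n number of replicates averaged.
#' @param schedule optional [acquisition_schedule()].
#' @param bleached_mean optional mean normalized bleached signal column.
#' @return A `recovery_curve` data.frame.
#' @export
recovery_curve <- function(time_s, mean, sem = NA_real_, n = 1L, schedule = NULL,
                           bleached_mean = NULL) {
  stopifnot(length(time_s) == length(mean), !is.unsorted(time_s, strictly = TRUE))
  out <- data.frame(time_s = as.numeric(time_s), mean = as.numeric(mean),
                    sem = as.numeric(rep_len(sem, length(time_s))))
  if (!is.null(bleached_mean)) out$bleached_mean <- as.numeric(bleached_mean)
  attr(out, "n") <- as.integer(n)
  attr(out, "schedule") <- schedule
  class(out) <- c("recovery_curve", "data.frame")
  out
}

#' Raw FRAP traces
#'
#' Per-frame intensities of the bleached region of interest, the whole
#' cell/nucleus, and the background, in arbitrary units, plus the number of
#' leading pre-bleach frames.
#'
#' @param times acquisition times in seconds (strictly increasing; any zero).
#' @param roi bleached-ROI intensity.
#' @param whole whole-cell (or whole-nucleus) intensity.
#' @param background background intensity.
#' @param n_prebleach number of leading pre-bleach frames (>= 1).
#' @return A `raw_frap_trace`.
#' @export
raw_frap_trace <- function(times, roi, whole, background, n_prebleach) {
  n <- length(times)
  if (!all(lengths(list(roi, whole, background)) == n)) {
    stop("times, roi, whole and background must have equal length")
  }
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  n_prebleach <- as.integer(n_prebleach)
  if (is.na(n_prebleach) || n_prebleach < 1 || n_prebleach >= n) {
    stop("n_prebleach must be >= 1 and smaller than the number of frames")
  }
  if (any(background > roi)) {
    warning("background exceeds the ROI intensity at ", sum(background > roi), " frame(s)")
  }
  structure(list(times = as.numeric(times), roi = as.numeric(roi),
                 whole = as.numeric(whole), background = as.numeric(background),
                 n_prebleach = n_prebleach),
            class = "raw_frap_trace")
}

#' Double normalization of a raw FRAP trace
#'
#' Standard double normalization: background-subtract both channels, divide
#' the ROI by the whole-cell signal (correcting acquisition photobleaching
#' and focus drift), then divide by the pre-bleach mean of that quotient so
#' the pre-bleach level is exactly 1. Times are re-zeroed to the first
#' post-bleach frame.
#'
#' @param trace a [raw_frap_trace()].
#' @param prebleach_window number of pre-bleach frames to average for the
#'   normalization (default: all of them).
#' @return A single-replicate `recovery_curve` (pre-bleach mean 1 by
#'   construction).
#' @export
normalize_frap <- function(trace, prebleach_window = NULL) {
  stopifnot(inherits(trace, "raw_frap_trace"))
  denom <- trace$whole - trace$background
  bad <- which(denom <= 0)
  if (length(bad)) {
    stop("whole-cell minus background is non-positive at frame(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  q <- (trace$roi - trace$background) / denom
  npre <- trace$n_prebleach
  win <- if (is.null(prebleach_window)) seq_len(npre) else {
    stopifnot(prebleach_window >= 1, prebleach_window <= npre)
    seq(npre - prebleach_window + 1, npre)
  }
  pre_mean <- mean(q[win])
  if (pre_mean <= 0) stop("pre-bleach mean is non-positive; cannot normalize")
  recovery_curve(time_s = trace$times - trace$times[npre + 1], mean = q / pre_mean,
                 n = 1L)
}

exp_model <- function(t, y0, A, k) {
  out <- rep(y0, length(t))
  for (j in seq_along(A)) out <- out + A[j] * (1 - exp(-k[j] * t))
  out
}

#' Fit a mono- or bi-exponential recovery model
#'
#' Least-squares fit of `f(t) = y0 + sum_j A_j (1 - exp(-k_j t))` to the
#' post-bleach frames (`time_s >= 0`) of a recovery curve. Because
#' bi-exponential least squares is multimodal, fitting is multi-start: a
#' log-spaced grid over the rates (1e-3..1 s^-1, 5 points per component)
#' with amplitudes and `y0` obtained by a linear solve at fixed rates, then
#' Levenberg-Marquardt refinement from the best starting points. Rates are
#' bounded positive; solutions are deterministic given the fixed start grid.
#'
#' @param curve a [recovery_curve()].
#' @param n_components 1 or 2 exponential components.
#' @param rate_grid starting grid for the rate constants, in s^-1.
#' @return An `exp_fit` list: `n_components`, `y0`, `amplitudes` and `rates`
#'   (sorted by decreasing rate), `fractions` (amplitudes normalized to
#'   their sum), `immobile_fraction` (`1 - (y0 + sum(A))`, clipped to
#'   [0, 1]), `sse`, `aic`, `n_obs`, `fitted` (function of t).
#' @export
fit_recovery <- function(curve, n_components = 2,
                         rate_grid = 10^seq(-3, 0, length.out = 5)) {
  stopifnot(inherits(curve, "recovery_curve"), n_components %in% c(1, 2))
  post <- curve$time_s >= 0
  t <- curve$time_s[post]
  y <- curve$mean[post]
  npar <- 2 * n_components + 1
  if (length(t) < 3 * npar) {
    stop("need at least ", 3 * npar, " post-bleach frames to fit ", n_components,
         " component(s); got ", length(t))
  }

  combos <- if (n_components == 1) {
    lapply(rate_grid, function(k) k)
  } else {
    cmb <- utils::combn(rate_grid, 2, simplify = FALSE)
    lapply(cmb, sort, decreasing = TRUE)
  }
  # linear solve for (y0, A) at fixed rates to rank the starts
  starts <- lapply(combos, function(ks) {
    X <- cbind(1, vapply(ks, function(k) 1 - exp(-k * t), numeric(length(t))))
    fit <- lm.fit(X, y)
    coef <- fit$coefficients
    coef[is.na(coef)] <- 0
    list(y0 = coef[1], A = coef[-1], k = ks, sse = sum(fit$residuals^2))
  })
  starts <- starts[order(vapply(starts, `[[`, numeric(1), "sse"))]

  best <- NULL
  for (s in utils::head(starts, 3)) {
    par0 <- c(s$y0, s$A, s$k)
    fit <- tryCatch({
      res <- minpack.lm::nls.lm(
        par = par0,
        fn = function(p) y - exp_model(t, p[1], p[2:(1 + n_components)],
                                       p[(2 + n_components):npar]),
        lower = c(-Inf, rep(-Inf, n_components), rep(1e-8, n_components)),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      p <- res$par
      list(y0 = p[1], A = p[2:(1 + n_components)], k = p[(2 + n_components):npar],
           sse = sum(res$fvec^2))
    }, error = function(e) NULL)
    if (!is.null(fit) && all(fit$k > 0) && (is.null(best) || fit$sse < best$sse)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    s <- starts[[1]]
    stop(sprintf(paste0("exponential fit did not converge from any start; best ",
                        "linear-solve start had sse %.4g (y0 %.3g, rates %s)"),
                 s$sse, s$y0, paste(signif(s$k, 3), collapse = ", ")))
  }

  ord <- order(best$k, decreasing = TRUE)
  A <- unname(best$A[ord])
  k <- unname(best$k[ord])
  y0 <- unname(best$y0)
  plateau <- y0 + sum(A)
  if (plateau > 1.05) {
    warning(sprintf("fitted plateau %.3f exceeds the pre-bleach level by > 5%%", plateau))
  }
  n <- length(t)
  structure(list(
    n_components = n_components,
    y0 = y0,
    amplitudes = A,
    rates = k,
    fractions = if (sum(A) != 0) A / sum(A) else rep(NA_real_, n_components),
    immobile_fraction = min(max(1 - plateau, 0), 1),
    sse = best$sse,
    aic = n * log(max(best$sse, 1e-300) / n) + 2 * npar,
    n_obs = n,
    fitted = function(tt) exp_model(tt, y0, A, k)
  ), class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit>  %d component(s), y0 = %.4g, sse = %.4g, aic = %.2f\n",
              x$n_components, x$y0, x$sse, x$aic))
  for (j in seq_len(x$n_components)) {
    cat(sprintf("  A%d = %.4g  k%d = %.4g s^-1 (t1/2 = %.1f s)  fraction %.2f\n",
                j, x$amplitudes[j], j, x$rates[j], log(2) / x$rates[j], x$fractions[j]))
  }
  cat(sprintf("  immobile fraction %.3f\n", x$immobile_fraction))
  invisible(x)
}

#' Select between mono- and bi-exponential recovery fits
#'
#' Fits both models and returns the bi-exponential fit only when it is
#' clearly supported: its AIC must be lower by at least `aic_margin`
#' (default 2) and its rate constants separated by at least `rate_sep`
#' (default 3-fold). Otherwise the mono-exponential fit is returned. Both
#' AIC values are recorded in the `"aic_table"` attribute.
#'
#' @inheritParams fit_recovery
#' @param aic_margin required AIC improvement of the 2-component model.
#' @param rate_sep required fold-separation of the two rate constants.
#' @return The selected `exp_fit`.
#' @export
select_model <- function(curve, aic_margin = 2, rate_sep = 3,
                         rate_grid = 10^seq(-3, 0, length.out = 5)) {
  f1 <- tryCatch(fit_recovery(curve, 1, rate_grid), error = function(e) e)
  f2 <- tryCatch(fit_recovery(curve, 2, rate_grid), error = function(e) e)
  if (inherits(f1, "error") && inherits(f2, "error")) {
    stop("both exponential fits failed: ", conditionMessage(f1))
  }
  pick <- if (inherits(f2, "error")) {
    f1
  } else if (inherits(f1, "error")) {
    f2
  } else if (f2$aic <= f1$aic - aic_margin &&
             max(f2$rates) / min(f2$rates) >= rate_sep) {
    f2
  } else {
    f1
  }
  attr(pick, "aic_table") <- c(
    aic_1 = if (inherits(f1, "error")) NA_real_ else f1$aic,
    aic_2 = if (inherits(f2, "error")) NA_real_ else f2$aic
  )
  pick
}

# interpolate a curve's post-bleach mean onto a time grid (never extrapolates)
interp_curve <- function(curve, grid) {
  post <- curve$time_s >= 0
  approx(curve$time_s[post], curve$mean[post], xout = grid, rule = 1)$y
}

#' Permutation comparison of two sets of recovery curves
#'
#' Replicate-level comparison of two conditions: the statistic is the mean
#' absolute difference between the condition mean curves over the shared
#' post-bleach frame grid, and its null distribution is obtained by
#' shuffling replicate labels between the conditions. Curves on different
#' frame grids are linearly interpolated onto the shared grid (never
#' extrapolated).
#'
#' @param reps_a,reps_b lists of [recovery_curve()] replicates (>= 3 each).
#' @param n_permutations number of label permutations.
#' @param seed integer seed (the caller's RNG state is untouched).
#' @return A `curve_comparison` list: `statistic`, `p_value`
#'   (`(1 + #permuted >= observed) / (1 + n_permutations)`),
#'   `n_permutations`, and the grid used.
#' @export
compare_curves <- function(reps_a, reps_b, n_permutations = 999, seed = 1) {
  stopifnot(is.list(reps_a), is.list(reps_b))
  if (length(reps_a) < 3 || length(reps_b) < 3) {
    stop("need at least 3 replicates per condition")
  }
  all_reps <- c(reps_a, reps_b)
  lo <- max(vapply(all_reps, function(cv) min(cv$time_s[cv$time_s >= 0]), numeric(1)))
  hi <- min(vapply(all_reps, function(cv) max(cv$time_s), numeric(1)))
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    stop("replicate time ranges do not overlap; cannot build a shared grid")
  }
  ref <- reps_a[[1]]$time_s
  grid <- ref[ref >= lo & ref <= hi]
  if (length(grid) < 2) stop("shared post-bleach grid has fewer than 2 frames")
  M <- t(vapply(all_reps, interp_curve, numeric(length(grid)), grid = grid))
  na <- length(reps_a)
  ntot <- nrow(M)
  stat_fun <- function(idx_a) {
    mean(abs(colMeans(M[idx_a, , drop = FALSE]) -
             colMeans(M[-idx_a, , drop = FALSE])))
  }
  observed <- stat_fun(seq_len(na))
  perm <- with_local_seed(seed, {
    vapply(seq_len(n_permutations), function(i) stat_fun(sample.int(ntot, na)),
           numeric(1))
  })
  structure(list(statistic = observed,
                 p_value = (1 + sum(perm >= observed)) / (1 + n_permutations),
                 n_permutations = as.integer(n_permutations),
                 grid = grid),
            class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf("<curve_comparison>  statistic = %.4g, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' FDR step-up adjustment of a vector of p-values (monotone, clipped at 1).
#'
#' @param p_values numeric vector with values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
fdr_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values <= 0 | p_values > 1)) {
    stop("p_values must all lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Retrieve the transcript retention time from an observed FRAP curve
#'
#' Grid search over candidate retention times: each candidate is plugged
#' into the kinetic parameters, the FRAP experiment is re-simulated with a
#' matched seed and the observed schedule, and the sum of squared errors
#' between the simulated and observed mean curves is computed on the
#' observed post-bleach frames. Returns the minimizer (ties broken toward
#' the smaller retention time) and the full SSE table.
#'
#' @param observed an observed (or simulated) [recovery_curve()].
#' @param gene a [build_gene()] model.
#' @param base_params [kinetic_params()] whose `retention_mean` is swept.
#' @param retention_grid candidate retention times in seconds.
#' @param n_sites sites per simulated curve.
#' @param seed seed shared by all grid simulations.
#' @param schedule acquisition schedule; defaults to the observed curve's.
#' @return A list with `best_retention` (seconds) and `table`, a data.frame
#'   of `retention_s` and `sse`.
#' @export
fit_retention_time <- function(observed, gene, base_params, retention_grid,
                               n_sites = 200, seed = 1, schedule = NULL) {
  stopifnot(inherits(observed, "recovery_curve"), length(retention_grid) >= 1)
  if (is.null(schedule)) schedule <- attr(observed, "schedule")
  if (is.null(schedule)) stop("no acquisition schedule on the observed curve; pass `schedule`")
  grid_r <- sort(as.numeric(retention_grid))
  t_obs <- observed$time_s[observed$time_s >= 0]
  y_obs <- observed$mean[observed$time_s >= 0]
  sse <- vapply(grid_r, function(r) {
    params <- base_params
    params$retention_mean <- r
    v <- validate_params(params)
    if (length(v)) stop("invalid parameters at retention ", r, ": ", paste(v, collapse = "; "))
    sim <- simulate_frap(gene, params, schedule, n_sites = n_sites, seed = seed)
    y_sim <- approx(sim$time_s[sim$time_s >= 0], sim$mean[sim$time_s >= 0],
                    xout = t_obs, rule = 2)$y
    sum((y_sim - y_obs)^2)
  }, numeric(1))
  list(best_retention = grid_r[which.min(sse)],
       table = data.frame(retention_s = grid_r, sse = sse))
}
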