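# Ensemble post-processing: replicate-averaged frequencies, fitted
# log-slopes beta(t), fitness-class histograms, and t0 fitting.

#' Replicate-averaged per-site frequencies
#'
#' Arithmetic mean, per site and per recorded time, of the less-fit allele
#' frequency across replicate trajectories. Ensemble averaging is what the
#' analytic predictions describe; in data it is approximated by combining
#' sequences from independent populations.
#'
#' @param trajectories list of `trajectory` objects sharing one selection
#'   profile and time grid (as from [run_ensemble()]).
#' @return An object of class `ensemble_freq`: list with `times`, `s_values`,
#'   `mean_f` (times x L matrix), `n_replicates`.
#' @export
ensemble_mean_frequencies <- function(trajectories) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1)
  ref <- trajectories[[1L]]
  for (tr in trajectories[-1L]) {
    if (!identical(tr$times, ref$times))
      stop("trajectories do not share a time grid", call. = FALSE)
    if (!identical(tr$profile, ref$profile))
      stop("trajectories do not share a selection profile", call. = FALSE)
  }
  mean_f <- Reduce(`+`, lapply(trajectories, `[[`, "site_frequencies")) /
    length(trajectories)
  structure(list(times = ref$times, s_values = ref$profile, mean_f = mean_f,
                 n_replicates = length(trajectories)),
            class = "ensemble_freq")
}

#' @export
print.ensemble_freq <- function(x, ...) {
  cat(sprintf("Ensemble frequencies: %d replicates, %d times, %d sites\n",
              x$n_replicates, length(x$times), length(x$s_values)))
  invisible(x)
}

#' Fit the log-slope beta at one time
#'
#' Ordinary least-squares regression of `log(mean_f)` on `s` over sites with
#' `mean_f > 0`; returns `beta = -slope` with its regression standard error.
#' Sites that have lost the less-fit allele in every replicate are excluded
#' (their log diverges); the exclusion count is reported. Unweighted OLS on
#' per-site points is the default; `weighted = TRUE` applies
#' inverse-variance weights `mean_f * n` (binomial, on the log scale).
#'
#' @param ens an [ensemble_mean_frequencies()] object.
#' @param t a recorded time.
#' @param weighted logical; use approximate inverse-variance weights.
#' @return list with `beta`, `stderr`, `n_sites_used`, `n_excluded`.
#' @export
fit_log_slope <- function(ens, t, weighted = FALSE) {
  stopifnot(inherits(ens, "ensemble_freq"))
  it <- match(t, ens$times)
  if (is.na(it)) stop("time ", t, " was not recorded", call. = FALSE)
  f <- ens$mean_f[it, ]
  use <- f > 0
  if (sum(use) < 3L)
    stop("fewer than 3 sites with nonzero frequency at t = ", t,
         ": polymorphism lost, slope not estimable", call. = FALSE)
  df <- data.frame(s = ens$s_values[use], logf = log(f[use]))
  fit <- if (weighted) {
    stats::lm(logf ~ s, data = df, weights = f[use])
  } else {
    stats::lm(logf ~ s, data = df)
  }
  co <- summary(fit)$coefficients
  list(beta = -co["s", "Estimate"], stderr = co["s", "Std. Error"],
       n_sites_used = sum(use), n_excluded = sum(!use))
}

#' Log-slope time series
#'
#' [fit_log_slope()] applied at every recorded time.
#'
#' @inheritParams fit_log_slope
#' @return An object of class `slope_series`: data.frame with columns
#'   `time`, `beta`, `stderr`, `n_sites_used`, `n_excluded`.
#' @export
slope_time_series <- function(ens, weighted = FALSE) {
  rows <- lapply(ens$times, function(t) {
    fit <- fit_log_slope(ens, t, weighted = weighted)
    data.frame(time = t, beta = fit$beta, stderr = fit$stderr,
               n_sites_used = fit$n_sites_used, n_excluded = fit$n_excluded)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("slope_series", "data.frame")
  out
}

#' Fit the traveling-wave onset time t0
#'
#' Single-parameter least squares of the linear prediction
#' `beta(t) = t0 + mu * N * phi'(0) * (t - t0)` against a fitted slope
#' series over a time window in the traveling-wave phase. Because the
#' prediction's time derivative `mu * N * phi'(0)` is fixed by theory, `t0`
#' only shifts the line vertically; the fit is the closed-form offset
#' estimate
#' `t0 = mean(beta - c * t) / (1 - c)` with `c = mu * N * phi'(0)`.
#'
#' @param series a [slope_time_series()] result.
#' @param params a [theory_params()] object.
#' @param sol a `wave_solution`.
#' @param window length-2 numeric; time range to fit over (default
#'   `c(1/s_av, max(time))`, the traveling-wave phase).
#' @return list with `t0`, `dbeta_dt` (the theoretical slope used),
#'   `n_points`, `residual_sd`.
#' @export
fit_t0 <- function(series, params, sol, window = NULL) {
  stopifnot(inherits(series, "data.frame"))
  if (is.null(window)) window <- c(1 / params$s_av, max(series$time))
  keep <- series$time >= window[1] & series$time <= window[2]
  if (!any(keep)) stop("empty fitting window", call. = FALSE)
  tt <- series$time[keep]
  bb <- series$beta[keep]
  c_rate <- params$mu * params$N * sol$phi_prime0
  if (c_rate >= 1)
    stop("mu * N * phi'(0) >= 1: outside the slow-wave regime", call. = FALSE)
  t0 <- mean(bb - c_rate * tt) / (1 - c_rate)
  resid <- bb - (t0 + c_rate * (tt - t0))
  list(t0 = t0, dbeta_dt = c_rate, n_points = sum(keep),
       residual_sd = stats::sd(resid))
}

#' Fitness-class histogram of a population
#'
#' Bins genomes by the effective number of deleterious alleles
#' `k = -W / s_av`, where `W` is the additive log-fitness. The histogram is
#' the fitness wave: during adaptation its mass moves toward `k = 0`.
#'
#' @param pop binary population matrix.
#' @param profile a `selection_profile`.
#' @param s_av positive; the intrinsic-DFE mean used to scale fitness.
#' @param binwidth bin width in `k` units (default 1, integer mutation
#'   counts).
#' @return data.frame with columns `k_mid`, `count`; counts sum to `nrow(pop)`.
#' @export
fitness_class_histogram <- function(pop, profile, s_av, binwidth = 1) {
  if (s_av <= 0) stop("`s_av` must be positive", call. = FALSE)
  k <- -genome_fitness(pop, profile) / s_av   # always >= 0: all s_i > 0
  bin <- floor(k / binwidth)
  counts <- tabulate(bin + 1L, nbins = max(bin) + 1L)
  data.frame(k_mid = (seq_along(counts) - 0.5) * binwidth, count = counts)
}
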