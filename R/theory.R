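# Closed-form theory: early-phase frequency of less-fit alleles, Fermi
# occupancy statistics, the traveling-wave decay of monomorphic less-fit
# sites, and the fixation probability of beneficial mutations under clonal
# interference.

#' Theory parameters
#'
#' Parameters of the analytic predictions. `U_b` is the beneficial mutation
#' rate per genome per generation; it is an input because it depends on the
#' (time-dependent) availability of less-fit sites — see
#' [beneficial_rate()] for the natural link `U_b ~ mu * L * mean(f)`.
#' `t0` is the onset time of the traveling-wave regime, of order `1/s_av`.
#'
#' @param f_in initial less-fit allele frequency, in `(0, 1)`.
#' @param s_av positive; mean of the intrinsic DFE.
#' @param N positive integer; population size.
#' @param mu per-site mutation probability per generation.
#' @param U_b beneficial mutation rate per genome per generation; must
#'   satisfy `U_b < s_av`.
#' @param t0 traveling-wave onset time in generations (default `1/s_av`).
#' @return An object of class `theory_params`.
#' @export
theory_params <- function(f_in, s_av, N, mu, U_b, t0 = 1 / s_av) {
  stopifnot(f_in > 0, f_in < 1, s_av > 0, N >= 1, mu >= 0, U_b > 0, t0 > 0)
  if (s_av / U_b <= 1)
    stop("requires s_av > U_b: log(s_av/U_b) must be positive", call. = FALSE)
  structure(list(f_in = f_in, s_av = s_av, N = as.integer(N), mu = mu,
                 U_b = U_b, t0 = t0),
            class = "theory_params")
}

#' Beneficial mutation rate implied by the current mutant frequency
#'
#' Convenience link `U_b = mu * L * mean_f`: beneficial mutations can arise
#' only at sites currently carrying the less-fit allele, so the per-genome
#' beneficial rate is the genomic rate times the mean less-fit occupancy.
#'
#' @param mu per-site mutation probability.
#' @param L number of sites.
#' @param mean_f mean less-fit allele frequency across sites.
#' @return beneficial rate per genome per generation.
#' @export
beneficial_rate <- function(mu, L, mean_f) mu * L * mean_f

#' Early-phase mean frequency of the less-fit allele
#'
#' Selection on standing variation only (valid for `t << 1/s_av`, before new
#' mutations matter):
#' `f(s, t) = f_in / ((1 - f_in) * exp(t * s) + f_in)`.
#' Independent of the intrinsic DFE; for small `f_in` it reduces to
#' `f_in * exp(-t * s)`, an exponential in `s` with log-slope `t`.
#'
#' @param s non-negative selection coefficient (vectorized).
#' @param t non-negative time in generations (vectorized).
#' @param f_in initial frequency in `[0, 1]`.
#' @return mean less-fit allele frequency in `[0, f_in]`.
#' @export
freq_early <- function(s, t, f_in) {
  stopifnot(all(s >= 0), all(t >= 0), f_in >= 0, f_in <= 1)
  f_in / ((1 - f_in) * exp(t * s) + f_in)
}

#' Analytic log-slope of the early-phase frequency
#'
#' `beta = -d log f / d s` evaluated on [freq_early()]:
#' `beta = t * (1 - f_in) * exp(t*s) / ((1 - f_in) * exp(t*s) + f_in)`.
#' Tends to `t` as `f_in -> 0`; equals 0 at `t = 0`.
#'
#' @inheritParams freq_early
#' @return log-slope (units of 1/s, i.e. generations).
#' @export
log_slope_early <- function(s, t, f_in) {
  stopifnot(all(s >= 0), all(t >= 0), f_in >= 0, f_in <= 1)
  e <- (1 - f_in) * exp(t * s)
  t * e / (e + f_in)
}

#' Fermi occupancy statistics
#'
#' Quasi-equilibrium occupancy of a two-state site under a slowly moving
#' fitness wave: solving `f = (1 - f) * exp(-beta * s)` gives
#' `f = 1 / (exp(beta * s) + 1)`. The early-phase solution [freq_early()] is
#' the same law with `beta = t` and chemical-potential-like offset
#' `log((1 - f_in) / f_in)`.
#'
#' @param s selection coefficient (any sign; vectorized).
#' @param beta non-negative log-slope.
#' @return occupancy in `(0, 1)`.
#' @export
fermi_frequency <- function(s, beta) {
  stopifnot(all(beta >= 0))
  1 / (exp(beta * s) + 1)
}

#' Traveling-wave solution: adaptation rate and interference boundary
#'
#' Closed forms for the stationary traveling wave with a Gaussian-tailed
#' intrinsic distribution of scale `s_av`:
#' `x_c^2 = 2 * v * log(N * s_av)` and
#' `x_c / v = log(s_av / U_b) / (sqrt(pi) * s_av)`, giving
#' `v = 2 * pi * s_av^2 * log(N * s_av) / log(s_av / U_b)^2`.
#' `v` is the mean rate of adaptation (fitness^2 per generation scale) and
#' `x_c` the fitness lead at the clonal-interference boundary.
#'
#' Regime diagnostics are attached and reported by `print()`: the closed
#' forms assume the multiple-mutation regime `v >> s_av^2`, equivalently
#' `log(N * s_av) >> log(s_av / U_b)^2`, and the truncated fixation
#' probability additionally assumes `x_c^2 >> v`. Violations are warnings,
#' not errors: moderate parameter sets remain informative outside the deep
#' asymptotic regime.
#'
#' @param N population size (`N * s_av > 1` required).
#' @param s_av mean of the intrinsic DFE.
#' @param U_b beneficial mutation rate per genome per generation
#'   (`U_b < s_av` required).
#' @return An object of class `wave_solution`: list with `v`, `x_c`,
#'   `phi_prime0` (= `x_c / (2 N v)`), `N`, `s_av`, `U_b`, and `diagnostics`.
#' @export
adaptation_rate <- function(N, s_av, U_b) {
  if (N * s_av <= 1)
    stop("requires N * s_av > 1: log(N * s_av) must be positive", call. = FALSE)
  if (s_av / U_b <= 1)
    stop("requires s_av > U_b: log(s_av / U_b) must be positive", call. = FALSE)
  logNs <- log(N * s_av)
  logSU <- log(s_av / U_b)
  v <- 2 * pi * s_av^2 * logNs / logSU^2
  x_c <- sqrt(2 * v * logNs)
  structure(list(
    v = v, x_c = x_c,
    phi_prime0 = x_c / (2 * N * v),
    N = as.integer(N), s_av = s_av, U_b = U_b,
    diagnostics = c(v_over_sav2 = v / s_av^2,
                    logNs_over_logSU2 = logNs / logSU^2,
                    xc2_over_v = x_c^2 / v)
  ), class = "wave_solution")
}

#' @export
print.wave_solution <- function(x, ...) {
  cat(sprintf("Traveling-wave solution (N = %d, s_av = %g, U_b = %g):\n",
              x$N, x$s_av, x$U_b))
  cat(sprintf("  v = %.4g  x_c = %.4g  phi'(0) = %.4g\n",
              x$v, x$x_c, x$phi_prime0))
  d <- x$diagnostics
  cat(sprintf("  regime diagnostics: v/s_av^2 = %.3g, log(Ns)/log^2(s/U_b) = %.3g, x_c^2/v = %.3g\n",
              d[1], d[2], d[3]))
  if (d["xc2_over_v"] < 10)
    cat("  note: x_c^2/v < 10 - the truncated fixation probability is approximate here\n")
  invisible(x)
}

# (exp(a*s) - 1)/s with the s -> 0 limit handled by series below a threshold
.expm1_over_s <- function(s, a) {
  out <- numeric(length(s))
  small <- s < 1e-6 / a
  out[small] <- a * (1 + a * s[small] / 2 + (a * s[small])^2 / 6)
  out[!small] <- expm1(a * s[!small]) / s[!small]
  out
}

#' Fixation probability of a beneficial mutation under clonal interference
#'
#' Probability that a new beneficial mutation of effect `s` escapes loss at
#' the high-fitness edge of the wave and ultimately fixes. The default
#' truncated form,
#' `phi(s) = v / (N * x_c) * exp(-s^2 / (2 v)) * (exp(s * x_c / v) - 1) / s`,
#' is valid when `x_c^2 >> v`; it satisfies `phi(0) = 1/N` (neutral limit)
#' exactly and is far below the unlinked one-locus value `phi = s` because of
#' interference among linked sites.
#'
#' With `full = TRUE` the neglected second term is restored by numerical
#' quadrature with prefactor `A = (1/N) / (x_c/v + 1/x_c)`:
#' `phi(s) = A * [exp(-s^2/2v) (exp(s x_c/v)-1)/s +
#'   exp(x_c^2/2v) (v/x_c) * integral_{x_c}^{Inf} dx/x exp(-(x-s)^2/2v)]`.
#'
#' @param s non-negative selection coefficient (vectorized).
#' @param sol a [adaptation_rate()] `wave_solution`.
#' @param full use the untruncated two-term form.
#' @return fixation probability.
#' @export
fixation_probability <- function(s, sol, full = FALSE) {
  stopifnot(inherits(sol, "wave_solution"))
  if (any(s < 0)) stop("`s` must be non-negative", call. = FALSE)
  v <- sol$v; x_c <- sol$x_c; N <- sol$N
  term1 <- exp(-s^2 / (2 * v)) * .expm1_over_s(s, x_c / v)
  if (!full) return(v / (N * x_c) * term1)
  A <- (1 / N) / (x_c / v + 1 / x_c)
  # tail integral over the wave nose; the exp(x_c^2/2v) prefactor is folded
  # into the integrand to avoid overflow, and the integrand decays as a
  # Gaussian of sd sqrt(v) beyond x_c, so a finite upper limit is exact to
  # double precision
  term2 <- vapply(s, function(si) {
    (v / x_c) * stats::integrate(
      function(x) exp((x_c^2 - (x - si)^2) / (2 * v)) / x,
      lower = x_c, upper = x_c + 12 * sqrt(v) + si,
      rel.tol = 1e-10)$value
  }, numeric(1))
  A * (term1 + term2)
}

#' Slope of the fixation probability at s = 0
#'
#' Closed form `phi'(0) = log(s_av / U_b) / (2 * sqrt(pi) * N * s_av)`,
#' identical to `x_c / (2 N v)` from the traveling-wave solution. This is the
#' quantity that sets the late-time growth rate of the log-slope `beta(t)`.
#'
#' @inheritParams adaptation_rate
#' @return positive number.
#' @export
phi_prime_zero <- function(N, s_av, U_b) {
  if (s_av / U_b <= 1)
    stop("requires s_av > U_b: log(s_av / U_b) must be positive", call. = FALSE)
  log(s_av / U_b) / (2 * sqrt(pi) * N * s_av)
}

#' Traveling-wave mean frequency of the less-fit allele
#'
#' For `t >= t0` the mean frequency is dominated by monomorphic less-fit
#' sites, lost through fixation of new beneficial alleles at rate
#' `mu * N * phi(s)` per site:
#' `f(s, t) = f_in * exp(-t0 * s) * exp(-mu * N * phi(s) * (t - t0))`,
#' the solution of `df/dt = -mu * N * phi(s) * f` with the early-phase
#' exponential as initial condition at `t0`. `phi` is time-independent in the
#' stationary wave.
#'
#' @param s non-negative selection coefficient (vectorized).
#' @param t time `>= t0`.
#' @param params a [theory_params()] object.
#' @param sol a `wave_solution`.
#' @return mean frequency.
#' @export
freq_traveling <- function(s, t, params, sol) {
  stopifnot(inherits(params, "theory_params"), inherits(sol, "wave_solution"))
  if (any(t < params$t0))
    stop("`t` < t0: the pre-wave phase is described by freq_early()",
         call. = FALSE)
  phi <- fixation_probability(s, sol)
  params$f_in * exp(-params$t0 * s - params$mu * params$N * phi * (t - params$t0))
}

#' Traveling-wave log-slope
#'
#' Linear growth `beta(t) = t0 + mu * N * phi'(0) * (t - t0)` for `t >= t0`,
#' obtained by expanding the exponent of [freq_traveling()] to first order in
#' `s`. The growth rate `d beta / d t = mu * N * phi'(0)` is much smaller
#' than the early-phase rate 1, because fixation under clonal interference is
#' slow.
#'
#' @param t time `>= t0` (vectorized).
#' @param params a [theory_params()] object.
#' @param sol a `wave_solution`.
#' @return log-slope `beta(t)`.
#' @export
slope_traveling <- function(t, params, sol) {
  stopifnot(inherits(params, "theory_params"), inherits(sol, "wave_solution"))
  if (any(t < params$t0))
    stop("`t` < t0: the pre-wave phase has beta = t", call. = FALSE)
  params$t0 + params$mu * params$N * sol$phi_prime0 * (t - params$t0)
}

#' Observable density of established beneficial mutations
#'
#' The distribution of naturally arising beneficial mutations is
#' `DFE(s, t) = f(s, t) * g(s)`: beneficial mutations can only occur at sites
#' currently carrying the less-fit allele. Experiments that count established
#' mutations additionally weight by the fixation probability, observing
#' `f * g * phi`. Because `f` is exponential in `s` with a slope that grows
#' in time while `g` has a fixed scale, the product appears exponential on a
#' log plot once `beta * s_av` is large — whatever the shape of `g`.
#'
#' @param f mean less-fit allele frequency (vectorized).
#' @param g intrinsic density at `s`.
#' @param phi optional fixation probability; omit for the bare `DFE = f * g`.
#' @return non-negative density values.
#' @export
observed_dfe <- function(f, g, phi = NULL) {
  stopifnot(all(f >= 0), all(f <= 1), all(g >= 0))
  if (is.null(phi)) return(f * g)
  stopifnot(all(phi >= 0), all(phi <= 1))
  f * g * phi
}

#' Theory curves as a tidy table
#'
#' Evaluates the piecewise prediction (early phase for `t < t0`, traveling
#' wave for `t >= t0`) on a grid, for overlay on simulation output.
#'
#' @param times numeric vector of generations.
#' @param s_grid numeric vector of selection coefficients.
#' @param params a [theory_params()] object.
#' @param sol a `wave_solution`.
#' @return data.frame with columns `t`, `s`, `f_theory`, `beta_theory`.
#' @export
theory_curves <- function(times, s_grid, params, sol) {
  grid <- expand.grid(s = s_grid, t = times)
  early <- grid$t < params$t0
  f <- numeric(nrow(grid))
  f[early] <- freq_early(grid$s[early], grid$t[early], params$f_in)
  if (any(!early))
    f[!early] <- freq_traveling(grid$s[!early], grid$t[!early], params, sol)
  beta_t <- ifelse(times < params$t0, times,
                   slope_traveling(pmax(times, params$t0), params, sol))
  data.frame(t = grid$t, s = grid$s, f_theory = f,
             beta_theory = rep(beta_t, each = length(s_grid)))
}
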