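test_that("early-phase frequency has the logistic-decay form", {
  expect_equal(freq_early(0.3, 0, 0.2), 0.2)
  expect_equal(freq_early(0, 57, 0.2), 0.2)
  expect_equal(freq_early(0.05, 20, 0.2), 0.2 / (0.8 * exp(1) + 0.2),
               tolerance = 1e-12)
  expect_equal(0.2 / (0.8 * exp(1) + 0.2), 0.08422, tolerance = 1e-4)

  # bounded by f_in, decreasing in s and t
  s <- seq(0, 0.2, by = 0.01)
  f5 <- freq_early(s, 5, 0.2)
  f9 <- freq_early(s, 9, 0.2)
  expect_true(all(f5 > 0 & f5 <= 0.2))
  expect_true(all(diff(f5) < 0))
  expect_true(all(f9[-1] < f5[-1]))
})

test_that("analytic log-slope matches its numerical derivative and limits", {
  expect_equal(log_slope_early(0, 10, 0.2), 8)     # t * (1 - f_in) at s = 0
  expect_equal(log_slope_early(0.07, 0, 0.2), 0)   # flat at t = 0
  expect_equal(log_slope_early(0.05, 12, 1e-9), 12, tolerance = 1e-6)

  h <- 1e-6
  for (s in c(0.01, 0.05, 0.12)) {
    num <- -(log(freq_early(s + h, 15, 0.3)) - log(freq_early(s - h, 15, 0.3))) / (2 * h)
    expect_equal(log_slope_early(s, 15, 0.3), num, tolerance = 1e-6)
  }
})

test_that("Fermi statistics solves its self-consistency and subsumes the early phase", {
  expect_equal(fermi_frequency(0, 4), 0.5)
  expect_equal(fermi_frequency(3, 1), 1 / (exp(3) + 1), tolerance = 1e-12)
  expect_equal(1 / (exp(3) + 1), 0.04743, tolerance = 1e-4)

  # f = (1 - f) exp(-beta s) holds
  f <- fermi_frequency(0.04, 25)
  expect_equal(f, (1 - f) * exp(-25 * 0.04), tolerance = 1e-12)

  # identity with the early phase: f_in = 1/2 gives pure Fermi with beta = t,
  # and generally freq_early = 1/(exp(ts + log((1-f_in)/f_in)) + 1)
  grid <- expand.grid(s = c(0, 0.02, 0.1), t = c(0, 4, 30),
                      f_in = c(0.05, 0.2, 0.5, 0.9))
  expect_equal(freq_early(grid$s, grid$t, 0.5)[grid$f_in == 0.5],
               fermi_frequency(grid$s, grid$t)[grid$f_in == 0.5])
  lhs <- freq_early(grid$s, grid$t, grid$f_in)
  rhs <- 1 / (exp(grid$t * grid$s + log((1 - grid$f_in) / grid$f_in)) + 1)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("the wave closed forms satisfy their defining relations", {
  sol <- adaptation_rate(1e4, 0.05, 1e-5)
  expect_equal(sol$x_c^2 / (2 * sol$v), log(1e4 * 0.05), tolerance = 1e-12)
  expect_equal(sol$x_c / sol$v, log(0.05 / 1e-5) / (sqrt(pi) * 0.05),
               tolerance = 1e-12)
  expect_equal(sol$v, 1.346e-3, tolerance = 1e-3)
  expect_equal(sol$x_c, 0.1293, tolerance = 1e-3)

  # doubling log(N s_av) at fixed s_av, U_b doubles v: N2 = N^2 * s_av
  sol2 <- adaptation_rate(1e8 * 0.05, 0.05, 1e-5)
  expect_equal(sol2$v / sol$v, 2, tolerance = 1e-12)

  expect_error(adaptation_rate(10, 0.05, 1e-5), "N \\* s_av")
  expect_error(adaptation_rate(1e4, 0.05, 0.2), "s_av > U_b")
})

test_that("fixation probability has the neutral limit, slope, and monotonicity", {
  sol <- adaptation_rate(1e4, 0.05, 1e-5)
  N <- 1e4
  expect_equal(fixation_probability(0, sol), 1 / N, tolerance = 1e-12)

  # three routes to phi'(0) agree: closed form, x_c/(2Nv), central difference
  p0 <- phi_prime_zero(1e4, 0.05, 1e-5)
  expect_equal(p0, 4.805e-3, tolerance = 1e-3)
  expect_equal(p0, sol$x_c / (2 * N * sol$v), tolerance = 1e-9)
  h <- 1e-4 * sol$v / sol$x_c
  num <- (fixation_probability(h, sol) - fixation_probability(0, sol)) / h
  expect_equal(num, p0, tolerance = 1e-3)
  # first-order expansion is accurate near the origin
  expect_equal(fixation_probability(h, sol), 1 / N + p0 * h, tolerance = 1e-6)

  # monotone below the interference boundary x_c, where the truncated form
  # is meaningful (the Gaussian factor wins beyond the wave nose)
  s <- seq(0, 0.85 * sol$x_c, length.out = 30)
  phi <- fixation_probability(s, sol)
  expect_true(all(diff(phi) > 0))
  expect_true(all(phi >= 1 / N))
  expect_error(fixation_probability(-0.01, sol), "non-negative")
})

test_that("the truncated fixation probability approximates the full two-term form", {
  sol <- adaptation_rate(1e4, 0.05, 1e-5)
  expect_gt(sol$diagnostics[["xc2_over_v"]], 10)
  s <- c(0.01, 0.05, 0.1)
  trunc <- fixation_probability(s, sol)
  full <- fixation_probability(s, sol, full = TRUE)
  expect_true(all(abs(full / trunc - 1) < 0.10))
})

test_that("traveling-wave frequency solves the fixation-driven decay ODE", {
  skip_if_not_installed("deSolve")
  sol <- adaptation_rate(1e4, 0.05, 1e-5)
  tp <- theory_params(f_in = 0.2, s_av = 0.05, N = 1e4, mu = 5e-4,
                      U_b = 1e-5, t0 = 20)
  s_vals <- c(0.005, 0.03, 0.08)
  expect_equal(freq_traveling(s_vals, 20, tp, sol),
               0.2 * exp(-20 * s_vals), tolerance = 1e-12)
  expect_error(freq_traveling(0.05, 10, tp, sol), "freq_early")

  for (s in s_vals) {
    rate <- 5e-4 * 1e4 * fixation_probability(s, sol)
    ode <- deSolve::ode(y = c(f = 0.2 * exp(-20 * s)), times = c(20, 45, 80),
                        func = function(t, y, p) list(-rate * y),
                        parms = NULL, rtol = 1e-12, atol = 1e-14)
    expect_equal(freq_traveling(s, c(45, 80), tp, sol),
                 unname(ode[2:3, "f"]), tolerance = 1e-9)
  }
})

test_that("the wave log-slope grows linearly at rate mu N phi'(0)", {
  sol <- adaptation_rate(1e4, 0.05, 1e-5)
  tp <- theory_params(f_in = 0.2, s_av = 0.05, N = 1e4, mu = 5e-4,
                      U_b = 1e-5, t0 = 20)
  expect_equal(slope_traveling(20, tp, sol), 20)
  expect_equal(slope_traveling(60, tp, sol), 20.96, tolerance = 1e-3)
  b <- slope_traveling(seq(20, 120, 10), tp, sol)
  expect_equal(diff(diff(b)), rep(0, 9), tolerance = 1e-12)
  expect_equal(diff(b)[1] / 10, 5e-4 * 1e4 * sol$phi_prime0, tolerance = 1e-12)
  expect_error(slope_traveling(5, tp, sol), "beta = t")
})

test_that("an exponential occupancy times any intrinsic density looks exponential", {
  expect_equal(observed_dfe(0, 3.1, 0.5), 0)
  expect_equal(observed_dfe(0.1, 2, 1e-3), 2e-4)
  expect_equal(observed_dfe(0.1, 2), 0.2)

  # beta * s_av >= 3: log(f * g) is nearly linear over s in [s_av, 4 s_av]
  dfe <- intrinsic_dfe(0.05)
  s <- seq(0.05, 0.2, length.out = 50)
  for (beta in c(60, 120)) {
    y <- log(observed_dfe(freq_early(s, beta, 1e-3), intrinsic_density(s, dfe)))
    expect_gt(summary(lm(y ~ s))$r.squared, 0.98)
  }
})
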