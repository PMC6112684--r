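test_that("homogenization yields the expected phase structure", {
  m <- cs_model()
  p <- pair_protocol(-0.010)
  # eCB: LTP inactivates after 14 pairings -> exactly two phases split at 14 s
  ph <- ou_phases(m, "eCB", p)
  expect_equal(nrow(ph), 2)
  expect_equal(ph$t_start, c(0, 14))
  expect_equal(ph$t_end, c(14, 100))
  # stationary mean of phase 1 is -beta/alpha = Gamma_p / (Gamma_p + Gamma_d),
  # and the long-time variance is sigma2 / (2 |alpha|)
  ph1 <- ph[1, ]
  ph1$t_end <- 1e6
  lim <- ou_mean_var(ph1, 0, 1e6)
  expect_equal(lim$mean, -ph$beta[1] / ph$alpha[1], tolerance = 1e-9)
  expect_equal(lim$var, ph$sigma2[1] / (2 * abs(ph$alpha[1])), tolerance = 1e-9)
  # second phase has no LTP drive left
  expect_equal(ph$beta[2], 0)
  # NMDAR splits at its own inactivation time, 74 s
  pn <- ou_phases(m, "NMDAR", p)
  expect_equal(pn$t_start, c(0, 74))
  expect_equal(pn$alpha[2], 0)  # no LTD: frozen after inactivation
  expect_equal(pn$sigma2[2], 0)

  # a disabled pathway: a single phase with zero coefficients
  m0 <- toy_model(gamma_p = 0, gamma_d = 0, theta0_p = Inf, theta0_d = Inf)
  p0 <- ou_phases(m0, m0$pathways[[1]], pair_protocol(0.010, n = 10))
  expect_equal(nrow(p0), 1)
  expect_equal(unlist(p0[, c("alpha", "beta", "sigma2")]), c(0, 0, 0),
               ignore_attr = TRUE)
})

test_that("the duty-cycled drift matches the per-period gate open times", {
  m <- cs_model()
  p <- pair_protocol(-0.010)
  ph <- ou_phases(m, "eCB", p)
  tr1 <- calcium_trace(build_schedule(pair_protocol(-0.010, n = 1)), m$calcium)
  eta_p <- ca_time_above(tr1, 6, -0.5, 0.99)
  eta_d <- ca_time_above(tr1, 13.5, -0.5, 0.99)
  expect_equal(ph$beta[1], 290 * eta_p / m$tau, tolerance = 1e-12)
  expect_equal(-ph$alpha[1], (290 * eta_p + 250 * eta_d) / m$tau, tolerance = 1e-12)
  expect_equal(ph$sigma2[1], (eta_p + eta_d) / m$tau^2, tolerance = 1e-12)
})

test_that("mean and variance propagation is invariant under phase subdivision", {
  m <- cs_model()
  ph <- ou_phases(m, "eCB", pair_protocol(-0.010))
  # split each phase at interior points
  split_at <- function(ph, t) {
    i <- which(ph$t_start < t & t < ph$t_end)
    top <- ph[i, ]; bot <- ph[i, ]
    top$t_end <- t; bot$t_start <- t
    out <- dplyr::arrange(dplyr::bind_rows(ph[-i, ], top, bot), t_start)
    attr(out, "period") <- attr(ph, "period")
    out
  }
  ph2 <- split_at(split_at(ph, 7.3), 55.1)
  for (rho0 in c(0, 1)) {
    a <- ou_mean_var(ph, rho0, c(5, 14, 60, 100))
    b <- ou_mean_var(ph2, rho0, c(5, 14, 60, 100))
    expect_equal(a$mean, b$mean, tolerance = 1e-12)
    expect_equal(a$var, b$var, tolerance = 1e-12)
  }
})

test_that("moments agree with a fine-step ODE integration of the moment equations", {
  skip_if_not_installed("deSolve")
  m <- cs_model()
  ph <- ou_phases(m, "eCB", pair_protocol(-0.010))
  # integrate the moment ODEs phase by phase so the coefficient jump at the
  # inactivation time coincides with a step boundary
  y <- c(m = 0, v = 0)
  for (k in seq_len(nrow(ph))) {
    rhs <- function(t, y, parms)
      list(c(ph$alpha[k] * y[1] + ph$beta[k],
             2 * ph$alpha[k] * y[2] + ph$sigma2[k]))
    tt <- seq(ph$t_start[k], ph$t_end[k], by = 0.02)
    num <- deSolve::ode(y, tt, rhs, NULL, method = "rk4")
    y <- num[nrow(num), c("m", "v")]
  }
  cf <- ou_mean_var(ph, 0, 100)
  expect_equal(cf$mean, unname(y["m"]), tolerance = 1e-6)
  expect_equal(cf$var, unname(y["v"]), tolerance = 1e-6)
})

test_that("switch probabilities handle midpoints, degeneracy and resolution", {
  ph <- tibble::tibble(t_start = 0, t_end = 10, alpha = 0, beta = 0.05,
                       sigma2 = 1e-4)
  attr(ph, "period") <- 1
  # mean hits rho* exactly with positive variance: probability one half
  expect_equal(ou_switch_probs(ph, rho_star = 0.5, n = 10)$U, 0.5)
  # zero variance degenerates to a point mass
  ph0 <- ph; ph0$sigma2 <- 0
  expect_equal(ou_switch_probs(ph0, rho_star = 0.6, n = 10)$U, 0)
  expect_equal(ou_switch_probs(ph0, rho_star = 0.4, n = 10)$U, 1)
  expect_equal(ou_switch_probs(ph0, rho_star = 0.4, n = 10)$D, 0)
  # measurement resolution rounds unobservably small probabilities to zero
  ph$beta <- 0.0389
  raw <- ou_switch_probs(ph, rho_star = 0.5, n = 10)$U
  expect_true(raw > 0 && raw < 5e-4)
  expect_equal(ou_switch_probs(ph, rho_star = 0.5, n = 10, resolution = 1000)$U, 0)
  expect_error(ou_switch_probs(ph, rho_star = 0.5, n = 0), "n must be")
})

test_that("the mean-field solution refuses frequencies where calcium does not relax", {
  m <- cs_model()
  expect_error(analytic_stdp(m, pair_protocol(-0.010, freq = 30, n = 20)),
               "too high.*simulate_stdp")
  # 1 Hz passes the validity check
  expect_s3_class(analytic_stdp(m, pair_protocol(-0.010, n = 5)), "stdp_sim")
})

test_that("the linearized ensemble converges to the analytic Gaussian law", {
  # with the cubic drift disabled the Euler ensemble must follow the
  # piecewise Ornstein-Uhlenbeck law; Kolmogorov-Smirnov at alpha = 0.01
  m <- toy_model(gamma_p = 150, gamma_d = 60, theta0_p = 4, theta0_d = 8,
                 sigma = 5, tau = 100)
  p <- pair_protocol(0.010, n = 10)
  sim <- simulate_stdp(m, p, sim_settings(n_synapses = 10000, seed = 51,
                                          linearize = TRUE, return_states = TRUE))
  ph <- ou_phases(m, m$pathways[[1]], p)
  mv <- ou_mean_var(ph, 0, 10)
  ks <- suppressWarnings(
    stats::ks.test(sim$states[1:10000, 1], "pnorm", mv$mean, sqrt(mv$var)))
  expect_gt(ks$p.value, 0.01)
})

test_that("switch probabilities respond monotonically to the LTP drive", {
  base <- tibble::tibble(t_start = 0, t_end = 20, alpha = -0.05, beta = 0.02,
                         sigma2 = 5e-5)
  attr(base, "period") <- 1
  us <- vapply(seq(0.01, 0.04, by = 0.005), function(b) {
    ph <- base
    ph$beta <- b
    ph$alpha <- -(b + 0.01)  # Gamma_d fixed at 0.01 * tau
    ou_switch_probs(ph, rho_star = 0.5, n = 20)$U
  }, numeric(1))
  expect_true(all(diff(us) >= 0))
})
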