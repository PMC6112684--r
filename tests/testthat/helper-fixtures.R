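# Shared fixtures and independent oracles.

cs_model <- function() stdp_preset("corticostriatal")

pair_protocol <- function(dt, freq = 1, n = 100) {
  stdp_protocol("pair", dt = dt, freq = freq, n_pairings = n)
}

# A minimal single-pathway model for focused dynamics tests.
toy_model <- function(gamma_p = 200, gamma_d = 0, theta0_p = 5, theta0_d = Inf,
                      mu_p = Inf, mu_d = Inf, sigma = 1, tau = 100,
                      c_pre = 7, c_post = 17, tau_ca = 0.018, delay_d = 0) {
  synapse_model(
    calcium = calcium_params(c_pre, c_post, tau_ca, delay_d),
    pathways = pathway_params("X", gamma_p, gamma_d, theta0_p, theta0_d, mu_p, mu_d),
    tau = tau, rho_star = 0.5, sigma = sigma,
    readout = readout_params(3, 0.5, 1),
    n_synapses_default = 200, steps_per_second_default = 1000)
}

# Brute-force grid oracle for the calcium trace: forward-iterate the decay
# with impulses on a fine grid, independent of the closed-form evaluators.
grid_trace <- function(trace, t0, t1, dt = 1e-5) {
  tt <- seq(t0, t1, by = dt)
  cc <- numeric(length(tt))
  ii <- numeric(length(tt))
  events <- trace$events
  c_cur <- sum(events$amplitude[events$time <= t0] *
                 exp(-(t0 - events$time[events$time <= t0]) / trace$tau_ca))
  i_cur <- 0
  dec <- exp(-dt / trace$tau_ca)
  for (k in seq_along(tt)) {
    if (k > 1) {
      i_cur <- i_cur + c_cur * dt
      c_cur <- c_cur * dec
      hit <- events$time > tt[k - 1] & events$time <= tt[k]
      if (any(hit)) c_cur <- c_cur + sum(events$amplitude[hit])
    }
    cc[k] <- c_cur
    ii[k] <- i_cur
  }
  list(t = tt, c = cc, integral = ii)
}

# Memoized reference simulations of the cortico-striatal model, reused by
# several regime-level tests to keep the suite fast.
.sim_cache <- new.env(parent = emptyenv())
cs_reference_sim <- function(dt, seed = 1) {
  key <- sprintf("dt%+.3f_seed%d", dt, seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_stdp(cs_model(), pair_protocol(dt),
                                       sim_settings(seed = seed))
  }
  .sim_cache[[key]]
}

expect_within <- function(x, lo, hi, label = deparse(substitute(x))) {
  expect_true(all(x >= lo & x <= hi),
              label = sprintf("%s in [%g, %g] (got %s)", label, lo, hi,
                              paste(signif(x, 4), collapse = ", ")))
}
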