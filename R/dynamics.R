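#' Simulation settings
#'
#' Controls the ensemble Euler-Maruyama integration.  Fields left `NULL` are
#' resolved against the model and protocol by [simulate_stdp()]: the ensemble
#' size and the Euler resolution default to the model's preset values, the
#' window end to 1.5 s (rounded up) after the last spike so that the noise
#' gates are long closed and every efficacy has settled into a basin before
#' classification.  For the standard 100-pairing, 1 Hz protocol the resolved
#' defaults reproduce the reference discretization: window \[-1, 101\] s and
#' 102000 steps (204000 for the scenario presets).
#'
#' @param n_synapses Ensemble size N per initial state (the simulator always
#'   runs one ensemble started depressed and one started potentiated).
#' @param t_start,t_end Simulation window, seconds.
#' @param n_iter Number of Euler steps.
#' @param seed RNG seed (integer); all randomness of a run derives from it.
#' @param record_per_pairing If `TRUE`, record switch fractions just before
#'   every pairing (one correlated trajectory per pairing count, as when a
#'   single long protocol is probed at increasing pairing numbers); if
#'   `FALSE`, only after the final pairing.
#' @param linearize Drop the cubic bistable drift (used to validate the
#'   Ornstein-Uhlenbeck mean-field solution; not for production runs).
#' @param return_states Also return the final efficacies of both ensembles.
#' @return An object of class `"sim_settings"`.
#' @export
sim_settings <- function(n_synapses = NULL, t_start = -1, t_end = NULL,
                         n_iter = NULL, seed = 0L, record_per_pairing = TRUE,
                         linearize = FALSE, return_states = FALSE) {
  structure(list(n_synapses = n_synapses, t_start = t_start, t_end = t_end,
                 n_iter = n_iter, seed = as.integer(seed),
                 record_per_pairing = isTRUE(record_per_pairing),
                 linearize = isTRUE(linearize),
                 return_states = isTRUE(return_states)),
            class = "sim_settings")
}

resolve_settings <- function(model, protocol, settings) {
  s <- settings
  sched <- build_schedule(protocol)
  ca <- model$calcium
  ev_min <- min(sched$pre_times + ca$delay_d, sched$post_times)
  ev_max <- max(sched$pre_times + ca$delay_d, sched$post_times)
  s$n_synapses <- as.integer(s$n_synapses %||% model$n_synapses_default)
  s$t_end <- s$t_end %||% ceiling(ev_max + 1.5)
  s$n_iter <- as.integer(s$n_iter %||%
                           round((s$t_end - s$t_start) * model$steps_per_second_default))
  stopifnot_msg(s$n_synapses >= 1, "n_synapses must be >= 1")
  stopifnot_msg(s$t_start < s$t_end, "t_start must be < t_end")
  stopifnot_msg(s$n_iter >= 1, "n_iter must be >= 1")
  stopifnot_msg(ev_min >= s$t_start && ev_max <= s$t_end,
                sprintf("spike schedule [%g, %g] s does not fit the simulation window [%g, %g] s",
                        ev_min, ev_max, s$t_start, s$t_end))
  s$schedule <- sched
  s
}

# Absolute time after which a piecewise-model gate is inactivated.  The
# inactivation state is resolved at pairing resolution: a mechanism is
# responsive during pairing k if the cumulative calcium at the start of
# pairing k is still below mu, and switches off at the start of the first
# pairing for which it is not.  (In the fully-relaxing regime this is the
# continuous-time crossing rounded up to the next pairing boundary, the same
# convention [inactivation_pairing()] reports.)
gate_cutoff <- function(mu, trace, boundaries) {
  if (is.infinite(mu)) return(Inf)
  ib <- ca_integral(trace, boundaries)
  k <- which(ib >= mu)
  if (length(k) == 0) Inf else boundaries[k[1]]
}

#' Simulate an ensemble of synapses through a stimulation protocol
#'
#' Integrates, for every pathway of the model, two ensembles of `n_synapses`
#' efficacies (one started depressed at rho = 0, one potentiated at rho = 1)
#' through the protocol with an Euler-Maruyama scheme.  All pathways share
#' the same closed-form calcium trace but have independent noise.  Within
#' each Euler step the LTP/LTD gate open times are computed exactly from the
#' trace (closed-form threshold crossings), so gate durations carry no
#' discretization bias; the noise increment for a step has variance
#' `(sigma/tau)^2` times the step's open gate time.
#'
#' After the protocol the noise gates are closed and the deterministic
#' bistable drift preserves basins, so classifying efficacies against
#' `rho_star` at any later time yields the steady-state switch fractions:
#' `U` (fraction of the depressed-start ensemble found potentiated) and `D`
#' (fraction of the potentiated-start ensemble found depressed).
#'
#' @param model A [synapse_model()].
#' @param protocol A [stdp_protocol()].
#' @param settings A [sim_settings()]; `NULL` fields are resolved from the
#'   model and protocol.
#' @return An object of class `"stdp_sim"`; its `outcomes` element is a
#'   tibble with columns `pairing`, `pathway`, `U`, `D`.  Use [tidy()] /
#'   [glance()] / [total_change()] to attach the macroscopic readout.
#' @examples
#' \donttest{
#' m <- stdp_preset("corticostriatal")
#' p <- stdp_protocol("pair", dt = -0.010, freq = 1, n_pairings = 100)
#' sim <- simulate_stdp(m, p, sim_settings(seed = 1))
#' glance(sim)
#' }
#' @export
simulate_stdp <- function(model, protocol, settings = sim_settings()) {
  stopifnot_msg(inherits(model, "synapse_model"), "model must be a synapse_model")
  stopifnot_msg(inherits(protocol, "stimulation_protocol"), "protocol must be a stimulation_protocol")
  s <- resolve_settings(model, protocol, settings)
  trace <- calcium_trace(s$schedule, model$calcium)
  bounds <- pairing_boundaries(protocol, model$calcium)

  gates <- t(vapply(model$pathways, function(p) {
    c(p$gamma_p, p$theta0_p,
      if (model$threshold_model == "piecewise") gate_cutoff(p$mu_p, trace, bounds) else Inf,
      p$mu_p,
      p$gamma_d, p$theta0_d,
      if (model$threshold_model == "piecewise") gate_cutoff(p$mu_d, trace, bounds) else Inf,
      p$mu_d)
  }, numeric(8)))

  snap <- if (s$record_per_pairing && protocol$n_pairings > 1)
    c(bounds[-1], s$t_end) else s$t_end
  pairings <- if (s$record_per_pairing && protocol$n_pairings > 1)
    seq_len(protocol$n_pairings) else protocol$n_pairings

  dt <- (s$t_end - s$t_start) / s$n_iter
  set.seed(s$seed)
  res <- cpp_simulate(trace$events$time, trace$events$amplitude, trace$tau_ca,
                      gates, model$tau, model$rho_star, model$sigma,
                      match(model$threshold_model, c("piecewise", "exponential")) - 1L,
                      model$epsilon, s$t_start, dt, s$n_iter, s$n_synapses,
                      snap, s$linearize, s$return_states)

  nms <- pathway_names(model)
  outcomes <- tibble::tibble(
    pairing = rep(pairings, times = length(nms)),
    pathway = rep(nms, each = length(pairings)),
    U = as.vector(res$U),
    D = as.vector(res$D))
  outcomes <- outcomes[order(outcomes$pairing, match(outcomes$pathway, nms)), ]

  structure(list(model = model, protocol = protocol, settings = s,
                 engine = "simulate", outcomes = outcomes,
                 states = res$states),
            class = "stdp_sim")
}

#' Per-pairing ensemble outcomes
#'
#' Convenience wrapper around [simulate_stdp()] returning the per-pairing
#' switch fractions as a tibble: one row per (pairing count, pathway), where
#' the snapshot for pairing count n is taken just before pairing n + 1 (so
#' all snapshots share one realization and are statistically dependent, as
#' when one long protocol is probed at increasing pairing numbers).
#'
#' @inheritParams simulate_stdp
#' @return A tibble with columns `pairing`, `pathway`, `U`, `D`.
#' @export
per_pairing_outcomes <- function(model, protocol, settings = sim_settings()) {
  settings$record_per_pairing <- TRUE
  simulate_stdp(model, protocol, settings)$outcomes
}

#' @export
print.stdp_sim <- function(x, ...) {
  cat(sprintf("<stdp_sim> engine=%s, %s, N=%d per initial state, seed=%d\n",
              x$engine, format(x$protocol)[1] %||% "", x$settings$n_synapses,
              x$settings$seed))
  print(x$protocol)
  fin <- dplyr::filter(x$outcomes, .data$pairing == max(.data$pairing))
  print(fin)
  invisible(x)
}
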