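#' Homogenized Ornstein-Uhlenbeck phases for one pathway
#'
#' At low pairing frequency the calcium trace returns to baseline between
#' pairings, every pairing opens the LTP/LTD gates for the same durations
#' `eta_p`, `eta_d` (seconds per period), and the linearized efficacy SDE
#' becomes an Ornstein-Uhlenbeck process with piecewise-constant
#' coefficients.  With \eqn{\Gamma^x = \gamma^x \eta^x / T} (duty-cycled
#' over the period T = 1/F), a phase has
#' \deqn{\alpha = -(\Gamma^p + \Gamma^d)/\tau, \qquad \beta = \Gamma^p/\tau,}
#' stationary mean \eqn{\tilde\rho = \Gamma^p/(\Gamma^p+\Gamma^d)}, and
#' diffusion with variance rate \eqn{\sigma^2 (\eta^p + \eta^d)/(T \tau^2)}
#' per unit time.  Phases split at the inactivation times `t = T * n`
#' (with `n` from [inactivation_pairing()]) where a mechanism's
#' contribution drops out.
#'
#' @param model A [synapse_model()].
#' @param pathway A [pathway_params()] object (or a pathway name of
#'   `model`).
#' @param protocol A [stdp_protocol()].  The pairing frequency must be low
#'   enough that calcium relaxes below `1e-6` of one pairing's total impulse
#'   amplitude between pairings; otherwise this refuses and directs to
#'   [simulate_stdp()].
#' @return A tibble of phases with columns `t_start`, `t_end`, `alpha`,
#'   `beta`, `sigma2` (diffusion variance rate, 1/s) tiling
#'   `[0, n_pairings * T]`, plus attributes `period` and `pathway`.
#' @export
ou_phases <- function(model, pathway, protocol) {
  if (is.character(pathway)) pathway <- get_pathway(model, pathway)
  stopifnot_msg(inherits(pathway, "pathway_params"), "pathway must be a pathway_params object")
  ca <- model$calcium
  Tper <- 1 / protocol$freq

  one <- protocol
  one$n_pairings <- 1L
  tr1 <- calcium_trace(build_schedule(one), ca)
  ev_min <- min(tr1$events$time)
  amp_tot <- sum(tr1$events$amplitude)
  residual <- ca_value(tr1, ev_min + Tper)
  if (residual >= 1e-6 * amp_tot)
    stop(sprintf(paste0("pairing frequency %g Hz is too high for the mean-field ",
                        "solution (calcium residual %.3g of one pairing's amplitude ",
                        "between pairings); use simulate_stdp() instead"),
                 protocol$freq, residual / amp_tot), call. = FALSE)

  eta_p <- if (is.finite(pathway$theta0_p)) ca_time_above(tr1, pathway$theta0_p, ev_min, ev_min + Tper) else 0
  eta_d <- if (is.finite(pathway$theta0_d)) ca_time_above(tr1, pathway$theta0_d, ev_min, ev_min + Tper) else 0

  n_p <- inactivation_pairing(pathway$mu_p, protocol, ca)
  n_d <- inactivation_pairing(pathway$mu_d, protocol, ca)
  t_total <- protocol$n_pairings * Tper
  brk <- c(0, t_total)
  if (!is.na(n_p)) brk <- c(brk, n_p * Tper)
  if (!is.na(n_d)) brk <- c(brk, n_d * Tper)
  brk <- sort(unique(brk[brk <= t_total]))

  phases <- lapply(seq_len(length(brk) - 1), function(k) {
    t0 <- brk[k]
    ep <- if (!is.na(n_p) && t0 >= n_p * Tper) 0 else eta_p
    ed <- if (!is.na(n_d) && t0 >= n_d * Tper) 0 else eta_d
    gp <- pathway$gamma_p * ep / Tper
    gd <- pathway$gamma_d * ed / Tper
    tibble::tibble(
      t_start = t0, t_end = brk[k + 1],
      alpha = -(gp + gd) / model$tau,
      beta = gp / model$tau,
      sigma2 = model$sigma^2 * (ep + ed) / (Tper * model$tau^2))
  })
  out <- dplyr::bind_rows(phases)
  attr(out, "period") <- Tper
  attr(out, "pathway") <- pathway$name
  out
}

#' Mean and variance of the homogenized efficacy process
#'
#' Propagates the Gaussian law of the piecewise-constant-coefficient
#' Ornstein-Uhlenbeck process exactly across phases: within a phase of
#' length L,
#' \deqn{m \mapsto m e^{\alpha L} - \frac{\beta}{\alpha}(1 - e^{\alpha L}),
#'  \qquad v \mapsto v e^{2\alpha L} - \frac{\sigma^2}{2\alpha}(1 - e^{2\alpha L})}
#' (with the obvious limits for \eqn{\alpha = 0}).  The variance is 0 at
#' t = 0.
#'
#' @param phases An [ou_phases()] tibble.
#' @param rho0 Initial efficacy.
#' @param t Time(s) within the tiled phases, seconds.
#' @return A tibble with columns `t`, `mean`, `var`.
#' @export
ou_mean_var <- function(phases, rho0, t) {
  stopifnot_msg(all(t >= phases$t_start[1] - 1e-12) &&
                  all(t <= phases$t_end[nrow(phases)] + 1e-12),
                sprintf("t must lie within the tiled phases [%g, %g] s",
                        phases$t_start[1], phases$t_end[nrow(phases)]))
  one <- function(tt) {
    m <- rho0; v <- 0
    for (k in seq_len(nrow(phases))) {
      if (tt <= phases$t_start[k]) break
      len <- min(tt, phases$t_end[k]) - phases$t_start[k]
      a <- phases$alpha[k]; b <- phases$beta[k]; s2 <- phases$sigma2[k]
      if (a == 0) {
        m <- m + b * len
        v <- v + s2 * len
      } else {
        e1 <- exp(a * len); e2 <- exp(2 * a * len)
        m <- m * e1 - (b / a) * (1 - e1)
        v <- v * e2 - (s2 / (2 * a)) * (1 - e2)
      }
    }
    c(m, v)
  }
  res <- vapply(t, one, numeric(2))
  tibble::tibble(t = t, mean = res[1, ], var = res[2, ])
}

#' Closed-form switch probabilities
#'
#' Gaussian switch probabilities of the homogenized process after `n`
#' pairings: `U = P(rho(nT) > rho_star | rho(0) = 0)` and
#' `D = P(rho(nT) < rho_star | rho(0) = 1)`, evaluated through the error
#' function, \eqn{U = \frac12\big(1 + \mathrm{erf}\big((m - \rho_*) /
#' \sqrt{2 v}\big)\big)} and symmetrically for D.  Zero variance degenerates
#' to a point mass (U, D in {0, 1}).
#'
#' Optionally the probabilities are rounded to the measurement resolution of
#' an N-synapse ensemble (`round(p * N) / N`): the mean-field solution
#' stands in for a finite-ensemble experiment, and probabilities below
#' `1/(2N)` are not observable in it.
#'
#' @param phases An [ou_phases()] tibble.
#' @param rho_star Bistability midpoint.
#' @param period Pairing period T = 1/F, seconds (defaults to the `period`
#'   attribute of `phases`).
#' @param n Pairing count(s) (>= 1).
#' @param resolution Ensemble size N whose measurement resolution to apply,
#'   or `Inf` for raw probabilities.
#' @return A tibble with columns `pairing`, `U`, `D`.
#' @export
ou_switch_probs <- function(phases, rho_star, n, period = attr(phases, "period"),
                            resolution = Inf) {
  stopifnot_msg(all(n >= 1), "pairing count n must be >= 1")
  stopifnot_msg(is.numeric(period) && period > 0, "period must be > 0 (seconds)")
  erf <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1
  up <- ou_mean_var(phases, 0, n * period)
  dn <- ou_mean_var(phases, 1, n * period)
  U <- ifelse(up$var > 0,
              0.5 * (1 + erf((up$mean - rho_star) / sqrt(2 * up$var))),
              as.numeric(up$mean > rho_star))
  D <- ifelse(dn$var > 0,
              0.5 * (1 - erf((dn$mean - rho_star) / sqrt(2 * dn$var))),
              as.numeric(dn$mean < rho_star))
  if (is.finite(resolution)) {
    U <- round(U * resolution) / resolution
    D <- round(D * resolution) / resolution
  }
  tibble::tibble(pairing = as.integer(n), U = U, D = D)
}

#' Mean-field solution of a full STDP protocol
#'
#' Computes per-pathway switch fractions for every pairing count with the
#' closed-form Ornstein-Uhlenbeck solution, returning an object of the same
#' shape as [simulate_stdp()] (so [tidy()], [glance()] and [total_change()]
#' apply unchanged).  Only valid at low pairing frequency; see
#' [ou_phases()].
#'
#' @inheritParams simulate_stdp
#' @param resolution Ensemble size whose measurement resolution to emulate
#'   (default: the model's default ensemble size; `Inf` for raw
#'   probabilities).
#' @return An object of class `"stdp_sim"` with `engine = "analytic"`.
#' @export
analytic_stdp <- function(model, protocol, resolution = NULL) {
  stopifnot_msg(inherits(model, "synapse_model"), "model must be a synapse_model")
  stopifnot_msg(inherits(protocol, "stimulation_protocol"), "protocol must be a stimulation_protocol")
  resolution <- resolution %||% model$n_synapses_default
  ns <- seq_len(protocol$n_pairings)
  outcomes <- purrr::map_dfr(model$pathways, function(p) {
    ph <- ou_phases(model, p, protocol)
    dplyr::mutate(ou_switch_probs(ph, model$rho_star, ns, resolution = resolution),
                  pathway = p$name, .after = "pairing")
  })
  outcomes <- outcomes[order(outcomes$pairing,
                             match(outcomes$pathway, pathway_names(model))), ]
  structure(list(model = model, protocol = protocol,
                 settings = sim_settings(n_synapses = if (is.finite(resolution))
                   as.integer(resolution) else model$n_synapses_default),
                 engine = "analytic", outcomes = outcomes),
            class = "stdp_sim")
}
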