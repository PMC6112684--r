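#' Closed-form calcium trace
#'
#' Represents the postsynaptic calcium concentration as a sum of decaying
#' exponentials: every postsynaptic spike contributes an instantaneous jump
#' `c_post` at the spike time, every presynaptic spike a jump `c_pre` at the
#' spike time plus the influx delay `delay_d`, and between jumps the
#' concentration decays with time constant `tau_ca`.  The trace is exact
#' (never gridded); [ca_value()], [ca_integral()] and [ca_time_above()]
#' evaluate it analytically.
#'
#' @param schedule A [build_schedule()] result (or any list with sorted
#'   `pre_times` / `post_times`).
#' @param calcium A [calcium_params()] object.
#' @return An object of class `"calcium_trace"`: a list with `events` (a
#'   tibble with columns `time`, `amplitude`, sorted by time) and `tau_ca`.
#' @export
calcium_trace <- function(schedule, calcium) {
  stopifnot_msg(inherits(calcium, "calcium_params"), "calcium must be a calcium_params object")
  times <- c(schedule$pre_times + calcium$delay_d, schedule$post_times)
  amps <- c(rep(calcium$c_pre, length(schedule$pre_times)),
            rep(calcium$c_post, length(schedule$post_times)))
  keep <- amps > 0
  ord <- order(times[keep])
  structure(list(events = tibble::tibble(time = times[keep][ord],
                                         amplitude = amps[keep][ord]),
                 tau_ca = calcium$tau_ca),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> %d impulse(s), tau_ca = %g s\n",
              nrow(x$events), x$tau_ca))
  invisible(x)
}

# concentration immediately after each event (right-continuous)
trace_peaks <- function(trace) {
  tt <- trace$events$time; aa <- trace$events$amplitude
  n <- length(tt)
  if (n == 0) return(numeric(0))
  pk <- numeric(n); acc <- 0; tprev <- tt[1]
  for (i in seq_len(n)) {
    acc <- acc * exp(-(tt[i] - tprev) / trace$tau_ca) + aa[i]
    tprev <- tt[i]
    pk[i] <- acc
  }
  pk
}

#' Evaluate a calcium trace
#'
#' `ca_value()` returns the concentration c(t); `ca_integral()` the running
#' integral \eqn{\int_{-\infty}^{t} c(s) ds} (the cumulative calcium that
#' drives threshold inactivation; the trace is 0 before its first impulse).
#' Both are exact closed forms and right-continuous at impulse times.
#'
#' @param trace A [calcium_trace()].
#' @param t Time(s) at which to evaluate, seconds.
#' @return Numeric vector of concentrations (`ca_value`) or
#'   concentration-seconds (`ca_integral`).
#' @examples
#' tr <- calcium_trace(list(pre_times = 0, post_times = numeric(0)),
#'                     calcium_params(7, 17.1, 0.018, 0))
#' ca_value(tr, 0.018)      # 7 * exp(-1)
#' ca_integral(tr, Inf)     # 7 * 0.018
#' @export
ca_value <- function(trace, t) {
  ev <- trace$events
  vapply(t, function(ti) {
    sel <- ev$time <= ti
    if (!any(sel)) return(0)
    sum(ev$amplitude[sel] * exp(-(ti - ev$time[sel]) / trace$tau_ca))
  }, numeric(1))
}

#' @rdname ca_value
#' @export
ca_integral <- function(trace, t) {
  ev <- trace$events
  vapply(t, function(ti) {
    sel <- ev$time <= ti
    if (!any(sel)) return(0)
    sum(ev$amplitude[sel] * trace$tau_ca *
          (1 - exp(-(ti - ev$time[sel]) / trace$tau_ca)))
  }, numeric(1))
}

#' Time spent above a calcium threshold
#'
#' Lebesgue measure of \eqn{\{t \in [t0, t1] : c(t) \ge \theta\}}, computed
#' exactly: between impulses the trace decays monotonically, so each
#' inter-impulse interval contributes at most one downward crossing, located
#' in closed form.  The comparison is closed at equality.
#'
#' @param trace A [calcium_trace()].
#' @param theta Threshold (> 0).
#' @param t0,t1 Window bounds, seconds (`t0 < t1`; `t1 = Inf` allowed).
#' @return Time above threshold, seconds.
#' @export
ca_time_above <- function(trace, theta, t0 = -Inf, t1 = Inf) {
  stopifnot_msg(theta > 0, "theta must be > 0")
  stopifnot_msg(t0 < t1, "window requires t0 < t1")
  if (is.infinite(theta)) return(0)
  ev <- trace$events
  n <- nrow(ev)
  if (n == 0) return(0)
  peaks <- trace_peaks(trace)
  total <- 0
  for (i in seq_len(n)) {
    a <- ev$time[i]
    b <- if (i < n) ev$time[i + 1] else Inf
    if (peaks[i] < theta) next
    # c(t) = peaks[i] * exp(-(t - a)/tau) >= theta until the crossing
    cross <- a + trace$tau_ca * log(peaks[i] / theta)
    lo <- max(a, t0); hi <- min(b, t1, cross)
    if (hi > lo) total <- total + (hi - lo)
  }
  total
}

#' Pairing count at which an inactivation level is reached
#'
#' For a repeated protocol in the fully-relaxing regime (calcium decays to
#' baseline between pairings), each completed pairing adds a fixed amount
#' `A * tau_ca` of cumulative calcium, where `A` is the summed impulse
#' amplitude of one pairing (for the pair pattern, `c_pre + c_post`).  The
#' mechanism with inactivation level `mu` therefore switches off after
#' pairing `n = ceiling(mu / (A * tau_ca))` -- that pairing is the last one
#' during which it is still responsive.
#'
#' @param mu Inactivation level (concentration-seconds; `Inf` = never).
#' @param protocol A [stdp_protocol()].  The pairing frequency must be low
#'   enough for per-pairing contributions to be well separated (the caller's
#'   responsibility; see the mean-field validity discussion in the vignette).
#' @param calcium A [calcium_params()] object.
#' @return The inactivation pairing index (integer), or `NA` if `mu` is
#'   infinite or unreachable within `protocol$n_pairings`.
#' @examples
#' p <- stdp_protocol("pair", dt = -0.010, freq = 1, n_pairings = 100)
#' cp <- calcium_params(7, 17.1, 0.018, 0.010)
#' inactivation_pairing(6, p, cp)   # 14
#' inactivation_pairing(32, p, cp)  # 74
#' @export
inactivation_pairing <- function(mu, protocol, calcium) {
  if (is.infinite(mu)) return(NA_integer_)
  off <- pairing_offsets(protocol)
  amp <- length(off$pre) * calcium$c_pre + length(off$post) * calcium$c_post
  per_pairing <- amp * calcium$tau_ca
  if (per_pairing <= 0) return(NA_integer_)
  n <- as.integer(ceiling(mu / per_pairing))
  n <- max(n, 1L)
  if (n > protocol$n_pairings) return(NA_integer_)
  n
}

# First event time of each pairing group, plus the trace end; used for
# per-pairing snapshots and pairing-resolution threshold inactivation.
pairing_boundaries <- function(protocol, calcium) {
  off <- pairing_offsets(protocol)
  first_off <- min(off$pre + calcium$delay_d, off$post)
  anchors <- (seq_len(protocol$n_pairings) - 1) / protocol$freq
  anchors + first_off
}
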