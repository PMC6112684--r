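#' Stimulation protocol
#'
#' Describes a deterministic repeated-pairing protocol.  Three patterns are
#' supported:
#' \describe{
#'   \item{`pair`}{One pre- and one postsynaptic spike per pairing, with
#'     spike timing `dt = t_post - t_pre` (negative: post before pre).}
#'   \item{`pre_post_pre`}{Two presynaptic spikes and one postsynaptic spike,
#'     with `dt1 = t_post - t_pre1` and `dt2 = t_post - t_pre2`; the naming
#'     convention requires `dt1 < dt2`.}
#'   \item{`post_pre_post`}{One presynaptic and two postsynaptic spikes, with
#'     `dt_i = t_post_i - t_pre`; requires `dt1 > dt2`.}
#' }
#' Pairing k (k = 0, ..., `n_pairings` - 1) is anchored at time k/`freq`:
#' its (first) presynaptic spike sits there and all other spikes are placed
#' relative to it.
#'
#' @param pattern `"pair"`, `"pre_post_pre"` or `"post_pre_post"`.
#' @param dt Spike timing \eqn{\Delta t} in seconds (pair pattern only).
#' @param dt1,dt2 Triplet timings \eqn{\Delta t_1, \Delta t_2} in seconds
#'   (triplet patterns only).
#' @param freq Pairing frequency F in Hz (> 0).
#' @param n_pairings Number of repetitions (>= 1).
#' @return An object of class `"stimulation_protocol"`.
#' @examples
#' stdp_protocol("pair", dt = -0.010, freq = 1, n_pairings = 100)
#' @export
stdp_protocol <- function(pattern = c("pair", "pre_post_pre", "post_pre_post"),
                          dt = NULL, dt1 = NULL, dt2 = NULL,
                          freq = 1, n_pairings = 100) {
  pattern <- match.arg(pattern)
  freq <- as.numeric(freq); n_pairings <- as.integer(n_pairings)
  stopifnot_msg(is.finite(freq) && freq > 0, "freq must be finite and > 0 (Hz)")
  stopifnot_msg(n_pairings >= 1, "n_pairings must be >= 1")
  if (pattern == "pair") {
    stopifnot_msg(!is.null(dt) && is.finite(dt), "pair pattern requires a finite dt (seconds)")
    stopifnot_msg(is.null(dt1) && is.null(dt2), "dt1/dt2 apply to triplet patterns only")
  } else {
    stopifnot_msg(is.null(dt), "dt applies to the pair pattern only")
    stopifnot_msg(!is.null(dt1) && !is.null(dt2) && is.finite(dt1) && is.finite(dt2),
                  "triplet patterns require finite dt1 and dt2 (seconds)")
    if (pattern == "pre_post_pre")
      stopifnot_msg(dt1 < dt2,
                    "pre_post_pre requires dt1 < dt2 (dt_i = t_post - t_pre_i; coincident presynaptic spikes are excluded)")
    else
      stopifnot_msg(dt1 > dt2,
                    "post_pre_post requires dt1 > dt2 (dt_i = t_post_i - t_pre; coincident postsynaptic spikes are excluded)")
  }
  structure(list(pattern = pattern,
                 dt = if (!is.null(dt)) as.numeric(dt),
                 dt1 = if (!is.null(dt1)) as.numeric(dt1),
                 dt2 = if (!is.null(dt2)) as.numeric(dt2),
                 freq = freq, n_pairings = n_pairings),
            class = "stimulation_protocol")
}

# Spike offsets of a single pairing relative to its anchor (the pre spike,
# or the only pre spike for triplets).
pairing_offsets <- function(protocol) {
  switch(protocol$pattern,
    pair = list(pre = 0, post = protocol$dt),
    # dt_i = t_post - t_pre_i, anchor = first pre spike (largest dt): pre
    # spikes at 0 and dt2 - ... place t_post = dt1 relative to pre1 at 0;
    # then t_pre2 = t_post - dt2 = dt1 - dt2 < 0?  dt1 < dt2 so dt1-dt2 < 0.
    # Anchor at the earlier pre spike instead: shift so min(pre) = 0.
    pre_post_pre = {
      pre <- c(0, protocol$dt1 - protocol$dt2)  # t_post - dt1 = 0 => pre1 at 0
      post <- protocol$dt1
      sh <- min(pre)
      list(pre = sort(pre - sh), post = post - sh)
    },
    post_pre_post = list(pre = 0, post = sort(c(protocol$dt1, protocol$dt2))))
}

#' Realized spike schedule of a protocol
#'
#' Expands a [stdp_protocol()] into explicit, sorted lists of pre- and
#' postsynaptic spike times.  Pairing k places its (first) presynaptic spike
#' at k/F; the remaining spikes follow the pattern's timing convention.
#'
#' @param protocol A [stdp_protocol()].
#' @return An object of class `"spike_schedule"`: a list with sorted numeric
#'   vectors `pre_times` and `post_times` (seconds).
#' @examples
#' build_schedule(stdp_protocol("pair", dt = 0.010, freq = 1, n_pairings = 2))
#' @export
build_schedule <- function(protocol) {
  stopifnot_msg(inherits(protocol, "stimulation_protocol"),
                "protocol must be a stimulation_protocol")
  off <- pairing_offsets(protocol)
  anchors <- (seq_len(protocol$n_pairings) - 1) / protocol$freq
  pre <- sort(as.vector(outer(off$pre, anchors, `+`)))
  post <- sort(as.vector(outer(off$post, anchors, `+`)))
  structure(list(pre_times = pre, post_times = post), class = "spike_schedule")
}

#' @export
print.stimulation_protocol <- function(x, ...) {
  tim <- if (x$pattern == "pair") sprintf("dt=%+g ms", 1000 * x$dt)
         else sprintf("dt1=%+g ms dt2=%+g ms", 1000 * x$dt1, 1000 * x$dt2)
  cat(sprintf("<stimulation_protocol> %s %s, %g Hz x %d pairings\n",
              x$pattern, tim, x$freq, x$n_pairings))
  invisible(x)
}

#' @export
print.spike_schedule <- function(x, ...) {
  cat(sprintf("<spike_schedule> %d pre, %d post spikes over [%.3f, %.3f] s\n",
              length(x$pre_times), length(x$post_times),
              min(x$pre_times, x$post_times), max(x$pre_times, x$post_times)))
  invisible(x)
}

#' @export
as_tibble.spike_schedule <- function(x, ...) {
  dplyr::arrange(
    dplyr::bind_rows(
      tibble::tibble(time = x$pre_times, site = "pre"),
      tibble::tibble(time = x$post_times, site = "post")),
    .data$time)
}

#' Fold a spike timing into the principal period of a frequency
#'
#' At pairing frequency F only timings modulo the period 1/F are
#' distinguishable; this folds `dt` into the interval `(-1/(2F), 1/(2F)]`.
#'
#' @param dt Spike timing(s), seconds.
#' @param freq Pairing frequency, Hz.
#' @return Folded timing(s), seconds.
#' @export
fold_dt <- function(dt, freq) {
  period <- 1 / freq
  folded <- dt - round(dt * freq) * period
  # round() halves away from the convention: map -T/2 to +T/2
  ifelse(folded <= -period / 2, folded + period, folded)
}
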