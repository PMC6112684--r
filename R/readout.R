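#' Coefficients of the sigmoid readout
#'
#' The macroscopic readout is the sigmoid
#' \deqn{H(r) = a + \frac{b}{1 + e^{-s (r - d)}}}
#' applied to the ratio r = U/D of ensemble switch fractions.  Its three
#' boundary conditions H(0) = LTD*, H(1) = 1 and H(Inf) = LTP* determine the
#' coefficients in closed form:
#' \deqn{\Delta = \frac{LTP^* - LTD^*}{LTP^* - 1}, \quad
#'       d = \frac{1}{s}\log\frac{\Delta - e^s}{1 - \Delta}, \quad
#'       b = \frac{LTP^* - LTD^*}{1 - \frac{1}{1 + e^{sd}}}, \quad
#'       a = LTP^* - b.}
#' The closed forms require `exp(s) > Delta` (checked by
#' [readout_params()]).
#'
#' @param readout A [readout_params()] object.
#' @return A named list with elements `a`, `b`, `d`, `delta`.
#' @examples
#' h_coefficients(readout_params(3.475, 0.55, 0.7))$d  # ~ 2.173
#' @export
h_coefficients <- function(readout) {
  stopifnot_msg(inherits(readout, "readout_params"), "readout must be a readout_params object")
  s <- readout$slope
  delta <- (readout$ltp_star - readout$ltd_star) / (readout$ltp_star - 1)
  stopifnot_msg(exp(s) > delta,
                sprintf("h_coefficients requires exp(slope) > Delta = %.6g", delta))
  d <- log((delta - exp(s)) / (1 - delta)) / s
  b <- (readout$ltp_star - readout$ltd_star) / (1 - 1 / (1 + exp(s * d)))
  a <- readout$ltp_star - b
  list(a = a, b = b, d = d, delta = delta)
}

#' Sigmoid readout map
#'
#' Evaluates H at the switch-fraction ratio `r = U/D`.  H is non-decreasing
#' with H(0) = LTD*, H(1) = 1 and H(Inf) = LTP*.
#'
#' @param r Ratio(s) U/D; non-negative, `Inf` allowed (`D = 0 < U`).
#' @param readout A [readout_params()] object.
#' @return Relative change(s) in macroscopic synaptic strength (1 = none).
#' @export
h_map <- function(r, readout) {
  stopifnot_msg(all(is.nan(r) | r >= 0), "ratio r must be >= 0 (or Inf)")
  co <- h_coefficients(readout)
  out <- co$a + co$b / (1 + exp(-readout$slope * (r - co$d)))
  out[is.infinite(r)] <- co$a + co$b
  out
}

# one H factor from a (U, D) pair; U = D = 0 is "no evidence" => neutral 1
h_factor <- function(U, D, readout) {
  r <- ifelse(U == 0 & D == 0, NA_real_, ifelse(D == 0, Inf, U / D))
  ifelse(is.na(r), 1, h_map(ifelse(is.na(r), 0, r), readout))
}

#' Macroscopic change in synaptic strength
#'
#' Combines per-pathway switch fractions into the total relative change in
#' macroscopic synaptic strength: the product over (included) pathways of
#' the sigmoid factors H(U/D).  A pathway with `U = D = 0` contributes a
#' neutral factor 1; `D = 0 < U` contributes H(Inf) = LTP*.  Pharmacological
#' blockade of a pathway corresponds to dropping it from `included`.
#'
#' @param x An [simulate_stdp()] / [analytic_stdp()] result, or a tibble
#'   with columns `pathway`, `U`, `D` (and optionally `pairing`).
#' @param included Character vector of pathway names to include (default:
#'   all pathways present).
#' @param readout A [readout_params()] object; defaults to the model readout
#'   when `x` is a simulation result (required otherwise).
#' @return A tibble with columns `pairing` (if present in the input) and
#'   `total_change`.
#' @examples
#' total_change(tibble::tibble(pathway = c("eCB", "NMDAR"),
#'                             U = c(0.7, 0), D = c(0, 0)),
#'              readout = readout_params(3.475, 0.55, 0.7))
#' @export
total_change <- function(x, included = NULL, readout = NULL) {
  if (inherits(x, "stdp_sim")) {
    readout <- readout %||% x$model$readout
    x <- x$outcomes
  }
  stopifnot_msg(!is.null(readout), "a readout_params object is required")
  stopifnot_msg(all(c("pathway", "U", "D") %in% names(x)),
                "x must have columns pathway, U, D")
  if (!"pairing" %in% names(x)) x$pairing <- NA_integer_
  included <- included %||% unique(x$pathway)
  stopifnot_msg(length(included) >= 1, "included pathway set must be non-empty")
  unknown <- setdiff(included, unique(x$pathway))
  stopifnot_msg(length(unknown) == 0,
                paste0("unknown pathway(s): ", paste(unknown, collapse = ", ")))
  x |>
    dplyr::filter(.data$pathway %in% included) |>
    dplyr::mutate(h = h_factor(.data$U, .data$D, readout)) |>
    dplyr::group_by(.data$pairing) |>
    dplyr::summarise(total_change = prod(.data$h), .groups = "drop")
}

# ---------------------------------------------------------------------------
# broom-style accessors

#' Tidy per-pairing outcomes of a simulation
#'
#' @param x An `stdp_sim` object.
#' @param included Pathways entering `total_change` (default all).
#' @param ... Unused.
#' @return A tibble with one row per (pairing, pathway): columns `pairing`,
#'   `pathway`, `U`, `D`, `h` (the pathway's sigmoid factor) and
#'   `total_change` (product over included pathways, repeated within a
#'   pairing).
#' @export
tidy.stdp_sim <- function(x, included = NULL, ...) {
  ro <- x$model$readout
  tc <- total_change(x, included = included)
  x$outcomes |>
    dplyr::mutate(h = h_factor(.data$U, .data$D, ro)) |>
    dplyr::left_join(tc, by = "pairing")
}

#' One-row summary of a simulation
#'
#' @param x An `stdp_sim` object.
#' @param ... Unused.
#' @return A one-row tibble: engine, protocol descriptors, ensemble size,
#'   seed and the final total change in macroscopic synaptic strength.
#' @export
glance.stdp_sim <- function(x, ...) {
  fin <- dplyr::filter(x$outcomes, .data$pairing == max(.data$pairing))
  tc <- total_change(x)
  tibble::tibble(
    engine = x$engine,
    pattern = x$protocol$pattern,
    dt = x$protocol$dt %||% NA_real_,
    freq = x$protocol$freq,
    n_pairings = x$protocol$n_pairings,
    n_synapses = x$settings$n_synapses,
    seed = x$settings$seed,
    total_change = tc$total_change[which.max(tc$pairing)])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
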