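#' Calcium transient parameters
#'
#' Parameters of the postsynaptic calcium model: each presynaptic spike evokes
#' an instantaneous calcium jump of amplitude `c_pre` (delayed by `delay_d`),
#' each postsynaptic spike a jump of `c_post`, and the concentration relaxes
#' exponentially back to baseline (taken as 0) with time constant `tau_ca`.
#'
#' @param c_pre Calcium amplitude per presynaptic spike (dimensionless
#'   concentration units, >= 0).
#' @param c_post Calcium amplitude per postsynaptic spike (>= 0).
#' @param tau_ca Calcium decay time constant, in seconds (> 0).
#' @param delay_d Delay of the presynaptic calcium influx relative to the
#'   presynaptic spike, in seconds.  May be negative.
#' @return An object of class `"calcium_params"`.
#' @examples
#' calcium_params(c_pre = 7, c_post = 17.1, tau_ca = 0.018, delay_d = 0.010)
#' @export
calcium_params <- function(c_pre, c_post, tau_ca, delay_d = 0) {
  x <- structure(
    list(c_pre = as.numeric(c_pre), c_post = as.numeric(c_post),
         tau_ca = as.numeric(tau_ca), delay_d = as.numeric(delay_d)),
    class = "calcium_params")
  validate_calcium_params(x)
}

validate_calcium_params <- function(x) {
  stopifnot_msg(is.finite(x$c_pre) && x$c_pre >= 0, "c_pre must be finite and >= 0")
  stopifnot_msg(is.finite(x$c_post) && x$c_post >= 0, "c_post must be finite and >= 0")
  stopifnot_msg(is.finite(x$tau_ca) && x$tau_ca > 0, "tau_ca must be finite and > 0 (seconds)")
  stopifnot_msg(is.finite(x$delay_d), "delay_d must be finite (seconds)")
  x
}

#' Signaling-pathway plasticity parameters
#'
#' One calcium-dependent signaling pathway (e.g. endocannabinoid or NMDAR).
#' While the calcium concentration exceeds the pathway's LTP (resp. LTD)
#' threshold, the pathway's efficacy drifts towards the potentiated (resp.
#' depressed) state at rate `gamma_p/tau` (resp. `gamma_d/tau`).  Each
#' mechanism inactivates for good once the cumulative calcium
#' \eqn{\int_0^t c(s)\,ds} exceeds its inactivation level `mu_p` / `mu_d`
#' (use `Inf` for a mechanism that never inactivates).  A pathway without an
#' LTD mechanism is encoded with `gamma_d = 0`.
#'
#' @param name Identifier string (e.g. `"eCB"`, `"NMDAR"`).
#' @param gamma_p,gamma_d Dimensionless LTP / LTD rates (>= 0).
#' @param theta0_p,theta0_d Base LTP / LTD calcium thresholds (> 0, `Inf`
#'   allowed for an absent mechanism).
#' @param mu_p,mu_d Cumulative-calcium inactivation levels, in
#'   concentration-seconds (> 0 or `Inf`).
#' @return An object of class `"pathway_params"`.
#' @export
pathway_params <- function(name, gamma_p, gamma_d,
                           theta0_p, theta0_d = Inf,
                           mu_p = Inf, mu_d = Inf) {
  x <- structure(
    list(name = as.character(name),
         gamma_p = as.numeric(gamma_p), gamma_d = as.numeric(gamma_d),
         theta0_p = as.numeric(theta0_p), theta0_d = as.numeric(theta0_d),
         mu_p = as.numeric(mu_p), mu_d = as.numeric(mu_d)),
    class = "pathway_params")
  validate_pathway_params(x)
}

validate_pathway_params <- function(x) {
  stopifnot_msg(nzchar(x$name), "pathway name must be a non-empty string")
  stopifnot_msg(is.finite(x$gamma_p) && x$gamma_p >= 0,
                sprintf("pathway '%s': gamma_p must be finite and >= 0", x$name))
  stopifnot_msg(is.finite(x$gamma_d) && x$gamma_d >= 0,
                sprintf("pathway '%s': gamma_d must be finite and >= 0", x$name))
  stopifnot_msg(x$theta0_p > 0, sprintf("pathway '%s': theta0_p must be > 0", x$name))
  stopifnot_msg(x$theta0_d > 0, sprintf("pathway '%s': theta0_d must be > 0", x$name))
  stopifnot_msg(x$mu_p > 0, sprintf("pathway '%s': mu_p must be > 0 (Inf allowed)", x$name))
  stopifnot_msg(x$mu_d > 0, sprintf("pathway '%s': mu_d must be > 0 (Inf allowed)", x$name))
  x
}

#' Sigmoid readout parameters
#'
#' Parameters of the sigmoid map `H` converting the ratio of ensemble switch
#' fractions U/D into the macroscopic relative change in synaptic strength
#' (1 = no change).  The coefficients of the sigmoid are fully determined by
#' the boundary conditions H(0) = `ltd_star`, H(1) = 1 and H(Inf) =
#' `ltp_star`; see [h_coefficients()].
#'
#' @param ltp_star Maximal potentiation (relative strength, > 1).
#' @param ltd_star Maximal depression (0 < `ltd_star` < 1).
#' @param slope Sigmoid slope `s` (> 0).  Must satisfy `exp(slope) > Delta`
#'   where `Delta = (ltp_star - ltd_star) / (ltp_star - 1)`, otherwise the
#'   coefficient closed forms are undefined.
#' @return An object of class `"readout_params"`.
#' @export
readout_params <- function(ltp_star, ltd_star, slope) {
  x <- structure(
    list(ltp_star = as.numeric(ltp_star), ltd_star = as.numeric(ltd_star),
         slope = as.numeric(slope)),
    class = "readout_params")
  validate_readout_params(x)
}

validate_readout_params <- function(x) {
  stopifnot_msg(is.finite(x$ltd_star) && x$ltd_star > 0 && x$ltd_star < 1,
                "ltd_star must satisfy 0 < ltd_star < 1")
  stopifnot_msg(is.finite(x$ltp_star) && x$ltp_star > 1,
                "ltp_star must be > 1")
  stopifnot_msg(is.finite(x$slope) && x$slope > 0, "slope must be > 0")
  delta <- (x$ltp_star - x$ltd_star) / (x$ltp_star - 1)
  stopifnot_msg(exp(x$slope) > delta,
                sprintf("readout requires exp(slope) > Delta = %.4g; got exp(%.4g) = %.4g",
                        delta, x$slope, exp(x$slope)))
  x
}

#' Full synapse model
#'
#' Bundles the calcium dynamics, the P signaling pathways, the bistable
#' efficacy dynamics and the macroscopic readout into one model object.
#'
#' @param calcium A [calcium_params()] object.
#' @param pathways A list of [pathway_params()] objects (length >= 1).
#' @param tau Efficacy time constant, in seconds (> 0; on the order of
#'   minutes, much slower than the calcium dynamics).
#' @param rho_star Unstable midpoint of the bistable efficacy dynamics, in
#'   (0, 1).
#' @param sigma Noise intensity (>= 0).  The efficacy SDE receives the
#'   diffusion term `(sigma/tau) * sqrt(A_p + A_d) dW` while the LTP/LTD
#'   gates `A_x` are open; see the package vignette for the convention.
#' @param readout A [readout_params()] object shared by all pathways.
#' @param threshold_model `"piecewise"` (thresholds jump to infinity when the
#'   cumulative calcium crosses `mu`) or `"exponential"` (thresholds grow as
#'   `theta0 + exp((I - mu)/epsilon)`).
#' @param epsilon Inactivation sharpness of the exponential threshold model
#'   (> 0; ignored by the piecewise model).
#' @param n_synapses_default,steps_per_second_default Default ensemble size
#'   and Euler resolution used by [sim_settings()] for this model.
#' @return An object of class `"synapse_model"`.
#' @seealso [stdp_preset()] for the shipped parameter presets.
#' @export
synapse_model <- function(calcium, pathways, tau, rho_star, sigma, readout,
                          threshold_model = c("piecewise", "exponential"),
                          epsilon = 1,
                          n_synapses_default = 1000,
                          steps_per_second_default = 1000) {
  threshold_model <- match.arg(threshold_model)
  if (inherits(pathways, "pathway_params")) pathways <- list(pathways)
  x <- structure(
    list(calcium = calcium, pathways = pathways,
         tau = as.numeric(tau), rho_star = as.numeric(rho_star),
         sigma = as.numeric(sigma), readout = readout,
         threshold_model = threshold_model, epsilon = as.numeric(epsilon),
         n_synapses_default = as.integer(n_synapses_default),
         steps_per_second_default = as.numeric(steps_per_second_default)),
    class = "synapse_model")
  validate_synapse_model(x)
}

validate_synapse_model <- function(x) {
  stopifnot_msg(inherits(x$calcium, "calcium_params"), "calcium must be a calcium_params object")
  stopifnot_msg(length(x$pathways) >= 1, "at least one pathway is required")
  for (p in x$pathways) stopifnot_msg(inherits(p, "pathway_params"),
                                      "pathways must be pathway_params objects")
  nms <- pathway_names(x)
  stopifnot_msg(!anyDuplicated(nms), "pathway names must be unique")
  stopifnot_msg(is.finite(x$tau) && x$tau > 0, "tau must be finite and > 0 (seconds)")
  stopifnot_msg(is.finite(x$rho_star) && x$rho_star > 0 && x$rho_star < 1,
                "rho_star must lie strictly in (0, 1)")
  stopifnot_msg(is.finite(x$sigma) && x$sigma >= 0, "sigma must be finite and >= 0")
  stopifnot_msg(inherits(x$readout, "readout_params"), "readout must be a readout_params object")
  stopifnot_msg(is.finite(x$epsilon) && x$epsilon > 0, "epsilon must be finite and > 0")
  x
}

#' Names of the pathways of a synapse model
#' @param model A [synapse_model()].
#' @return Character vector of pathway names, in model order.
#' @export
pathway_names <- function(model) {
  vapply(model$pathways, function(p) p$name, character(1))
}

#' Retrieve one pathway of a model by name
#' @param model A [synapse_model()].
#' @param name Pathway name.
#' @return The matching [pathway_params()] object.
#' @export
get_pathway <- function(model, name) {
  i <- match(name, pathway_names(model))
  stopifnot_msg(!is.na(i), sprintf("unknown pathway '%s'; model has: %s",
                                   name, paste(pathway_names(model), collapse = ", ")))
  model$pathways[[i]]
}

# ---------------------------------------------------------------------------
# Presets

preset_names <- c("corticostriatal", "scenario1", "scenario2", "scenario3",
                  "hebbian_asymmetric", "hebbian_symmetric")

#' Load a shipped parameter preset
#'
#' Returns one of the model parameterizations shipped with the package, each
#' stored as a YAML config under `inst/extdata/presets/` and documented
#' field-by-field there:
#' \describe{
#'   \item{`corticostriatal`}{Two-pathway (eCB + NMDAR) model of
#'     cortico-striatal anti-Hebbian STDP, with eCB-LTP inactivating after 14
#'     pairings and NMDAR-LTP after 74 pairings (at 1 Hz pair protocols).}
#'   \item{`scenario1`, `scenario2`, `scenario3`}{One- and two-pathway models
#'     all producing symmetric anti-Hebbian LTD at 100 pairings / 1 Hz but
#'     distinguishable at other pairing numbers and frequencies.}
#'   \item{`hebbian_asymmetric`, `hebbian_symmetric`}{Classical single-pathway
#'     Hebbian STDP parameterizations.}
#' }
#' All times are stored internally in seconds.
#'
#' @param preset_name One of `"corticostriatal"`, `"scenario1"`,
#'   `"scenario2"`, `"scenario3"`, `"hebbian_asymmetric"`,
#'   `"hebbian_symmetric"`.
#' @return A [synapse_model()].
#' @examples
#' m <- stdp_preset("corticostriatal")
#' m$calcium$c_post            # 17.1
#' get_pathway(m, "eCB")$mu_d  # Inf: eCB-LTD never inactivates
#' @export
stdp_preset <- function(preset_name) {
  if (!is.character(preset_name) || length(preset_name) != 1 ||
      !preset_name %in% preset_names) {
    stop("unknown preset '", paste(preset_name, collapse = ","),
         "'; available presets: ", paste(preset_names, collapse = ", "),
         call. = FALSE)
  }
  path <- system.file("extdata", "presets", paste0(preset_name, ".yaml"),
                      package = "calstdp", mustWork = TRUE)
  read_model_config(path)
}

# ---------------------------------------------------------------------------
# Config file I/O
#
# Schema (YAML or JSON): sections `calcium`, `pathways` (list), `dynamics`,
# `readout`, `thresholds`, `defaults`.  Time-valued fields (tau_ca, delay_d,
# tau) accept a "ms" or "s" suffix; bare numbers are seconds.  `inf` (any
# case, optionally signed or as YAML `.inf`) denotes infinity.

config_schema <- list(
  calcium    = c("c_pre", "c_post", "tau_ca", "delay_d"),
  pathway    = c("name", "gamma_p", "gamma_d", "theta0_p", "theta0_d", "mu_p", "mu_d"),
  dynamics   = c("tau", "rho_star", "sigma"),
  readout    = c("ltp_star", "ltd_star", "slope"),
  thresholds = c("model", "epsilon"),
  defaults   = c("n_synapses", "steps_per_second")
)

parse_quantity <- function(x, field, time = FALSE) {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x) || length(x) != 1)
    stop("field '", field, "' must be a number or a quantity string", call. = FALSE)
  s <- trimws(x)
  if (grepl("^[+-]?\\.?inf(inity)?$", s, ignore.case = TRUE))
    return(if (startsWith(s, "-")) -Inf else Inf)
  m <- regmatches(s, regexec("^([+-]?[0-9.eE+-]+)\\s*(ms|s)?$", s))[[1]]
  if (length(m) == 0 || is.na(suppressWarnings(v <- as.numeric(m[2]))))
    stop("cannot parse value '", s, "' for field '", field, "'", call. = FALSE)
  unit <- m[3]
  if (nzchar(unit) && !time)
    stop("field '", field, "' does not accept a time unit suffix", call. = FALSE)
  if (identical(unit, "ms")) v <- v / 1000
  v
}

check_keys <- function(section, got, what) {
  allowed <- config_schema[[section]]
  extra <- setdiff(names(got), allowed)
  if (length(extra) > 0)
    stop("unknown key(s) in ", what, ": ", paste(extra, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
}

need <- function(sec, key, what) {
  if (is.null(sec[[key]])) stop("missing required field '", key, "' in ", what,
                                call. = FALSE)
  sec[[key]]
}

#' Read a synapse model from a config file
#'
#' Reads the documented YAML/JSON schema (the same one the shipped presets
#' use) and validates all model invariants with actionable messages.  Unknown
#' keys are rejected.  Time-valued fields accept `"ms"`/`"s"` unit suffixes
#' and are converted to seconds; `inf` denotes infinity.
#'
#' @param path Path to a YAML (or JSON) config file.
#' @return A [synapse_model()].
#' @seealso [write_model_config()] for the inverse operation.
#' @export
read_model_config <- function(path) {
  stopifnot_msg(file.exists(path), sprintf("config file '%s' does not exist", path))
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed config file '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  synapse_model_from_config(cfg)
}

synapse_model_from_config <- function(cfg) {
  top_allowed <- c("calcium", "pathways", "dynamics", "readout", "thresholds", "defaults")
  extra <- setdiff(names(cfg), top_allowed)
  if (length(extra) > 0)
    stop("unknown top-level section(s): ", paste(extra, collapse = ", "), call. = FALSE)

  ca <- need(cfg, "calcium", "config")
  check_keys("calcium", ca, "section 'calcium'")
  calcium <- calcium_params(
    c_pre  = parse_quantity(need(ca, "c_pre", "calcium"), "c_pre"),
    c_post = parse_quantity(need(ca, "c_post", "calcium"), "c_post"),
    tau_ca = parse_quantity(need(ca, "tau_ca", "calcium"), "tau_ca", time = TRUE),
    delay_d = parse_quantity(ca$delay_d %||% 0, "delay_d", time = TRUE))

  pw <- need(cfg, "pathways", "config")
  stopifnot_msg(is.list(pw) && length(pw) >= 1, "config must list at least one pathway")
  pathways <- lapply(seq_along(pw), function(i) {
    p <- pw[[i]]
    check_keys("pathway", p, sprintf("pathway %d", i))
    pathway_params(
      name = need(p, "name", sprintf("pathway %d", i)),
      gamma_p = parse_quantity(p$gamma_p %||% 0, "gamma_p"),
      gamma_d = parse_quantity(p$gamma_d %||% 0, "gamma_d"),
      theta0_p = parse_quantity(p$theta0_p %||% Inf, "theta0_p"),
      theta0_d = parse_quantity(p$theta0_d %||% Inf, "theta0_d"),
      mu_p = parse_quantity(p$mu_p %||% Inf, "mu_p"),
      mu_d = parse_quantity(p$mu_d %||% Inf, "mu_d"))
  })

  dyn <- need(cfg, "dynamics", "config")
  check_keys("dynamics", dyn, "section 'dynamics'")
  ro <- need(cfg, "readout", "config")
  check_keys("readout", ro, "section 'readout'")
  th <- cfg$thresholds %||% list(model = "piecewise", epsilon = 1)
  check_keys("thresholds", th, "section 'thresholds'")
  df <- cfg$defaults %||% list()
  check_keys("defaults", df, "section 'defaults'")

  synapse_model(
    calcium = calcium, pathways = pathways,
    tau = parse_quantity(need(dyn, "tau", "dynamics"), "tau", time = TRUE),
    rho_star = parse_quantity(need(dyn, "rho_star", "dynamics"), "rho_star"),
    sigma = parse_quantity(need(dyn, "sigma", "dynamics"), "sigma"),
    readout = readout_params(
      ltp_star = parse_quantity(need(ro, "ltp_star", "readout"), "ltp_star"),
      ltd_star = parse_quantity(need(ro, "ltd_star", "readout"), "ltd_star"),
      slope = parse_quantity(need(ro, "slope", "readout"), "slope")),
    threshold_model = th$model %||% "piecewise",
    epsilon = parse_quantity(th$epsilon %||% 1, "epsilon"),
    n_synapses_default = df$n_synapses %||% 1000,
    steps_per_second_default = df$steps_per_second %||% 1000)
}

fmt_cfg_num <- function(x) {
  if (is.infinite(x)) return(if (x > 0) "inf" else "-inf")
  x
}

#' Write a synapse model to a YAML config file
#'
#' The written file round-trips through [read_model_config()] to a model
#' equal to the input.  Times are written in seconds.
#'
#' @param model A [synapse_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  cfg <- list(
    calcium = lapply(unclass(model$calcium), fmt_cfg_num),
    pathways = lapply(model$pathways, function(p) lapply(unclass(p), fmt_cfg_num)),
    dynamics = list(tau = model$tau, rho_star = model$rho_star, sigma = model$sigma),
    readout = lapply(unclass(model$readout), fmt_cfg_num),
    thresholds = list(model = model$threshold_model, epsilon = model$epsilon),
    defaults = list(n_synapses = model$n_synapses_default,
                    steps_per_second = model$steps_per_second_default))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

# ---------------------------------------------------------------------------

#' @export
print.synapse_model <- function(x, ...) {
  cat("<synapse_model> ", length(x$pathways), " pathway(s): ",
      paste(pathway_names(x), collapse = ", "), "\n", sep = "")
  cat(sprintf("  calcium: c_pre=%g c_post=%g tau_ca=%gs delay_d=%gs\n",
              x$calcium$c_pre, x$calcium$c_post, x$calcium$tau_ca, x$calcium$delay_d))
  for (p in x$pathways)
    cat(sprintf("  %s: gamma_p=%g gamma_d=%g theta0_p=%g theta0_d=%g mu_p=%g mu_d=%g\n",
                p$name, p$gamma_p, p$gamma_d, p$theta0_p, p$theta0_d, p$mu_p, p$mu_d))
  cat(sprintf("  dynamics: tau=%gs rho_star=%g sigma=%g thresholds=%s\n",
              x$tau, x$rho_star, x$sigma, x$threshold_model))
  cat(sprintf("  readout: LTP*=%g LTD*=%g slope=%g\n",
              x$readout$ltp_star, x$readout$ltd_star, x$readout$slope))
  invisible(x)
}

#' @export
print.pathway_params <- function(x, ...) {
  cat(sprintf("<pathway_params> %s: gamma_p=%g gamma_d=%g theta0_p=%g theta0_d=%g mu_p=%g mu_d=%g\n",
              x$name, x$gamma_p, x$gamma_d, x$theta0_p, x$theta0_d, x$mu_p, x$mu_d))
  invisible(x)
}

stopifnot_msg <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
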