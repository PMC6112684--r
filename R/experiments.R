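#' Qualitative plasticity bands
#'
#' Band constants used throughout the package (and its tests) to translate
#' figure-level statements into checks: a total change above `ltp` counts as
#' LTP, below `ltd` as LTD, and within `1 +/- neutral` as no plasticity.
#'
#' @format A named list with elements `ltp` (1.15), `ltd` (0.90) and
#'   `neutral` (0.10).
#' @export
plasticity_bands <- list(ltp = 1.15, ltd = 0.90, neutral = 0.10)

new_sweep <- function(data, meta) {
  attr(data, "meta") <- meta
  class(data) <- c("stdp_sweep", class(data))
  data
}

#' Spike-timing / pairing-number map of plasticity
#'
#' Runs one protocol per spike timing in `dt_grid` and records the total
#' change in macroscopic synaptic strength at every pairing count up to
#' `n_pairings` (per timing, all pairing counts come from one realization
#' and are therefore correlated, as when a single long protocol is probed at
#' increasing pairing numbers).  With `engine = "analytic"` the closed-form
#' mean-field solution is used instead (low frequency only).
#'
#' Restricting `included` to a subset of pathway names computes the map
#' under pharmacological blockade of the excluded pathways: blockade acts at
#' the readout, i.e. the total change is the product of sigmoid factors over
#' the included pathways only.
#'
#' @param model A [synapse_model()].
#' @param dt_grid Spike timings, seconds.
#' @param n_pairings Maximum pairing count.
#' @param freq Pairing frequency, Hz.
#' @param engine `"simulate"` or `"analytic"`.
#' @param settings A [sim_settings()]; simulation `i` of the grid uses seed
#'   `settings$seed + i - 1`.
#' @param included Pathway names entering the readout product (default all).
#' @return A tibble of class `"stdp_sweep"` with columns `dt`, `pairing`,
#'   `total_change` and a `meta` attribute.
#' @export
stdp_heatmap <- function(model, dt_grid, n_pairings = 100, freq = 1,
                         engine = c("simulate", "analytic"),
                         settings = sim_settings(), included = NULL) {
  engine <- match.arg(engine)
  check_model_frequency(freq)
  runs <- purrr::imap(dt_grid, function(dt, i) {
    protocol <- stdp_protocol("pair", dt = dt, freq = freq, n_pairings = n_pairings)
    sim <- if (engine == "simulate") {
      st <- settings
      st$seed <- settings$seed + i - 1L
      st$record_per_pairing <- TRUE
      simulate_stdp(model, protocol, st)
    } else {
      analytic_stdp(model, protocol, resolution = settings$n_synapses)
    }
    dplyr::mutate(total_change(sim, included = included), dt = dt, .before = 1)
  })
  new_sweep(dplyr::bind_rows(runs),
            meta = list(kind = "heatmap", engine = engine, freq = freq,
                        n_pairings = n_pairings, seed = settings$seed,
                        included = included %||% pathway_names(model)))
}

#' @rdname stdp_heatmap
#' @param included_pathways Pathway names kept active (the blockade
#'   complement).
#' @export
blockade_heatmap <- function(model, included_pathways, dt_grid,
                             n_pairings = 100, freq = 1,
                             engine = c("simulate", "analytic"),
                             settings = sim_settings()) {
  stdp_heatmap(model, dt_grid, n_pairings = n_pairings, freq = freq,
               engine = engine, settings = settings,
               included = included_pathways)
}

#' Frequency dependence of STDP
#'
#' For each pairing frequency, runs `replicates` independent simulations per
#' spike timing and reports the mean and standard deviation of the total
#' change after `n_pairings` pairings.  Timings are folded into the
#' principal period `(-1/(2F), 1/(2F)]` (see [fold_dt()]): at frequency F
#' only timings modulo the period are distinguishable.
#'
#' @param model A [synapse_model()].
#' @param freqs Pairing frequencies, Hz.
#' @param dt_grid Spike timings, seconds (folded per frequency).
#' @param n_pairings Pairing count at which the change is read out.
#' @param settings A [sim_settings()]; replicate r of grid point i uses seed
#'   `settings$seed + (i - 1) * replicates + r - 1`.
#' @param replicates Number of independent simulations per grid point.
#' @return A tibble of class `"stdp_sweep"` with columns `freq`, `dt`,
#'   `dt_folded`, `mean_change`, `sd_change`, `replicates`.
#' @export
frequency_sweep <- function(model, freqs, dt_grid, n_pairings = 100,
                            settings = sim_settings(), replicates = 30) {
  grid <- tidyr::expand_grid(freq = freqs, dt = dt_grid)
  rows <- purrr::pmap(list(grid$freq, grid$dt, seq_len(nrow(grid))),
                      function(f, dt, i) {
    check_model_frequency(f)
    dtf <- fold_dt(dt, f)
    protocol <- stdp_protocol("pair", dt = dtf, freq = f, n_pairings = n_pairings)
    tc <- vapply(seq_len(replicates), function(r) {
      st <- settings
      st$seed <- settings$seed + (i - 1L) * replicates + r - 1L
      st$record_per_pairing <- FALSE
      total_change(simulate_stdp(model, protocol, st))$total_change
    }, numeric(1))
    tibble::tibble(freq = f, dt = dt, dt_folded = dtf,
                   mean_change = mean(tc),
                   sd_change = stats::sd(tc),
                   replicates = replicates)
  })
  new_sweep(dplyr::bind_rows(rows),
            meta = list(kind = "frequency_sweep", n_pairings = n_pairings,
                        seed = settings$seed, replicates = replicates))
}

#' Triplet-protocol plasticity map
#'
#' Computes the total change for triplet protocols over a (dt1, dt2) grid:
#' combinations with `dt1 < dt2` are pre-post-pre stimulations (two pre-,
#' one postsynaptic spike; the upper-left triangle of the map), `dt1 > dt2`
#' post-pre-post (the lower-right triangle); coincident-spike diagonals are
#' excluded.
#'
#' @param model A [synapse_model()].
#' @param dt1_grid,dt2_grid Triplet timings, seconds.
#' @param n_pairings Maximum pairing count.
#' @param freq Pairing frequency, Hz.
#' @param settings A [sim_settings()]; grid point i uses seed
#'   `settings$seed + i - 1`.
#' @param pairings Pairing counts to keep in the output (default: only
#'   `n_pairings`; use e.g. `c(10, 25, 50, 100)` for establishment maps).
#' @return A tibble of class `"stdp_sweep"` with columns `dt1`, `dt2`,
#'   `pattern`, `pairing`, `total_change`.
#' @export
triplet_map <- function(model, dt1_grid, dt2_grid, n_pairings = 100, freq = 1,
                        settings = sim_settings(), pairings = n_pairings) {
  check_model_frequency(freq)
  grid <- tidyr::expand_grid(dt1 = dt1_grid, dt2 = dt2_grid)
  grid <- dplyr::filter(grid, .data$dt1 != .data$dt2)
  rows <- purrr::pmap(list(grid$dt1, grid$dt2, seq_len(nrow(grid))),
                      function(d1, d2, i) {
    pattern <- if (d1 < d2) "pre_post_pre" else "post_pre_post"
    protocol <- stdp_protocol(pattern, dt1 = d1, dt2 = d2, freq = freq,
                              n_pairings = n_pairings)
    st <- settings
    st$seed <- settings$seed + i - 1L
    st$record_per_pairing <- TRUE
    tc <- total_change(simulate_stdp(model, protocol, st))
    dplyr::mutate(dplyr::filter(tc, .data$pairing %in% pairings),
                  dt1 = d1, dt2 = d2, pattern = pattern, .before = 1)
  })
  new_sweep(dplyr::bind_rows(rows),
            meta = list(kind = "triplet_map", freq = freq,
                        n_pairings = n_pairings, seed = settings$seed))
}

#' Classify the dynamical establishment of plasticity
#'
#' Deterministic surrogate for by-eye phase classification of a total-change
#' versus pairing-count curve: pairing counts with change above `1 + delta`
#' are marked potentiating (P), below `1 - delta` depressing (D), the rest
#' neutral; runs shorter than `min_run` pairings are merged into their
#' longer neighbor; the label concatenates the polarities of the surviving
#' significant runs in order of appearance (e.g. `"PD"` for an early
#' potentiation followed by depression, `"PP"` for potentiation, silence,
#' re-potentiation).
#'
#' @param curve A tibble with columns `pairing` and `total_change` (e.g.
#'   from [total_change()] or [stdp_heatmap()]), or a numeric vector of
#'   total changes indexed by pairing count.
#' @param delta Significance band around 1 (relative strength).
#' @param min_run Minimum run length, in pairings.
#' @return An object of class `"phase_label"`: a list with `label` (one of
#'   `"none"`, `"D"`, `"P"`, `"PD"`, `"PP"`, `"PPD"`, `"PDP"`, `"other"`)
#'   and `runs`, a tibble of the surviving runs with their pairing-count
#'   boundaries.
#' @export
classify_phases <- function(curve, delta = 0.1, min_run = 5) {
  stopifnot_msg(delta > 0, "delta must be > 0")
  stopifnot_msg(min_run >= 1, "min_run must be >= 1")
  if (is.data.frame(curve)) {
    curve <- curve[order(curve$pairing), ]
    tc <- curve$total_change
    pairing <- curve$pairing
  } else {
    tc <- as.numeric(curve)
    pairing <- seq_along(tc)
  }
  pol <- ifelse(tc > 1 + delta, 1L, ifelse(tc < 1 - delta, -1L, 0L))
  r <- rle(pol)
  repeat {
    short <- which(r$lengths < min_run)
    if (length(short) == 0 || length(r$lengths) == 1) break
    i <- short[which.min(r$lengths[short])]
    nb <- c(if (i > 1) i - 1L, if (i < length(r$lengths)) i + 1L)
    nb <- nb[which.max(r$lengths[nb])]
    r$values[i] <- r$values[nb]
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  runs <- tibble::tibble(
    polarity = c("D", "neutral", "P")[r$values + 2L],
    from = pairing[starts], to = pairing[ends])
  sig <- dplyr::filter(runs, .data$polarity != "neutral")
  label <- paste(sig$polarity, collapse = "")
  if (label == "") label <- "none"
  else if (!label %in% c("D", "P", "PD", "PP", "PPD", "PDP")) label <- "other"
  structure(list(label = label, runs = runs, delta = delta, min_run = min_run),
            class = "phase_label")
}

#' @export
print.phase_label <- function(x, ...) {
  cat(sprintf("<phase_label> %s (delta=%g, min_run=%d)\n", x$label, x$delta,
              as.integer(x$min_run)))
  print(x$runs)
  invisible(x)
}

check_model_frequency <- function(freq) {
  if (freq > 40)
    warning(sprintf(paste0("pairing frequency %g Hz is above 40 Hz, where the ",
                           "calcium trace no longer relaxes between pairings and ",
                           "the model loses biological relevance"), freq),
            call. = FALSE)
  invisible(freq)
}
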