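#' @keywords internal
"_PACKAGE"

# Default seed used by all generators unless one is supplied explicitly.
.default_seed <- 20190607L

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

.check_weights <- function(w, max_components = Inf) {
  if (length(w) < 1L || length(w) > max_components)
    stop("between 1 and ", max_components, " mixture components are supported",
         call. = FALSE)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-12)
    stop("component weights must be nonnegative and sum to 1 (within 1e-12)",
         call. = FALSE)
  invisible(w)
}

#' Specify a binomial activating-unit population
#'
#' Describes a population of cells whose nuclear proportion of a transcription
#' factor arises from \code{n_units} independent activating units, each
#' switching on with probability \code{p}. A two-component spec models a
#' responder/non-responder mixture: each cell is assigned to a component with
#' the given weight and its unit count drawn from Binomial(\code{n_units},
#' \code{p}) for that component's \code{p}.
#'
#' @param n_units Number of activating units per cell (positive integer).
#' @param components List of one or two components, each a list or named
#'   vector with elements \code{weight} and \code{p}. Weights must sum to 1.
#' @param n_cells Number of cells to simulate.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class \code{binomial_population_spec}.
#' @examples
#' spec <- binomial_population_spec(13, list(c(weight = 0.2, p = 0.1),
#'                                           c(weight = 0.8, p = 0.85)), 1000)
#' head(gen_nuclear_proportions(spec))
#' @export
binomial_population_spec <- function(n_units, components, n_cells,
                                     seed = .default_seed) {
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 1L) stop("n_units must be a positive integer")
  comps <- .normalize_components(components, c("weight", "p"))
  .check_weights(comps$weight, max_components = 2L)
  if (any(comps$p < 0 | comps$p > 1)) stop("component p must lie in [0, 1]")
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1L) stop("n_cells must be a positive integer")
  structure(list(n_units = n_units, components = comps,
                 n_cells = n_cells, seed = as.integer(seed)),
            class = "binomial_population_spec")
}

#' Specify a base-10 log-normal fluorescence population
#'
#' Each component is a normal distribution on log10 fluorescence with mean
#' \code{mu} and standard deviation \code{sigma}; generated values are
#' \code{10^x}. One component describes a resting (non-responder) population;
#' two components describe a responder/non-responder mixture of reporter
#' expression.
#'
#' @param components List of components, each with \code{weight}, \code{mu}
#'   (mean of log10 fluorescence) and \code{sigma} (SD of log10 fluorescence,
#'   nonnegative). Weights must sum to 1.
#' @param n_cells Number of cells to simulate.
#' @param seed Integer seed.
#' @return An object of class \code{lognormal_population_spec}.
#' @export
lognormal_population_spec <- function(components, n_cells,
                                      seed = .default_seed) {
  comps <- .normalize_components(components, c("weight", "mu", "sigma"))
  .check_weights(comps$weight)
  if (any(comps$sigma < 0)) stop("component sigma must be >= 0")
  if (any(!is.finite(comps$mu))) stop("component mu must be finite")
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1L) stop("n_cells must be a positive integer")
  structure(list(components = comps, n_cells = n_cells,
                 seed = as.integer(seed)),
            class = "lognormal_population_spec")
}

.normalize_components <- function(components, fields) {
  if (!is.list(components)) components <- list(components)
  rows <- lapply(components, function(cmp) {
    cmp <- unlist(cmp)
    if (is.null(names(cmp)) || !all(fields %in% names(cmp))) {
      if (length(cmp) == length(fields)) names(cmp) <- fields
      else stop("each component needs fields: ", paste(fields, collapse = ", "))
    }
    cmp[fields]
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- fields
  out
}

#' Specify a Hill dose-response simulation
#'
#' Per-cell responses follow the Hill equation
#' \eqn{r = r_{max} d^n / (d^n + EC_{50}^n)} with multiplicative Gaussian
#' noise of coefficient of variation \code{noise_cv}, truncated at zero
#' (responses are nonnegative rates or percentages).
#'
#' @param ec50 Half-maximal dose (same unit as \code{doses}); must be > 0.
#' @param hill_n Hill coefficient (> 0).
#' @param r_max Maximal response (rate or percent).
#' @param doses Vector of doses (>= 0).
#' @param cells_per_dose Number of cells measured at each dose.
#' @param noise_cv Coefficient of variation of multiplicative noise (>= 0).
#' @param dose_unit Unit label carried into the output table.
#' @param seed Integer seed.
#' @return An object of class \code{hill_curve_spec}.
#' @export
hill_curve_spec <- function(ec50, hill_n, r_max, doses, cells_per_dose,
                            noise_cv = 0, dose_unit = "uM",
                            seed = .default_seed) {
  if (!is.finite(ec50) || ec50 <= 0) stop("ec50 must be > 0")
  if (!is.finite(hill_n) || hill_n <= 0) stop("hill_n must be > 0")
  if (length(doses) < 1L) stop("at least one dose is required")
  if (any(doses < 0)) stop("doses must be >= 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  cells_per_dose <- as.integer(cells_per_dose)
  if (is.na(cells_per_dose) || cells_per_dose < 1L)
    stop("cells_per_dose must be a positive integer")
  structure(list(ec50 = ec50, hill_n = hill_n, r_max = r_max,
                 doses = as.numeric(doses), cells_per_dose = cells_per_dose,
                 noise_cv = noise_cv, dose_unit = dose_unit,
                 seed = as.integer(seed)),
            class = "hill_curve_spec")
}

#' Specify a synthetic fura-2 ratio trace
#'
#' The noiseless trace is piecewise linear in the 356/380 ratio R: slope
#' \code{basal_slope} before \code{event_time} (e.g. Ca2+ readmission,
#' ionomycin or Ba2+ addition); after the event the basal drift continues
#' and \code{event_slope} adds on top of it (total post-event slope
#' \code{basal_slope + event_slope}), so basal-corrected rate estimates
#' recover \code{event_slope}. R is clipped from above at \code{plateau_R}
#' and additive Gaussian noise of SD \code{noise_sd} is superimposed.
#'
#' @param duration Trace length in seconds (> 0).
#' @param sample_interval Sampling interval in seconds (> 0).
#' @param baseline_R Resting ratio.
#' @param basal_slope Pre-event drift, ratio units per second.
#' @param event_time Time of the addition event, seconds, in [0, duration].
#' @param event_slope Post-event slope, ratio units per second.
#' @param plateau_R Upper clip for R.
#' @param noise_sd SD of additive Gaussian noise in ratio units (>= 0).
#' @param event_name Name recorded for the event annotation.
#' @param seed Integer seed.
#' @return An object of class \code{trace_spec}.
#' @export
trace_spec <- function(duration, sample_interval, baseline_R = 0.3,
                       basal_slope = 0, event_time, event_slope,
                       plateau_R = Inf, noise_sd = 0,
                       event_name = "addition", seed = .default_seed) {
  if (duration <= 0) stop("duration must be > 0")
  if (sample_interval <= 0) stop("sample_interval must be > 0")
  if (event_time < 0 || event_time > duration)
    stop("event_time must lie within [0, duration]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(duration = duration, sample_interval = sample_interval,
                 baseline_R = baseline_R, basal_slope = basal_slope,
                 event_time = event_time, event_slope = event_slope,
                 plateau_R = plateau_R, noise_sd = noise_sd,
                 event_name = event_name, seed = as.integer(seed)),
            class = "trace_spec")
}

#' Generate nuclear proportions from a binomial activating-unit model
#'
#' Each cell's component is sampled with the spec weights; its active-unit
#' count k is Binomial(\code{n_units}, p) and the returned nuclear proportion
#' is k / \code{n_units}, so values lie on \{0, 1/n, ..., 1\}.
#'
#' @param spec A \code{\link{binomial_population_spec}}.
#' @return Numeric vector of length \code{n_cells} with attribute
#'   \code{"component"} giving each cell's (1-based) source component.
#' @export
gen_nuclear_proportions <- function(spec) {
  stopifnot(inherits(spec, "binomial_population_spec"))
  with_seed(spec$seed, {
    comp <- sample.int(nrow(spec$components), spec$n_cells, replace = TRUE,
                       prob = spec$components$weight)
    k <- stats::rbinom(spec$n_cells, spec$n_units, spec$components$p[comp])
    structure(k / spec$n_units, component = comp)
  })
}

#' Generate fluorescence values from a base-10 log-normal mixture
#'
#' @param spec A \code{\link{lognormal_population_spec}}.
#' @return Positive numeric vector of length \code{n_cells} with attribute
#'   \code{"component"} giving each cell's source component.
#' @export
gen_fluorescence <- function(spec) {
  stopifnot(inherits(spec, "lognormal_population_spec"))
  with_seed(spec$seed, {
    comp <- sample.int(nrow(spec$components), spec$n_cells, replace = TRUE,
                       prob = spec$components$weight)
    x <- stats::rnorm(spec$n_cells, spec$components$mu[comp],
                      spec$components$sigma[comp])
    structure(10^x, component = comp)
  })
}

#' Generate a per-cell Hill dose-response table
#'
#' @param spec A \code{\link{hill_curve_spec}}.
#' @return Data frame with columns \code{dose}, \code{dose_unit},
#'   \code{cell_id}, \code{response}. Responses are truncated at zero.
#' @export
gen_dose_response <- function(spec) {
  stopifnot(inherits(spec, "hill_curve_spec"))
  with_seed(spec$seed, {
    dose <- rep(spec$doses, each = spec$cells_per_dose)
    mu <- hill_response(dose, spec$ec50, spec$hill_n, spec$r_max)
    resp <- mu * (1 + stats::rnorm(length(dose), 0, spec$noise_cv))
    resp <- pmax(resp, 0)
    data.frame(dose = dose, dose_unit = spec$dose_unit,
               cell_id = sprintf("cell_%04d", seq_along(dose)),
               response = resp, stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic fura-2 ratio trace
#'
#' @param spec A \code{\link{trace_spec}}.
#' @return A \code{\link{ca_trace}} with the event annotated at
#'   \code{event_time}.
#' @export
gen_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  with_seed(spec$seed, {
    t <- seq(0, spec$duration, by = spec$sample_interval)
    base <- spec$baseline_R + spec$basal_slope * t
    post <- t > spec$event_time
    R <- base
    R[post] <- base[post] + spec$event_slope * (t[post] - spec$event_time)
    R <- pmin(R, spec$plateau_R)
    if (spec$noise_sd > 0) R <- R + stats::rnorm(length(t), 0, spec$noise_sd)
    ev <- stats::setNames(spec$event_time, spec$event_name)
    ca_trace(t, R, events = ev)
  })
}

#' Flow-cytometry population parameters for the bundled reference scenario
#'
#' Returns the three log10-normal parameter sets used throughout the package
#' examples: a resting single-component population and two stimulated
#' two-component (non-responder/responder) mixtures, one for a low
#' thapsigargin dose and one for a saturating dose under depolarising
#' high-K+ conditions.
#'
#' @param n_cells Cells per condition.
#' @param seed Base seed; each condition uses an offset of it.
#' @return Named list of \code{\link{lognormal_population_spec}} objects with
#'   elements \code{rest}, \code{tg30nM}, \code{highK}.
#' @export
facs_reference_specs <- function(n_cells = 15000, seed = .default_seed) {
  list(
    rest = lognormal_population_spec(
      list(c(weight = 1, mu = 2.06, sigma = 0.21)), n_cells, seed = seed),
    tg30nM = lognormal_population_spec(
      list(c(weight = 0.38, mu = 2.37, sigma = 0.17),
           c(weight = 0.62, mu = 3.61, sigma = 0.75)), n_cells,
      seed = seed + 1L),
    highK = lognormal_population_spec(
      list(c(weight = 0.31, mu = 2.29, sigma = 0.17),
           c(weight = 0.69, mu = 4.07, sigma = 0.67)), n_cells,
      seed = seed + 2L)
  )
}

#' Write generated tables in the canonical CSV layouts
#'
#' Helpers writing the four table shapes used across the pipeline:
#' translocation (cell_id, condition, nuclear, cytosolic), fluorescence
#' (cell_id, condition, channel, value), dose-response
#' (dose, dose_unit, cell_id, response) and trace (t_s, R).
#'
#' @param x Object to write (see individual functions).
#' @param path Output CSV path.
#' @param condition,channel Labels recorded in the table.
#' @return The written data frame, invisibly.
#' @name synth_io
NULL

#' @rdname synth_io
#' @export
write_fluorescence_csv <- function(x, path, condition = "cond",
                                   channel = "RFP") {
  df <- data.frame(cell_id = sprintf("cell_%05d", seq_along(x)),
                   condition = condition, channel = channel,
                   value = as.numeric(x), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname synth_io
#' @export
write_trace_csv <- function(x, path) {
  stopifnot(inherits(x, "ca_trace"))
  df <- data.frame(t_s = x$t, R = x$R)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
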