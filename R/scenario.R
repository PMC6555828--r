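# End-to-end orchestration: declarative scenario configs (YAML/JSON or R
# lists) that generate synthetic populations, run every fitting stage and
# collect the results into a single report.

# FNV-1a hash of a character scalar, reported as 8 hex digits; used to stamp
# reports with a digest of the generating config.
.config_hash <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    # h can exceed the integer range, so xor only its low 16 bits (b < 256)
    lo <- bitwXor(h %% 65536, b)
    h <- (h %/% 65536) * 65536 + lo
    # 32-bit multiply by the FNV prime 16777619, done in two 16-bit halves
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Load a scenario configuration
#'
#' A scenario declares named population specs and fit options for any of the
#' four stages: \code{facs} (log-normal mixtures), \code{binomial}
#' (activating-unit populations), \code{hill} (dose-response curves) and
#' \code{trace} (fura-2 ratio traces). Accepts a YAML or JSON file path or
#' an equivalent nested list.
#'
#' @param config Path to a YAML/JSON file, or a list.
#' @return Validated config list of class \code{scenario_config}.
#' @export
load_scenario <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file path")
  known <- c("seed", "facs", "binomial", "hill", "trace", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) config$seed <- .default_seed
  structure(config, class = c("scenario_config", "list"))
}

#' Bundled reference scenario
#'
#' The default end-to-end scenario: the three FACS parameter sets from
#' \code{\link{facs_reference_specs}}, a responder/non-responder binomial
#' population, the two Ca2+-entry dose-response curves and the paired
#' normalized reporter-activation curves, plus one annotated trace.
#'
#' @param seed Base seed for every generator.
#' @param n_cells_facs Cells per FACS condition.
#' @return A \code{scenario_config}.
#' @export
reference_scenario <- function(seed = .default_seed, n_cells_facs = 15000) {
  load_scenario(list(
    seed = seed,
    facs = list(
      rest = list(components = list(c(weight = 1, mu = 2.06, sigma = 0.21)),
                  n_cells = n_cells_facs, mixture = FALSE),
      tg30nM = list(components = list(c(weight = 0.38, mu = 2.37, sigma = 0.17),
                                      c(weight = 0.62, mu = 3.61, sigma = 0.75)),
                    n_cells = n_cells_facs, mixture = TRUE),
      highK = list(components = list(c(weight = 0.31, mu = 2.29, sigma = 0.17),
                                     c(weight = 0.69, mu = 4.07, sigma = 0.67)),
                   n_cells = n_cells_facs, mixture = TRUE)),
    binomial = list(
      tg30nM = list(n_units = 13,
                    components = list(c(weight = 0.2, p = 0.1),
                                      c(weight = 0.8, p = 0.85)),
                    n_cells = 2000)),
    hill = list(
      thapsigargin_entry = list(ec50 = 0.025, hill_n = 0.8, r_max = 0.03,
                                doses = signif(10^seq(log10(0.003), log10(2),
                                                      length.out = 8), 3),
                                cells_per_dose = 15, noise_cv = 0.05,
                                dose_unit = "uM", r_max_mode = "free"),
      ltc4_entry = list(ec50 = 10, hill_n = 1, r_max = 0.03,
                        doses = signif(10^seq(log10(0.1), log10(160),
                                              length.out = 7), 3),
                        cells_per_dose = 20, noise_cv = 0.05,
                        dose_unit = "nM", r_max_mode = "free"),
      nfat_reporter = list(ec50 = 1, hill_n = 1, r_max = 100,
                           doses = signif(10^seq(log10(0.1), log10(160),
                                                 length.out = 7), 3),
                           cells_per_dose = 20, noise_cv = 0.05,
                           dose_unit = "nM", r_max_mode = "fixed"),
      cfos_protein = list(ec50 = 9.8, hill_n = 1, r_max = 100,
                          doses = signif(10^seq(log10(0.1), log10(160),
                                                length.out = 7), 3),
                          cells_per_dose = 20, noise_cv = 0.05,
                          dose_unit = "nM", r_max_mode = "fixed")),
    trace = list(
      readmission = list(duration = 200, sample_interval = 0.5,
                         baseline_R = 0.3, basal_slope = 0.0002,
                         event_time = 60, event_slope = 0.012,
                         plateau_R = 1.6, noise_sd = 0.005,
                         event_name = "readmission",
                         window_s = 20, basal_window_s = 30))))
}

#' Run a scenario end to end
#'
#' Generates every declared population, runs the matching fit stage
#' (single-component or mixture log-normal fits for \code{facs}, binomial
#' mixture fits for \code{binomial}, Hill fits for \code{hill},
#' basal-corrected rates for \code{trace}), and returns a report. If
#' \code{config$out_dir} is set, intermediate CSVs are written there.
#'
#' @param config A \code{scenario_config}, list, or file path (see
#'   \code{\link{load_scenario}}).
#' @return An \code{analysis_report}: per-stage named lists of fit objects,
#'   plus \code{seed} and \code{config_hash}. Deterministic given the seed.
#' @export
run_scenario <- function(config) {
  config <- load_scenario(config)
  seed <- config$seed
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  hash <- .config_hash(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                        digits = NA))
  report <- list(seed = seed, config_hash = hash,
                 version = as.character(utils::packageVersion("caswitch")),
                 facs = list(), binomial = list(), hill = list(),
                 trace = list())
  i <- 0L
  for (nm in names(config$facs)) {
    cfg <- config$facs[[nm]]; i <- i + 1L
    spec <- lognormal_population_spec(cfg$components, cfg$n_cells,
                                      seed = seed + i)
    vals <- gen_fluorescence(spec)
    if (!is.null(out_dir))
      write_fluorescence_csv(vals, file.path(out_dir, paste0("facs_", nm, ".csv")),
                             condition = nm)
    mixture <- isTRUE(cfg$mixture)
    report$facs[[nm]] <- if (mixture) fit_lognormal_mixture(vals)
                         else fit_lognormal(vals)
  }
  for (nm in names(config$binomial)) {
    cfg <- config$binomial[[nm]]; i <- i + 1L
    spec <- binomial_population_spec(cfg$n_units, cfg$components, cfg$n_cells,
                                     seed = seed + i)
    props <- gen_nuclear_proportions(spec)
    report$binomial[[nm]] <-
      if (nrow(spec$components) > 1) fit_binomial_mixture(props, cfg$n_units)
      else fit_binomial(props, cfg$n_units)
  }
  for (nm in names(config$hill)) {
    cfg <- config$hill[[nm]]; i <- i + 1L
    spec <- hill_curve_spec(cfg$ec50, cfg$hill_n, cfg$r_max, cfg$doses,
                            cfg$cells_per_dose, cfg$noise_cv,
                            dose_unit = if (is.null(cfg$dose_unit)) "uM"
                                        else cfg$dose_unit,
                            seed = seed + i)
    tab <- gen_dose_response(spec)
    if (!is.null(out_dir))
      utils::write.csv(tab, file.path(out_dir, paste0("dose_", nm, ".csv")),
                       row.names = FALSE)
    mode <- if (is.null(cfg$r_max_mode)) "free" else cfg$r_max_mode
    report$hill[[nm]] <- fit_hill(tab, r_max_mode = mode,
                                  r_max_fixed = if (mode == "fixed") cfg$r_max
                                                else 100)
  }
  for (nm in names(config$trace)) {
    cfg <- config$trace[[nm]]; i <- i + 1L
    spec <- trace_spec(cfg$duration, cfg$sample_interval, cfg$baseline_R,
                       cfg$basal_slope, cfg$event_time, cfg$event_slope,
                       if (is.null(cfg$plateau_R)) Inf else cfg$plateau_R,
                       cfg$noise_sd,
                       event_name = if (is.null(cfg$event_name)) "addition"
                                    else cfg$event_name,
                       seed = seed + i)
    tr <- gen_trace(spec)
    if (!is.null(out_dir))
      write_trace_csv(tr, file.path(out_dir, paste0("trace_", nm, ".csv")))
    report$trace[[nm]] <- rate_of_rise(
      tr, names(tr$events)[1],
      window_s = if (is.null(cfg$window_s)) 20 else cfg$window_s,
      basal_window_s = if (is.null(cfg$basal_window_s)) 30
                       else cfg$basal_window_s)
  }
  structure(report, class = c("analysis_report", "list"))
}

# Walk a report by a path of component names.
.report_value <- function(report, path) {
  out <- Reduce(function(acc, key) {
    if (is.null(acc)) return(NULL)
    acc[[key]]
  }, path, report)
  if (is.null(out)) stop("no value at path: ", paste(path, collapse = "/"))
  out
}

#' Check a report against declared acceptance targets
#'
#' Each target names a value inside the report (by component path), a
#' reference value, a comparison mode and a tolerance. Supported modes:
#' \code{eq} (|value - ref| <= tol), \code{le} (value <= ref + tol),
#' \code{ge} (value >= ref - tol).
#'
#' @param report An \code{analysis_report} from \code{\link{run_scenario}}.
#' @param targets A list of targets (or a path to a YAML/JSON file of them);
#'   each has \code{id}, \code{path} (character vector into the report),
#'   optional \code{scale} multiplier, \code{ref}, \code{cmp}, \code{tol}.
#' @return Data frame with one row per target (id, value, ref, cmp, tol,
#'   pass) and attribute \code{all_pass}.
#' @export
check_acceptance <- function(report, targets) {
  if (is.character(targets) && length(targets) == 1L) {
    targets <- if (grepl("\\.json$", targets, ignore.case = TRUE))
      jsonlite::read_json(targets, simplifyVector = FALSE)
    else yaml::read_yaml(targets)
  }
  rows <- lapply(targets, function(tg) {
    for (f in c("id", "path", "ref", "cmp", "tol"))
      if (is.null(tg[[f]])) stop("target missing field '", f, "'")
    value <- .report_value(report, unlist(tg$path))
    if (!is.numeric(value) || length(value) != 1L)
      stop("target '", tg$id, "' path does not resolve to a scalar")
    if (!is.null(tg$scale)) value <- value * tg$scale
    pass <- switch(tg$cmp,
                   eq = abs(value - tg$ref) <= tg$tol,
                   le = value <= tg$ref + tg$tol,
                   ge = value >= tg$ref - tg$tol,
                   stop("unknown comparison mode '", tg$cmp, "'"))
    data.frame(id = tg$id, value = value, ref = tg$ref, cmp = tg$cmp,
               tol = tg$tol, pass = pass, stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(id = character(0), value = numeric(0), ref = numeric(0),
               cmp = character(0), tol = numeric(0), pass = logical(0))
  attr(out, "all_pass") <- all(out$pass)
  out
}
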