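# Hill dose-response fitting: Ca2+-entry rate vs SERCA-inhibitor or agonist
# dose, and normalized reporter-activation curves.

#' Evaluate the Hill equation
#'
#' response = r_max * d^n / (d^n + ec50^n). Zero at zero dose, r_max/2 at
#' d = ec50, asymptotically r_max, monotone increasing in dose.
#'
#' @param dose Dose(s), >= 0.
#' @param ec50 Half-maximal dose (> 0).
#' @param hill_n Hill coefficient (> 0).
#' @param r_max Maximal response.
#' @return Response(s) on the scale of \code{r_max}.
#' @export
hill_response <- function(dose, ec50, hill_n, r_max = 1) {
  if (any(dose < 0)) stop("dose must be >= 0")
  # compute on the log scale to avoid overflow at extreme doses
  out <- numeric(length(dose))
  pos <- dose > 0
  z <- hill_n * (log(dose[pos]) - log(ec50))
  out[pos] <- r_max / (1 + exp(-z)) # d^n/(d^n+K^n) = logistic in n*log(d/K)
  out
}

#' Predict from a fitted Hill model
#'
#' @param fit A \code{hill_fit}.
#' @param dose Dose(s), >= 0.
#' @return Predicted response(s).
#' @export
hill_predict <- function(fit, dose) {
  stopifnot(inherits(fit, "hill_fit"))
  hill_response(dose, fit$ec50, fit$hill_n, fit$r_max)
}

# Normalize a dose-response input to a data frame with dose/response
# (per-cell) columns.
.as_series <- function(series) {
  if (is.data.frame(series)) {
    if (!all(c("dose", "response") %in% names(series)))
      stop("series must have 'dose' and 'response' columns")
    return(series)
  }
  if (is.list(series) && all(c("dose", "response") %in% names(series)))
    return(data.frame(dose = series$dose, response = series$response))
  stop("series must be a data frame with dose and response columns")
}

# Per-dose summary: mean response and cell count at each distinct dose.
.dose_means <- function(series) {
  agg <- stats::aggregate(response ~ dose, data = series,
                          FUN = function(r) c(mean = mean(r), n = length(r)))
  data.frame(dose = agg$dose, response = agg$response[, "mean"],
             n = agg$response[, "n"])
}

# Weighted SSE of the Hill model against per-dose means, with r_max either
# fixed or profiled out in closed form (conditionally linear).
.hill_sse <- function(theta, d, y, w, r_max_fixed) {
  ec50 <- 10^theta[1]
  n <- exp(theta[2])
  f <- hill_response(d, ec50, n, 1)
  if (is.null(r_max_fixed)) {
    denom <- sum(w * f^2)
    r_max <- if (denom > 0) sum(w * f * y) / denom else 0
  } else r_max <- r_max_fixed
  sum(w * (y - r_max * f)^2)
}

#' Fit the Hill equation to a dose-response series
#'
#' Nonlinear least squares on per-dose mean responses (weighted by the
#' number of cells per dose), parameterized in log10(EC50) and log(Hill n)
#' to enforce positivity, with deterministic multi-start across the dose
#' range. The maximal response is either fixed (normalized percent-response
#' curves) or profiled out in closed form (raw rate curves).
#'
#' @param series Data frame with columns \code{dose} and \code{response}
#'   (per-cell rows; replicates at a dose are averaged and weighted by
#'   count). An optional \code{dose_unit} column is carried into the fit.
#' @param r_max_mode \code{"free"} (estimate the maximum) or \code{"fixed"}.
#' @param r_max_fixed The fixed maximum when \code{r_max_mode = "fixed"}
#'   (default 100, for percent-response curves).
#' @return A \code{hill_fit} with \code{ec50}, \code{hill_n}, \code{r_max},
#'   \code{sse}, \code{dose_unit}, and flags \code{degenerate} (no dose
#'   dependence) and \code{extrapolated} (EC50 outside the positive dose
#'   range).
#' @export
fit_hill <- function(series, r_max_mode = c("free", "fixed"),
                     r_max_fixed = 100) {
  r_max_mode <- match.arg(r_max_mode)
  series <- .as_series(series)
  dose_unit <- if ("dose_unit" %in% names(series))
    unique(as.character(series$dose_unit))[1] else NA_character_
  dm <- .dose_means(series)
  if (sum(dm$dose > 0) < 3L)
    stop("need at least 3 distinct positive doses")
  d <- dm$dose; y <- dm$response; w <- dm$n
  degenerate <- stats::var(y) < .Machine$double.eps * max(1, mean(y)^2)
  fixed <- if (r_max_mode == "fixed") r_max_fixed else NULL
  pos <- sort(unique(d[d > 0]))
  # starts: EC50 at low/middle/high of the positive dose range, n = 1
  starts <- lapply(log10(c(pos[1], stats::median(pos), pos[length(pos)])),
                   function(l) c(l, 0))
  fits <- lapply(starts, function(th0) {
    stats::nlminb(th0, .hill_sse, d = d, y = y, w = w, r_max_fixed = fixed,
                  control = list(rel.tol = 1e-14, x.tol = 1e-12,
                                 iter.max = 1000, eval.max = 2000))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  ec50 <- 10^best$par[1]
  hill_n <- exp(best$par[2])
  if (is.null(fixed)) {
    f <- hill_response(d, ec50, hill_n, 1)
    r_max <- sum(w * f * y) / sum(w * f^2)
  } else r_max <- fixed
  structure(list(ec50 = ec50, hill_n = hill_n, r_max = r_max,
                 r_max_mode = r_max_mode, sse = best$objective,
                 dose_unit = dose_unit, dose_range = range(pos),
                 n_doses = length(unique(d)), n_cells = nrow(series),
                 degenerate = degenerate,
                 extrapolated = ec50 < pos[1] || ec50 > pos[length(pos)],
                 ci = NULL),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  unit <- if (is.na(x$dose_unit)) "" else paste0(" ", x$dose_unit)
  cat("Hill fit:", x$n_cells, "cells at", x$n_doses, "doses\n")
  cat(sprintf("  EC50 (apparent K_D): %.4g%s\n", x$ec50, unit))
  cat(sprintf("  Hill coefficient:    %.3f\n", x$hill_n))
  cat(sprintf("  maximal response:    %.4g (%s)\n", x$r_max, x$r_max_mode))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI EC50:   [%.4g, %.4g]\n", x$ci$ec50[1], x$ci$ec50[2]))
    cat(sprintf("  95%% CI Hill n: [%.4g, %.4g]\n",
                x$ci$hill_n[1], x$ci$hill_n[2]))
  }
  if (isTRUE(x$degenerate)) cat("  [degenerate: no dose dependence]\n")
  if (isTRUE(x$extrapolated)) cat("  [EC50 outside the dose range]\n")
  invisible(x)
}

# Resample cells within each dose (case bootstrap) and refit once.
.hill_boot_once <- function(series, r_max_mode, r_max_fixed) {
  idx <- unlist(lapply(split(seq_len(nrow(series)), series$dose),
                       function(i) i[sample.int(length(i), replace = TRUE)]))
  fit_hill(series[idx, , drop = FALSE], r_max_mode, r_max_fixed)
}

#' Bootstrap confidence intervals for a Hill fit
#'
#' Case-resampling bootstrap at the cell level within each dose; percentile
#' 95% intervals for the EC50 and the Hill coefficient.
#'
#' @param series Per-cell dose-response data frame (as for
#'   \code{\link{fit_hill}}).
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @inheritParams fit_hill
#' @return The \code{hill_fit} for the full data with a \code{ci} element:
#'   a list of 95% percentile intervals for \code{ec50} and \code{hill_n},
#'   plus the bootstrap draws in \code{boot}.
#' @export
bootstrap_ci <- function(series, B = 999, seed = .default_seed,
                         r_max_mode = c("free", "fixed"), r_max_fixed = 100) {
  if (B < 100) stop("B must be at least 100")
  r_max_mode <- match.arg(r_max_mode)
  series <- .as_series(series)
  fit <- fit_hill(series, r_max_mode, r_max_fixed)
  draws <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      fb <- .hill_boot_once(series, r_max_mode, r_max_fixed)
      c(ec50 = fb$ec50, hill_n = fb$hill_n)
    }, numeric(2)))
  })
  fit$ci <- list(
    ec50 = unname(stats::quantile(draws[, "ec50"], c(0.025, 0.975))),
    hill_n = unname(stats::quantile(draws[, "hill_n"], c(0.025, 0.975))),
    B = B, boot = draws)
  fit
}

#' Compare the EC50s of two dose-response series
#'
#' Fits both series, reports the EC50 ratio (series b over series a), and a
#' bootstrap percentile interval for the ratio from paired case resampling
#' of the two series. Separation is declared when the interval excludes 1 —
#' e.g. a left-shifted NFAT-reporter curve versus a c-fos curve.
#'
#' @param series_a,series_b Per-cell dose-response data frames. If both
#'   carry a \code{dose_unit} column the units must match.
#' @param B Bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @inheritParams fit_hill
#' @return List with \code{fit_a}, \code{fit_b}, \code{ratio}
#'   (ec50_b / ec50_a), \code{ci} (95% percentile interval for the ratio)
#'   and logical \code{separated}.
#' @export
compare_ec50 <- function(series_a, series_b, B = 999, seed = .default_seed,
                         r_max_mode = c("free", "fixed"), r_max_fixed = 100) {
  if (B < 100) stop("B must be at least 100")
  r_max_mode <- match.arg(r_max_mode)
  series_a <- .as_series(series_a); series_b <- .as_series(series_b)
  ua <- if ("dose_unit" %in% names(series_a))
    unique(as.character(series_a$dose_unit)) else NULL
  ub <- if ("dose_unit" %in% names(series_b))
    unique(as.character(series_b$dose_unit)) else NULL
  if (!is.null(ua) && !is.null(ub) && !identical(sort(ua), sort(ub)))
    stop("dose units differ between the two series")
  fit_a <- fit_hill(series_a, r_max_mode, r_max_fixed)
  fit_b <- fit_hill(series_b, r_max_mode, r_max_fixed)
  ratios <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      fa <- .hill_boot_once(series_a, r_max_mode, r_max_fixed)
      fb <- .hill_boot_once(series_b, r_max_mode, r_max_fixed)
      fb$ec50 / fa$ec50
    }, numeric(1))
  })
  ci <- unname(stats::quantile(ratios, c(0.025, 0.975)))
  list(fit_a = fit_a, fit_b = fit_b, ratio = fit_b$ec50 / fit_a$ec50,
       ci = ci, separated = ci[1] > 1 || ci[2] < 1, B = B)
}
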