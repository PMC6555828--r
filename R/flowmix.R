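# FACS analysis: base-10 log-normal single and two-component mixture fits,
# mixture summaries (mean, median, tail fractions), quadrant statistics and
# reporter-positivity calls.

.check_positive_values <- function(values) {
  bad <- sum(!is.finite(values) | values <= 0)
  if (bad > 0)
    stop(bad, " nonpositive or non-finite fluorescence value(s); ",
         "exclude them before fitting (see drop_nonpositive())")
  invisible(values)
}

#' Drop nonpositive fluorescence values
#'
#' Flow-cytometry exports can contain zero or negative values after
#' compensation; model fitting requires strictly positive fluorescence.
#' Removes offending values and reports how many were dropped.
#'
#' @param values Numeric fluorescence values.
#' @param quiet Suppress the message.
#' @return The positive finite values; the number removed is attached as
#'   attribute \code{"n_dropped"}.
#' @export
drop_nonpositive <- function(values, quiet = FALSE) {
  keep <- is.finite(values) & values > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0 && !quiet)
    message("dropped ", n_dropped, " nonpositive/non-finite value(s)")
  structure(values[keep], n_dropped = n_dropped)
}

#' Fit a single base-10 log-normal component
#'
#' Maximum-likelihood fit of log10(H) ~ N(mu, sigma): mu-hat is the mean of
#' the log10 values and sigma-hat the population (divisor-N) standard
#' deviation, consistent with the likelihood used by the mixture EM.
#'
#' @param values Positive fluorescence values (>= 2).
#' @return A \code{lognormal_component} with fields \code{mu}, \code{sigma},
#'   \code{n_obs}, \code{loglik} (of log10 values) and a \code{degenerate}
#'   flag when sigma is 0.
#' @export
fit_lognormal <- function(values) {
  .check_positive_values(values)
  if (length(values) < 2L) stop("need at least 2 values")
  x <- log10(values)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  ll <- if (sigma > 0) sum(stats::dnorm(x, mu, sigma, log = TRUE)) else Inf
  structure(list(mu = mu, sigma = sigma, n_obs = length(x), loglik = ll,
                 degenerate = sigma == 0),
            class = "lognormal_component")
}

# One EM run for a 2-component normal mixture on x (log10 values).
.norm_mix_em <- function(x, w0, mu0, sd0, max_iter, tol) {
  eps_sd <- 1e-6
  w <- c(w0, 1 - w0); mu <- mu0; sd <- pmax(sd0, eps_sd)
  ll_old <- -Inf; trajectory <- numeric(0); converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sd[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trajectory <- c(trajectory, ll)
    if (ll < ll_old - 1e-9)
      stop("internal error: EM log-likelihood decreased")
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    r1 <- d1 / tot
    s1 <- sum(r1); s2 <- length(x) - s1
    if (s1 < 1e-8 || s2 < 1e-8) break  # a component emptied out
    w[1] <- s1 / length(x); w[2] <- 1 - w[1]
    mu[1] <- sum(r1 * x) / s1
    mu[2] <- sum((1 - r1) * x) / s2
    sd[1] <- sqrt(sum(r1 * (x - mu[1])^2) / s1)
    sd[2] <- sqrt(sum((1 - r1) * (x - mu[2])^2) / s2)
    sd <- pmax(sd, eps_sd)
  }
  list(w = w, mu = mu, sd = sd, loglik = ll, trajectory = trajectory,
       converged = converged)
}

#' Fit a two-component base-10 log-normal mixture
#'
#' Decomposes a fluorescence population into non-responders and responders:
#' log10(H) ~ alpha * N(mu_n, sigma_n) + (1 - alpha) * N(mu_r, sigma_r),
#' where alpha is the non-responder fraction. Fitted by EM on log10 values
#' with deterministic multi-start: splits at the 20/80 and 35/65 quantiles
#' plus a 2-means-style split; the best log-likelihood wins, ties going to
#' the smaller alpha. The smaller-mean component is labelled non-responder.
#'
#' @param values Positive fluorescence values (>= 20).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Log-likelihood convergence tolerance (default 1e-8).
#' @return A \code{lognormal_mixture_fit} with fields \code{alpha}
#'   (non-responder weight), \code{nonresponder} and \code{responder}
#'   (each a \code{lognormal_component}), \code{loglik}, \code{n_obs},
#'   \code{converged} and \code{degenerate} (boundary alpha or collapsed
#'   components).
#' @export
fit_lognormal_mixture <- function(values, max_iter = 500, tol = 1e-8) {
  .check_positive_values(values)
  if (length(values) < 20L) stop("need at least 20 values for a mixture fit")
  x <- log10(values)
  starts <- list()
  for (q in c(0.2, 0.35, 0.5, 0.65, 0.8)) {
    thr <- stats::quantile(x, q, names = FALSE)
    lo <- x <= thr
    if (all(lo) || !any(lo)) next
    starts[[length(starts) + 1L]] <-
      list(w0 = mean(lo), mu0 = c(mean(x[lo]), mean(x[!lo])),
           sd0 = c(stats::sd(x[lo]), stats::sd(x[!lo])))
  }
  # 2-means-style split: iterate nearest-centre assignment from the range ends
  ctr <- range(x)
  if (diff(ctr) > 0) {
    for (i in 1:10) {
      lo <- abs(x - ctr[1]) <= abs(x - ctr[2])
      new_ctr <- c(mean(x[lo]), mean(x[!lo]))
      if (isTRUE(all.equal(new_ctr, ctr))) break
      ctr <- new_ctr
    }
    lo <- abs(x - ctr[1]) <= abs(x - ctr[2])
    if (any(lo) && !all(lo))
      starts[[length(starts) + 1L]] <-
        list(w0 = mean(lo), mu0 = c(mean(x[lo]), mean(x[!lo])),
             sd0 = c(stats::sd(x[lo]), stats::sd(x[!lo])))
  }
  if (length(starts) == 0L)
    starts <- list(list(w0 = 0.5, mu0 = mean(x) + c(-0.1, 0.1),
                        sd0 = rep(max(stats::sd(x), 0.05), 2)))
  starts <- lapply(starts, function(s) {
    s$sd0[!is.finite(s$sd0) | s$sd0 <= 0] <- max(stats::sd(x) / 2, 1e-3)
    s
  })
  runs <- lapply(starts, function(s)
    .norm_mix_em(x, s$w0, s$mu0, s$sd0, max_iter, tol))
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  # ties in log-likelihood go to the smaller non-responder weight
  alpha_of <- function(r) r$w[which.min(r$mu)]
  best_idx <- order(-lls, vapply(runs, alpha_of, numeric(1)))[1]
  best <- runs[[best_idx]]
  ord <- order(best$mu)  # non-responder (smaller mean) first
  w <- best$w[ord]; mu <- best$mu[ord]; sd <- best$sd[ord]
  degenerate <- min(w) < 1e-3 || abs(diff(mu)) < 1e-6
  comp <- function(i) structure(list(mu = mu[i], sigma = sd[i],
                                     n_obs = length(x), loglik = NA_real_,
                                     degenerate = sd[i] <= 1e-6),
                                class = "lognormal_component")
  structure(list(alpha = w[1], nonresponder = comp(1), responder = comp(2),
                 loglik = best$loglik, n_obs = length(x),
                 converged = best$converged, degenerate = degenerate,
                 em_trajectory = best$trajectory),
            class = "lognormal_mixture_fit")
}

#' @export
print.lognormal_mixture_fit <- function(x, ...) {
  cat("Two-component base-10 log-normal mixture (n =", x$n_obs, ")\n")
  cat(sprintf("  non-responders: alpha = %.3f, mu = %.3f, sigma = %.3f\n",
              x$alpha, x$nonresponder$mu, x$nonresponder$sigma))
  cat(sprintf("  responders:     1-alpha = %.3f, mu = %.3f, sigma = %.3f\n",
              1 - x$alpha, x$responder$mu, x$responder$sigma))
  cat("  log-likelihood:", format(x$loglik), "\n")
  if (isTRUE(x$degenerate)) cat("  [degenerate fit]\n")
  if (!isTRUE(x$converged)) cat("  [did not converge]\n")
  invisible(x)
}

# Internal: mixture parameters as (weights, mus, sigmas) from a fit object
# (a lognormal_component counts as a 1-component mixture).
.mix_params <- function(fit) {
  if (inherits(fit, "lognormal_component"))
    return(list(w = 1, mu = fit$mu, sigma = fit$sigma))
  if (inherits(fit, "lognormal_mixture_fit"))
    return(list(w = c(fit$alpha, 1 - fit$alpha),
                mu = c(fit$nonresponder$mu, fit$responder$mu),
                sigma = c(fit$nonresponder$sigma, fit$responder$sigma)))
  stop("fit must be a lognormal_component or lognormal_mixture_fit")
}

# CDF of the fluorescence mixture at threshold x (fluorescence scale).
.mix_cdf <- function(fit, x) {
  pp <- .mix_params(fit)
  lx <- log10(x)
  vapply(lx, function(l) {
    sum(ifelse(pp$sigma > 0,
               pp$w * stats::pnorm(l, pp$mu, pp$sigma),
               pp$w * as.numeric(l >= pp$mu)))
  }, numeric(1))
}

#' Median of a fitted fluorescence mixture
#'
#' Solves mixtureCDF(x) = 0.5 for x on the fluorescence scale, to relative
#' tolerance 1e-10. For a single component the median is exactly 10^mu
#' (log-normal median). Degenerate sigma = 0 components are treated as point
#' masses.
#'
#' @param fit A \code{lognormal_component} or \code{lognormal_mixture_fit}.
#' @return Median fluorescence in original (a.u.) units.
#' @export
mixture_median <- function(fit) {
  pp <- .mix_params(fit)
  if (length(pp$w) == 1L || any(pp$w >= 1 - 1e-12))
    return(10^pp$mu[which.max(pp$w)])
  lo <- min(pp$mu - 10 * pmax(pp$sigma, 1e-6))
  hi <- max(pp$mu + 10 * pmax(pp$sigma, 1e-6))
  f <- function(l) .mix_cdf(fit, 10^l) - 0.5
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  10^root
}

#' Mean of a fitted fluorescence mixture (closed form)
#'
#' The mean of a base-10 log-normal component is
#' 10^mu * exp((sigma * ln 10)^2 / 2); the mixture mean is the weighted sum.
#' The mean always exceeds the median when any component has sigma > 0 — the
#' right skew that makes raw-scale FACS means look inflated relative to
#' medians.
#'
#' @param fit A \code{lognormal_component} or \code{lognormal_mixture_fit}.
#' @return Mean fluorescence in original (a.u.) units.
#' @export
mixture_mean <- function(fit) {
  pp <- .mix_params(fit)
  sum(pp$w * 10^pp$mu * exp((pp$sigma * log(10))^2 / 2))
}

#' Fraction of cells at or above a fluorescence threshold
#'
#' Empirical mode (numeric \code{x}): the proportion of values >= threshold
#' (inclusive). Model mode (a fit object): 1 - mixtureCDF just below the
#' threshold, matching the same ">=" convention (the distinction only
#' matters for point masses).
#'
#' @param x Numeric fluorescence values, or a fitted mixture/component.
#' @param threshold Positive fluorescence threshold.
#' @return Fraction in [0, 1].
#' @export
fraction_above <- function(x, threshold) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (is.numeric(x)) return(mean(x >= threshold))
  pp <- .mix_params(x)
  lx <- log10(threshold)
  sum(ifelse(pp$sigma > 0,
             pp$w * stats::pnorm(lx, pp$mu, pp$sigma, lower.tail = FALSE),
             pp$w * as.numeric(pp$mu >= lx)))
}

#' Derive a responder threshold from a blank (unstained) sample
#'
#' The threshold is twice the largest intensity observed in the blank group.
#' Using the maximum (not a quantile) makes the rule sensitive to blank
#' outliers; callers should inspect the blank distribution.
#'
#' @param blank_values Nonempty numeric blank intensities.
#' @return Threshold = 2 * max(blank_values).
#' @export
derive_blank_threshold <- function(blank_values) {
  if (length(blank_values) == 0L) stop("blank sample is empty")
  2 * max(blank_values)
}

#' Quadrant statistics for a two-channel scatter
#'
#' Divides paired per-cell fluorescence values into four quadrants using
#' per-channel thresholds, following the convention with y = NFAT reporter
#' (RFP) and x = c-fos reporter (YFP): Q1 = high y only, Q2 = high both,
#' Q3 = high x only, Q4 = neither. "High" means strictly above the
#' threshold.
#'
#' @param x_values,y_values Equal-length paired fluorescence values.
#' @param x_threshold,y_threshold Channel thresholds.
#' @return A \code{quadrant_stats} list with the thresholds, counts and
#'   percentages \code{q1}..\code{q4} (summing to 100).
#' @export
quadrant_stats <- function(x_values, y_values, x_threshold, y_threshold) {
  if (length(x_values) != length(y_values))
    stop("x_values and y_values must have equal length")
  if (length(x_values) == 0L) stop("no cells supplied")
  hx <- x_values > x_threshold
  hy <- y_values > y_threshold
  n <- length(x_values)
  counts <- c(q1 = sum(!hx & hy), q2 = sum(hx & hy),
              q3 = sum(hx & !hy), q4 = sum(!hx & !hy))
  pct <- 100 * counts / n
  structure(list(x_threshold = x_threshold, y_threshold = y_threshold,
                 n = n, counts = counts,
                 q1 = pct[["q1"]], q2 = pct[["q2"]],
                 q3 = pct[["q3"]], q4 = pct[["q4"]]),
            class = "quadrant_stats")
}

#' Call reporter-positive cells against an autofluorescence blank
#'
#' A cell is reporter-positive when its fluorescence strictly exceeds
#' mean(blank) + 3 * SD(blank), i.e. expression must clear the cell
#' autofluorescence by three standard deviations.
#'
#' @param values Per-cell fluorescence values to score.
#' @param blank_values Autofluorescence sample (>= 2 values, so the SD is
#'   defined).
#' @return List with \code{threshold}, logical \code{positive} mask and
#'   \code{fraction} positive.
#' @export
reporter_positive <- function(values, blank_values) {
  if (length(blank_values) < 2L)
    stop("blank sample needs at least 2 values to estimate an SD")
  thr <- mean(blank_values) + 3 * stats::sd(blank_values)
  pos <- values > thr
  list(threshold = thr, positive = pos, fraction = mean(pos))
}
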