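# Fura-2 ratio trace analysis: basal-corrected rates of rise following
# solution additions (Ca2+ readmission, ionomycin challenge, Ba2+ entry).

#' Construct a fura-2 ratio trace
#'
#' @param t Time in seconds, strictly increasing.
#' @param R 356/380 nm fluorescence ratio (dimensionless), finite.
#' @param events Named numeric vector of addition times, e.g.
#'   \code{c(readmission = 300)}.
#' @return A \code{ca_trace} list with elements \code{t}, \code{R},
#'   \code{events}.
#' @export
ca_trace <- function(t, R, events = numeric(0)) {
  if (length(t) != length(R)) stop("t and R must have equal length")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (any(!is.finite(R))) stop("R must be finite")
  events <- unlist(events)
  if (length(events) > 0 && is.null(names(events)))
    stop("events must be named")
  structure(list(t = as.numeric(t), R = as.numeric(R), events = events),
            class = "ca_trace")
}

#' Read a trace CSV (t_s, R) with an optional events sidecar
#'
#' @param path CSV with columns \code{t_s} and \code{R}.
#' @param events_path Optional CSV with columns \code{event} and \code{t_s}.
#' @return A \code{ca_trace}.
#' @export
read_trace_csv <- function(path, events_path = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "R") %in% names(df)))
    stop("trace CSV must have columns t_s and R")
  ev <- numeric(0)
  if (!is.null(events_path)) {
    edf <- utils::read.csv(events_path)
    if (!all(c("event", "t_s") %in% names(edf)))
      stop("events CSV must have columns event and t_s")
    ev <- stats::setNames(edf$t_s, edf$event)
  }
  ca_trace(df$t_s, df$R, ev)
}

.ols_slope <- function(t, R) {
  ct <- t - mean(t)
  slope <- sum(ct * (R - mean(R))) / sum(ct^2)
  pred <- mean(R) + slope * ct
  ss_tot <- sum((R - mean(R))^2)
  r2 <- if (ss_tot > 0) 1 - sum((R - pred)^2) / ss_tot else 1
  list(slope = slope, r2 = r2)
}

#' Basal-corrected rate of rise after an addition event
#'
#' Estimates the initial rate of rise of the ratio signal after an event:
#' an ordinary least-squares slope over \code{window_s} seconds from signal
#' onset, minus the OLS slope over the \code{basal_window_s} seconds
#' preceding the event (basal drift subtraction). Onset is the first
#' post-event sample where R exceeds the basal mean by 3 basal SDs; if the
#' signal never crosses that level the event time itself is used and the
#' estimate is flagged.
#'
#' @param trace A \code{\link{ca_trace}}.
#' @param event Name of an annotated event.
#' @param window_s Length of the post-onset analysis window in seconds
#'   (default 20).
#' @param basal_window_s Length of the pre-event basal window in seconds
#'   (default 30).
#' @return A \code{rate_estimate} with \code{slope} (R/s, basal-corrected),
#'   \code{basal_slope}, \code{window}, \code{r2} of the post-onset fit,
#'   \code{corrected = TRUE}, \code{onset} time and \code{onset_detected}.
#' @export
rate_of_rise <- function(trace, event, window_s = 20, basal_window_s = 30) {
  stopifnot(inherits(trace, "ca_trace"))
  if (!event %in% names(trace$events))
    stop("event '", event, "' is not annotated on this trace")
  t_ev <- trace$events[[event]]
  t <- trace$t; R <- trace$R
  basal_idx <- which(t >= t_ev - basal_window_s & t <= t_ev)
  if (length(basal_idx) < 4L)
    stop("fewer than 4 samples in the basal window")
  if (min(t) > t_ev - basal_window_s)
    stop("basal window extends before the start of the trace")
  basal <- .ols_slope(t[basal_idx], R[basal_idx])
  basal_mean <- mean(R[basal_idx])
  basal_sd <- stats::sd(R[basal_idx])
  post_idx <- which(t > t_ev)
  crossing <- post_idx[R[post_idx] > basal_mean + 3 * basal_sd]
  onset_detected <- length(crossing) > 0
  t_onset <- if (onset_detected) t[crossing[1]] else t_ev
  win_idx <- which(t >= t_onset & t <= t_onset + window_s)
  if (length(win_idx) < 4L)
    stop("fewer than 4 samples in the analysis window")
  if (max(t) < t_onset + window_s)
    stop("analysis window extends past the end of the trace")
  post <- .ols_slope(t[win_idx], R[win_idx])
  structure(list(slope = post$slope - basal$slope,
                 raw_slope = post$slope, basal_slope = basal$slope,
                 window = c(t_onset, t_onset + window_s),
                 basal_window = c(t_ev - basal_window_s, t_ev),
                 onset = t_onset, onset_detected = onset_detected,
                 corrected = TRUE, r2 = post$r2, event = event),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Rate estimate after '%s'%s\n", x$event,
              if (!is.null(x$label)) paste0(" (", x$label, ")") else ""))
  cat(sprintf("  corrected slope: %.5g R/s (raw %.5g, basal %.5g)\n",
              x$slope, x$raw_slope, x$basal_slope))
  cat(sprintf("  window: [%.1f, %.1f] s, R^2 = %.3f\n",
              x$window[1], x$window[2], x$r2))
  if (!x$onset_detected) cat("  [no onset detected; event time used]\n")
  invisible(x)
}

#' Store-content proxy: initial rate of the ionomycin-evoked transient
#'
#' The initial rate of rise of cytosolic Ca2+ after ionomycin challenge in
#' Ca2+-free solution reflects the free Ca2+ remaining in the stores, so it
#' serves as a proxy for store content (a flat response indicates empty
#' stores). Same estimator as \code{\link{rate_of_rise}}.
#'
#' @param trace A \code{\link{ca_trace}}.
#' @param ionomycin_event Name of the ionomycin addition event.
#' @inheritParams rate_of_rise
#' @return A \code{rate_estimate} labelled "store-content proxy".
#' @export
store_content_proxy <- function(trace, ionomycin_event = "ionomycin",
                                window_s = 20, basal_window_s = 30) {
  est <- rate_of_rise(trace, ionomycin_event, window_s, basal_window_s)
  est$label <- "store-content proxy"
  est
}

#' Ba2+ entry rate
#'
#' Ba2+ permeates CRAC channels, binds fura-2 and is not extruded by
#' Ca2+-ATPases, so the rate of rise of the Ba2+-induced signal estimates
#' store-operated divalent-cation influx directly. Same estimator as
#' \code{\link{rate_of_rise}}.
#'
#' @param trace A \code{\link{ca_trace}}.
#' @param ba_event Name of the Ba2+ addition event.
#' @inheritParams rate_of_rise
#' @return A \code{rate_estimate} labelled "Ba2+ entry".
#' @export
ba_entry_rate <- function(trace, ba_event = "ba2", window_s = 20,
                          basal_window_s = 30) {
  est <- rate_of_rise(trace, ba_event, window_s, basal_window_s)
  est$label <- "Ba2+ entry"
  est
}
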