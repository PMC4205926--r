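#' Trapezoid area under a curve over a window
#'
#' Standard linear trapezoid with linear interpolation at the window edges.
#'
#' @param times sampling times (h), strictly increasing.
#' @param values sampled values.
#' @param window numeric length-2, `c(start, end)`; must lie within the
#'   sampled range.
#' @return area (value units x h).
#' @export
auc_trapezoid <- function(times, values, window) {
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (length(window) != 2 || window[2] <= window[1])
    stop("`window` must be c(start, end) with end > start", call. = FALSE)
  if (window[1] < times[1] || window[2] > times[length(times)])
    stop("window wider than the sampled data", call. = FALSE)
  inside <- times > window[1] & times < window[2]
  tt <- c(window[1], times[inside], window[2])
  vv <- stats::approx(times, values, xout = tt)$y
  sum(diff(tt) * (vv[-length(vv)] + vv[-1]) / 2)
}

.interp_at <- function(result, var, t) {
  if (!var %in% names(result))
    stop("required output variable missing: ", var, call. = FALSE)
  stats::approx(result$time, result[[var]], xout = t)$y
}

#' Clinical endpoints from a simulated time course
#'
#' Computes, for each requested protocol day, the fasting plasma glucose and
#' insulin (read just before the morning fasting clock time, i.e. pre-dose
#' and pre-meal), the OGTT glucose AUC over the protocol's AUC window, the
#' 2-h post-load glucose, and the percent change in fasting insulin versus
#' the reference day.
#'
#' @param result simulation result (data.frame with `time`, `G_plasma`,
#'   `I_plasma`, ...).
#' @param protocol the [protocol()] that produced it.
#' @param days protocol days to evaluate; defaults to the OGTT days (plus
#'   the reference day).
#' @param reference_day day whose fasting insulin anchors the percent
#'   change (default 0, the first dosing day).
#' @param require_ogtt error (instead of returning `NA`) when a requested
#'   day carries no flagged OGTT event to anchor the AUC window.
#' @return data.frame with one row per day: `day`, `FPG` (mM), `FPI` (pM),
#'   `AUC_glucose` (mM.h, `NA` when the day has no OGTT),
#'   `G_2h_post_OGTT` (mM), `FPI_pct_change` (%).
#' @export
compute_endpoints <- function(result, protocol, days = NULL,
                              reference_day = 0, require_ogtt = FALSE) {
  for (var in c("G_plasma", "I_plasma"))
    if (!var %in% names(result))
      stop("required output variable missing: ", var, call. = FALSE)
  ogtt_days <- vapply(protocol$ogtt, `[[`, 0, "day")
  if (is.null(days)) days <- sort(unique(c(reference_day, ogtt_days)))

  fasting_t <- function(day) day * 24 + protocol$fasting_clock - 0.05
  fpg <- vapply(days, function(d) .interp_at(result, "G_plasma", fasting_t(d)), 0)
  fpi <- vapply(days, function(d) .interp_at(result, "I_plasma", fasting_t(d)), 0)
  fpi_ref <- .interp_at(result, "I_plasma", fasting_t(reference_day))

  auc <- g2h <- rep(NA_real_, length(days))
  for (i in seq_along(days)) {
    k <- which(ogtt_days == days[i])
    if (!length(k)) {
      if (require_ogtt)
        stop("no flagged OGTT event on day ", days[i],
             ": AUC window undefined", call. = FALSE)
      next
    }
    ev <- protocol$ogtt[[k[1]]]
    win <- c(ev$time, ev$time + protocol$auc_window)
    auc[i] <- auc_trapezoid(result$time, result$G_plasma, win)
    if (protocol$incremental_auc) {
      base <- .interp_at(result, "G_plasma", ev$time)
      auc[i] <- auc[i] - base * protocol$auc_window
    }
    g2h[i] <- .interp_at(result, "G_plasma", ev$time + 2)
  }
  data.frame(day = days, FPG = fpg, FPI = fpi, AUC_glucose = auc,
             G_2h_post_OGTT = g2h,
             FPI_pct_change = 100 * (fpi - fpi_ref) / fpi_ref)
}
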