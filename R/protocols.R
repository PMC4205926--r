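#' Meal definition
#'
#' @param time clock time (h, 0-24).
#' @param kcal caloric content.
#' @param carb,fat,prot energy fractions; must be non-negative and sum to 1.
#' @return object of class `meal`.
#' @export
meal <- function(time, kcal, carb = 0.5, fat = 0.3, prot = 0.2) {
  stopifnot(time >= 0, time < 24, kcal >= 0)
  fr <- c(carb, fat, prot)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
    stop("macronutrient fractions must be >= 0 and sum to 1", call. = FALSE)
  structure(list(time = time, kcal = kcal, carb = carb, fat = fat,
                 prot = prot), class = "meal")
}

#' Standard three-meal daily schedule
#' @param kcal_per_day total daily energy.
#' @param carb,fat,prot shared macronutrient fractions.
#' @return list of three [meal()]s at 08:00, 13:00 and 19:00.
#' @export
standard_meals <- function(kcal_per_day = 1800, carb = 0.5, fat = 0.3,
                           prot = 0.2) {
  lapply(c(8, 13, 19), meal, kcal = kcal_per_day / 3, carb = carb,
         fat = fat, prot = prot)
}

#' Dosing regimen
#'
#' Contiguous segments of once- or twice-daily oral dosing, e.g. the
#' escalating schedule `500 mg qd x 7 d, 500 mg bid x 7 d, 1000 mg bid x
#' 14 d`.
#'
#' @param drug drug name (must match a [drug_parameters()] name).
#' @param segments list of `list(dose_mg=, schedule=, n_days=)`; schedules
#'   are `"qd"` or `"bid"`.
#' @param morning_time clock time of the (first) daily dose (h); `bid` adds
#'   a second dose 12 h later.
#' @return object of class `regimen`.
#' @export
regimen <- function(drug, segments, morning_time = 8) {
  for (s in segments) {
    stopifnot(all(c("dose_mg", "schedule", "n_days") %in% names(s)))
    if (!s$schedule %in% c("qd", "bid"))
      stop("unknown schedule token: ", s$schedule, call. = FALSE)
    if (s$dose_mg < 0) stop("doses must be >= 0", call. = FALSE)
    if (s$n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  }
  structure(list(drug = drug, segments = segments,
                 morning_time = morning_time), class = "regimen")
}

#' Expand regimen segments into timed dose events
#'
#' Day 0 is the first dosing day; `qd` gives one event per day at the
#' morning clock time, `bid` two events 12 h apart.  Segments are contiguous
#' in time, so the event count is `sum(n_days * doses_per_day)`.
#'
#' @param segments list of segments as in [regimen()], or a `regimen`.
#' @param morning_time clock time of the morning dose (h).
#' @return data.frame with columns `time` (h from day-0 midnight),
#'   `dose_mg`, `day`, sorted by time.
#' @export
build_regimen <- function(segments, morning_time = 8) {
  if (inherits(segments, "regimen")) {
    morning_time <- segments$morning_time
    segments <- segments$segments
  }
  day0 <- 0
  out <- list()
  for (s in segments) {
    if (!s$schedule %in% c("qd", "bid"))
      stop("unknown schedule token: ", s$schedule, call. = FALSE)
    days <- day0 + seq_len(s$n_days) - 1
    clock <- if (s$schedule == "qd") morning_time
             else c(morning_time, morning_time + 12)
    grid <- expand.grid(clock = clock, day = days)
    out[[length(out) + 1]] <- data.frame(time = grid$day * 24 + grid$clock,
                                         dose_mg = s$dose_mg,
                                         day = grid$day)
    day0 <- day0 + s$n_days
  }
  if (!length(out))
    return(data.frame(time = numeric(), dose_mg = numeric(),
                      day = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$time), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Oral glucose tolerance test event
#'
#' A carbohydrate-only bolus into the gut at the stated day and clock time,
#' flagged so endpoint computation knows where the OGTT window starts.
#' Day 0 is the first dosing day of the protocol.
#'
#' @param glucose_g glucose load (g), `> 0`.
#' @param day protocol day index (0-based).
#' @param clock_time clock time (h).
#' @return object of class `ogtt_event` with element `time = day*24 +
#'   clock_time`.
#' @export
build_ogtt <- function(glucose_g = 75, day = 0, clock_time = 8) {
  if (glucose_g <= 0) stop("OGTT glucose load must be > 0", call. = FALSE)
  structure(list(glucose_g = glucose_g, day = day, clock_time = clock_time,
                 time = day * 24 + clock_time), class = "ogtt_event")
}

#' Simulation protocol
#'
#' Timed external inputs of one simulation: daily meal schedule, drug
#' regimens, OGTT events, requested outputs and output interval.  A run-in
#' period (meals only, negative time) lets the physiology settle onto its
#' fed periodic orbit before day 0, the first dosing day.
#'
#' @param duration_days protocol length from day 0 (days).
#' @param meals list of [meal()]s (at most three per day).
#' @param regimens list of [regimen()]s.
#' @param ogtt list of [build_ogtt()] events.
#' @param outputs character vector of state/output names to report.
#' @param output_interval sampling interval (h), `> 0`.
#' @param run_in_days meals-only settling days before day 0.
#' @param fasting_clock clock time at which fasting (pre-dose, pre-meal)
#'   values are read (h).
#' @param auc_window OGTT glucose AUC window length (h).
#' @param incremental_auc report AUC above the pre-load fasting level
#'   instead of total AUC.
#' @return object of class `protocol`.
#' @export
protocol <- function(duration_days, meals = standard_meals(),
                     regimens = list(), ogtt = list(),
                     outputs = c("G_plasma", "I_plasma", "Cpep", "Gn_1",
                                 "FFA_plasma", "TAG_plasma", "GLP1", "GIP"),
                     output_interval = 0.25, run_in_days = 3,
                     fasting_clock = 8, auc_window = 2,
                     incremental_auc = FALSE) {
  stopifnot(duration_days >= 1, output_interval > 0, run_in_days >= 0,
            auc_window > 0)
  if (length(meals) > 3) stop("at most three meals per day", call. = FALSE)
  for (m in meals) stopifnot(inherits(m, "meal"))
  if (inherits(regimens, "regimen")) regimens <- list(regimens)
  if (inherits(ogtt, "ogtt_event")) ogtt <- list(ogtt)
  horizon <- duration_days * 24
  for (r in regimens) {
    ev <- build_regimen(r)
    if (nrow(ev) && max(ev$time) > horizon)
      stop("regimen extends beyond protocol duration", call. = FALSE)
  }
  for (o in ogtt) {
    stopifnot(inherits(o, "ogtt_event"))
    if (o$time > horizon)
      stop("OGTT event outside protocol duration", call. = FALSE)
  }
  structure(list(duration_days = duration_days, meals = meals,
                 regimens = regimens, ogtt = ogtt, outputs = outputs,
                 output_interval = output_interval,
                 run_in_days = run_in_days, fasting_clock = fasting_clock,
                 auc_window = auc_window,
                 incremental_auc = incremental_auc),
            class = "protocol")
}
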