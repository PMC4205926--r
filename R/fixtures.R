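#' Representative T2DM phenotype overrides
#'
#' The three canonical insulin-resistance defects — hepatic insulin
#' sensitivity, peripheral insulin sensitivity and beta-cell function — set
#' so that the fasting steady state and the OGTT response of the
#' representative patient match a newly treated T2DM profile (fasting
#' glucose ~10.1 mM, fasting insulin ~90 pM, 0-2 h OGTT glucose AUC
#' ~29.9 mM.h).  Values frozen from a one-off calibration run.
#'
#' @return named list of parameter overrides.
#' @export
t2dm_overrides <- function() {
  list(SI_hepatic = 0.0931, SI_peripheral = 0.7464, B_func = 0.4581)
}

#' Representative T2DM virtual patient
#'
#' @param base healthy [mdsp_parameters()].
#' @return `virtual_patient` carrying [t2dm_overrides()].
#' @export
t2dm_representative_vp <- function(base = mdsp_parameters()) {
  make_vp(base, t2dm_overrides(), phenotypes = "t2dm", id = "t2dm_rep",
          name = "Representative T2DM patient",
          note = "calibrated to FPG ~10.1 mM, OGTT AUC ~29.9 mM.h, FPI ~90 pM")
}

#' Escalating metformin regimen of the 28-day short-term study
#'
#' 500 mg once daily for 7 days, 500 mg twice daily for 7 days, then
#' 1000 mg twice daily for 14 days.
#'
#' @param morning_time clock time of the morning dose (h).
#' @return [regimen()].
#' @export
eriksson_regimen <- function(morning_time = 8) {
  regimen("metformin", list(
    list(dose_mg = 500,  schedule = "qd",  n_days = 7),
    list(dose_mg = 500,  schedule = "bid", n_days = 7),
    list(dose_mg = 1000, schedule = "bid", n_days = 14)),
    morning_time = morning_time)
}

#' 28-day escalating-metformin study protocol
#'
#' The full simulated trial: three daily meals, the escalating metformin
#' regimen, and 75 g OGTTs on the mornings of days 0, 7, 14 and 28 (each
#' read pre-dose; day 0 is pre-treatment baseline).  Fasting glucose and
#' insulin are read just before the 08:00 measurement; the protocol runs
#' one day past the last dosing day so the day-28 OGTT completes.
#'
#' @param ogtt_days OGTT measurement days.
#' @param run_in_days meals-only settling days before day 0.
#' @return [protocol()].
#' @export
eriksson_protocol <- function(ogtt_days = c(0, 7, 14, 28),
                              run_in_days = 3) {
  protocol(
    duration_days = 29,
    meals = standard_meals(1800),
    regimens = list(eriksson_regimen()),
    ogtt = lapply(ogtt_days, function(d) build_ogtt(75, day = d,
                                                    clock_time = 8)),
    outputs = c("G_plasma", "I_plasma", "Cpep", "Gn_1", "FFA_plasma"),
    output_interval = 0.25,
    run_in_days = run_in_days)
}
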