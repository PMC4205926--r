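#' Default pharmacodynamic hypothesis switches
#'
#' Mechanisms whose clinical support is debated are carried as explicit
#' on/off hypotheses so their impact on efficacy can be evaluated:
#' * `metformin_beta_cell` — direct metformin improvement of beta-cell
#'   function (off by default; opinions differ on whether the effect is
#'   direct).
#' * `gpr40_incretin_secretion` — GPR40-mediated intestinal GLP-1/GIP
#'   secretion (off by default; multiple-dose clinical data showed no
#'   incretin rise after an OGTT).
#'
#' @return named logical vector.
#' @export
default_hypotheses <- function() {
  c(metformin_beta_cell = FALSE, gpr40_incretin_secretion = FALSE)
}

#' Pharmacodynamic rate multipliers from drug concentrations
#'
#' Maps per-drug exposures to the dimensionless multipliers consumed by the
#' metabolic model.  Each effect is a Hill function of its driving
#' concentration ([hill_multiplier()]); effects of several drugs on a shared
#' rate tag combine multiplicatively.  Effects guarded by a hypothesis
#' switch contribute 1 while the switch is off.  The function is pure: the
#' same inputs always give the same multipliers.
#'
#' @param concentrations named numeric vector, drug name -> plasma
#'   concentration (ng/mL).
#' @param dp_all named list of [drug_parameters()], one per drug present.
#' @param hypotheses named logical vector of switch states
#'   ([default_hypotheses()]).
#' @param gut_exposure named numeric vector of gut-tissue exposures (ng/mL)
#'   for effects with `driver = "gut"`; defaults to the plasma
#'   concentrations.
#' @return [rate_multipliers()] vector.
#' @export
pd_effects <- function(concentrations, dp_all,
                       hypotheses = default_hypotheses(),
                       gut_exposure = concentrations) {
  eff <- rate_multipliers()
  for (drug in names(concentrations)) {
    dp <- dp_all[[drug]]
    if (is.null(dp))
      stop("no drug parameters for: ", drug, call. = FALSE)
    eff <- .apply_drug_effects(eff, dp, concentrations[[drug]],
                               gut_exposure[[drug]] %||% concentrations[[drug]],
                               hypotheses)
  }
  eff
}

.apply_drug_effects <- function(eff, dp, conc, gut_conc, hypotheses) {
  for (e in dp$effects) {
    if (!is.na(e$hypothesis %||% NA) && !isTRUE(hypotheses[[e$hypothesis]]))
      next
    C <- if (identical(e$driver %||% "plasma", "gut")) gut_conc else conc
    eff[[e$tag]] <- eff[[e$tag]] * hill_multiplier(C, e$emax, e$ec50, e$n, e$mode)
  }
  eff
}

.effect <- function(tag, mode, emax, ec50, n = 1, driver = "plasma",
                    hypothesis = NA_character_) {
  list(tag = tag, mode = mode, emax = emax, ec50 = ec50, n = n,
       driver = driver, hypothesis = hypothesis)
}

#' Metformin PK/PD parameter fixture
#'
#' Oral three-compartment kinetics calibrated to published single-dose
#' (500 mg) and steady-state (500 mg bid) profile shapes in healthy adults;
#' the same kinetics are used for T2DM patients, where reported differences
#' are small.  Pharmacodynamic Hill parameters were calibrated once against
#' the 28-day escalating-regimen outcomes of the representative T2DM
#' virtual patient and are frozen here.  Systemic effects (hepatic glucose
#' production, peripheral insulin sensitivity, lipolysis, beta-cell
#' function) are driven by plasma concentration; intestinal effects
#' (absorption delay, GI glucose utilisation) by the slow gut-tissue
#' exposure.
#'
#' @return [drug_parameters()] for metformin.
#' @export
metformin_parameters <- function() {
  drug_parameters(
    name = "metformin", topology = "oral_3c",
    ka = 0.9, F = 0.55, V_central = 100, V_peripheral = 200,
    CL = 34, Q = 20, k_gut_tissue = 0.042,
    effects = list(
      .effect("hepatic_glucose_production", "inhibition",
              emax = 0.82, ec50 = 842, n = 3),
      .effect("muscle_insulin_sensitivity", "activation",
              emax = 0.45, ec50 = 842, n = 2),
      .effect("gi_glucose_utilization", "activation",
              emax = 1.0, ec50 = 130, n = 1.5, driver = "gut"),
      .effect("gut_absorption_delay", "inhibition",
              emax = 0.52, ec50 = 80, n = 2, driver = "gut"),
      .effect("ffa_release", "inhibition",
              emax = 0.20, ec50 = 1500, n = 1),
      .effect("beta_cell_function", "activation",
              emax = 0.49, ec50 = 200, n = 3.2,
              hypothesis = "metformin_beta_cell")
    ))
}

#' TAK-875 (fasiglifam) PK/PD parameter fixture
#'
#' Oral kinetics with enterohepatic recirculation: a fraction of central
#' elimination is secreted into bile, accumulates in the gallbladder and
#' re-enters the gut at meal triggers, producing the secondary concentration
#' rises seen after meals.  The pharmacodynamic effect is a single lumped
#' amplification of the Ca-pathway gain on glucose-stimulated insulin
#' secretion; GPR40-driven intestinal incretin secretion is carried as an
#' off-by-default hypothesis.
#'
#' @return [drug_parameters()] for TAK-875.
#' @export
tak875_parameters <- function() {
  drug_parameters(
    name = "tak875", topology = "oral_ehrc",
    ka = 0.5, F = 0.8, V_central = 10, V_peripheral = 15,
    CL = 1.5, Q = 1.5, biliary_frac = 0.8, k_bile = 0.5,
    gb_empty_frac = 0.6, k_gut_tissue = 0.04,
    effects = list(
      .effect("insulin_secretion_ca_gain", "activation",
              emax = 1.6, ec50 = 5000, n = 1.2),
      .effect("incretin_secretion_gain", "activation",
              emax = 0.8, ec50 = 5000, n = 1,
              hypothesis = "gpr40_incretin_secretion")
    ))
}

#' Built-in drug parameter sets, keyed by drug name
#' @return named list of [drug_parameters()].
#' @export
builtin_drugs <- function() {
  list(metformin = metformin_parameters(), tak875 = tak875_parameters())
}
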