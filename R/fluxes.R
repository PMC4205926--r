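# All physiological fluxes at a given state.  Units: glucose fluxes mmol/h,
# nutrient fluxes g/h, hormone fluxes pM/h (per their compartment volumes).
# `v` is the parameter value vector, `eff` a complete rate_multipliers set.
.metabolic_fluxes <- function(state, v, eff) {
  G     <- state[["G_plasma"]]
  G6P   <- state[["G6P_liver"]]
  GlyL  <- state[["Gly_liver"]]
  GlyM  <- state[["Gly_muscle"]]
  I     <- state[["I_plasma"]]
  Iport <- state[["I_portal"]]
  Gn1   <- state[["Gn_1"]]
  FFA   <- state[["FFA_plasma"]]
  TAGp  <- state[["TAG_plasma"]]
  TAGa  <- state[["TAG_adipose"]]
  C3    <- state[["C3_pool"]]

  m_hgp  <- eff[["hepatic_glucose_production"]]
  m_sens <- eff[["muscle_insulin_sensitivity"]]
  m_gi   <- eff[["gi_glucose_utilization"]]
  m_ffa  <- eff[["ffa_release"]]

  # insulin signals (normalised to 1 at the healthy reference)
  z_liv <- v[["SI_hepatic"]] * state[["E_liver"]]
  z_per <- v[["SI_peripheral"]] * state[["E_muscle"]]
  h_liv <- v[["h_ins_liver"]]

  # glucagon drive on hepatic output, 1 at reference
  f_gn <- v[["f_gn_basal"]] + (1 - v[["f_gn_basal"]]) * Gn1 / v[["Gn_ref"]]

  # --- liver ------------------------------------------------------------
  glucokinase <- v[["V_glucokinase"]] * (G / v[["G_ref"]])^v[["h_glucokinase"]] *
    .phi_act(z_liv, v[["K_ins_gk"]])
  g6pase <- v[["V_g6pase"]] * (G6P / v[["G6P_ref"]])^v[["h_g6p_export"]] *
    f_gn * m_hgp
  glycogen_synthesis <- v[["V_glysyn"]] * (G6P / v[["G6P_ref"]]) *
    .phi_act(z_liv, v[["K_ins_syn"]]) *
    max(1 - GlyL / v[["Gly_liver_max"]], 0)
  glycogenolysis <- v[["V_glyphos"]] *
    (GlyL / v[["Gly_liver_ref"]])^v[["h_gly_liver"]] *
    .psi_inh(z_liv, v[["K_ins_phos"]], h_liv) * f_gn * m_hgp
  gluconeogenesis <- v[["V_gng"]] * (C3 / v[["C3_ref"]])^v[["h_c3_gng"]] *
    .psi_inh(z_liv, v[["K_ins_gng"]], h_liv) * f_gn * m_hgp
  liver_oxidation <- v[["k_liver_ox"]] * (G6P / v[["G6P_ref"]])^v[["h_liver_ox"]]
  vldl <- v[["vldl_ref"]] * (G6P / v[["G6P_ref"]])

  # --- muscle -----------------------------------------------------------
  gam <- (G / (v[["K_m_glc_muscle"]] + G)) /
    (v[["G_ref"]] / (v[["K_m_glc_muscle"]] + v[["G_ref"]]))
  muscle_uptake <- (v[["u_muscle_basal"]] +
    v[["u_muscle_ins"]] * z_per^v[["h_ins_muscle"]] * m_sens) * gam
  muscle_glysyn <- v[["f_glysyn_muscle"]] * muscle_uptake *
    max(1 - GlyM / v[["Gly_muscle_max"]], 0)
  muscle_glyturn <- v[["k_glyphos_muscle"]] * GlyM
  muscle_oxidation <- muscle_uptake - muscle_glysyn + muscle_glyturn

  # --- other tissues ----------------------------------------------------
  brain <- v[["brain_uptake"]]   # constant, insulin- and glucose-independent
  other_uptake <- v[["u_adipose_other"]] * (G / v[["G_ref"]])
  gi_uptake <- v[["u_gi"]] * (G / v[["G_ref"]]) * m_gi
  renal <- .renal_flux(G, v)

  # --- lipids -----------------------------------------------------------
  lipolysis <- v[["lipolysis_ref"]] * (TAGa / v[["TAG_adipose_ref"]]) *
    .psi_inh(z_per, v[["K_ins_lip"]]) * m_ffa
  reesterification <- v[["reest_ref"]] * (FFA / v[["FFA_ref"]]) *
    .phi_act(z_per, 1)
  ffa_oxidation <- v[["k_ffa_ox"]] * FFA * v[["V_ffa"]]
  lpl_clearance <- (v[["vldl_ref"]] / (v[["TAG_plasma_ref"]] * v[["V_tag"]])) *
    TAGp * v[["V_tag"]]

  # --- substrate pool ---------------------------------------------------
  cori <- v[["cori_frac"]] * (muscle_oxidation + other_uptake + gi_uptake)
  c3_leak <- v[["k_c3_leak"]] * C3

  list(glucokinase = glucokinase, g6pase = g6pase,
       glycogen_synthesis = glycogen_synthesis,
       glycogenolysis = glycogenolysis, gluconeogenesis = gluconeogenesis,
       liver_oxidation = liver_oxidation, vldl = vldl,
       muscle_uptake = muscle_uptake, muscle_glysyn = muscle_glysyn,
       muscle_glyturn = muscle_glyturn, muscle_oxidation = muscle_oxidation,
       brain_uptake = brain,
       other_uptake = other_uptake, gi_uptake = gi_uptake, renal = renal,
       lipolysis = lipolysis, reesterification = reesterification,
       ffa_oxidation = ffa_oxidation, lpl_clearance = lpl_clearance,
       cori = cori, c3_leak = c3_leak, f_gn = f_gn,
       z_liv = z_liv, z_per = z_per)
}

# renal excretion with a smooth quadratic knee of width `renal_knee`
.renal_flux <- function(G, v) {
  x <- G - v[["renal_threshold"]]
  w <- v[["renal_knee"]]
  s <- v[["renal_slope"]]
  ifelse(x <= 0, 0, ifelse(x < w, s * x^2 / (2 * w), s * (x - w / 2)))
}

#' Renal glucose excretion
#'
#' Kidneys reabsorb all filtered glucose below a threshold concentration;
#' above it, excretion grows linearly with the excess, with a smooth
#' quadratic knee (width `renal_knee`) so the right-hand side stays
#' continuously differentiable for the stiff integrator.
#'
#' @param G_plasma plasma glucose (mM), vectorised.
#' @param params [mdsp_parameters()].
#' @return excretion flux (mmol/h).
#' @export
renal_glucose_excretion <- function(G_plasma, params) {
  if (any(G_plasma < 0)) stop("G_plasma must be >= 0", call. = FALSE)
  vapply(G_plasma, .renal_flux, 0, v = params$values)
}

#' Gut nutrient absorption fluxes
#'
#' Nutrients transit stomach -> gut lumen -> blood.  Appearance in blood is
#' first-order in the gut pool; the bioavailable fraction reaches the
#' circulation and the rest is lost to a sink.  A `delay_factor` below 1
#' (metformin's delayed, more distal glucose absorption) scales down the
#' carbohydrate absorption rate constant: the appearance peak shifts later
#' while the total amount absorbed is unchanged.
#'
#' @param t time (h); absorption is autonomous, the argument mirrors the
#'   right-hand-side signature.
#' @param state [metabolic_state()].
#' @param params [mdsp_parameters()].
#' @param delay_factor dimensionless, `> 0`.
#' @return named vector `c(carb=, fat=, prot=)` of bioavailable nutrient
#'   appearance rates (g/h).
#' @export
gut_absorption_flux <- function(t, state, params, delay_factor = 1) {
  if (delay_factor <= 0) stop("delay_factor must be > 0", call. = FALSE)
  v <- params$values
  gut <- c(state[["gut_carb"]], state[["gut_fat"]], state[["gut_prot"]])
  if (any(gut < 0)) stop("gut pools must be >= 0", call. = FALSE)
  k <- c(v[["k_abs_carb"]] * delay_factor, v[["k_abs_fat"]], v[["k_abs_prot"]])
  f <- c(v[["f_bio_carb"]], v[["f_bio_fat"]], v[["f_bio_prot"]])
  setNames(k * gut * f, c("carb", "fat", "prot"))
}

#' Hepatic glucose fluxes
#'
#' The liver phosphorylates glucose to G6P (glucokinase), exports glucose
#' from G6P (G6Pase), cycles G6P with glycogen (synthase/phosphorylase) and
#' produces G6P from three-carbon substrates (gluconeogenesis).  Insulin
#' pushes the net flux towards uptake/storage; glucagon stimulates
#' glycogenolysis and gluconeogenesis.  The `hepatic_glucose_production`
#' multiplier (metformin) scales gluconeogenesis, glycogenolysis and the
#' G6Pase export step.
#'
#' @param state [metabolic_state()].
#' @param params [mdsp_parameters()].
#' @param effects [rate_multipliers()].
#' @return named vector of non-negative fluxes (mmol/h):
#'   `glucokinase`, `G6Pase`, `glycogen_synthesis`, `glycogenolysis`,
#'   `gluconeogenesis`.
#' @export
hepatic_glucose_fluxes <- function(state, params, effects = rate_multipliers()) {
  .validate_effects(effects)
  f <- .metabolic_fluxes(state, params$values, effects)
  c(glucokinase = f$glucokinase, G6Pase = f$g6pase,
    glycogen_synthesis = f$glycogen_synthesis,
    glycogenolysis = f$glycogenolysis, gluconeogenesis = f$gluconeogenesis)
}

#' Muscle glucose handling
#'
#' Insulin-regulated glucose uptake split into glycogen storage and
#' oxidation.  Muscle glycogen is used locally only: no flux returns glucose
#' to the circulation.
#'
#' @inheritParams hepatic_glucose_fluxes
#' @return named vector (mmol/h): `uptake`, `glycogen_synthesis`,
#'   `oxidation`.
#' @export
muscle_glucose_dynamics <- function(state, params, effects = rate_multipliers()) {
  .validate_effects(effects)
  f <- .metabolic_fluxes(state, params$values, effects)
  c(uptake = f$muscle_uptake, glycogen_synthesis = f$muscle_glysyn,
    oxidation = f$muscle_oxidation)
}

#' Insulin secretion rate
#'
#' Multistep glucose-coupled secretion: plasma glucose sets the Ca and cAMP
#' signalling activities (states `S_ca`, `S_camp`, relaxing on minute time
#' scales), incretins potentiate the cAMP branch, and the product is scaled
#' by beta-cell mass and function.  The `insulin_secretion_ca_gain`
#' multiplier (GPR40 agonism) amplifies the Ca branch; `beta_cell_function`
#' (metformin hypothesis) scales the functional capacity.  C-peptide is
#' co-released in equal molar amount.
#'
#' @inheritParams hepatic_glucose_fluxes
#' @return secretion rate (pmol/h).
#' @export
insulin_secretion_rate <- function(state, params, effects = rate_multipliers()) {
  .validate_effects(effects)
  v <- params$values
  stopifnot(state[["S_ca"]] >= 0, state[["S_camp"]] >= 0,
            v[["B_mass"]] >= 0, v[["B_func"]] >= 0)
  S_ca_ref <- .hill01(v[["G_ref"]], v[["K_ca"]], v[["n_ca"]])
  S_camp_ref <- .camp_drive(v[["G_ref"]], v[["GLP1_ref"]], v[["GIP_ref"]], v)
  v[["ISR_ref"]] * v[["B_mass"]] * v[["B_func"]] *
    effects[["beta_cell_function"]] *
    (state[["S_ca"]] / S_ca_ref) * effects[["insulin_secretion_ca_gain"]] *
    (state[["S_camp"]] / S_camp_ref)
}

#' Glucagon two-compartment dynamics
#'
#' Secretion into the first compartment falls with both plasma glucose and
#' insulin; the two compartments exchange mass conservatively and clearance
#' acts on the first.  The secretion scale is tied to the clearance constant
#' so that the reference state is a fixed point (and `k_gn_clear = 0` gives
#' an exactly conservative system).
#'
#' @inheritParams hepatic_glucose_fluxes
#' @return named vector `c(Gn_1=, Gn_2=)` of derivatives (pM/h).
#' @export
glucagon_dynamics <- function(state, params) {
  v <- params$values
  stopifnot(state[["Gn_1"]] >= 0, state[["Gn_2"]] >= 0)
  d <- .glucagon_rhs(state[["G_plasma"]], state[["I_plasma"]],
                     state[["Gn_1"]], state[["Gn_2"]], v)
  c(Gn_1 = d[[1]], Gn_2 = d[[2]])
}

.glucagon_secretion <- function(G, I, v) {
  fG <- v[["K_gn_glc"]]^2 / (v[["K_gn_glc"]]^2 + G^2)
  fI <- v[["K_gn_ins"]] / (v[["K_gn_ins"]] + I)
  fG_ref <- v[["K_gn_glc"]]^2 / (v[["K_gn_glc"]]^2 + v[["G_ref"]]^2)
  fI_ref <- v[["K_gn_ins"]] / (v[["K_gn_ins"]] + v[["I_ref"]])
  gsr_ref <- v[["k_gn_clear"]] * v[["Gn_ref"]]
  gsr_ref * (fG * fI) / (fG_ref * fI_ref)
}

.glucagon_rhs <- function(G, I, Gn1, Gn2, v) {
  sec <- .glucagon_secretion(G, I, v)
  ex12 <- v[["k_gn_exch_12"]] * Gn1
  ex21 <- v[["k_gn_exch_21"]] * Gn2
  c(sec - ex12 + ex21 - v[["k_gn_clear"]] * Gn1,
    ex12 - ex21)
}
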