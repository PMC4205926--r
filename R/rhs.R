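# Full metabolic right-hand side.  `v` parameter values, `eff` complete rate
# multipliers.  Timed inputs (meals, doses, OGTT boluses) are impulses
# applied between integration segments, so the RHS itself is autonomous.
.metabolic_rhs_core <- function(t, y, v, eff) {
  fl <- .metabolic_fluxes(y, v, eff)

  # the absorption-delay multiplier slows the whole gut chain: gastric
  # emptying and mucosal uptake (a shift to later, more distal absorption)
  delay <- eff[["gut_absorption_delay"]]
  k_ge <- v[["k_gastric"]] * delay
  kac <- v[["k_abs_carb"]] * delay
  kaf <- v[["k_abs_fat"]]
  kap <- v[["k_abs_prot"]]
  out_c <- kac * y[["gut_carb"]]
  out_f <- kaf * y[["gut_fat"]]
  out_p <- kap * y[["gut_prot"]]
  abs_c <- out_c * v[["f_bio_carb"]]
  abs_f <- out_f * v[["f_bio_fat"]]
  abs_p <- out_p * v[["f_bio_prot"]]

  carb_mmol <- abs_c * 1000 / v[["mw_glucose"]]
  fat_mmol  <- abs_f * 1000 / v[["mw_tag"]]
  prot_glc  <- v[["f_prot_gng"]] * abs_p * 1000 / v[["mw_glucose"]]

  isr <- v[["ISR_ref"]] * v[["B_mass"]] * v[["B_func"]] *
    eff[["beta_cell_function"]] *
    (y[["S_ca"]] / .hill01(v[["G_ref"]], v[["K_ca"]], v[["n_ca"]])) *
    eff[["insulin_secretion_ca_gain"]] *
    (y[["S_camp"]] /
       .camp_drive(v[["G_ref"]], v[["GLP1_ref"]], v[["GIP_ref"]], v))

  k_portal_out <- v[["ISR_ref"]] / (v[["I_portal_ref"]] * v[["V_portal"]])
  portal_outflow <- k_portal_out * y[["I_portal"]] * v[["V_portal"]]

  dgn <- .glucagon_rhs(y[["G_plasma"]], y[["I_plasma"]],
                       y[["Gn_1"]], y[["Gn_2"]], v)

  m_inc <- eff[["incretin_secretion_gain"]]
  glp1_sec <- v[["k_glp1_clear"]] * v[["GLP1_ref"]] +
    v[["s_glp1_meal"]] * abs_c * m_inc
  gip_sec <- v[["k_gip_clear"]] * v[["GIP_ref"]] +
    v[["s_gip_meal"]] * abs_c * m_inc

  g_per_mmol_glyc <- v[["mw_glycosyl"]] / 1000
  d <- c(
    # stomach -> gut -> absorbed/lost (g)
    -k_ge * y[["stom_carb"]],
    -k_ge * y[["stom_fat"]],
    -k_ge * y[["stom_prot"]],
    k_ge * y[["stom_carb"]] - out_c,
    k_ge * y[["stom_fat"]] - out_f,
    k_ge * y[["stom_prot"]] - out_p,
    abs_c, abs_f, abs_p,
    out_c - abs_c, out_f - abs_f, out_p - abs_p,
    # plasma glucose (mM)
    (carb_mmol + fl$g6pase - fl$glucokinase - v[["brain_uptake"]] -
       fl$muscle_uptake - fl$other_uptake - fl$gi_uptake - fl$renal) /
      v[["V_glucose"]],
    # hepatic G6P (mmol)
    fl$glucokinase + fl$glycogenolysis + fl$gluconeogenesis -
      fl$g6pase - fl$glycogen_synthesis - fl$liver_oxidation,
    # glycogen stores (g)
    (fl$glycogen_synthesis - fl$glycogenolysis) * g_per_mmol_glyc,
    (fl$muscle_glysyn - fl$muscle_glyturn) * g_per_mmol_glyc,
    # lipids
    (fl$vldl + fat_mmol - fl$lpl_clearance) / v[["V_tag"]],
    (fl$lipolysis - fl$reesterification - fl$ffa_oxidation) / v[["V_ffa"]],
    (fl$lpl_clearance + fl$reesterification / 3 - fl$lipolysis / 3) *
      v[["mw_tag"]] / 1000,
    # three-carbon substrate pool (mmol)
    v[["c3_basal_input"]] + fl$cori + prot_glc - fl$gluconeogenesis -
      fl$c3_leak,
    # insulin / C-peptide (pM)
    ((1 - v[["hepatic_extraction"]]) * portal_outflow -
       v[["k_insulin_clear"]] * y[["I_plasma"]] * v[["V_insulin"]]) /
      v[["V_insulin"]],
    (isr - portal_outflow) / v[["V_portal"]],
    isr / v[["V_cpep"]] - v[["k_cpep_clear"]] * y[["Cpep"]],
    # glucagon (pM)
    dgn[[1L]], dgn[[2L]],
    # incretins (pM)
    glp1_sec - v[["k_glp1_clear"]] * y[["GLP1"]],
    gip_sec - v[["k_gip_clear"]] * y[["GIP"]],
    # beta-cell signalling / insulin action (dimensionless)
    (.camp_drive(y[["G_plasma"]], y[["GLP1"]], y[["GIP"]], v) -
       y[["S_camp"]]) / v[["tau_S_camp"]],
    (.hill01(y[["G_plasma"]], v[["K_ca"]], v[["n_ca"]]) - y[["S_ca"]]) /
      v[["tau_S_ca"]],
    ((0.5 * y[["I_plasma"]] / v[["I_ref"]] +
        0.5 * y[["I_portal"]] / v[["I_portal_ref"]]) - y[["E_liver"]]) /
      v[["tau_E_liver"]],
    (y[["I_plasma"]] / v[["I_ref"]] - y[["E_muscle"]]) / v[["tau_E_muscle"]]
  )
  names(d) <- .state_names
  d
}

#' Metabolic model right-hand side
#'
#' Time derivative of every state variable at a given state, under a given
#' set of pharmacodynamic rate multipliers.  Meals, doses and OGTT loads are
#' discrete impulses handled by the simulation driver between integration
#' segments, so the continuous right-hand side depends only on the state.
#'
#' @param t time (h); the system is autonomous, the argument mirrors the
#'   ODE-solver signature.
#' @param state [metabolic_state()]; all pools must be non-negative.
#' @param params [mdsp_parameters()].
#' @param effects [rate_multipliers()]; every rate tag must be present.
#' @param inputs unused placeholder for protocol-driven continuous inputs
#'   (all protocol inputs in this model are impulsive).
#' @return named numeric vector of derivatives (per-field d/dt).
#' @export
metabolic_rhs <- function(t, state, params, effects = rate_multipliers(),
                          inputs = NULL) {
  .validate_state(state)
  .validate_effects(effects)
  y <- as.numeric(state)
  names(y) <- .state_names
  .metabolic_rhs_core(t, y, params$values, effects)
}

# indices of states with trivially neutral directions at fasting (gut chain
# and cumulative trackers): pinned to zero during root finding
.gut_idx <- 1:12
.dyn_idx <- 13:31

#' Fasting steady state of the metabolic model
#'
#' Finds the drug-free, meal-free fixed point: a long pre-integration damps
#' the fast physiology onto its slow manifold, then damped Newton iterations
#' (finite-difference Jacobian on the dynamic states, gut chain pinned at
#' zero) polish the slow pools to a true fixed point.  Deterministic for
#' fixed parameters.
#'
#' @param params [mdsp_parameters()].
#' @param tol convergence tolerance on `max |d/dt| / max(|state|, 1)`.
#' @param init optional starting [metabolic_state()]; defaults to the
#'   reference state.
#' @param pre_hours length of the damping pre-integration (h).
#' @param max_newton maximum Newton iterations.
#' @return the steady [metabolic_state()], with attribute `residual`.
#' @export
steady_state <- function(params, tol = 1e-9, init = NULL, pre_hours = 300,
                         max_newton = 50) {
  v <- params$values
  eff <- rate_multipliers()
  y <- if (is.null(init)) as.numeric(metabolic_state(params)) else {
    .validate_state(init)
    as.numeric(setNames(init, .state_names))
  }
  names(y) <- .state_names
  y[.gut_idx] <- 0

  scaled_res <- function(y) {
    d <- .metabolic_rhs_core(0, y, v, eff)[.dyn_idx]
    max(abs(d) / pmax(abs(y[.dyn_idx]), 1))
  }

  # damping pre-integration (no meals, no drugs)
  sol <- deSolve::lsoda(
    y, c(0, pre_hours),
    function(t, y, p) list(.metabolic_rhs_core(t, y, v, eff)),
    parms = NULL, rtol = 1e-8, atol = 1e-10)
  y <- sol[nrow(sol), 1 + seq_along(y)]
  names(y) <- .state_names

  f_dyn <- function(x) {
    yy <- y
    yy[.dyn_idx] <- x
    .metabolic_rhs_core(0, yy, v, eff)[.dyn_idx]
  }
  x <- y[.dyn_idx]
  res <- scaled_res(y)
  for (it in seq_len(max_newton)) {
    if (res < tol) break
    fx <- f_dyn(x)
    n <- length(x)
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- max(abs(x[j]), 1e-3) * 1e-6
      xj <- x
      xj[j] <- xj[j] + h
      J[, j] <- (f_dyn(xj) - fx) / h
    }
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      xn <- x + lam * step
      ok <- all(xn > 0) || all(xn[xn <= 0] > -1e-12)
      if (ok) {
        yn <- y
        yn[.dyn_idx] <- pmax(xn, 0)
        rn <- scaled_res(yn)
        if (rn < res || lam < 1e-4) {
          x <- pmax(xn, 0)
          y <- yn
          res <- rn
          break
        }
      }
      lam <- lam / 2
      if (lam < 1e-6) break
    }
    if (lam < 1e-6) break
  }

  if (res >= tol) {
    # fallback: a much longer integration, then report
    sol <- deSolve::lsoda(
      y, c(0, 5000),
      function(t, y, p) list(.metabolic_rhs_core(t, y, v, eff)),
      parms = NULL, rtol = 1e-10, atol = 1e-12)
    y <- sol[nrow(sol), 1 + seq_along(y)]
    names(y) <- .state_names
    res <- scaled_res(y)
    if (res >= tol * 100)
      stop(sprintf("steady_state did not converge: residual %.3g", res),
           call. = FALSE)
  }
  # the gut chain is structurally empty at the fasting fixed point; clear
  # integration roundoff (denormal negatives) before returning
  y[.gut_idx] <- 0
  class(y) <- c("metabolic_state", "numeric")
  attr(y, "residual") <- res
  y
}
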