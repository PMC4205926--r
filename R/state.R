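# State-vector layout of the metabolic model.  The order is fixed per model
# version: serialised results and the ODE right-hand side both rely on it.
.state_names <- c(
  # gut nutrient handling (g); stomach -> gut lumen -> absorbed/lost trackers
  "stom_carb", "stom_fat", "stom_prot",
  "gut_carb", "gut_fat", "gut_prot",
  "abs_carb", "abs_fat", "abs_prot",
  "loss_carb", "loss_fat", "loss_prot",
  # glucose pools
  "G_plasma",            # mM
  "G6P_liver",           # mmol
  "Gly_liver",           # g
  "Gly_muscle",          # g
  # lipids
  "TAG_plasma",          # mM
  "FFA_plasma",          # mM
  "TAG_adipose",         # g
  # gluconeogenic substrate
  "C3_pool",             # mmol
  # hormones
  "I_plasma", "I_portal", "Cpep",            # pM
  "Gn_1", "Gn_2",                            # pM-equivalent
  "GLP1", "GIP",                             # pM
  # beta-cell signalling and insulin action (dimensionless)
  "S_camp", "S_ca", "E_liver", "E_muscle"
)

#' Construct a metabolic state vector
#'
#' Builds the model's state vector at the healthy reference values (all gut
#' pools empty, hormones and stores at their fasting set points), optionally
#' modified by named arguments.  Beta-cell mass and function are carried as
#' parameters (`B_mass`, `B_func`), constant over the day-to-month
#' simulations the model targets.
#'
#' @param params an [mdsp_parameters()] object supplying reference values.
#' @param ... named state overrides, e.g. `G_plasma = 9`.
#' @return named numeric vector of class `metabolic_state`.
#' @export
metabolic_state <- function(params = mdsp_parameters(), ...) {
  v <- params$values
  s <- setNames(numeric(length(.state_names)), .state_names)
  s["G_plasma"]    <- v[["G_ref"]]
  s["G6P_liver"]   <- v[["G6P_ref"]]
  s["Gly_liver"]   <- v[["Gly_liver_ref"]]
  s["Gly_muscle"]  <- v[["Gly_muscle_ref"]]
  s["TAG_plasma"]  <- v[["TAG_plasma_ref"]]
  s["FFA_plasma"]  <- v[["FFA_ref"]]
  s["TAG_adipose"] <- v[["TAG_adipose_ref"]]
  s["C3_pool"]     <- v[["C3_ref"]]
  s["I_plasma"]    <- v[["I_ref"]]
  s["I_portal"]    <- v[["I_portal_ref"]]
  s["Cpep"]        <- v[["Cpep_ref"]]
  s["Gn_1"]        <- v[["Gn_ref"]]
  s["Gn_2"]        <- v[["Gn_ref"]]
  s["GLP1"]        <- v[["GLP1_ref"]]
  s["GIP"]         <- v[["GIP_ref"]]
  s["S_ca"]        <- .hill01(v[["G_ref"]], v[["K_ca"]], v[["n_ca"]])
  s["S_camp"]      <- .camp_drive(v[["G_ref"]], v[["GLP1_ref"]], v[["GIP_ref"]], v)
  s["E_liver"]     <- 1
  s["E_muscle"]    <- 1
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), .state_names)
    if (length(unknown))
      stop("unknown state field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    s[names(ov)] <- unlist(ov)
  }
  class(s) <- c("metabolic_state", "numeric")
  s
}

.validate_state <- function(state) {
  if (length(state) != length(.state_names))
    stop("state vector length must be ", length(.state_names), call. = FALSE)
  if (any(!is.finite(state))) stop("state contains non-finite values", call. = FALSE)
  if (any(state < 0))
    stop("negative state field(s): ",
         paste(.state_names[state < 0], collapse = ", "), call. = FALSE)
  invisible(state)
}

# cAMP drive: glucose-dependent with incretin potentiation, floor at 0.05
.camp_drive <- function(G, GLP1, GIP, v) {
  base <- v[["camp_basal"]] +
    (1 - v[["camp_basal"]]) * .hill01(G, v[["K_camp"]], v[["n_camp"]])
  inc <- 1 + v[["a_glp1"]] * (GLP1 - v[["GLP1_ref"]]) / v[["GLP1_ref"]] +
    v[["a_gip"]] * (GIP - v[["GIP_ref"]]) / v[["GIP_ref"]]
  pmax(base * pmax(inc, 0.05), 0.01)
}
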