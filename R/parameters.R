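#' @importFrom stats setNames
NULL

# Single source of truth for the metabolic model's input-parameter listing.
# Every parameter of the model appears here: the full listing IS the model's
# input interface.  Columns: name, value (healthy adult reference), unit,
# category (used for UI grouping and unit conversion), description.
.param_def <- function() {
  p <- list(
    # -- physiology: volumes and reference concentrations ------------------
    c("body_weight",        80,    "kg",     "PHYSIOLOGY", "body weight"),
    c("V_glucose",          15,    "L",      "VOLUME", "glucose distribution volume"),
    c("V_insulin",          12,    "L",      "VOLUME", "systemic insulin distribution volume"),
    c("V_portal",           1,     "L",      "VOLUME", "portal vein insulin volume"),
    c("V_cpep",             12,    "L",      "VOLUME", "C-peptide distribution volume"),
    c("V_tag",              4,     "L",      "VOLUME", "plasma triglyceride volume"),
    c("V_ffa",              10,    "L",      "VOLUME", "free fatty acid distribution volume"),
    c("G_ref",              5,     "mM",     "REFERENCE", "healthy fasting plasma glucose"),
    c("I_ref",              60,    "pM",     "REFERENCE", "healthy fasting systemic insulin"),
    c("I_portal_ref",       180,   "pM",     "REFERENCE", "healthy fasting portal insulin"),
    c("Cpep_ref",           500,   "pM",     "REFERENCE", "healthy fasting C-peptide"),
    c("Gn_ref",             70,    "pM",     "REFERENCE", "healthy fasting plasma glucagon"),
    c("GLP1_ref",           8,     "pM",     "REFERENCE", "basal GLP-1"),
    c("GIP_ref",            15,    "pM",     "REFERENCE", "basal GIP"),
    c("G6P_ref",            5,     "mmol",   "REFERENCE", "hepatic G6P reference pool"),
    c("Gly_liver_ref",      75,    "g",      "REFERENCE", "hepatic glycogen reference store"),
    c("Gly_muscle_ref",     250,   "g",      "REFERENCE", "muscle glycogen reference store"),
    c("TAG_plasma_ref",     1.2,   "mM",     "REFERENCE", "fasting plasma triglyceride"),
    c("FFA_ref",            0.5,   "mM",     "REFERENCE", "fasting free fatty acids"),
    c("TAG_adipose_ref",    12000, "g",      "REFERENCE", "adipose triglyceride store"),
    c("C3_ref",             30,    "mmol",   "REFERENCE", "three-carbon gluconeogenic substrate pool"),
    # -- gut absorption ----------------------------------------------------
    c("k_gastric",          1.0,   "1/h",    "RATE", "gastric emptying rate constant"),
    c("k_abs_carb",         1.0,   "1/h",    "RATE", "intestinal carbohydrate absorption rate"),
    c("k_abs_fat",          0.9,   "1/h",    "RATE", "intestinal fat absorption rate"),
    c("k_abs_prot",         1.0,   "1/h",    "RATE", "intestinal protein absorption rate"),
    c("f_bio_carb",         1.0,   "frac",   "FRACTION", "bioavailable fraction of dietary carbohydrate"),
    c("f_bio_fat",          0.95,  "frac",   "FRACTION", "bioavailable fraction of dietary fat"),
    c("f_bio_prot",         0.90,  "frac",   "FRACTION", "bioavailable fraction of dietary protein"),
    c("kcal_per_g_carb",    4,     "kcal/g", "NUTRITION", "energy density of carbohydrate"),
    c("kcal_per_g_fat",     9,     "kcal/g", "NUTRITION", "energy density of fat"),
    c("kcal_per_g_prot",    4,     "kcal/g", "NUTRITION", "energy density of protein"),
    c("mw_glucose",         180.2, "g/mol",  "CONSTANT", "glucose molar mass"),
    c("mw_tag",             885,   "g/mol",  "CONSTANT", "triacylglycerol molar mass"),
    c("mw_glycosyl",        162,   "g/mol",  "CONSTANT", "glycogen glucosyl-unit molar mass"),
    # -- glucose fluxes (healthy fasting reference values, mmol/h) ---------
    c("brain_uptake",       25,    "mmol/h", "RATE", "constant insulin-independent brain glucose uptake"),
    c("V_glucokinase",      10,    "mmol/h", "RATE", "hepatic glucokinase flux at reference state"),
    c("h_glucokinase",      1.5,   "dimensionless", "SHAPE", "glucokinase glucose-dependence exponent"),
    c("K_ins_gk",           1,     "dimensionless", "SHAPE", "insulin half-activation of glucokinase"),
    c("V_g6pase",           50,    "mmol/h", "RATE", "hepatic G6Pase export flux at reference state"),
    c("h_g6p_export",       0.4,   "dimensionless", "SHAPE", "G6P dependence exponent of G6Pase export"),
    c("V_glysyn",           30,    "mmol/h", "RATE", "hepatic glycogen synthase scale"),
    c("Gly_liver_max",      150,   "g",      "CAPACITY", "hepatic glycogen capacity"),
    c("K_ins_syn",          1,     "dimensionless", "SHAPE", "insulin half-activation of glycogen synthesis"),
    c("V_glyphos",          15,    "mmol/h", "RATE", "hepatic glycogen phosphorylase flux at reference"),
    c("h_gly_liver",        0.35,   "dimensionless", "SHAPE", "glycogen-store dependence exponent of glycogenolysis"),
    c("K_ins_phos",         0.5,     "dimensionless", "SHAPE", "insulin suppression constant, glycogenolysis"),
    c("V_gng",              42,    "mmol/h", "RATE", "gluconeogenesis flux at reference state"),
    c("K_ins_gng",          0.5,     "dimensionless", "SHAPE", "insulin suppression constant, gluconeogenesis"),
    c("h_c3_gng",           0.3,   "dimensionless", "SHAPE", "substrate-pool dependence exponent of gluconeogenesis"),
    c("h_ins_liver",        1.5,   "dimensionless", "SHAPE", "insulin suppression exponent in liver"),
    c("f_gn_basal",         0.55,   "frac",   "SHAPE", "glucagon-independent fraction of hepatic output drive"),
    c("k_liver_ox",         2,     "mmol/h", "RATE", "hepatic G6P oxidation + lipogenesis at reference"),
    c("h_liver_ox",         2,     "dimensionless", "SHAPE", "G6P dependence exponent of hepatic oxidation"),
    c("f_dnl",              0.5,   "frac",   "FRACTION", "fraction of hepatic G6P disposal exported as TAG"),
    c("u_muscle_basal",     2,     "mmol/h", "RATE", "insulin-independent muscle glucose uptake"),
    c("u_muscle_ins",       6,     "mmol/h", "RATE", "insulin-dependent muscle uptake at reference"),
    c("K_m_glc_muscle",     5,     "mM",     "SHAPE", "muscle uptake glucose half-saturation"),
    c("h_ins_muscle",       1.3,   "dimensionless", "SHAPE", "insulin-signal exponent of muscle uptake"),
    c("f_glysyn_muscle",    1.0,   "frac",   "FRACTION", "maximal fraction of muscle uptake stored as glycogen"),
    c("Gly_muscle_max",     400,   "g",      "CAPACITY", "muscle glycogen capacity"),
    c("k_glyphos_muscle",   0.012, "1/h",    "RATE", "muscle glycogen turnover (local oxidation)"),
    c("u_adipose_other",    4,     "mmol/h", "RATE", "adipose + other tissue uptake at reference glucose"),
    c("u_gi",               3,     "mmol/h", "RATE", "splanchnic/GI glucose utilisation at reference"),
    c("renal_threshold",    10,    "mM",     "THRESHOLD", "renal glucose reabsorption threshold"),
    c("renal_slope",        4.0,   "mmol/h/mM", "RATE", "renal excretion slope above threshold"),
    c("renal_knee",         0.1,   "mM",     "SHAPE", "smoothing width of the renal threshold knee"),
    # -- insulin / C-peptide ----------------------------------------------
    c("ISR_ref",            4800,  "pmol/h", "RATE", "insulin secretion at reference state"),
    c("B_mass",             1,     "dimensionless", "BETA_CELL", "beta-cell mass scaler"),
    c("B_func",             1,     "dimensionless", "BETA_CELL", "beta-cell function scaler"),
    c("K_ca",               7.5,   "mM",     "SHAPE", "glucose half-activation of Ca signalling"),
    c("n_ca",               2.5,   "dimensionless", "SHAPE", "Hill exponent of Ca signalling"),
    c("K_camp",             6,     "mM",     "SHAPE", "glucose half-activation of cAMP signalling"),
    c("n_camp",             2,     "dimensionless", "SHAPE", "Hill exponent of cAMP signalling"),
    c("camp_basal",         0.4,   "frac",   "SHAPE", "glucose-independent fraction of cAMP drive"),
    c("a_glp1",             0.3,   "dimensionless", "SHAPE", "GLP-1 potentiation of cAMP drive"),
    c("a_gip",              0.15,   "dimensionless", "SHAPE", "GIP potentiation of cAMP drive"),
    c("tau_S_ca",           0.15,  "h",      "TIME", "Ca signalling relaxation time"),
    c("tau_S_camp",         0.25,  "h",      "TIME", "cAMP signalling relaxation time"),
    c("hepatic_extraction", 0.5,   "frac",   "FRACTION", "first-pass hepatic insulin extraction"),
    c("k_insulin_clear",    10 / 3, "1/h",   "RATE", "peripheral insulin clearance rate constant"),
    c("k_cpep_clear",       0.8,   "1/h",    "RATE", "renal C-peptide clearance rate constant"),
    c("tau_E_liver",        0.3,   "h",      "TIME", "hepatic insulin-action delay"),
    c("tau_E_muscle",       0.3,   "h",      "TIME", "peripheral insulin-action delay"),
    c("SI_hepatic",         1,     "dimensionless", "SENSITIVITY", "hepatic insulin sensitivity"),
    c("SI_peripheral",      1,     "dimensionless", "SENSITIVITY", "peripheral insulin sensitivity"),
    # -- glucagon ----------------------------------------------------------
    c("k_gn_clear",         0.85,  "1/h",    "RATE", "glucagon clearance rate constant"),
    c("K_gn_glc",           6.5,     "mM",     "SHAPE", "glucose half-suppression of glucagon secretion"),
    c("K_gn_ins",           120,   "pM",     "SHAPE", "insulin half-suppression of glucagon secretion"),
    c("k_gn_exch_12",       0.5,   "1/h",    "RATE", "glucagon exchange, secretory to peripheral pool"),
    c("k_gn_exch_21",       0.5,   "1/h",    "RATE", "glucagon exchange, peripheral to secretory pool"),
    # -- incretins ---------------------------------------------------------
    c("k_glp1_clear",       3,     "1/h",    "RATE", "GLP-1 clearance rate constant"),
    c("k_gip_clear",        2,     "1/h",    "RATE", "GIP clearance rate constant"),
    c("s_glp1_meal",        1.7,   "pM.h/g", "RATE", "GLP-1 secretion per unit carbohydrate absorption"),
    c("s_gip_meal",         5,     "pM.h/g", "RATE", "GIP secretion per unit carbohydrate absorption"),
    # -- lipids ------------------------------------------------------------
    c("lipolysis_ref",      10,    "mmol/h", "RATE", "adipose FFA release at reference state"),
    c("K_ins_lip",          1.5,   "dimensionless", "SHAPE", "insulin suppression constant, lipolysis"),
    c("reest_ref",          7,     "mmol/h", "RATE", "FFA re-esterification at reference state"),
    c("k_ffa_ox",           0.6,   "1/h",    "RATE", "FFA oxidation rate constant"),
    c("vldl_ref",           1.0,   "mmol/h", "RATE", "hepatic TAG secretion at reference state"),
    # -- three-carbon substrate pool --------------------------------------
    c("c3_basal_input",     54,    "mmol/h", "RATE", "basal lactate/glycerol/amino-acid supply"),
    c("cori_frac",          0.4,   "frac",   "FRACTION", "fraction of peripheral glucose disposal recycled"),
    c("f_prot_gng",         0.5,   "frac",   "FRACTION", "glucose-equivalent yield of absorbed protein"),
    c("k_c3_leak",          0.6,   "1/h",    "RATE", "non-gluconeogenic clearance of the substrate pool"),
    # -- meals (defaults; value sets override these) ----------------------
    c("meal_kcal",          600,   "kcal",   "DOSE", "caloric content per meal"),
    c("meal_frac_carb",     0.5,   "frac",   "FRACTION", "carbohydrate energy fraction of meals"),
    c("meal_frac_fat",      0.3,   "frac",   "FRACTION", "fat energy fraction of meals"),
    c("meal_frac_prot",     0.2,   "frac",   "FRACTION", "protein energy fraction of meals"),
    c("meal_time_1",        8,     "h",      "TIME", "clock time of meal 1"),
    c("meal_time_2",        13,    "h",      "TIME", "clock time of meal 2"),
    c("meal_time_3",        19,    "h",      "TIME", "clock time of meal 3"),
    c("ogtt_glucose",       75,    "g",      "DOSE", "oral glucose tolerance test load"),
    c("ogtt_auc_window",    2,     "h",      "TIME", "OGTT glucose AUC window")
  )
  df <- data.frame(
    name = vapply(p, `[`, "", 1L),
    value = as.numeric(vapply(p, `[`, "", 2L)),
    unit = vapply(p, `[`, "", 3L),
    category = vapply(p, `[`, "", 4L),
    description = vapply(p, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(df$name), all(is.finite(df$value)))
  df
}

#' Full input-parameter listing of the metabolic model
#'
#' Returns the model's complete parameter set: a named value vector plus
#' per-parameter unit and category metadata.  The full listing is the model's
#' entire input interface; virtual patients and therapy value sets are
#' resolved against it and a serialised task carries every name.
#'
#' @param phenotype `"healthy"` for the reference parameterisation, or
#'   `"t2dm"` for the representative type-2-diabetes phenotype (reduced
#'   hepatic/peripheral insulin sensitivity and beta-cell function,
#'   calibrated so the fasting steady state matches a typical newly treated
#'   T2DM patient).
#' @return an object of class `mdsp_parameters`: list with `values` (named
#'   numeric) and `meta` (data.frame of name/unit/category/description).
#' @export
mdsp_parameters <- function(phenotype = c("healthy", "t2dm")) {
  phenotype <- match.arg(phenotype)
  def <- .param_def()
  values <- setNames(def$value, def$name)
  if (phenotype == "t2dm")
    values[names(t2dm_overrides())] <- unlist(t2dm_overrides())
  structure(
    list(values = values, meta = def[, c("name", "unit", "category", "description")]),
    class = "mdsp_parameters", phenotype = phenotype)
}

#' @export
print.mdsp_parameters <- function(x, ...) {
  cat(sprintf("<mdsp_parameters> %d parameters (phenotype: %s)\n",
              length(x$values), attr(x, "phenotype") %||% "custom"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply named overrides to a parameter set
#'
#' @param params an `mdsp_parameters` object.
#' @param overrides named list/vector of replacement values; every name must
#'   exist in the listing.
#' @return modified `mdsp_parameters`.
#' @export
set_parameters <- function(params, overrides) {
  stopifnot(inherits(params, "mdsp_parameters"))
  if (length(overrides) == 0) return(params)
  ov <- unlist(overrides)
  unknown <- setdiff(names(ov), names(params$values))
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params$values[names(ov)] <- ov
  attr(params, "phenotype") <- "custom"
  params
}

#' Export the parameter listing as plain text
#'
#' One `name<TAB>value<TAB>unit` line per parameter, the textual contract by
#' which a simulation task fully specifies its model inputs.
#'
#' @param params `mdsp_parameters`.
#' @param path file to write; if `NULL`, the lines are returned invisibly.
#' @return character vector of lines, invisibly.
#' @export
write_parameter_listing <- function(params, path = NULL) {
  stopifnot(inherits(params, "mdsp_parameters"))
  lines <- sprintf("%s\t%s\t%s", names(params$values),
                   format(params$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   params$meta$unit[match(names(params$values), params$meta$name)])
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
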