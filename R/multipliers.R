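.rate_tags <- c(
  "hepatic_glucose_production",   # inhibition: gluconeogenesis, glycogenolysis, G6Pase export
  "muscle_insulin_sensitivity",   # activation: insulin-dependent muscle uptake
  "gi_glucose_utilization",       # activation: splanchnic/GI glucose disposal
  "gut_absorption_delay",         # inhibition: carbohydrate absorption rate constant
  "ffa_release",                  # inhibition: adipose lipolysis
  "insulin_secretion_ca_gain",    # activation: Ca-pathway gain on insulin secretion
  "incretin_secretion_gain",      # activation: meal-driven incretin secretion
  "beta_cell_function"            # activation: beta-cell function scaler
)

#' Pharmacodynamic rate multipliers
#'
#' The dimensionless factors by which active drugs scale the model's
#' physiological rates.  With no drug on board every factor is exactly 1 and
#' the simulated trajectory is bit-for-bit the drug-free one.  Inhibition
#' factors live in (0, 1], activation factors in [1, 1 + Emax].
#'
#' @param ... named factors overriding the drug-free default of 1; names must
#'   be among the model's rate tags.
#' @return named numeric vector of class `rate_multipliers` covering every
#'   rate tag.
#' @export
rate_multipliers <- function(...) {
  m <- setNames(rep(1, length(.rate_tags)), .rate_tags)
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), .rate_tags)
    if (length(unknown))
      stop("unknown rate tag(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    m[names(ov)] <- unlist(ov)
  }
  class(m) <- c("rate_multipliers", "numeric")
  m
}

.validate_effects <- function(effects) {
  missing <- setdiff(.rate_tags, names(effects))
  if (length(missing))
    stop("missing rate tag(s) in effects: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(effects)
}
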