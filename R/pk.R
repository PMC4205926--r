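# Per-drug PK state layouts.  Oral three-compartment: gut depot counted as
# a compartment.  The EHRC topology adds a bile duct, a gallbladder and a
# re-entry depot for recirculated drug.  `cum_elim` and `cum_nonabs`
# trackers close the mass balance exactly.
.pk_states <- list(
  oral_3c   = c("depot", "central", "peripheral", "cum_elim", "cum_nonabs",
                "gut_exposure"),
  oral_ehrc = c("depot", "recirc", "central", "peripheral", "bile",
                "gallbladder", "cum_elim", "cum_nonabs", "gut_exposure")
)

#' Drug parameter set
#'
#' Bundles the compartmental PK constants of an orally dosed drug with the
#' Hill parameters of each pharmacodynamic effect it exerts on the metabolic
#' model.  Effects are either driven by the instantaneous plasma
#' concentration (`driver = "plasma"`) or by a slow gut-tissue exposure
#' compartment (`driver = "gut"`) that first-order-tracks plasma
#' concentration with rate `k_gut_tissue` — the local exposure relevant for
#' intestinal drug action.
#'
#' @param name drug name (key used in regimens and concentration maps).
#' @param topology `"oral_3c"` (depot + central + peripheral) or
#'   `"oral_ehrc"` (adds biliary recirculation through the gallbladder).
#' @param ka first-order absorption rate constant (1/h).
#' @param F bioavailable fraction of the swallowed dose, in `[0, 1]`.
#' @param V_central,V_peripheral distribution volumes (L).
#' @param CL central elimination clearance (L/h).
#' @param Q inter-compartmental clearance (L/h).
#' @param biliary_frac fraction of central elimination routed to bile
#'   (EHRC only; 0 turns recirculation off).
#' @param k_bile bile-duct to gallbladder transfer rate (1/h).
#' @param gb_empty_frac fraction of gallbladder content released into the
#'   gut at each emptying trigger (meals, OGTT start).
#' @param k_gut_tissue turnover of the gut-tissue exposure compartment
#'   (1/h).
#' @param effects list of effects, each
#'   `list(tag=, mode=, emax=, ec50=, n=, driver=, hypothesis=)`; `ec50` in
#'   ng/mL, `hypothesis` names an on/off switch or is `NA` for always-on.
#' @return object of class `drug_parameters`.
#' @export
drug_parameters <- function(name, topology = c("oral_3c", "oral_ehrc"),
                            ka, F, V_central, V_peripheral, CL, Q,
                            biliary_frac = 0, k_bile = 0.5,
                            gb_empty_frac = 0.6, k_gut_tissue = 0.04,
                            effects = list()) {
  topology <- match.arg(topology)
  stopifnot(F >= 0, F <= 1, V_central > 0, V_peripheral > 0, CL > 0, Q >= 0,
            ka > 0, biliary_frac >= 0, biliary_frac <= 1,
            gb_empty_frac >= 0, gb_empty_frac <= 1)
  for (e in effects) {
    stopifnot(all(c("tag", "mode", "emax", "ec50", "n") %in% names(e)))
    if (!e$tag %in% .rate_tags)
      stop("unknown rate tag in effect: ", e$tag, call. = FALSE)
    if (e$mode == "inhibition" && e$emax > 1)
      stop("inhibition emax must be <= 1 (", e$tag, ")", call. = FALSE)
  }
  structure(list(name = name, topology = topology, ka = ka, F = F,
                 V_central = V_central, V_peripheral = V_peripheral,
                 CL = CL, Q = Q, biliary_frac = biliary_frac,
                 k_bile = k_bile, gb_empty_frac = gb_empty_frac,
                 k_gut_tissue = k_gut_tissue, effects = effects),
            class = "drug_parameters")
}

#' Empty PK state for a drug
#' @param dp [drug_parameters()].
#' @return named numeric vector (mg; `gut_exposure` in ng/mL).
#' @export
pk_state <- function(dp) {
  setNames(numeric(length(.pk_states[[dp$topology]])),
           .pk_states[[dp$topology]])
}

#' Administer an oral bolus dose
#'
#' Increments the gut depot; every other compartment is untouched.
#'
#' @param pk PK state vector from [pk_state()].
#' @param dose_mg dose (mg), `>= 0`.
#' @return updated PK state.
#' @export
apply_dose <- function(pk, dose_mg) {
  if (dose_mg < 0) stop("dose must be >= 0", call. = FALSE)
  pk[["depot"]] <- pk[["depot"]] + dose_mg
  pk
}

# plasma concentration in ng/mL (mg/L * 1000)
.pk_conc <- function(pk, dp) pk[["central"]] / dp$V_central * 1000

#' Metformin-type oral three-compartment PK right-hand side
#'
#' Linear ODEs: first-order absorption from the gut depot (bioavailable
#' fraction `F`, the rest tracked as non-absorbed loss), central-peripheral
#' exchange by inter-compartmental clearance `Q`, first-order central
#' elimination by `CL`.  A slow gut-tissue exposure compartment tracks
#' plasma concentration for locally acting effects.
#'
#' @param t time (h); the system is autonomous.
#' @param pk PK state from [pk_state()].
#' @param dp [drug_parameters()].
#' @return named derivative vector (mg/h; gut exposure ng/mL/h).
#' @export
metformin_pk_rhs <- function(t, pk, dp) {
  C  <- pk[["central"]] / dp$V_central
  Cp <- pk[["peripheral"]] / dp$V_peripheral
  absorbed <- dp$ka * dp$F * pk[["depot"]]
  lost     <- dp$ka * (1 - dp$F) * pk[["depot"]]
  elim     <- dp$CL * C
  exch     <- dp$Q * (C - Cp)
  c(depot = -dp$ka * pk[["depot"]],
    central = absorbed - elim - exch,
    peripheral = exch,
    cum_elim = elim,
    cum_nonabs = lost,
    gut_exposure = dp$k_gut_tissue * (.pk_conc(pk, dp) - pk[["gut_exposure"]]))
}

#' Oral PK with enterohepatic recirculation (TAK-875 type)
#'
#' As the three-compartment oral model, plus: a fraction `biliary_frac` of
#' central elimination is secreted into a bile duct that drains into the
#' gallbladder; at emptying triggers (meal times, OGTT start — handled as
#' discrete events by the simulation driver, see
#' [gallbladder_empty()]) a fraction of gallbladder content re-enters the
#' gut in solubilised form and is completely reabsorbed.  Only the
#' non-biliary share of elimination removes drug from the body, so the total
#' mass cleared to infinity is `F * dose` regardless of the biliary
#' fraction.
#'
#' @inheritParams metformin_pk_rhs
#' @param meal_times gallbladder trigger times (h); unused by the continuous
#'   right-hand side (triggers are impulses), kept for signature symmetry.
#' @return named derivative vector (mg/h).
#' @export
tak875_pk_rhs <- function(t, pk, dp, meal_times = numeric()) {
  C  <- pk[["central"]] / dp$V_central
  Cp <- pk[["peripheral"]] / dp$V_peripheral
  absorbed <- dp$ka * dp$F * pk[["depot"]]
  lost     <- dp$ka * (1 - dp$F) * pk[["depot"]]
  reabs    <- dp$ka * pk[["recirc"]]
  elim_tot <- dp$CL * C
  to_bile  <- dp$biliary_frac * elim_tot
  cleared  <- elim_tot - to_bile
  exch     <- dp$Q * (C - Cp)
  c(depot = -dp$ka * pk[["depot"]],
    recirc = -reabs,
    central = absorbed + reabs - elim_tot - exch,
    peripheral = exch,
    bile = to_bile - dp$k_bile * pk[["bile"]],
    gallbladder = dp$k_bile * pk[["bile"]],
    cum_elim = cleared,
    cum_nonabs = lost,
    gut_exposure = dp$k_gut_tissue * (.pk_conc(pk, dp) - pk[["gut_exposure"]]))
}

#' Gallbladder emptying impulse
#'
#' Moves `gb_empty_frac` of the gallbladder content into the re-entry depot;
#' applied by the simulation driver at meal times and OGTT starts.
#'
#' @param pk EHRC PK state.
#' @param dp [drug_parameters()].
#' @return updated PK state.
#' @export
gallbladder_empty <- function(pk, dp) {
  released <- dp$gb_empty_frac * pk[["gallbladder"]]
  pk[["gallbladder"]] <- pk[["gallbladder"]] - released
  pk[["recirc"]] <- pk[["recirc"]] + released
  pk
}

.pk_rhs <- function(pk, dp) {
  if (dp$topology == "oral_3c") metformin_pk_rhs(0, pk, dp)
  else tak875_pk_rhs(0, pk, dp)
}

#' Simulate a drug's PK in isolation
#'
#' Runs only the pharmacokinetic sub-model under a dose schedule (and, for
#' EHRC drugs, gallbladder emptying triggers), with no metabolic coupling.
#'
#' @param dp [drug_parameters()].
#' @param doses data.frame with columns `time` (h) and `dose_mg`.
#' @param times output time grid (h).
#' @param trigger_times gallbladder-emptying times (h); ignored for
#'   non-EHRC topologies.
#' @param rtol,atol solver tolerances.
#' @return data.frame: `time`, one column per PK compartment, and `conc`
#'   (central concentration, ng/mL).
#' @export
simulate_pk <- function(dp, doses, times, trigger_times = numeric(),
                        rtol = 1e-8, atol = 1e-10) {
  y0 <- pk_state(dp)
  # doses at (or before) the first output time are part of the initial state
  t0 <- min(times)
  for (i in which(doses$time <= t0))
    y0 <- apply_dose(y0, doses$dose_mg[i])
  doses <- doses[doses$time > t0, , drop = FALSE]
  ev_times <- sort(unique(c(doses$time,
                            if (dp$topology == "oral_ehrc") trigger_times)))
  ev_times <- ev_times[ev_times > t0 & ev_times <= max(times)]
  eventfun <- function(t, y, parms) {
    i <- which(abs(doses$time - t) < 1e-9)
    if (length(i)) y <- apply_dose(y, sum(doses$dose_mg[i]))
    if (dp$topology == "oral_ehrc" &&
        any(abs(trigger_times - t) < 1e-9))
      y <- gallbladder_empty(y, dp)
    y
  }
  rhs <- function(t, y, parms) list(unname(.pk_rhs(setNames(y, names(y0)), dp)))
  times_all <- sort(unique(c(times, ev_times)))
  sol <- deSolve::lsoda(y0, times_all, rhs, parms = NULL, rtol = rtol,
                        atol = atol,
                        events = if (length(ev_times))
                          list(func = eventfun, time = ev_times))
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  out <- out[out$time %in% times, , drop = FALSE]
  out$conc <- out$central / dp$V_central * 1000
  rownames(out) <- NULL
  out
}

#' Non-compartmental summary of a concentration profile
#'
#' @param times sampling times (h), strictly increasing.
#' @param conc concentrations, same length as `times`.
#' @return list with `Cmax`, `Tmax` (time of first maximum) and `AUC_0_t`
#'   (linear trapezoid over the full grid).
#' @export
pk_metrics <- function(times, conc) {
  if (length(times) != length(conc))
    stop("`times` and `conc` must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  cmax <- max(conc)
  list(Cmax = cmax,
       Tmax = times[which(conc == cmax)[1]],
       AUC_0_t = sum(diff(times) * (head(conc, -1) + conc[-1]) / 2))
}

#' @importFrom utils head tail
NULL
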