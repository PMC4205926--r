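#' Simulate a protocol on the metabolic model
#'
#' Integrates the coupled metabolic + pharmacokinetic system over a
#' protocol: a meals-only run-in settles the physiology onto its fed
#' periodic orbit, then doses, meals and OGTT loads are applied as discrete
#' events (the integrator restarts at every discontinuity with a state
#' jump).  Drug plasma and gut-tissue exposures are converted each step into
#' Hill-type rate multipliers that scale the physiological rates; with no
#' dose on board every multiplier is exactly 1 and the trajectory is
#' bit-for-bit the drug-free one.
#'
#' @param params [mdsp_parameters()] (a resolved virtual patient).
#' @param protocol [protocol()].
#' @param drugs named list of [drug_parameters()]; defaults to the built-in
#'   set for every drug named in the protocol's regimens.
#' @param hypotheses named logical vector of pharmacodynamic hypothesis
#'   switches ([default_hypotheses()]).
#' @param init initial [metabolic_state()]; defaults to the fasting steady
#'   state of `params`.
#' @param rtol,atol solver tolerances (stiffness-switching `lsoda`).
#' @return a `timeseries_result`: data.frame with `time` (h; day 0 starts at
#'   0) and one column per requested output, with solver metadata attached.
#' @export
simulate_protocol <- function(params, protocol, drugs = NULL,
                              hypotheses = default_hypotheses(),
                              init = NULL, rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(params, "mdsp_parameters"), inherits(protocol, "protocol"))
  v <- params$values

  drug_names <- vapply(protocol$regimens, function(r) r$drug, "")
  if (is.null(drugs)) drugs <- builtin_drugs()[unique(drug_names)]
  drugs <- drugs[!vapply(drugs, is.null, TRUE)]
  missing_dp <- setdiff(unique(drug_names), names(drugs))
  if (length(missing_dp))
    stop("no drug parameters for: ", paste(missing_dp, collapse = ", "),
         call. = FALSE)

  # ---- state layout -----------------------------------------------------
  n_met <- length(.state_names)
  pk_idx <- list()
  y0 <- if (is.null(init)) as.numeric(steady_state(params)) else {
    .validate_state(init)
    as.numeric(setNames(init, .state_names))
  }
  names(y0) <- .state_names
  for (d in names(drugs)) {
    s <- pk_state(drugs[[d]])
    pk_idx[[d]] <- length(y0) + seq_along(s)
    y0 <- c(y0, setNames(s, paste0(d, ".", names(s))))
  }

  # ---- event schedule ---------------------------------------------------
  t0 <- -protocol$run_in_days * 24
  t_end <- protocol$duration_days * 24
  ogtt_times <- vapply(protocol$ogtt, `[[`, 0, "time")

  ev <- list()
  add_ev <- function(time, type, drug = NA, amount = NA, meal = NULL)
    ev[[length(ev) + 1]] <<- list(time = time, type = type, drug = drug,
                                  amount = amount, meal = meal)
  for (day in seq(protocol$run_in_days * -1, protocol$duration_days - 1)) {
    for (m in protocol$meals) {
      tm <- day * 24 + m$time
      # meals are suspended from an OGTT start until 3 h post-load
      if (any(tm >= ogtt_times & tm < ogtt_times + 3)) next
      add_ev(tm, "meal", meal = m)
    }
  }
  for (o in protocol$ogtt) add_ev(o$time, "ogtt", amount = o$glucose_g)
  for (r in protocol$regimens) {
    doses <- build_regimen(r)
    for (i in seq_len(nrow(doses))) { # zero-dose events kept: placebo arms
      td <- doses$time[i]
      # doses falling inside an OGTT window are taken after the test
      # (3 h post-load), so tolerance-test mornings stay pre-dose
      hit <- which(td >= ogtt_times & td < ogtt_times + 3)
      if (length(hit)) td <- ogtt_times[hit[1]] + 3
      add_ev(td, "dose", drug = r$drug, amount = doses$dose_mg[i])
    }
  }
  ev <- ev[vapply(ev, function(e) e$time >= t0 & e$time <= t_end, TRUE)]
  ev_times <- sort(unique(vapply(ev, `[[`, 0, "time")))

  has_ehrc <- vapply(drugs, function(d) d$topology == "oral_ehrc", TRUE)
  trigger_times <- sort(unique(c(
    vapply(Filter(function(e) e$type %in% c("meal", "ogtt"), ev), `[[`, 0,
           "time"))))

  eventfun <- function(t, y, parms) {
    for (e in ev) {
      if (abs(e$time - t) > 1e-9) next
      if (e$type == "meal") {
        m <- e$meal
        y[["stom_carb"]] <- y[["stom_carb"]] +
          m$kcal * m$carb / v[["kcal_per_g_carb"]]
        y[["stom_fat"]] <- y[["stom_fat"]] +
          m$kcal * m$fat / v[["kcal_per_g_fat"]]
        y[["stom_prot"]] <- y[["stom_prot"]] +
          m$kcal * m$prot / v[["kcal_per_g_prot"]]
      } else if (e$type == "ogtt") {
        y[["stom_carb"]] <- y[["stom_carb"]] + e$amount
      } else if (e$type == "dose") {
        nm <- paste0(e$drug, ".depot")
        y[[nm]] <- y[[nm]] + e$amount
      }
    }
    if (any(has_ehrc) && any(abs(trigger_times - t) < 1e-9)) {
      for (d in names(drugs)[has_ehrc]) {
        dp <- drugs[[d]]
        gb <- paste0(d, ".gallbladder")
        rc <- paste0(d, ".recirc")
        released <- dp$gb_empty_frac * y[[gb]]
        y[[gb]] <- y[[gb]] - released
        y[[rc]] <- y[[rc]] + released
      }
    }
    y
  }
  all_ev_times <- sort(unique(c(ev_times, if (any(has_ehrc)) trigger_times)))

  # ---- coupled right-hand side -----------------------------------------
  dnames <- names(drugs)
  rhs <- function(t, y, parms) {
    eff <- rate_multipliers()
    for (d in dnames) {
      dp <- drugs[[d]]
      pk <- y[pk_idx[[d]]]
      names(pk) <- .pk_states[[dp$topology]]
      conc <- pk[["central"]] / dp$V_central * 1000
      eff <- .apply_drug_effects(eff, dp, conc, pk[["gut_exposure"]],
                                 hypotheses)
    }
    dm <- .metabolic_rhs_core(t, y[seq_len(n_met)], v, eff)
    dd <- lapply(dnames, function(d) {
      pk <- y[pk_idx[[d]]]
      names(pk) <- .pk_states[[drugs[[d]]$topology]]
      unname(.pk_rhs(pk, drugs[[d]]))
    })
    list(c(unname(dm), unlist(dd)))
  }

  grid <- seq(t0, t_end, by = protocol$output_interval)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  times_all <- sort(unique(c(grid, all_ev_times)))
  sol <- deSolve::lsoda(
    y0, times_all, rhs, parms = NULL, rtol = rtol, atol = atol,
    maxsteps = 50000,
    events = if (length(all_ev_times))
      list(func = eventfun, time = all_ev_times))
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  out <- out[out$time %in% grid, , drop = FALSE]
  rownames(out) <- NULL

  for (d in dnames)
    out[[paste0("conc_", d)]] <-
      out[[paste0(d, ".central")]] / drugs[[d]]$V_central * 1000

  valid <- c(names(y0), paste0("conc_", dnames))
  unknown <- setdiff(protocol$outputs, valid)
  if (length(unknown))
    stop("unknown output variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keep <- unique(c("time", protocol$outputs,
                   unlist(lapply(dnames, function(d)
                     c(paste0("conc_", d),
                       paste0(d, ".", .pk_states[[drugs[[d]]$topology]]))))))
  res <- out[, keep, drop = FALSE]
  attr(res, "solver") <- list(method = "lsoda", rtol = rtol, atol = atol)
  attr(res, "run_in_days") <- protocol$run_in_days
  class(res) <- c("timeseries_result", "data.frame")
  res
}
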