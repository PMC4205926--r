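#' Calibrate a virtual patient to observable targets
#'
#' Adjusts a small set of free parameters until the patient's simulated
#' observables match the requested targets (relative least squares,
#' Nelder-Mead on log-transformed parameters, deterministic for fixed
#' settings).  Supported observables:
#' * `fasting_glucose` (mM), `fasting_insulin` (pM), `fasting_cpeptide`
#'   (pM) — read from the fasting steady state;
#' * `morning_glucose`, `morning_insulin` — the pre-dose, pre-meal morning
#'   values on the fed periodic orbit (what a trial's day-0 FPG/FPI assay
#'   measures; they sit a few percent above the meal-free steady state);
#' * `ogtt_auc` (mM.h) — glucose AUC of a standard OGTT performed at the
#'   fed periodic state (meals-only run-in, load and AUC window from
#'   `ogtt_protocol`);
#' * `body_weight` (kg) — a direct parameter map.
#'
#' @param targets named numeric vector of observable targets.
#' @param free_params parameter names allowed to move (all must exist in
#'   the listing and be positive at the start).
#' @param base [mdsp_parameters()] starting point.
#' @param phenotypes tags for the returned patient.
#' @param ogtt_protocol [protocol()] defining the OGTT observable; default:
#'   2-day meals-only run-in, 75 g load at 08:00 on day 0, total AUC over
#'   the protocol's window.
#' @param tol relative tolerance per target for convergence reporting.
#' @param maxit Nelder-Mead iteration budget.
#' @return calibrated `virtual_patient` with attributes `residuals` (per
#'   target relative error), `converged`, and `observables`.
#' @export
calibrate_vp <- function(targets, free_params, base = mdsp_parameters(),
                         phenotypes = "calibrated",
                         ogtt_protocol = NULL, tol = 0.02, maxit = 400) {
  stopifnot(inherits(base, "mdsp_parameters"), length(targets) >= 1)
  known <- c("fasting_glucose", "fasting_insulin", "fasting_cpeptide",
             "morning_glucose", "morning_insulin", "ogtt_auc",
             "body_weight")
  bad <- setdiff(names(targets), known)
  if (length(bad))
    stop("unknown target observable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(free_params, names(base$values))
  if (length(unknown))
    stop("unknown free parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  if ("body_weight" %in% names(targets)) {
    base <- set_parameters(base, list(body_weight = targets[["body_weight"]]))
    targets <- targets[names(targets) != "body_weight"]
    if (!length(targets))
      return(make_vp(base, list(), phenotypes, note = "weight-matched"))
  }

  need_ogtt <- any(c("ogtt_auc", "morning_glucose", "morning_insulin") %in%
                     names(targets))
  if (need_ogtt && is.null(ogtt_protocol))
    ogtt_protocol <- protocol(duration_days = 1,
                              ogtt = build_ogtt(75, day = 0, clock_time = 8),
                              outputs = c("G_plasma", "I_plasma"),
                              run_in_days = 2)

  observe <- function(values) {
    p <- base
    p$values[free_params] <- values
    ss <- steady_state(p)
    obs <- c(fasting_glucose = ss[["G_plasma"]],
             fasting_insulin = ss[["I_plasma"]],
             fasting_cpeptide = ss[["Cpep"]])
    if (need_ogtt) {
      res <- simulate_protocol(p, ogtt_protocol, init = ss)
      ep <- compute_endpoints(res, ogtt_protocol, days = 0)
      obs <- c(obs, morning_glucose = ep$FPG[1],
               morning_insulin = ep$FPI[1], ogtt_auc = ep$AUC_glucose[1])
    }
    obs[names(targets)]
  }

  objective <- function(logx) {
    obs <- tryCatch(observe(exp(logx)), error = function(e) NULL)
    if (is.null(obs)) return(1e6)
    sum(((obs - targets) / targets)^2)
  }

  start <- log(base$values[free_params])
  square <- length(targets) == length(free_params)
  obs0 <- tryCatch(observe(exp(start)), error = function(e) NULL)
  resid0 <- if (is.null(obs0)) Inf else max(abs((obs0 - targets) / targets))
  if (square && is.finite(resid0) && resid0 < 0.10) {
    # the start point is already in the solution's basin: a local Newton
    # polish is deterministic and avoids wandering along ridges of
    # near-equivalent parameter trade-offs
    par <- start
    obs <- obs0
    resid <- (obs0 - targets) / targets
  } else {
    fit <- stats::optim(start, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    par <- fit$par
    obs <- observe(exp(par))
    resid <- (obs - targets) / targets
  }
  values <- exp(par)

  # square systems admit an exact fit: polish with damped Newton on the
  # relative residual vector
  if (square) {
    for (it in seq_len(6)) {
      if (max(abs(resid)) < tol / 4) break
      n <- length(par)
      J <- matrix(0, n, n)
      for (j in seq_len(n)) {
        pj <- par
        pj[j] <- pj[j] + 1e-3
        oj <- tryCatch(observe(exp(pj)), error = function(e) NULL)
        if (is.null(oj)) break
        J[, j] <- ((oj - targets) / targets - resid) / 1e-3
      }
      step <- tryCatch(solve(J, -resid), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        cand <- par + lam * step
        oc <- tryCatch(observe(exp(cand)), error = function(e) NULL)
        if (!is.null(oc)) {
          rc <- (oc - targets) / targets
          if (max(abs(rc)) < max(abs(resid))) {
            par <- cand
            obs <- oc
            resid <- rc
            break
          }
        }
        lam <- lam / 2
        if (lam < 0.1) break
      }
      if (lam < 0.1) break
    }
    values <- exp(par)
  }
  if (any(abs(resid) > tol))
    stop(sprintf(
      "calibration did not converge: worst relative residual %.3g (%s)",
      max(abs(resid)), names(targets)[which.max(abs(resid))]),
      call. = FALSE)
  vp <- make_vp(base, as.list(setNames(values, free_params)), phenotypes,
                note = sprintf("calibrated to %s",
                               paste(names(targets), collapse = ", ")))
  attr(vp, "residuals") <- resid
  attr(vp, "observables") <- obs
  attr(vp, "converged") <- all(abs(resid) <= tol)
  vp
}
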