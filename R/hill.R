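#' Hill-type pharmacodynamic multiplier
#'
#' Converts a drug concentration into a dimensionless factor applied to a
#' physiological rate.  Activation gives `1 + emax * C^n / (ec50^n + C^n)`
#' (bounded by `[1, 1 + emax]`), inhibition gives
#' `1 - emax * C^n / (ec50^n + C^n)` (bounded by `[1 - emax, 1]`).  At zero
#' concentration the factor is exactly 1, so an untreated simulation is
#' bit-for-bit identical to one with the drug machinery attached but no dose.
#'
#' @param C drug concentration (same units as `ec50`); may be a vector.
#' @param emax maximal fractional effect, `>= 0` (and `<= 1` for inhibition).
#' @param ec50 concentration of half-maximal effect, `> 0`.
#' @param n Hill coefficient, `> 0`.
#' @param mode `"activation"` or `"inhibition"`.
#' @return dimensionless multiplier, same length as `C`.
#' @examples
#' hill_multiplier(0, 0.8, 10)                      # 1
#' hill_multiplier(10, 0.8, 10, 1, "activation")    # 1.4
#' @export
hill_multiplier <- function(C, emax, ec50, n = 1,
                            mode = c("activation", "inhibition")) {
  mode <- match.arg(mode)
  if (!is.numeric(ec50) || ec50 <= 0) stop("`ec50` must be > 0", call. = FALSE)
  if (!is.numeric(n) || n <= 0) stop("`n` must be > 0", call. = FALSE)
  if (emax < 0) stop("`emax` must be >= 0", call. = FALSE)
  if (mode == "inhibition" && emax > 1)
    stop("inhibition `emax` must be <= 1", call. = FALSE)
  if (any(C < 0)) stop("concentration must be >= 0", call. = FALSE)
  h <- ifelse(C == 0, 0, C^n / (ec50^n + C^n))
  if (mode == "activation") 1 + emax * h else 1 - emax * h
}

# saturating insulin-action functions, normalised to 1 at the reference
# signal z = 1.  phi: activation (bounded above by (K+1)/K * ... );
# psi: suppression, ->0 as z -> Inf, (K+1)/K at z = 0.
.phi_act <- function(z, K) (K + 1) * z / (K + z)
.psi_inh <- function(z, K, h = 1.5) (K + 1) / (K + z^h)

# glucose dependence used by beta-cell signalling, in [0, 1]
.hill01 <- function(x, K, n) x^n / (K^n + x^n)
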