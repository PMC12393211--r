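# Closed-form apparent qBOLD parameters and phase-encode-reversal
# log-ratio predictions under the echo-shift model.

#' Apparent R2' in the linear-exponential regime
#'
#' Slope of `-ln S_shift` versus `tau` in the linear-exponential regime.
#' With `a = gamma * Gy / v`:
#' `R2'_app = (-R2 a + R2') / (1 + a)` on the branch `tau >= k0y/v`
#' (effective offset positive) and `(R2 a + R2') / (1 + a)` on
#' `tau < k0y/v`. Tends to `R2'` as `a -> 0`. At the branch point both forms
#' coincide only for `a = 0`; the upper branch is returned for
#' `tau_branch = 1`.
#'
#' @param R2 Irreversible relaxation rate (1/s).
#' @param R2prime Reversible relaxation rate (1/s).
#' @param Gy Phase-encode MFG (uT/m).
#' @param v k-space velocity (rad/(mm*ms)).
#' @param gamma Gyromagnetic ratio (rad/(s*T)).
#' @param tau_branch `+1` for the `tau >= k0y/v` branch (default), `-1` for
#'   the other.
#' @return Apparent rate (1/s).
#' @examples
#' apparent_r2prime(10, 4.26, Gy = 28.8, v = 0.077) # a = 0.1 -> (4.26-1)/1.1
#' @export
apparent_r2prime <- function(R2, R2prime, Gy, v, gamma = 267.51e6,
                             tau_branch = 1) {
  stopifnot(tau_branch %in% c(-1, 1))
  a <- .grad_rate(gamma, Gy) / v
  if (any(abs(1 + a) < 1e-12)) stop("singular denominator: gamma*Gy/v = -1")
  (-tau_branch * R2 * a + R2prime) / (1 + a)
}

#' Apparent DBV from log-linear extrapolation
#'
#' Apparent deoxygenated blood volume obtained when the linear-exponential
#' fit at high `tau` is extrapolated to `tau = 0` and compared with the
#' (quadratic-regime) signal actually measured there, under a baseline
#' k-space shift `k0y` and MFG `Gy`. With
#' `q = delta_omega * (k0y / v) / (1 + gamma Gy / v)` (signed, `k0y/v` in
#' seconds):
#' `DBV_app = DBV * (1 + q + 0.3 q^2)`.
#' Tends to `DBV` as `k0y/v -> 0`; positive `k0y` inflates, negative `k0y`
#' deflates the estimate (the extrapolated line and the measured `tau = 0`
#' signal move in opposite directions).
#'
#' @param DBV True deoxygenated blood volume fraction.
#' @param delta_omega Characteristic frequency (rad/s).
#' @param k0y Baseline k-space shift (rad/mm).
#' @param Gy Phase-encode MFG (uT/m).
#' @param v k-space velocity (rad/(mm*ms)).
#' @param gamma Gyromagnetic ratio (rad/(s*T)).
#' @return Apparent DBV (fraction; may exceed the true value).
#' @export
apparent_dbv <- function(DBV, delta_omega, k0y, Gy = 0, v, gamma = 267.51e6) {
  a <- .grad_rate(gamma, Gy) / v
  if (any(abs(1 + a) < 1e-12)) stop("singular denominator: gamma*Gy/v = -1")
  q <- delta_omega * (k0y / v) * .MS / (1 + a)
  DBV * (1 + q + 0.3 * q^2)
}

#' Predicted reversed-PE log-ratio from effective offsets
#'
#' In the linear-exponential regime the log of the signal ratio between two
#' acquisitions with opposite phase-encode direction is
#' `ln(S / S_rev) = -(R2' + R2) * (tau_eff - tau_eff_rev)`.
#' Antisymmetric under swapping the two effective offsets.
#'
#' @param R2,R2prime Relaxation rates (1/s).
#' @param tau_eff,tau_eff_rev Effective offsets of the two acquisitions (ms).
#' @return Dimensionless log-ratio(s).
#' @export
predict_ln_ratio_from_taueff <- function(R2, R2prime, tau_eff, tau_eff_rev) {
  -(R2prime + R2) * (tau_eff - tau_eff_rev) * .MS
}

#' Predicted reversed-PE log-ratio from the MFG
#'
#' Expressing the effective offsets through the MFG gives, with
#' `a = gamma * Gy / v` and `k0y = 0`:
#' `ln(S / S_rev) = 2 (R2' + R2) tau a / (1 - a^2)`.
#' Odd in `Gy`, proportional to `tau`, and `~ 2 (R2'+R2) tau a` for small
#' gradients. Requires `|a| < 1`.
#'
#' @param R2,R2prime Relaxation rates (1/s).
#' @param tau Nominal offset(s) (ms).
#' @param Gy Phase-encode MFG(s) (uT/m).
#' @param v k-space velocity (rad/(mm*ms)).
#' @param gamma Gyromagnetic ratio (rad/(s*T)).
#' @return Dimensionless log-ratio(s).
#' @export
predict_ln_ratio_from_gy <- function(R2, R2prime, tau, Gy, v,
                                     gamma = 267.51e6) {
  a <- .grad_rate(gamma, Gy) / v
  if (any(abs(a) >= 1)) stop("|gamma*Gy/v| >= 1: outside the model's domain")
  2 * (R2prime + R2) * tau * .MS * a / (1 - a^2)
}

#' R2-contamination correction factor
#'
#' Multiplying the echo-shifted signal by
#' `C(tau) = exp(R2 * (tau_eff - tau))` removes the R2 contamination of the
#' trajectory exactly: `C * S_shift = S0 exp(-R2 TE) f(tau_eff)`, whose only
#' dependence on the effective offset is through the kernel `f`.
#'
#' @param tau Nominal offset(s) (ms).
#' @param tau_eff Effective offset(s) (ms), e.g. from [estimate_tau_eff()] or
#'   [tau_eff()].
#' @param R2 Irreversible relaxation rate (1/s).
#' @return Multiplicative correction factor(s); 1 when `tau_eff = tau` or
#'   `R2 = 0`.
#' @export
correction_factor <- function(tau, tau_eff, R2) {
  exp(R2 * (tau_eff - tau) * .MS)
}
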