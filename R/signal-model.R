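# ASE-EPI echo-shift signal model.

#' k-space trajectory of an intravoxel phase ramp
#'
#' Position in k-space of a voxel's signal at time `t` after the spin echo
#' under a macroscopic field gradient: `k(t) = gamma * G * t + k0`.
#'
#' @param t Time(s) from the spin echo (ms).
#' @param field A [field_state()]; uses `Gy` (uT/m) and `k0y` (rad/mm).
#' @param gamma Gyromagnetic ratio (rad/(s*T)).
#' @return k-space position(s) in the PE direction (rad/mm); linear in `t`,
#'   equal to `k0y` at `t = 0`.
#' @export
k_trajectory <- function(t, field, gamma = 267.51e6) {
  stopifnot(inherits(field, "field_state"))
  .grad_rate(gamma, field$Gy) * t + field$k0y
}

#' Effective spin-echo offset under a phase-encode MFG
#'
#' The EPI echo train reads the k-space center not at the nominal offset
#' `tau` but at the effective offset
#' `tau_eff = (tau - k0y / v) / (1 + pe_sign * gamma * Gy / v)`:
#' the intravoxel phase ramp displaces the voxel's echo to a different
#' phase-encode line, i.e. a different time. `tau_eff -> tau` as `v -> Inf`
#' and `tau_eff -> tau - k0y/v` as `Gy -> 0`.
#'
#' @param tau Nominal offset(s) between spin echo and TE (ms).
#' @param field A [field_state()].
#' @param readout An [epi_readout()]; uses `v` and `pe_sign`.
#' @param gamma Gyromagnetic ratio (rad/(s*T)).
#' @return Effective offset(s) in ms.
#' @examples
#' ro <- epi_readout(v = 0.077)
#' tau_eff(48, field_state(Gy = 50), ro) # ~40.9 ms
#' @export
tau_eff <- function(tau, field, readout, gamma = 267.51e6) {
  stopifnot(inherits(field, "field_state"), inherits(readout, "epi_readout"))
  a <- readout$pe_sign * .grad_rate(gamma, field$Gy) / readout$v
  if (abs(1 + a) < 1e-12) {
    stop("pathological gradient: gamma*Gy/v = -1, echo never sampled")
  }
  (tau - field$k0y / readout$v) / (1 + a)
}

#' Through-plane dephasing attenuation
#'
#' Multiplicative signal loss from a through-plane MFG `Gz` over a boxcar
#' slice profile of thickness `dz`:
#' `|sinc(gamma * Gz * dz * t / 2)|`. Equals 1 at `t = 0` or `Gz = 0`.
#' The boxcar profile is a modelling choice; other profiles would change the
#' envelope shape but not the `t`/`Gz` scaling.
#'
#' @param t Time(s) from the spin echo (ms).
#' @param Gz Through-plane gradient (uT/m).
#' @param dz Slice thickness (mm).
#' @param gamma Gyromagnetic ratio (rad/(s*T)).
#' @return Attenuation factor(s) in `[0, 1]`.
#' @export
through_plane_attenuation <- function(t, Gz, dz, gamma = 267.51e6) {
  x <- .grad_rate(gamma, Gz) * dz * t / 2
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- abs(sin(x[nz]) / x[nz])
  out
}

#' In-plane signal dropout flag
#'
#' A voxel's signal drops out when its displaced echo center falls outside
#' the sampled k-space: the solved echo-center k-value
#' `kappa = pe_sign * gamma * Gy * tau_eff + k0y` is quantized to the
#' nearest phase-encode line, and the voxel is flagged when that line lies
#' outside the acquisition window -- `|kappa| >= pi/dy + dk/2`, the
#' half-width of sampled k-space plus half a line spacing. Equivalently,
#' `tau_eff` lies outside the readout window. A baseline shift at the
#' nominal half-width `pi/dy` (0.90 rad/mm for 3.5 mm voxels) therefore
#' does not yet drop out; one exceeding it by more than half a line does.
#'
#' @inheritParams tau_eff
#' @return Logical vector, `TRUE` where the echo is not sampled.
#' @examples
#' ro <- epi_readout() # dy = 3.5 mm -> dropout limit pi/3.5 = 0.90 rad/mm
#' dropout_flag(0, field_state(k0y = 0.85), ro)
#' dropout_flag(0, field_state(k0y = 0.95), ro)
#' @export
dropout_flag <- function(tau, field, readout, gamma = 267.51e6) {
  te <- tau_eff(tau, field, readout, gamma)
  kappa <- readout$pe_sign * .grad_rate(gamma, field$Gy) * te + field$k0y
  abs(kappa) >= pi / readout$dy + readout$dk / 2
}

.f_fun <- function(f, tissue) {
  dw <- compute_delta_omega(tissue)
  if (is.function(f)) return(f)
  switch(match.arg(f, c("qbold", "linear", "quadratic")),
    qbold = function(t) qbold_f(t, tissue$DBV, dw),
    linear = function(t) f_linear_regime(t, tissue$DBV, dw),
    quadratic = function(t) f_quadratic_regime(t, tissue$DBV, dw)
  )
}

#' ASE signal without echo shift
#'
#' Single-compartment ASE signal at nominal offset `tau`:
#' `S(tau) = S0 * exp(-R2 * TE) * f(tau)`.
#'
#' @param tau Nominal offset(s) (ms).
#' @param tissue A [tissue_params()].
#' @param TE Echo time (ms).
#' @param f Signal kernel: `"qbold"`, `"linear"`, `"quadratic"`, or a
#'   function of `t` (ms).
#' @return Signal magnitude(s).
#' @export
ase_signal <- function(tau, tissue, TE = 74, f = "qbold") {
  stopifnot(inherits(tissue, "tissue_params"))
  fn <- .f_fun(f, tissue)
  tissue$S0 * exp(-tissue$R2 * TE * .MS) * fn(tau)
}

#' ASE signal with echo shift
#'
#' The echo-shift signal model: under a phase-encode MFG the k-space center
#' is read out at `tau_eff` instead of `tau`, so
#' `S_shift(tau) = S0 exp(-R2 TE) exp(-R2 (tau_eff - tau)) f(tau_eff)`,
#' i.e. the trajectory is contaminated by an R2 decay and `f` is sampled at
#' the effective offset. Optionally multiplied by the through-plane
#' attenuation (evaluated at `tau_eff`) and zeroed where the echo leaves the
#' sampled k-space ([dropout_flag()]).
#'
#' @inheritParams tau_eff
#' @param tissue A [tissue_params()].
#' @param f Signal kernel, see [ase_signal()].
#' @param through_plane Apply [through_plane_attenuation()] with the field's
#'   `Gz`? Default `TRUE` (no-op when `Gz = 0`).
#' @param dropout Zero the signal where the echo is unsampled? Default `TRUE`.
#' @return Signal magnitude(s); reduces exactly to [ase_signal()] when
#'   `Gy = 0` and `k0y = 0`.
#' @export
ase_signal_shifted <- function(tau, tissue, field, readout, f = "qbold",
                               through_plane = TRUE, dropout = TRUE) {
  stopifnot(inherits(tissue, "tissue_params"))
  te <- tau_eff(tau, field, readout, gamma = tissue$gamma)
  fn <- .f_fun(f, tissue)
  s <- tissue$S0 * exp(-tissue$R2 * readout$TE * .MS) *
    exp(-tissue$R2 * (te - tau) * .MS) * fn(te)
  if (through_plane && field$Gz != 0) {
    s <- s * through_plane_attenuation(te, field$Gz, readout$dz, tissue$gamma)
  }
  if (dropout) {
    s[dropout_flag(tau, field, readout, gamma = tissue$gamma)] <- 0
  }
  s
}

#' Default nominal-offset grid
#'
#' The symmetric tau grid used by the simulation scenarios: `n` equidistant
#' points from -50 to +50 ms.
#'
#' @param n Number of points (default 10000).
#' @return Numeric vector of offsets (ms).
#' @export
default_tau_grid <- function(n = 10000) seq(-50, 50, length.out = n)

#' Simulate an ASE signal trajectory
#'
#' Evaluates the echo-shift signal model on a tau grid and returns a tidy
#' trajectory: nominal offset, effective offset, magnitude and dropout flag.
#'
#' @inheritParams ase_signal_shifted
#' @param tau Grid of nominal offsets (ms); default [default_tau_grid()].
#' @return A tibble with columns `tau`, `tau_eff`, `signal`, `dropout`
#'   (signal is 0 where dropout is `TRUE`).
#' @examples
#' traj <- ase_trajectory(tissue_params(), epi_readout(v = 0.077),
#'                        field_state(Gy = 50), tau = default_tau_grid(501))
#' @export
ase_trajectory <- function(tissue, readout, field = field_state(),
                           tau = default_tau_grid(), f = "qbold",
                           through_plane = TRUE) {
  te <- tau_eff(tau, field, readout, gamma = tissue$gamma)
  drop <- dropout_flag(tau, field, readout, gamma = tissue$gamma)
  s <- ase_signal_shifted(tau, tissue, field, readout, f = f,
                          through_plane = through_plane, dropout = TRUE)
  tibble(tau = tau, tau_eff = te, signal = s, dropout = drop)
}
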