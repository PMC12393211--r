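# Log-linear qBOLD parameter estimation from signal-vs-tau trajectories.

#' Fit the linear-exponential regime of a trajectory
#'
#' Least-squares fit of `ln(signal)` versus `tau` over a high-tau window
#' (default tau in \[45, 50\] ms, a closed interval sampled at the
#' trajectory's native grid). The negated slope (converted to 1/s) estimates
#' the apparent R2'; the intercept extrapolates the log-signal to `tau = 0`.
#'
#' @param traj A trajectory tibble as returned by [ase_trajectory()]
#'   (columns `tau`, `signal`, `dropout`).
#' @param window Closed fit interval in ms, `c(lo, hi)`.
#' @return A list with `r2prime_hat` (1/s), `intercept_ln`, `n_points`, and
#'   `valid`. The estimate is invalid (not an error) when fewer than 3
#'   usable points lie in the window or any windowed point is flagged
#'   dropout / non-positive.
#' @export
fit_linear_exponential <- function(traj, window = c(45, 50)) {
  stopifnot(is.data.frame(traj), all(c("tau", "signal") %in% names(traj)),
            length(window) == 2, window[1] < window[2])
  drop <- if ("dropout" %in% names(traj)) traj$dropout else FALSE
  inw <- traj$tau >= window[1] & traj$tau <= window[2]
  usable <- inw & !drop & traj$signal > 0
  if (sum(usable) < 3 || any(inw & !usable)) {
    return(list(r2prime_hat = NA_real_, intercept_ln = NA_real_,
                n_points = sum(usable), valid = FALSE))
  }
  fit <- lm(log(signal) ~ tau, data = traj[usable, ])
  cf <- coef(fit)
  list(r2prime_hat = -unname(cf["tau"]) / .MS, # per-ms slope -> 1/s
       intercept_ln = unname(cf["(Intercept)"]),
       n_points = sum(usable), valid = TRUE)
}

#' Estimate DBV from the extrapolated intercept
#'
#' `DBV_hat = intercept_ln - ln(signal_at_tau0)`: the gap at `tau = 0`
#' between the extrapolated linear-exponential trajectory and the signal
#' actually simulated/measured there.
#'
#' @param intercept_ln Log-signal at `tau = 0` extrapolated from the
#'   linear-exponential fit.
#' @param signal_at_tau0 Signal at the grid point nearest `tau = 0` (`> 0`).
#' @return Estimated DBV (fraction).
#' @export
estimate_dbv <- function(intercept_ln, signal_at_tau0) {
  if (!is.finite(signal_at_tau0) || signal_at_tau0 <= 0) {
    stop("`signal_at_tau0` must be positive")
  }
  intercept_ln - log(signal_at_tau0)
}

#' Estimate OEF from fitted R2' and DBV
#'
#' Inverts `R2' = DBV * (4/3) pi gamma B0 delta_chi0 Hct OEF`:
#' `OEF_hat = R2prime_hat / (DBV_hat * (4/3) pi gamma B0 delta_chi0 Hct)`.
#'
#' @param r2prime_hat Fitted apparent R2' (1/s).
#' @param dbv_hat Fitted apparent DBV (fraction, `> 0`).
#' @param tissue A [tissue_params()] supplying `gamma`, `B0`, `delta_chi0`,
#'   `Hct`.
#' @return Estimated OEF (fraction); `NA` with a warning-free invalid result
#'   when `dbv_hat <= 0`.
#' @export
estimate_oef <- function(r2prime_hat, dbv_hat, tissue) {
  stopifnot(inherits(tissue, "tissue_params"))
  pref <- 4 / 3 * pi * tissue$gamma * tissue$B0 * tissue$delta_chi0 * 1e-6 *
    tissue$Hct
  out <- r2prime_hat / (dbv_hat * pref)
  out[!is.finite(dbv_hat) | dbv_hat <= 0] <- NA_real_
  out
}

#' Log-linear qBOLD fit of a trajectory
#'
#' Runs the full log-linear qBOLD pipeline on one trajectory: fit the
#' linear-exponential window ([fit_linear_exponential()]), take the signal at
#' the grid point nearest `tau = 0`, estimate DBV from the extrapolation gap
#' ([estimate_dbv()]) and OEF from the pair ([estimate_oef()]).
#'
#' @inheritParams fit_linear_exponential
#' @param tissue A [tissue_params()] supplying the constants that link R2',
#'   DBV and OEF.
#' @return An object of class `"qbold_fit"`: list with `r2prime_hat` (1/s),
#'   `dbv_hat`, `oef_hat`, `intercept_ln`, `n_points`, `valid`. Use
#'   [tidy.qbold_fit()] / [glance.qbold_fit()] for tibble output.
#' @examples
#' tis <- tissue_params()
#' traj <- ase_trajectory(tis, epi_readout(v = 0.077), tau = default_tau_grid(2001))
#' fit_qbold(traj, tis)
#' @export
fit_qbold <- function(traj, tissue, window = c(45, 50)) {
  lin <- fit_linear_exponential(traj, window)
  i0 <- which.min(abs(traj$tau))
  s0 <- traj$signal[i0]
  drop0 <- if ("dropout" %in% names(traj)) traj$dropout[i0] else FALSE
  out <- list(r2prime_hat = lin$r2prime_hat, dbv_hat = NA_real_,
              oef_hat = NA_real_, intercept_ln = lin$intercept_ln,
              n_points = lin$n_points, valid = lin$valid, window = window)
  if (lin$valid && !drop0 && is.finite(s0) && s0 > 0) {
    out$dbv_hat <- estimate_dbv(lin$intercept_ln, s0)
    out$oef_hat <- estimate_oef(lin$r2prime_hat, out$dbv_hat, tissue)
  } else {
    out$valid <- FALSE
  }
  structure(out, class = "qbold_fit")
}

#' @export
print.qbold_fit <- function(x, ...) {
  cat("<qbold_fit>", if (!x$valid) "(invalid)", "\n")
  cat(sprintf("  R2' = %.4g 1/s   DBV = %.4g   OEF = %.4g   (n = %d in [%g, %g] ms)\n",
              x$r2prime_hat, x$dbv_hat, x$oef_hat, x$n_points,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Tidy a log-linear qBOLD fit
#'
#' @param x A `"qbold_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per estimated quantity (`r2prime`, `dbv`,
#'   `oef`) and columns `term`, `estimate`.
#' @export
tidy.qbold_fit <- function(x, ...) {
  tibble(term = c("r2prime", "dbv", "oef"),
         estimate = c(x$r2prime_hat, x$dbv_hat, x$oef_hat))
}

#' @rdname tidy.qbold_fit
#' @return `glance()`: a one-row tibble with the estimates, fit window,
#'   number of points and validity flag.
#' @export
glance.qbold_fit <- function(x, ...) {
  tibble(r2prime_hat = x$r2prime_hat, dbv_hat = x$dbv_hat,
         oef_hat = x$oef_hat, intercept_ln = x$intercept_ln,
         n_points = x$n_points, valid = x$valid)
}

#' Sweep the log-linear qBOLD fit over MFG and baseline-shift grids
#'
#' Simulates an echo-shifted trajectory for every `(Gy, k0y)` combination,
#' applies [fit_qbold()], and tabulates the fitted apparent parameters next
#' to their closed-form predictions ([apparent_r2prime()],
#' [apparent_dbv()]).
#'
#' @param tissue A [tissue_params()].
#' @param readout An [epi_readout()].
#' @param gy Vector of phase-encode MFGs (uT/m).
#' @param k0y Vector of baseline k-space shifts (rad/mm).
#' @param tau Simulation grid (ms).
#' @param f Signal kernel for the simulated trajectories.
#' @param window Fit window (ms).
#' @return A tibble of class `"qbold_sweep"`, one row per combination:
#'   `Gy`, `k0y`, `gamma_gy_over_v`, fitted `r2prime_hat`, `dbv_hat`,
#'   `oef_hat`, `valid`, and closed-form `r2prime_pred`, `dbv_pred`.
#' @export
sweep_qbold <- function(tissue, readout, gy = seq(-50, 50, length.out = 11),
                        k0y = 0, tau = default_tau_grid(), f = "qbold",
                        window = c(45, 50)) {
  dw <- compute_delta_omega(tissue)
  r2p <- tissue$DBV * dw
  grid <- tidyr::expand_grid(Gy = gy, k0y = k0y)
  rows <- purrr::pmap(grid, function(Gy, k0y) {
    fld <- field_state(Gy = Gy, k0y = k0y)
    fit <- fit_qbold(ase_trajectory(tissue, readout, fld, tau = tau, f = f),
                     tissue, window)
    tibble(
      Gy = Gy, k0y = k0y,
      gamma_gy_over_v = readout$pe_sign * .grad_rate(tissue$gamma, Gy) / readout$v,
      r2prime_hat = fit$r2prime_hat, dbv_hat = fit$dbv_hat,
      oef_hat = fit$oef_hat, valid = fit$valid,
      r2prime_pred = apparent_r2prime(tissue$R2, r2p, readout$pe_sign * Gy,
                                      readout$v, tissue$gamma),
      dbv_pred = apparent_dbv(tissue$DBV, dw, k0y, readout$pe_sign * Gy,
                              readout$v, tissue$gamma)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("qbold_sweep", class(out))
  out
}
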