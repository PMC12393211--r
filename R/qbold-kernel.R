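# Static-dephasing qBOLD attenuation kernel.
#
# f(t) = exp(-DBV * I(|delta_omega * t|)) with the dimensionless integral
#   I(x) = int_0^1 (2+u) sqrt(1-u) / (3 u^2) * [1 - J0(1.5 x u)] du.
# I depends only on x = delta_omega*|t|, so it is computed once by adaptive
# quadrature on a dense grid and cached as a spline for vectorised use.

# integrand of I(x); series expansion of 1 - J0(z) below z = 1e-4 because the
# u -> 0 endpoint is a finite 0/0 limit: 1 - J0(z) ~ z^2/4 - z^4/64
.qbold_integrand <- function(u, x) {
  z <- 1.5 * x * u
  b <- ifelse(abs(z) < 1e-4, z^2 / 4 - z^4 / 64, 1 - besselJ(z, 0))
  (2 + u) * sqrt(pmax(1 - u, 0)) / (3 * u^2) * b
}

# I(x) by adaptive quadrature, vectorised over x
.qbold_integral_quad <- function(x) {
  vapply(abs(x), function(xx) {
    if (xx == 0) return(0)
    out <- tryCatch(
      integrate(.qbold_integrand, lower = 0, upper = 1, x = xx,
                rel.tol = 1e-10, abs.tol = 1e-9, subdivisions = 500L),
      error = function(e) {
        stop(sprintf(
          "qBOLD kernel quadrature failed at delta_omega*t = %.6g: %s",
          xx, conditionMessage(e)
        ), call. = FALSE)
      }
    )
    if (out$message != "OK") {
      stop(sprintf("qBOLD kernel quadrature did not converge at x = %.6g: %s",
                   xx, out$message), call. = FALSE)
    }
    out$value
  }, numeric(1))
}

.QBOLD_SPLINE_XMAX <- 40

# cached spline of I(x) on [0, 40]; beyond the grid the exact quadrature is
# used (rarely needed: x = delta_omega*t ~ 7 for gray matter at tau = 50 ms)
.qbold_spline <- function() {
  sp <- .es_cache$qbold_spline
  if (is.null(sp)) {
    xg <- seq(0, .QBOLD_SPLINE_XMAX, by = 0.02)
    sp <- splinefun(xg, .qbold_integral_quad(xg), method = "natural")
    .es_cache$qbold_spline <- sp
  }
  sp
}

.qbold_integral <- function(x, method = c("spline", "quadrature")) {
  method <- match.arg(method)
  x <- abs(x)
  if (method == "quadrature") return(.qbold_integral_quad(x))
  out <- numeric(length(x))
  inside <- x <= .QBOLD_SPLINE_XMAX
  if (any(inside)) out[inside] <- .qbold_spline()(x[inside])
  if (any(!inside)) out[!inside] <- .qbold_integral_quad(x[!inside])
  out
}

#' Static-dephasing qBOLD signal kernel
#'
#' Signal attenuation of a randomly oriented vessel network in the static
#' dephasing regime,
#' `f(t) = exp(-DBV * integral_0^1 (2+u) sqrt(1-u)/(3u^2) (1 - J0(1.5 delta_omega t u)) du)`,
#' evaluated as a function of the time offset `t` from the spin echo.
#' The integral depends only on `delta_omega * |t|` and is computed by
#' adaptive quadrature (absolute tolerance 1e-9); the default `"spline"`
#' method interpolates a cached dense quadrature table (absolute error
#' < 1e-7) and is vectorised, `"quadrature"` integrates each point afresh.
#'
#' @param t Time offset(s) from the spin echo (ms).
#' @param DBV Deoxygenated blood volume fraction, in `[0, 1]`.
#' @param delta_omega Characteristic frequency (rad/s), see
#'   [compute_delta_omega()].
#' @param method `"spline"` (default, fast) or `"quadrature"` (reference).
#' @return Attenuation factor(s) in `(0, 1]`; even in `t`, `f(0) = 1`.
#' @seealso [f_linear_regime()], [f_quadratic_regime()]
#' @examples
#' tis <- tissue_params()
#' qbold_f(c(0, 24, 48), tis$DBV, compute_delta_omega(tis))
#' @export
qbold_f <- function(t, DBV, delta_omega, method = c("spline", "quadrature")) {
  stopifnot(DBV >= 0, DBV <= 1, delta_omega >= 0)
  x <- delta_omega * abs(t) * .MS
  exp(-DBV * .qbold_integral(x, method = match.arg(method)))
}

#' Linear-exponential regime of the qBOLD kernel
#'
#' Asymptotic form of [qbold_f()] for large offsets (`delta_omega*|t| >> 1`):
#' `f(t) = exp(DBV - R2' |t|)` with `R2' = DBV * delta_omega`.
#'
#' @inheritParams qbold_f
#' @return Attenuation factor(s); even in `t`, equals `exp(DBV)` at `t = 0`.
#' @export
f_linear_regime <- function(t, DBV, delta_omega) {
  stopifnot(DBV >= 0, DBV <= 1, delta_omega >= 0)
  exp(DBV - DBV * delta_omega * abs(t) * .MS)
}

#' Quadratic-exponential regime of the qBOLD kernel
#'
#' Small-offset approximation of [qbold_f()]:
#' `f(t) = exp(-0.3 DBV (delta_omega t)^2)`.
#'
#' @inheritParams qbold_f
#' @return Attenuation factor(s) in `(0, 1]`; equals 1 at `t = 0`.
#' @export
f_quadratic_regime <- function(t, DBV, delta_omega) {
  stopifnot(DBV >= 0, DBV <= 1, delta_omega >= 0)
  exp(-0.3 * DBV * (delta_omega * t * .MS)^2)
}
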