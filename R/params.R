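#' Tissue and scanner parameters
#'
#' Constructors for the parameter containers used by the signal model:
#' `tissue_params()` holds the physiological and field constants of the
#' single-compartment static-dephasing tissue model, `epi_readout()` the
#' EPI readout geometry and timing, and `field_state()` the macroscopic
#' field gradients (MFGs) and baseline k-space shift seen by a voxel.
#'
#' Defaults reproduce a healthy gray-matter voxel at 3 T with the 64-line,
#' 224 mm field-of-view single-shot EPI readout used throughout the package
#' examples.
#'
#' @param S0 Baseline signal (arbitrary units), `> 0`.
#' @param R2 Irreversible transverse relaxation rate (1/s), `>= 0`.
#' @param DBV Deoxygenated blood volume fraction, in `[0, 1]`.
#' @param OEF Oxygen extraction fraction, in `[0, 1]`.
#' @param Hct Hematocrit fraction, in `[0, 1]`.
#' @param delta_chi0 Susceptibility difference between fully deoxygenated
#'   blood and tissue (ppm).
#' @param B0 Main field strength (T), `> 0`.
#' @param gamma Proton gyromagnetic ratio in rad/(s*T).
#' @return `tissue_params()`: an object of class `"tissue_params"`.
#' @examples
#' tis <- tissue_params()
#' compute_delta_omega(tis)
#' @export
tissue_params <- function(S0 = 1, R2 = 10, DBV = 0.03, OEF = 0.4, Hct = 0.4,
                          delta_chi0 = 0.264, B0 = 3, gamma = 267.51e6) {
  stopifnot(S0 > 0, R2 >= 0, B0 > 0, gamma > 0, delta_chi0 >= 0)
  for (nm in c("DBV", "OEF", "Hct")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must lie in [0, 1], got %s", nm, format(v)))
    }
  }
  structure(
    list(S0 = S0, R2 = R2, DBV = DBV, OEF = OEF, Hct = Hct,
         delta_chi0 = delta_chi0, B0 = B0, gamma = gamma),
    class = "tissue_params"
  )
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("<tissue_params>\n")
  cat(sprintf("  S0=%g  R2=%g 1/s  DBV=%g  OEF=%g  Hct=%g\n",
              x$S0, x$R2, x$DBV, x$OEF, x$Hct))
  cat(sprintf("  delta_chi0=%g ppm  B0=%g T  gamma=%g rad/(s*T)\n",
              x$delta_chi0, x$B0, x$gamma))
  cat(sprintf("  derived: delta_omega=%.4g rad/s  R2'=%.4g 1/s\n",
              compute_delta_omega(x), r2prime(x)))
  invisible(x)
}

#' Characteristic frequency and reversible relaxation rate
#'
#' `compute_delta_omega()` returns the characteristic frequency offset
#' `delta_omega = (4/3) pi gamma B0 delta_chi0 Hct OEF` (rad/s) induced by the
#' deoxygenated blood vessel network; `r2prime()` returns the reversible
#' relaxation rate `R2' = DBV * delta_omega` (1/s) of the static dephasing
#' regime.
#'
#' @param tissue A [tissue_params()] object.
#' @return A non-negative rate (rad/s for `compute_delta_omega`, 1/s for
#'   `r2prime`). Zero iff `OEF`, `Hct` or `delta_chi0` is zero.
#' @examples
#' compute_delta_omega(tissue_params()) # ~142 rad/s for gray matter at 3 T
#' @export
compute_delta_omega <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_params"))
  4 / 3 * pi * tissue$gamma * tissue$B0 * tissue$delta_chi0 * 1e-6 *
    tissue$Hct * tissue$OEF
}

#' @rdname compute_delta_omega
#' @export
r2prime <- function(tissue) tissue$DBV * compute_delta_omega(tissue)

#' EPI readout geometry and timing
#'
#' Describes the single-shot EPI phase-encode (PE) readout: matrix size,
#' field of view, effective echo spacing and the resulting k-space velocity
#' `v` in the PE direction. When `v` is not supplied it is derived from the
#' geometry as `(2*pi / fov_y) / t_eff_es`; when both are supplied and
#' disagree by more than 1% a warning is raised and the supplied `v` wins.
#'
#' @param n_p Number of phase-encode lines.
#' @param fov_y Field of view in the PE direction (mm).
#' @param t_eff_es Effective echo spacing (ms), i.e. time between successive
#'   sampled PE lines after parallel-imaging acceleration.
#' @param v k-space velocity in the PE direction (rad/(mm*ms)); optional.
#' @param dz Slice thickness (mm).
#' @param TE Echo time (ms).
#' @param i_center 0-based index of the nominal k-space-center line
#'   (default `n_p / 2` for even matrices).
#' @param pe_sign `+1` or `-1`; phase-encode polarity. Reversing the PE
#'   direction flips the sign of the PE-direction MFG as seen by the readout.
#' @return An object of class `"epi_readout"` with element `dy = fov_y / n_p`.
#' @examples
#' epi_readout()                 # v derived from geometry (~0.079 rad/(mm*ms))
#' epi_readout(v = 0.077)        # explicit scanner-reported velocity
#' @export
epi_readout <- function(n_p = 64, fov_y = 224, t_eff_es = 0.354, v = NULL,
                        dz = 2.9, TE = 74, i_center = n_p %/% 2,
                        pe_sign = 1L) {
  stopifnot(n_p >= 2, fov_y > 0, t_eff_es > 0, dz > 0, TE >= 0,
            i_center >= 0, i_center < n_p, pe_sign %in% c(-1, 1))
  dk <- 2 * pi / fov_y
  v_geom <- dk / t_eff_es
  if (is.null(v)) {
    v <- v_geom
  } else {
    stopifnot(v > 0)
    if (abs(v - v_geom) / v_geom > 0.01) {
      warning(sprintf(
        "supplied v = %.4g rad/(mm*ms) differs from geometric (2*pi/fov_y)/t_eff_es = %.4g by >1%%; using supplied v",
        v, v_geom
      ))
    }
  }
  structure(
    list(n_p = as.integer(n_p), fov_y = fov_y, t_eff_es = t_eff_es, v = v,
         dy = fov_y / n_p, dz = dz, TE = TE, i_center = as.integer(i_center),
         pe_sign = as.integer(pe_sign), dk = dk),
    class = "epi_readout"
  )
}

#' @export
print.epi_readout <- function(x, ...) {
  cat("<epi_readout>\n")
  cat(sprintf("  n_p=%d  fov_y=%g mm (dy=%g mm)  dz=%g mm  TE=%g ms\n",
              x$n_p, x$fov_y, x$dy, x$dz, x$TE))
  cat(sprintf("  t_eff_es=%g ms  v=%.4g rad/(mm*ms)  i_center=%d  pe_sign=%+d\n",
              x$t_eff_es, x$v, x$i_center, x$pe_sign))
  invisible(x)
}

#' Reverse the phase-encode direction of a readout
#'
#' Returns a copy of `readout` with `pe_sign` negated, modelling acquisition
#' of the same slice with the opposite phase-encode polarity (the k-space
#' velocity magnitude is unchanged).
#'
#' @param readout An [epi_readout()] object.
#' @return An `epi_readout` object.
#' @export
reverse_pe <- function(readout) {
  stopifnot(inherits(readout, "epi_readout"))
  readout$pe_sign <- -readout$pe_sign
  readout
}

#' Macroscopic field gradients seen by a voxel
#'
#' `Gy` is the macroscopic field gradient (MFG) in the phase-encode direction,
#' `Gz` the through-plane MFG, and `k0y` a baseline k-space shift in the PE
#' direction present already at the spin echo (e.g. from a y-shimming
#' preparation gradient or eddy currents). The frequency-encode direction is
#' deliberately absent: its readout is too fast for an appreciable echo shift.
#'
#' @param Gy,Gz Gradients in uT/m.
#' @param k0y Baseline k-space shift (rad/mm).
#' @return An object of class `"field_state"`.
#' @examples
#' field_state(Gy = 50)
#' @export
field_state <- function(Gy = 0, Gz = 0, k0y = 0) {
  stopifnot(is.finite(Gy), is.finite(Gz), is.finite(k0y))
  structure(list(Gy = Gy, Gz = Gz, k0y = k0y), class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state> Gy=%g uT/m  Gz=%g uT/m  k0y=%g rad/mm\n",
              x$Gy, x$Gz, x$k0y))
  invisible(x)
}
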