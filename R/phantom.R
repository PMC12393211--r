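# Synthetic-data generator: complex multi-tau ASE-EPI image stacks with
# per-voxel MFG-induced k-space echo displacement, plus matching B0 maps.

#' Generate a smooth synthetic B0 off-resonance map
#'
#' Sum of randomly placed Gaussian blobs, rescaled so the largest in-plane
#' gradient magnitude matches `gradient_max`. Emulates the smooth
#' susceptibility-induced off-resonance patterns near air/tissue interfaces.
#'
#' @param shape Matrix dimensions `c(ny, nx)`.
#' @param smoothness Blob standard deviation in voxel units.
#' @param amplitude Peak field amplitude (Hz) before gradient rescaling;
#'   `0` gives a flat field.
#' @param n_blobs Number of Gaussian blobs.
#' @param gradient_max If non-`NULL`, rescale so the maximum in-plane
#'   gradient magnitude equals this value (uT/m) for voxels of size
#'   `voxel_size` mm.
#' @param voxel_size In-plane voxel size (mm) used for the rescaling.
#' @param gamma Gyromagnetic ratio (rad/(s*T)) used to convert Hz/mm to uT/m.
#' @param seed Mandatory integer seed; the field is reproducible.
#' @return A `ny x nx` matrix of off-resonance values in Hz.
#' @examples
#' b0 <- make_b0_field(c(64, 64), seed = 1, gradient_max = 86)
#' @export
make_b0_field <- function(shape = c(64, 64), smoothness = 10, amplitude = 50,
                          n_blobs = 8, gradient_max = NULL, voxel_size = 3.5,
                          gamma = 267.51e6, seed) {
  if (missing(seed)) stop("`seed` is mandatory for reproducible fields")
  ny <- shape[1]; nx <- shape[2]
  if (amplitude == 0) return(matrix(0, ny, nx))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cy <- stats::runif(n_blobs, 1, ny)
  cx <- stats::runif(n_blobs, 1, nx)
  w <- stats::runif(n_blobs, -1, 1)
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  f <- matrix(0, ny, nx)
  for (b in seq_len(n_blobs)) {
    f <- f + w[b] * exp(-((yy - cy[b])^2 + (xx - cx[b])^2) / (2 * smoothness^2))
  }
  f <- f * amplitude / max(abs(f))
  if (!is.null(gradient_max)) {
    g <- compute_mfg(f, voxel_sizes = c(voxel_size, voxel_size), gamma = gamma)
    gmax <- max(sqrt(g$Gy_map^2 + g$Gx_map^2))
    if (gmax > 0) f <- f * gradient_max / gmax
  }
  f
}

# save/restore global RNG state so seeded generators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Macroscopic field gradients from a B0 map
#'
#' Central differences along each in-plane axis (one-sided forward/backward
#' differences at the edges), converted to uT/m. Exact for linear and, at
#' interior voxels, quadratic fields.
#'
#' @param B0_map Matrix (`ny x nx`) of off-resonance values.
#' @param voxel_sizes `c(dy, dx)` voxel sizes in mm (row axis first).
#' @param unit Unit of `B0_map`: `"Hz"` (default) or `"rad/s"`.
#' @param gamma Gyromagnetic ratio (rad/(s*T)).
#' @return A list of class `"mfg_maps"` with `Gy_map` and `Gx_map`
#'   (uT/m, same shape as the input, edges one-sided) and the input metadata.
#' @export
compute_mfg <- function(B0_map, voxel_sizes = c(3.5, 3.5),
                        unit = c("Hz", "rad/s"), gamma = 267.51e6) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(B0_map), all(dim(B0_map) >= 3), length(voxel_sizes) == 2)
  omega <- if (unit == "Hz") 2 * pi * B0_map else B0_map # rad/s
  # d omega / d length [rad/(s*mm)] -> field gradient [T/mm] = (1/gamma)*d/dl
  # -> uT/m: * 1e9 ... wait: T/mm * 1e6 uT/T * 1e3 mm/m = 1e9
  grad1 <- function(m, h, axis) {
    n <- dim(m)[axis]
    idx_p <- c(2:n, n); idx_m <- c(1, 1:(n - 1))
    den <- rep(2 * h, n); den[1] <- h; den[n] <- h
    if (axis == 1) {
      (m[idx_p, , drop = FALSE] - m[idx_m, , drop = FALSE]) / den
    } else {
      sweep(m[, idx_p, drop = FALSE] - m[, idx_m, drop = FALSE], 2, den, "/")
    }
  }
  to_uT_m <- 1e9 / gamma
  structure(
    list(Gy_map = grad1(omega, voxel_sizes[1], 1) * to_uT_m,
         Gx_map = grad1(omega, voxel_sizes[2], 2) * to_uT_m,
         unit = unit, voxel_sizes = voxel_sizes),
    class = "mfg_maps"
  )
}

#' Define a phantom object for the EPI forward model
#'
#' Per-voxel maps on the readout grid: proton density `rho` (multiplies the
#' tissue `S0`; default an elliptical "brain" occupying ~70% of the field of
#' view), the phase-encode MFG `gy_map`, a baseline k-space shift `k0y_map`,
#' and a through-plane MFG `gz_map`. Scalars are recycled to the grid.
#'
#' @param tissue A [tissue_params()] (uniform across the object).
#' @param n Matrix size (`n x n` grid).
#' @param gy_map,k0y_map,gz_map Scalars or `n x n` matrices (uT/m, rad/mm,
#'   uT/m).
#' @param rho `NULL` (default: an ellipse with a raised-cosine edge taper --
#'   a band-limited object keeps Gibbs ringing out of the discrete forward
#'   model), scalar, or `n x n` matrix.
#' @return An object of class `"ase_phantom"` with a logical `mask` marking
#'   the quantitative region (the full-density plateau, `rho >= 0.999`).
#' @examples
#' ph <- phantom_object(tissue_params(), n = 32, gy_map = 30)
#' @export
phantom_object <- function(tissue, n = 64, gy_map = 0, k0y_map = 0,
                           gz_map = 0, rho = NULL) {
  stopifnot(inherits(tissue, "tissue_params"))
  as_map <- function(x, nm) {
    if (is.null(dim(x))) {
      stopifnot(length(x) == 1)
      matrix(x, n, n)
    } else {
      if (!all(dim(x) == c(n, n))) stop(sprintf("`%s` must be %dx%d", nm, n, n))
      x
    }
  }
  if (is.null(rho)) {
    cc <- (n + 1) / 2
    yy <- matrix(seq_len(n), n, n); xx <- t(yy)
    r <- sqrt(((yy - cc) / (0.35 * n))^2 + ((xx - cc) / (0.35 * n))^2)
    w <- 0.12 # raised-cosine taper half-width (relative radius)
    rho <- ifelse(r <= 1 - w, 1,
                  ifelse(r >= 1 + w, 0,
                         0.5 * (1 + cos(pi * (r - (1 - w)) / (2 * w)))))
  }
  rho <- as_map(rho, "rho")
  structure(
    list(tissue = tissue, n = as.integer(n), rho = rho,
         gy_map = as_map(gy_map, "gy_map"), k0y_map = as_map(k0y_map, "k0y_map"),
         gz_map = as_map(gz_map, "gz_map"), mask = rho >= 0.999),
    class = "ase_phantom"
  )
}

# sampled PE lines: line index i (0-based) is read at t_i = tau + (i - i_center)
# * t_eff_es and samples ky_i = -(i - i_center) * dk. The opposite signs of the
# index-to-time and index-to-ky maps make the solved echo line consistent with
# tau_eff = (tau - k0y/v)/(1 + pe_sign*gamma*Gy/v): the echo of a voxel with
# phase ramp slope kappa(t) is read when ky_i = kappa(t_i).
.pe_lines <- function(readout, tau) {
  m <- seq_len(readout$n_p) - 1 - readout$i_center
  list(m = m, t = tau + m * readout$t_eff_es, ky = -m * readout$dk)
}

.sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

#' Forward-simulate one complex ASE-EPI slice
#'
#' Simulates the EPI acquisition of a phantom at nominal offset `tau`,
#' voxel by voxel in the phase-encode direction. k-space line `i`, read at
#' `t_i = tau + (i - i_center) * t_eff_es` after the spin echo, receives
#' from voxel `j` the contribution
#' `rho_j A_j(t_i) W(ky_i - kappa_j(t_i)) exp(-i (ky_i - kappa_j(t*_j)) y_j)`,
#' the transform of a boxcar voxel carrying a locally linear phase ramp of
#' slope `kappa_j(t) = pe_sign * gamma * Gy_j * t + k0y_j` (the voxel's
#' displaced k-space position); `A_j` is the relaxation/dephasing envelope
#' `S0 exp(-R2 (TE + t - tau)) f(t) * through-plane factor` and `W` the
#' boxcar voxel profile transform `sinc(k dy / 2)`. The voxel-center phase
#' is locked to the voxel's own echo time `t*_j` (the closed-form effective
#' offset): letting it follow each line time would additionally reproduce
#' EPI geometric distortion and its Jacobian intensity modulation, which is
#' out of scope here -- the phantom emulates distortion-corrected data. The inverse transform of
#' the sampled lines yields the complex image; its magnitude approximates
#' the closed-form echo-shifted signal within discretisation error. Echoes
#' displaced beyond the sampled k-space are simply not received (physical
#' dropout, not an error). The frequency-encode direction is treated as
#' ideal.
#'
#' @param object An [phantom_object()].
#' @param readout An [epi_readout()].
#' @param tau Nominal offset (ms), scalar.
#' @param pe_sign Override of `readout$pe_sign` (optional).
#' @param noise_sd Standard deviation of circular Gaussian noise added to
#'   each k-space sample (in units of the k-space signal; 0 = noiseless).
#' @param seed Seed for the noise (required when `noise_sd > 0`).
#' @param f Signal kernel, see [ase_signal()].
#' @return A complex `n x n` matrix (rows = phase-encode direction).
#' @export
forward_epi_acquisition <- function(object, readout, tau,
                                    pe_sign = readout$pe_sign, noise_sd = 0,
                                    seed = NULL, f = "qbold") {
  stopifnot(inherits(object, "ase_phantom"), inherits(readout, "epi_readout"),
            length(tau) == 1, object$n == readout$n_p)
  tis <- object$tissue
  n <- object$n
  ln <- .pe_lines(readout, tau)
  fn <- .f_fun(f, tis)
  y <- (seq_len(n) - 1 - readout$i_center) * readout$dy
  # envelope common to all voxels (uniform tissue): n-vector over lines
  env_t <- tis$S0 * exp(-tis$R2 * (readout$TE + ln$t - tau) * .MS) * fn(ln$t)
  grate <- .grad_rate(tis$gamma, 1) # rad/(mm*ms) per uT/m
  # per-voxel echo time and echo-center k-value (closed form)
  a_map <- pe_sign * grate * object$gy_map / readout$v
  te_map <- (tau - object$k0y_map / readout$v) / (1 + a_map)
  kstar_map <- pe_sign * grate * object$gy_map * te_map + object$k0y_map
  ksp <- matrix(0i, n, n) # [line, x]
  for (jx in seq_len(n)) {
    rho <- object$rho[, jx]
    nz <- which(rho != 0)
    if (length(nz) == 0) next
    kappa <- outer(ln$t, pe_sign * grate * object$gy_map[nz, jx]) +
      matrix(object$k0y_map[nz, jx], n, length(nz), byrow = TRUE)
    W <- .sinc((matrix(ln$ky, n, length(nz)) - kappa) * readout$dy / 2)
    phase <- exp(-1i * outer(ln$ky, y[nz])) *
      matrix(exp(1i * kstar_map[nz, jx] * y[nz]), n, length(nz), byrow = TRUE)
    tp <- if (any(object$gz_map[nz, jx] != 0)) {
      t(vapply(seq_along(nz), function(k) {
        through_plane_attenuation(ln$t, object$gz_map[nz[k], jx], readout$dz,
                                  tis$gamma)
      }, numeric(n)))
    } else NULL
    contrib <- W * phase *
      matrix(rho[nz], n, length(nz), byrow = TRUE) * env_t
    if (!is.null(tp)) contrib <- contrib * t(tp)
    ksp[, jx] <- rowSums(contrib)
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("`seed` required when noise_sd > 0")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    ksp <- ksp + complex(real = rnorm(n * n, sd = noise_sd),
                         imaginary = rnorm(n * n, sd = noise_sd))
  }
  # inverse transform along the PE axis per column: img_j = (1/n) sum_i K_i e^{+i ky_i y_j}
  exp(1i * outer(y, ln$ky)) %*% ksp / n
}

#' Acquire a multi-tau complex image stack
#'
#' Runs [forward_epi_acquisition()] for every nominal offset in `tau_list`
#' and bundles the result with its readout metadata.
#'
#' @inheritParams forward_epi_acquisition
#' @param tau_list Strictly increasing offsets (ms); default the 9-point
#'   acquisition grid 0, 6, ..., 48 ms.
#' @param pe_direction Label, one of `"PA"`, `"AP"`, `"RL"`, `"LR"`;
#'   `"AP"` and `"LR"` are the reversed polarities (`pe_sign = -1`).
#' @param noise_sd,seed k-space noise; sub-seeds are drawn per tau.
#' @return An object of class `"ase_stack"`: list with complex `data`
#'   array `[tau, y, x]`, `tau`, `readout`, `pe_direction`, `mask`.
#' @export
acquire_stack <- function(object, readout, tau_list = seq(0, 48, by = 6),
                          pe_direction = c("PA", "AP", "RL", "LR"),
                          noise_sd = 0, seed = NULL, f = "qbold") {
  pe_direction <- match.arg(pe_direction)
  stopifnot(all(diff(tau_list) > 0))
  ps <- if (pe_direction %in% c("PA", "RL")) 1L else -1L
  readout$pe_sign <- ps
  dat <- array(0i, dim = c(length(tau_list), object$n, object$n))
  for (it in seq_along(tau_list)) {
    s <- if (noise_sd > 0) seed + it - 1L else NULL
    dat[it, , ] <- forward_epi_acquisition(object, readout, tau_list[it],
                                           noise_sd = noise_sd, seed = s, f = f)
  }
  structure(
    list(data = dat, tau = tau_list, readout = readout,
         pe_direction = pe_direction, mask = object$mask),
    class = "ase_stack"
  )
}

#' @export
print.ase_stack <- function(x, ...) {
  cat(sprintf("<ase_stack> %d tau values (%s ms), %dx%d, PE %s (pe_sign %+d)\n",
              length(x$tau), paste(x$tau, collapse = ","),
              dim(x$data)[2], dim(x$data)[3], x$pe_direction,
              x$readout$pe_sign))
  invisible(x)
}

#' Acquire a reversed phase-encode pair
#'
#' Two stacks of the same object differing only in phase-encode polarity,
#' together with the ground-truth effective-offset maps of both polarities
#' (closed-form, per voxel and tau).
#'
#' @inheritParams acquire_stack
#' @param pe_directions Length-2 label pair, e.g. `c("PA", "AP")`.
#' @param seeds Length-2 integer seeds (only used when `noise_sd > 0`).
#' @return A list with `fwd`, `rev` (two [acquire_stack()] results) and
#'   `tau_eff_true`, `tau_eff_true_rev` (arrays `[tau, y, x]`, ms).
#' @export
make_reversed_pair <- function(object, readout, tau_list = seq(0, 48, by = 6),
                               pe_directions = c("PA", "AP"), noise_sd = 0,
                               seeds = c(NULL, NULL), f = "qbold") {
  stopifnot(length(pe_directions) == 2)
  fwd <- acquire_stack(object, readout, tau_list, pe_directions[1],
                       noise_sd = noise_sd, seed = seeds[1], f = f)
  rev <- acquire_stack(object, readout, tau_list, pe_directions[2],
                       noise_sd = noise_sd, seed = seeds[2], f = f)
  list(fwd = fwd, rev = rev,
       tau_eff_true = phantom_tau_eff(object, fwd$readout, tau_list),
       tau_eff_true_rev = phantom_tau_eff(object, rev$readout, tau_list))
}

#' Ground-truth effective offsets of a phantom
#'
#' Closed-form per-voxel effective offsets for each nominal offset, from the
#' phantom's gradient and baseline-shift maps.
#'
#' @param object An [phantom_object()].
#' @param readout An [epi_readout()] (its `pe_sign` is honoured).
#' @param tau_list Offsets (ms).
#' @return Array `[tau, y, x]` of effective offsets (ms).
#' @export
phantom_tau_eff <- function(object, readout, tau_list) {
  a <- readout$pe_sign * .grad_rate(object$tissue$gamma, object$gy_map) /
    readout$v
  out <- array(NA_real_, c(length(tau_list), object$n, object$n))
  for (it in seq_along(tau_list)) {
    out[it, , ] <- (tau_list[it] - object$k0y_map / readout$v) / (1 + a)
  }
  out
}

#' Magnitude images of a stack
#'
#' @param stack An [acquire_stack()] result.
#' @return Numeric array `[tau, y, x]` of magnitudes.
#' @export
stack_magnitude <- function(stack) {
  stopifnot(inherits(stack, "ase_stack"))
  Mod(stack$data)
}
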