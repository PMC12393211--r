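# Shared fixtures: baseline gray-matter tissue, the 64-line EPI readout, and
# small phantom builders. All synthetic, generated in code.

gm_tissue <- function(...) tissue_params(...)

# readout with the scanner-reported k-space velocity (differs ~3% from the
# geometric value; the constructor warns, which is expected here)
gm_readout <- function(...) {
  suppressWarnings(epi_readout(v = 0.077, ...))
}

# readout with geometry-consistent velocity, used by phantom/estimator tests
phantom_readout <- function(n = 32, ...) {
  epi_readout(n_p = n, fov_y = 3.5 * n, ...)
}

small_phantom <- function(n = 32, gy = 0, k0y = 0, tissue = gm_tissue(), ...) {
  phantom_object(tissue, n = n, gy_map = gy, k0y_map = k0y, ...)
}

# trajectory realising the regime assumptions of the closed-form apparent
# parameters: linear-exponential kernel everywhere except the point nearest
# tau = 0, which carries the quadratic-exponential signal
regime_trajectory <- function(tissue, readout, field, tau = default_tau_grid(2001)) {
  lin <- ase_trajectory(tissue, readout, field, tau = tau, f = "linear")
  quad <- ase_trajectory(tissue, readout, field, tau = tau, f = "quadratic")
  i0 <- which.min(abs(lin$tau))
  lin$signal[i0] <- quad$signal[i0]
  lin$dropout[i0] <- quad$dropout[i0]
  lin
}

# smooth in-plane Gy map bounded by gmax, zero outside nothing (full grid)
smooth_gy_map <- function(n, gmax = 40) {
  y <- seq(-1, 1, length.out = n)
  outer(y, y, function(a, b) gmax * sin(pi * a / 2) * cos(pi * b / 3))
}

# erode a logical mask by one voxel (drop object-edge voxels where sinc
# leakage from neighbours with different shifts distorts the estimate)
erode_mask <- function(m, k = 1) {
  for (i in seq_len(k)) {
    n1 <- nrow(m); n2 <- ncol(m)
    p <- matrix(FALSE, n1 + 2, n2 + 2)
    p[2:(n1 + 1), 2:(n2 + 1)] <- m
    m <- p[2:(n1 + 1), 2:(n2 + 1)] & p[1:n1, 2:(n2 + 1)] &
      p[3:(n1 + 2), 2:(n2 + 1)] & p[2:(n1 + 1), 1:n2] & p[2:(n1 + 1), 3:(n2 + 2)]
  }
  m
}
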