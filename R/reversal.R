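# Phase-encode-reversal analysis: log-ratio maps, Theil-Sen regression,
# slope-vs-tau tables, and mitigation operators.

#' Voxelwise log-ratio of a reversed phase-encode pair
#'
#' `ln(S / S_rev)` per voxel for one nominal offset; voxels outside the mask
#' or with a non-positive magnitude in either stack are `NA`.
#'
#' @param stack_fwd,stack_rev Two [acquire_stack()] results with matched
#'   geometry and offsets.
#' @param tau Nominal offset (ms), present in both stacks.
#' @return A matrix of log-ratios (`NA` where excluded).
#' @export
ln_ratio_map <- function(stack_fwd, stack_rev, tau) {
  stopifnot(inherits(stack_fwd, "ase_stack"), inherits(stack_rev, "ase_stack"))
  if (!all(dim(stack_fwd$data) == dim(stack_rev$data)) ||
      !all(stack_fwd$tau == stack_rev$tau)) {
    stop("geometry/offset mismatch between the two stacks")
  }
  it <- match(tau, stack_fwd$tau)
  if (is.na(it)) stop(sprintf("tau = %g ms not in the stacks", tau))
  s <- Mod(stack_fwd$data[it, , ])
  sr <- Mod(stack_rev$data[it, , ])
  out <- matrix(NA_real_, nrow(s), ncol(s))
  ok <- stack_fwd$mask & s > 0 & sr > 0
  out[ok] <- log(s[ok] / sr[ok])
  out
}

#' Theil-Sen robust linear regression
#'
#' Slope as the median of all pairwise slopes, intercept as
#' `median(y - slope * x)`, with a 95% (by default) confidence interval on
#' the slope from the standard order-statistic rule (normal approximation to
#' the Kendall statistic). For more than `n_exact` points the pairwise
#' slopes are subsampled (`max_pairs` random pairs, seeded) and the same
#' interval is applied to the sample.
#'
#' @param x,y Numeric vectors (non-finite pairs dropped); at least 3 distinct
#'   points with non-degenerate `x` spread required.
#' @param conf Confidence level for the slope interval.
#' @param n_exact Largest n for which all `n(n-1)/2` pairs are used.
#' @param max_pairs Number of sampled pairs above `n_exact`.
#' @param seed Seed for the pair subsampling.
#' @return An object of class `"theil_sen_fit"`: list with `slope`,
#'   `intercept`, `ci_low`, `ci_high`, `n`, `n_pairs`, `exact`, `conf`.
#'   Use [tidy.theil_sen_fit()] / [glance.theil_sen_fit()] for tibbles.
#' @examples
#' f <- theil_sen_fit(1:20, 2 * (1:20) + 1)
#' f$slope; f$intercept
#' @export
theil_sen_fit <- function(x, y, conf = 0.95, n_exact = 1e4, max_pairs = 1e6,
                          seed = 1L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite (x, y) pairs")
  if (max(x) - min(x) <= 0) stop("degenerate x: zero spread")
  if (n <= n_exact) {
    ii <- rep(seq_len(n - 1), times = (n - 1):1)
    jj <- sequence((n - 1):1, from = 2:n)
    exact <- TRUE
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    ii <- sample.int(n, max_pairs, replace = TRUE)
    jj <- sample.int(n, max_pairs, replace = TRUE)
    keep <- ii != jj
    ii <- ii[keep]; jj <- jj[keep]
    exact <- FALSE
  }
  dx <- x[jj] - x[ii]
  nz <- dx != 0
  slopes <- sort((y[jj][nz] - y[ii][nz]) / dx[nz])
  np <- length(slopes)
  if (np == 0) stop("degenerate x: no pair with distinct x")
  slope <- median(slopes)
  intercept <- median(y - slope * x)
  # Sen's order-statistic interval on the sorted pairwise slopes
  z <- qnorm(1 - (1 - conf) / 2)
  vs <- n * (n - 1) * (2 * n + 5) / 18
  cw <- z * sqrt(vs)
  if (!exact) cw <- cw * np / (n * (n - 1) / 2) # rescale to sampled pairs
  lo <- max(1, floor((np - cw) / 2))
  hi <- min(np, ceiling((np + cw) / 2) + 1)
  structure(
    list(slope = slope, intercept = intercept,
         ci_low = slopes[lo], ci_high = slopes[hi],
         n = n, n_pairs = np, exact = exact, conf = conf),
    class = "theil_sen_fit"
  )
}

#' @export
print.theil_sen_fit <- function(x, ...) {
  cat(sprintf("<theil_sen_fit> slope = %.4g [%.4g, %.4g] (%.0f%% CI), intercept = %.4g, n = %d\n",
              x$slope, x$ci_low, x$ci_high, 100 * x$conf, x$intercept, x$n))
  invisible(x)
}

#' Tidy a Theil-Sen fit
#'
#' @param x A `"theil_sen_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per term (`slope`, `intercept`), the slope
#'   row carrying `conf.low` / `conf.high`.
#' @export
tidy.theil_sen_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept),
         conf.low = c(x$ci_low, NA_real_),
         conf.high = c(x$ci_high, NA_real_))
}

#' @rdname tidy.theil_sen_fit
#' @return `glance()`: a one-row tibble with slope, CI, n and pair count.
#' @export
glance.theil_sen_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, ci_low = x$ci_low,
         ci_high = x$ci_high, n = x$n, n_pairs = x$n_pairs, exact = x$exact)
}

#' Regression slopes versus nominal offset for a reversed pair
#'
#' For every nominal offset: compute the voxelwise log-ratio
#' ([ln_ratio_map()]), estimate the effective-offset maps of both stacks by
#' simulated signal dropout and take their difference
#' ([tau_eff_difference()]), then Theil-Sen-regress the log-ratio against
#' the offset difference and (optionally) against a supplied MFG map.
#' Voxels with unreliable offset estimates or undefined log-ratios are
#' excluded; the remaining count is reported per row.
#'
#' @param stack_fwd,stack_rev A reversed phase-encode pair.
#' @param gy_map Optional matrix of per-voxel phase-encode MFGs (uT/m) for
#'   the `x_label = "Gy"` regressions.
#' @param taus Offsets to analyse (default all in the stack).
#' @param smoothing_sd Passed to [estimate_tau_eff()].
#' @param conf Confidence level.
#' @return A tibble of class `"slope_table"`, one row per `tau` and
#'   `x_label` (`"tau_eff_diff"` in 1/ms, `"Gy"` in 1/(uT/m)):
#'   `tau`, `x_label`, `slope`, `intercept`, `ci_low`, `ci_high`,
#'   `n_voxels`, `v`.
#' @export
slope_vs_tau_table <- function(stack_fwd, stack_rev, gy_map = NULL,
                               taus = stack_fwd$tau, smoothing_sd = 2,
                               conf = 0.95) {
  stopifnot(length(taus) >= 1)
  rows <- purrr::map(taus, function(tau) {
    lr <- ln_ratio_map(stack_fwd, stack_rev, tau)
    mf <- estimate_tau_eff(stack_fwd, tau, smoothing_sd = smoothing_sd)
    mr <- estimate_tau_eff(stack_rev, tau, smoothing_sd = smoothing_sd)
    dd <- tau_eff_difference(mf, mr)
    keep <- dd$reliable & is.finite(lr)
    out <- list()
    if (sum(keep) >= 3 && max(dd$diff[keep]) > min(dd$diff[keep])) {
      ts <- theil_sen_fit(dd$diff[keep], lr[keep], conf = conf)
      out$tau_eff_diff <- tibble(
        tau = tau, x_label = "tau_eff_diff", slope = ts$slope,
        intercept = ts$intercept, ci_low = ts$ci_low, ci_high = ts$ci_high,
        n_voxels = ts$n, v = stack_fwd$readout$v
      )
    }
    if (!is.null(gy_map)) {
      keep_g <- is.finite(lr) & is.finite(gy_map) & stack_fwd$mask
      if (sum(keep_g) >= 3 && max(gy_map[keep_g]) > min(gy_map[keep_g])) {
        tg <- theil_sen_fit(gy_map[keep_g], lr[keep_g], conf = conf)
        out$gy <- tibble(
          tau = tau, x_label = "Gy", slope = tg$slope,
          intercept = tg$intercept, ci_low = tg$ci_low, ci_high = tg$ci_high,
          n_voxels = tg$n, v = stack_fwd$readout$v
        )
      }
    }
    dplyr::bind_rows(out)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("slope_table", class(out))
  out
}

#' Geometric-mean combination of a reversed pair
#'
#' `sqrt(S * S_rev)` per voxel and offset. The first-order dependence on
#' `gamma*Gy/v` cancels between the two polarities, so the residual against
#' the unshifted signal scales as `(gamma*Gy/v)^2`.
#'
#' @param stack_fwd,stack_rev A reversed phase-encode pair.
#' @return Magnitude array `[tau, y, x]`; zero magnitudes stay zero.
#' @export
geometric_mean_combine <- function(stack_fwd, stack_rev) {
  stopifnot(inherits(stack_fwd, "ase_stack"), inherits(stack_rev, "ase_stack"))
  if (!all(dim(stack_fwd$data) == dim(stack_rev$data))) {
    stop("geometry mismatch between the two stacks")
  }
  sqrt(Mod(stack_fwd$data) * Mod(stack_rev$data))
}

#' Root-mean-square combination of signal trajectories
#'
#' Pointwise RMS across trajectories sharing a common tau grid, emulating
#' the combination of multiple y-shimmed acquisitions (different baseline
#' shifts `k0y`).
#'
#' @param trajectories A list of trajectory tibbles ([ase_trajectory()]) on
#'   identical tau grids.
#' @return A tibble with columns `tau` and `signal` (the RMS trajectory).
#' @export
rms_combine <- function(trajectories) {
  stopifnot(is.list(trajectories), length(trajectories) >= 2)
  tau <- trajectories[[1]]$tau
  for (tr in trajectories[-1]) {
    if (length(tr$tau) != length(tau) || any(tr$tau != tau)) {
      stop("trajectories must share a common tau grid")
    }
  }
  s2 <- Reduce(`+`, lapply(trajectories, function(tr) tr$signal^2))
  tibble(tau = tau, signal = sqrt(s2 / length(trajectories)))
}
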