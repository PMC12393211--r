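# File interfaces: trajectory CSV, NIfTI volumes with JSON sidecars.

#' Write / read a signal trajectory as CSV
#'
#' Columns `tau_ms`, `tau_eff_ms`, `signal`, `dropout`.
#'
#' @param traj A trajectory tibble ([ase_trajectory()]).
#' @param path Output CSV path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a trajectory tibble with the package's
#'   internal column names.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- data.frame(tau_ms = traj$tau, tau_eff_ms = traj$tau_eff,
                    signal = traj$signal, dropout = traj$dropout)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  tibble(tau = d$tau_ms, tau_eff = d$tau_eff_ms, signal = d$signal,
         dropout = as.logical(d$dropout))
}

#' Write a complex image stack as NIfTI magnitude/phase plus JSON sidecar
#'
#' Writes `<prefix>_mag.nii`, `<prefix>_phase.nii` (both `[y, x, tau]`) and
#' `<prefix>.json` holding the readout metadata needed to re-interpret the
#' stack (`tau` list, `t_eff_es`, `i_center`, `v`, `fov_y`, `pe_direction`).
#'
#' @param stack An [acquire_stack()] result.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_stack_nifti <- function(stack, prefix) {
  stopifnot(inherits(stack, "ase_stack"))
  perm <- aperm(stack$data, c(2, 3, 1)) # [y, x, tau]
  RNifti::writeNifti(RNifti::asNifti(Mod(perm)), paste0(prefix, "_mag.nii"))
  RNifti::writeNifti(RNifti::asNifti(Arg(perm)), paste0(prefix, "_phase.nii"))
  ro <- stack$readout
  meta <- list(tau_ms = stack$tau, t_eff_es_ms = ro$t_eff_es,
               i_center = ro$i_center, v = ro$v, fov_y_mm = ro$fov_y,
               dz_mm = ro$dz, TE_ms = ro$TE, n_p = ro$n_p,
               pe_direction = stack$pe_direction, pe_sign = ro$pe_sign)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_stack_nifti
#' @param mask Optional logical matrix; defaults to magnitude > 0 at the
#'   first offset.
#' @return `read_stack_nifti()`: an `"ase_stack"` reassembled from the three
#'   files.
#' @export
read_stack_nifti <- function(prefix, mask = NULL) {
  mag <- as.array(RNifti::readNifti(paste0(prefix, "_mag.nii")))
  ph <- as.array(RNifti::readNifti(paste0(prefix, "_phase.nii")))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dat <- aperm(mag * exp(1i * ph), c(3, 1, 2)) # [tau, y, x]
  ro <- epi_readout(n_p = meta$n_p, fov_y = meta$fov_y_mm,
                    t_eff_es = meta$t_eff_es_ms, v = meta$v, dz = meta$dz_mm,
                    TE = meta$TE_ms, i_center = meta$i_center,
                    pe_sign = meta$pe_sign)
  if (is.null(mask)) mask <- Mod(dat[1, , ]) > 0
  structure(
    list(data = dat, tau = meta$tau_ms, readout = ro,
         pe_direction = meta$pe_direction, mask = mask),
    class = "ase_stack"
  )
}

#' Write a 2-D map (B0, Gy, effective offset, ...) as NIfTI
#'
#' @param map A numeric matrix.
#' @param path Output path (`.nii`).
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(array(map, dim = c(dim(map), 1))), path)
  invisible(path)
}
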