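#' 3D gamma-index dose comparison
#'
#' Compares an evaluated dose distribution against a reference with the
#' combined dose-difference / distance-to-agreement criterion used for
#' delivery QA: at each reference voxel r,
#' `gamma(r) = min over r' of sqrt( (|r - r'|/dist_mm)^2 +
#' ((D_eval(r') - D_ref(r)) / (dose_pct/100 * D_ref(r)))^2 )`,
#' with *local* dose normalization (the denominator uses the reference
#' dose at r).  Voxels below `cutoff_pct` of the reference maximum are
#' excluded.  The default criterion is 3% local dose difference and
#' 3 mm distance to agreement.
#'
#' The search lattice steps at `step_frac` of the voxel spacing
#' (half-voxel by default, with trilinear interpolation of the
#' evaluated dose) and is capped at `radius_factor * dist_mm`: any voxel
#' whose true gamma exceeds that cap is irrelevant to pass/fail and is
#' reported at the best value found within the cap.
#'
#' @param ref_dose,eval_dose 3D dose arrays on the same grid.
#' @param grid the [voxel_grid()].
#' @param dose_pct dose-difference criterion (percent, local).
#' @param dist_mm distance-to-agreement criterion (mm).
#' @param cutoff_pct low-dose cutoff (percent of the reference maximum).
#' @param step_frac search step as a fraction of the voxel spacing.
#' @param radius_factor search radius cap in units of `dist_mm`.
#' @param interp trilinear interpolation of the evaluated dose
#'   (`FALSE` restricts the search to the voxel lattice).
#' @return An object of class `gamma_result`: `gamma` (array, `NA`
#'   below cutoff), `pass_rate` (percent of evaluated voxels with
#'   gamma <= 1), `n_evaluated`, and the criteria used.
#' @examples
#' g <- voxel_grid(c(12, 12, 4), 2)
#' d <- array(runif(prod(g$dims), 40, 60), dim = g$dims)
#' gamma_index(d, d, g)$pass_rate   # identical plans: 100
#' @export
gamma_index <- function(ref_dose, eval_dose, grid, dose_pct = 3,
                        dist_mm = 3, cutoff_pct = 10, step_frac = 0.5,
                        radius_factor = 3, interp = TRUE) {
  if (!identical(dim(ref_dose), dim(eval_dose)))
    stop("dose grids do not match; resample first")
  if (!identical(dim(ref_dose), grid$dims)) stop("dose does not match grid")
  if (dose_pct <= 0 || dist_mm <= 0) stop("criteria must be positive")
  cutoff_abs <- cutoff_pct / 100 * max(ref_dose)
  if (!any(ref_dose >= cutoff_abs) || max(ref_dose) <= 0)
    stop("all reference voxels are below the low-dose cutoff")
  g <- .gamma_search(as.numeric(ref_dose), as.numeric(eval_dose),
                     grid$dims, grid$spacing, dose_pct / 100, dist_mm,
                     cutoff_abs, grid$spacing * step_frac,
                     radius_factor * dist_mm, interp)
  g <- array(g, dim = grid$dims)
  ev <- !is.na(g)
  structure(list(gamma = g, pass_rate = 100 * mean(g[ev] <= 1),
                 n_evaluated = sum(ev),
                 criteria = list(dose_pct = dose_pct, dist_mm = dist_mm,
                                 cutoff_pct = cutoff_pct)),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma %g%%/%g mm (cutoff %g%%): pass rate %.1f%% over %d voxels\n",
              x$criteria$dose_pct, x$criteria$dist_mm,
              x$criteria$cutoff_pct, x$pass_rate, x$n_evaluated))
  invisible(x)
}

#' Resample a dose grid by trilinear interpolation
#'
#' Maps a dose defined on `from_grid` onto the voxel centers of
#' `to_grid`.  Target voxels outside the source extent are returned as
#' `NA` (excluded); entirely disjoint extents are an error.
#'
#' @param dose 3D array on `from_grid`.
#' @param from_grid,to_grid [voxel_grid()] objects with overlapping
#'   extents.
#' @return 3D array on `to_grid`.
#' @export
resample_dose <- function(dose, from_grid, to_grid) {
  stopifnot(identical(dim(dose), from_grid$dims))
  axf <- grid_axes(from_grid)
  axt <- grid_axes(to_grid)
  overlap <- function(a, b) min(max(a), max(b)) >= max(min(a), min(b))
  if (!overlap(axf$x, axt$x) || !overlap(axf$y, axt$y) ||
      !overlap(axf$z, axt$z))
    stop("grid extents are disjoint; cannot resample")
  # fractional source indices of every target voxel center
  fi <- (axt$x - from_grid$origin[1]) / from_grid$spacing[1]
  fj <- (axt$y - from_grid$origin[2]) / from_grid$spacing[2]
  fk <- (axt$z - from_grid$origin[3]) / from_grid$spacing[3]
  nx <- from_grid$dims[1]; ny <- from_grid$dims[2]; nz <- from_grid$dims[3]
  out <- array(NA_real_, dim = to_grid$dims)
  FI <- rep(fi, times = length(fj) * length(fk))
  FJ <- rep(rep(fj, each = length(fi)), times = length(fk))
  FK <- rep(fk, each = length(fi) * length(fj))
  ok <- FI >= 0 & FJ >= 0 & FK >= 0 & FI <= nx - 1 & FJ <= ny - 1 &
    FK <= nz - 1
  i0 <- pmin(floor(FI[ok]), nx - 2); i0[i0 < 0] <- 0
  j0 <- pmin(floor(FJ[ok]), ny - 2); j0[j0 < 0] <- 0
  k0 <- pmin(floor(FK[ok]), nz - 2); k0[k0 < 0] <- 0
  if (nx == 1) i0 <- rep(0, sum(ok))
  if (ny == 1) j0 <- rep(0, sum(ok))
  if (nz == 1) k0 <- rep(0, sum(ok))
  u <- FI[ok] - i0; v <- FJ[ok] - j0; w <- FK[ok] - k0
  at <- function(di, dj, dk) {
    ii <- pmin(i0 + di, nx - 1); jj <- pmin(j0 + dj, ny - 1)
    kk <- pmin(k0 + dk, nz - 1)
    dose[kk * nx * ny + jj * nx + ii + 1]
  }
  val <- at(0, 0, 0) * (1 - u) * (1 - v) * (1 - w) +
    at(1, 0, 0) * u * (1 - v) * (1 - w) +
    at(0, 1, 0) * (1 - u) * v * (1 - w) +
    at(1, 1, 0) * u * v * (1 - w) +
    at(0, 0, 1) * (1 - u) * (1 - v) * w +
    at(1, 0, 1) * u * (1 - v) * w +
    at(0, 1, 1) * (1 - u) * v * w +
    at(1, 1, 1) * u * v * w
  out[ok] <- val
  out
}

#' Write a gamma result as a NIfTI map plus JSON summary
#' @param gr a `gamma_result`; `grid` its [voxel_grid()]; `dir` output
#'   directory.
#' @param grid the [voxel_grid()].
#' @param dir output directory.
#' @export
save_gamma_result <- function(gr, grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (rnifti_available()) {
    gmap <- gr$gamma
    gmap[is.na(gmap)] <- -1
    write_nifti_grid(gmap, grid, file.path(dir, "gamma_map.nii.gz"))
  }
  jsonlite::write_json(
    list(pass_rate_pct = gr$pass_rate, n_evaluated = gr$n_evaluated,
         criteria = gr$criteria),
    file.path(dir, "gamma_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
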