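#' Structure-geometry operators
#'
#' Margin expansion, fall-off shells, the skin ring and boolean mask
#' algebra — the geometric vocabulary a planning wishlist is written in.
#' All distances are Euclidean between voxel centers, computed with an
#' exact separable distance transform, so `expand()` is a true
#' isotropic-margin expansion rather than a morphological kernel
#' dilation.
#'
#' @name geometry
NULL

#' Squared Euclidean distance to a mask (mm^2)
#'
#' @param mask logical 3D array.
#' @param grid the [voxel_grid()] the mask lives on.
#' @return numeric array of squared distances (0 inside the mask,
#'   `Inf` if the mask is empty).
#' @export
distance_sq_to <- function(mask, grid) {
  mask <- as_mask(mask, grid)
  d <- .edt_sq(as.logical(mask), grid$dims, grid$spacing)
  array(d, dim = grid$dims)
}

#' Expand a mask by an isotropic margin
#'
#' The planning-target-volume construction: `PTV = expand(CTV, 5)` with
#' the 5 mm setup margin used for daily image guidance.
#'
#' @param mask logical 3D array.
#' @param grid the [voxel_grid()].
#' @param margin_mm nonnegative margin in mm.
#' @return logical array; all voxels whose center lies within
#'   `margin_mm` of the input mask.  The input is always contained in
#'   the output.
#' @export
expand_mask <- function(mask, grid, margin_mm) {
  if (!is.numeric(margin_mm) || length(margin_mm) != 1L ||
      is.na(margin_mm) || margin_mm < 0)
    stop("`margin_mm` must be a single nonnegative number")
  if (margin_mm == 0) return(as_mask(mask, grid))
  distance_sq_to(mask, grid) <= margin_mm^2
}

#' Fall-off shell around a structure
#'
#' A thin band of normal tissue at a given distance from a target, used
#' by dose fall-off objectives ("shell 5 mm", "shell 50 mm", ...).  The
#' band contains the voxels outside `mask`, inside `external`, whose
#' distance to `mask` lies in `(distance_mm, distance_mm + thickness_mm]`.
#'
#' @param mask structure the shell surrounds.
#' @param grid the [voxel_grid()].
#' @param distance_mm inner distance of the band (>= 0).
#' @param thickness_mm band thickness (> 0); the default 5 mm gives the
#'   thin fall-off bands conventional in prioritized planning.
#' @param external body contour; the shell never leaves the patient.
#' @param exclude optional mask (e.g. the union of all PTVs) removed
#'   from the shell so fall-off objectives cannot fight target coverage.
#' @return logical array; empty (with a warning) when no voxel
#'   qualifies, in which case callers drop the structure.
#' @export
shell_mask <- function(mask, grid, distance_mm, thickness_mm = 5,
                       external = NULL, exclude = NULL) {
  if (distance_mm < 0) stop("`distance_mm` must be >= 0")
  if (thickness_mm <= 0) stop("`thickness_mm` must be > 0")
  d2 <- distance_sq_to(mask, grid)
  out <- d2 > distance_mm^2 & d2 <= (distance_mm + thickness_mm)^2
  out <- out & !as_mask(mask, grid)
  if (!is.null(external)) out <- out & as_mask(external, grid)
  if (!is.null(exclude)) out <- out & !as_mask(exclude, grid)
  if (!any(out))
    warning(sprintf("shell at %g mm is empty; structure dropped",
                    distance_mm))
  out
}

#' Ring of tissue just under the skin
#'
#' All voxels inside the body contour within `depth_mm` of the patient
#' surface ("skin ring"); used to suppress superficial dose.  Where the
#' body is cropped by the grid boundary (cranial/caudal scan edges) no
#' surface exists and no ring is produced there.
#'
#' @param external body mask.
#' @param grid the [voxel_grid()].
#' @param depth_mm ring depth in mm (> 0).  A depth larger than the body
#'   half-width simply returns all of `external`.
#' @param exclude optional mask removed from the ring (PTVs).
#' @return logical array.
#' @export
inner_ring <- function(external, grid, depth_mm, exclude = NULL) {
  if (depth_mm <= 0) stop("`depth_mm` must be > 0")
  ext <- as_mask(external, grid)
  d2_out <- distance_sq_to(!ext, grid)   # distance to nearest outside voxel
  out <- ext & d2_out <= depth_mm^2
  if (!is.null(exclude)) out <- out & !as_mask(exclude, grid)
  out
}

#' Boolean mask algebra
#'
#' @param a,b logical arrays on the same grid.
#' @param grid the [voxel_grid()].
#' @return logical array with set semantics.
#' @export
mask_subtract <- function(a, b, grid) {
  a <- as_mask(a, grid); b <- as_mask(b, grid)
  a & !b
}

#' @rdname mask_subtract
#' @export
mask_union <- function(a, b, grid) {
  a <- as_mask(a, grid); b <- as_mask(b, grid)
  a | b
}

#' Unspecified tissue
#'
#' Body voxels not claimed by any named target, organ at risk or
#' auxiliary planning structure; carries its own maximum-dose constraint
#' in the wishlists.
#'
#' @param external body mask.
#' @param structures list of logical masks to exclude.
#' @param grid the [voxel_grid()].
#' @return logical array.
#' @export
unspecified_tissue <- function(external, structures, grid) {
  out <- as_mask(external, grid)
  for (m in structures) out <- out & !as_mask(m, grid)
  out
}
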