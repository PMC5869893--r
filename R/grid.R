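#' Regular 3D voxel grid
#'
#' All doses and structure masks in one planning problem live on a common
#' regular grid.  Coordinates are voxel-center based and in mm throughout:
#' the world position of array element `(i, j, k)` (1-based in R) is
#' `origin + (c(i, j, k) - 1) * spacing`.  Axes follow the convention
#' x = left-right, y = posterior-anterior, z = inferior-superior.
#'
#' @param dims integer vector of length 3, voxel counts per axis (>= 1).
#' @param spacing numeric vector of length 3, voxel spacing in mm (> 0).
#'   A scalar is recycled (isotropic grid).
#' @param origin numeric vector of length 3, world position (mm) of the
#'   center of voxel `(1, 1, 1)`.  Default centers the grid on the world
#'   origin.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(50, 40, 40), 4)
#' prod(g$dims)
#' @export
voxel_grid <- function(dims, spacing, origin = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("`dims` must be 3 positive integers")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  if (is.null(origin)) origin <- -(dims - 1L) * spacing / 2
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid:", paste(x$dims, collapse = " x "), "voxels,",
      paste(signif(x$spacing, 4), collapse = " x "), "mm spacing\n")
  invisible(x)
}

#' @export
format.voxel_grid <- function(x, ...)
  sprintf("%s voxels @ %s mm", paste(x$dims, collapse = "x"),
          paste(signif(x$spacing, 4), collapse = "x"))

#' Axis coordinate vectors of a grid (mm, voxel centers)
#' @param grid a [voxel_grid()].
#' @return list with numeric vectors `x`, `y`, `z`.
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$dims[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$dims[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$dims[3]) - 1) * grid$spacing[3])
}

#' World coordinates of every voxel center
#' @inheritParams grid_axes
#' @return an `n x 3` matrix (mm), rows in array (column-major) order.
#' @export
grid_coords <- function(grid) {
  ax <- grid_axes(grid)
  cbind(x = rep(ax$x, times = grid$dims[2] * grid$dims[3]),
        y = rep(rep(ax$y, each = grid$dims[1]), times = grid$dims[3]),
        z = rep(ax$z, each = grid$dims[1] * grid$dims[2]))
}

#' Volume of one voxel in ml
#' @inheritParams grid_axes
#' @export
voxel_volume_ml <- function(grid) prod(grid$spacing) / 1000

#' @keywords internal
same_grid <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' @keywords internal
stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("grids do not match (dims/spacing/origin)")
  invisible(TRUE)
}

#' @keywords internal
empty_mask <- function(grid) array(FALSE, dim = grid$dims)

#' @keywords internal
as_mask <- function(m, grid) {
  if (!is.array(m) || !identical(dim(m), grid$dims))
    stop("mask does not match grid dims")
  storage.mode(m) <- "logical"
  m
}

# ---- NIfTI I/O (external interface; needs RNifti) -----------------------

rnifti_available <- function() requireNamespace("RNifti", quietly = TRUE)

nifti_from_grid <- function(arr, grid) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$spacing
  img
}

#' Write a dose grid or mask as NIfTI
#'
#' @param arr 3D numeric or logical array matching `grid$dims`.
#' @param grid the [voxel_grid()] the array lives on.
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_grid <- function(arr, grid, path) {
  if (!rnifti_available()) stop("NIfTI output requires the RNifti package")
  storage.mode(arr) <- "double"
  RNifti::writeNifti(nifti_from_grid(arr, grid), path)
  invisible(path)
}

#' Read a NIfTI volume written by [write_nifti_grid()]
#' @param path NIfTI file.
#' @return list with `array` and `spacing` (mm).
#' @export
read_nifti_grid <- function(path) {
  if (!rnifti_available()) stop("NIfTI input requires the RNifti package")
  img <- RNifti::readNifti(path)
  list(array = array(as.numeric(img), dim = dim(img)),
       spacing = RNifti::pixdim(img)[seq_len(3)])
}
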