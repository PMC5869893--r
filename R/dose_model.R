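#' Equi-angular coplanar beam set
#'
#' Rotational (VMAT-like) delivery is approximated for optimization by
#' `n_beams` static intensity-modulated beams at equal gantry spacing
#' (`k * 360 / n` degrees), the standard arc surrogate of fluence
#' pre-optimization.  Gantry 0 enters from anterior; angles increase
#' rotating about the cranio-caudal axis.
#'
#' @param n_beams number of beams (>= 1); 20 for the packaged plans.
#' @param isocenter world position (mm); place at the centroid of the
#'   phase target (`PTV-LN` for phase 1, `PTV-P` for the boost).
#' @param beamlet_size beamlet pitch at the isocenter plane (mm).
#' @param sad source-axis distance (mm).
#' @return An object of class `beam_set`.
#' @examples
#' make_beams(4, c(0, 0, 0))$angles   # 0, 90, 180, 270
#' @export
make_beams <- function(n_beams, isocenter, beamlet_size = 10, sad = 1000) {
  n_beams <- as.integer(n_beams)
  if (is.na(n_beams) || n_beams < 1L) stop("`n_beams` must be >= 1")
  if (beamlet_size <= 0) stop("`beamlet_size` must be > 0")
  stopifnot(length(isocenter) == 3L, all(is.finite(isocenter)))
  structure(list(angles = (seq_len(n_beams) - 1) * 360 / n_beams,
                 isocenter = as.numeric(isocenter),
                 beamlet_size = beamlet_size, sad = sad),
            class = "beam_set")
}

#' @export
print.beam_set <- function(x, ...) {
  cat("beam_set:", length(x$angles), "beams,",
      x$beamlet_size, "mm beamlets, SAD", x$sad, "mm\n")
  invisible(x)
}

#' Centroid of a mask in world coordinates (mm)
#' @param mask logical array; `grid` a [voxel_grid()].
#' @param grid a [voxel_grid()].
#' @export
mask_centroid <- function(mask, grid) {
  mask <- as_mask(mask, grid)
  if (!any(mask)) stop("cannot take the centroid of an empty mask")
  colMeans(grid_coords(grid)[as.vector(mask), , drop = FALSE])
}

#' Physics parameters of the pencil-beam surrogate
#'
#' Homogeneous water-equivalent body: exponential depth attenuation
#' (`mu_cm`, broad-beam effective attenuation, default 0.04/cm for
#' high-energy photons), Gaussian lateral beamlet profile (`sigma_mm`,
#' default 5 mm at the isocenter plane), ray-march step for radiological
#' depth, lateral support cutoff, and the dose such that unit uniform
#' fluence on all beams delivers `calibration_gy` at the isocenter.
#' Influence entries below `column_cutoff` of their column maximum are
#' dropped to preserve sparsity.
#'
#' @param mu_cm linear attenuation (1/cm).
#' @param sigma_mm lateral Gaussian width (mm).
#' @param step_mm ray-march step (mm).
#' @param lateral_cut_mm lateral support radius (mm).
#' @param calibration_gy dose at isocenter for unit uniform fluence (Gy).
#' @param column_cutoff relative per-column sparsity cutoff.
#' @export
physics_params <- function(mu_cm = 0.04, sigma_mm = 5, step_mm = 2,
                           lateral_cut_mm = 2.7 * sigma_mm,
                           calibration_gy = 2, column_cutoff = 1e-4) {
  stopifnot(mu_cm >= 0, sigma_mm > 0, step_mm > 0, lateral_cut_mm > 0,
            calibration_gy > 0, column_cutoff >= 0, column_cutoff < 1)
  structure(list(mu_cm = mu_cm, sigma_mm = sigma_mm, step_mm = step_mm,
                 lateral_cut_mm = lateral_cut_mm,
                 calibration_gy = calibration_gy,
                 column_cutoff = column_cutoff), class = "physics_params")
}

#' Compute the dose-influence matrix
#'
#' Builds the sparse linear map from beamlet fluence weights to voxel
#' dose (Gy per unit weight) for every beam in `beams`.  Each beamlet
#' deposits dose along its divergent ray: exponential in radiological
#' depth from the body entry, Gaussian laterally; dose is identically
#' zero outside the body contour.  The per-beam beamlet grid is shaped
#' to the divergent projection of `field_mask` plus `field_margin_mm`.
#'
#' @param grid a [voxel_grid()].
#' @param external body mask; only voxels inside it receive dose.
#' @param beams a [make_beams()] beam set.
#' @param physics a [physics_params()].
#' @param field_mask mask whose beam's-eye-view defines the fluence
#'   aperture (default: the body itself).
#' @param field_margin_mm aperture margin around the field mask (mm).
#' @return An object of class `dose_influence` with elements `D`
#'   (sparse `dgCMatrix`, kept voxels x beamlets), `kept` (linear voxel
#'   indices inside the body), `beamlets` (index table: beam, row, col,
#'   angle, lateral/axial center, `hits_body` flag), `grid`, `beams`,
#'   `physics`, and `calibration` (Gy per raw unit).
#' @export
compute_dij <- function(grid, external, beams, physics = physics_params(),
                        field_mask = NULL, field_margin_mm = 12) {
  external <- as_mask(external, grid)
  if (!any(external)) stop("`external` is empty")
  if (is.null(field_mask)) field_mask <- external
  field_mask <- as_mask(field_mask, grid)
  kept <- which(as.vector(external))            # 1-based linear indices
  iso <- beams$isocenter
  bs <- beams$beamlet_size

  fc <- grid_coords(grid)[as.vector(field_mask), , drop = FALSE]
  blocks <- list()
  tables <- list()
  for (b in seq_along(beams$angles)) {
    th <- beams$angles[b] * pi / 180
    us <- c(sin(th), cos(th), 0)
    e1 <- c(cos(th), -sin(th), 0)
    S <- iso + beams$sad * us
    w <- sweep(fc, 2, S)
    zeta <- -(w %*% us)
    mag <- beams$sad / zeta
    s_iso <- (w %*% e1) * mag
    z_iso <- w[, 3] * mag
    s_lo <- floor((min(s_iso) - field_margin_mm) / bs) * bs
    s_hi <- ceiling((max(s_iso) + field_margin_mm) / bs) * bs
    z_lo <- floor((min(z_iso) - field_margin_mm) / bs) * bs
    z_hi <- ceiling((max(z_iso) + field_margin_mm) / bs) * bs
    ncol_b <- as.integer(round((s_hi - s_lo) / bs)) + 1L
    nrow_b <- as.integer(round((z_hi - z_lo) / bs)) + 1L

    tr <- .beam_dij_triplets(as.logical(external), grid$dims, grid$spacing,
                             grid$origin, as.integer(kept - 1L), iso,
                             beams$angles[b], beams$sad,
                             s_lo, bs, ncol_b, z_lo, bs, nrow_b,
                             physics$mu_cm / 10, physics$sigma_mm,
                             physics$step_mm, physics$lateral_cut_mm)
    M <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                              dims = c(length(kept), nrow_b * ncol_b))
    blocks[[b]] <- M
    tables[[b]] <- data.frame(
      beam = b, angle = beams$angles[b],
      row = rep(seq_len(nrow_b), each = ncol_b),
      col = rep(seq_len(ncol_b), times = nrow_b),
      s_mm = s_lo + (rep(seq_len(ncol_b), times = nrow_b) - 1) * bs,
      z_mm = z_lo + (rep(seq_len(nrow_b), each = ncol_b) - 1) * bs)
  }
  D <- do.call(cbind, blocks)
  beamlets <- do.call(rbind, tables)

  # per-column relative sparsity cutoff
  if (physics$column_cutoff > 0) {
    cmax <- apply_col_max(D)
    D <- Matrix::drop0(drop_small_cols(D, physics$column_cutoff * cmax))
  }
  # calibrate: unit uniform fluence -> calibration_gy at the isocenter voxel
  iso_idx <- round((iso - grid$origin) / grid$spacing) + 1
  iso_lin <- (iso_idx[3] - 1) * prod(grid$dims[1:2]) +
    (iso_idx[2] - 1) * grid$dims[1] + iso_idx[1]
  row_at_iso <- match(iso_lin, kept)
  raw <- if (!is.na(row_at_iso)) sum(D[row_at_iso, ]) else 0
  cal <- if (raw > 0) physics$calibration_gy / raw else 1
  D <- D * cal

  beamlets$hits_body <- Matrix::colSums(D) > 0
  structure(list(D = D, kept = kept, beamlets = beamlets, grid = grid,
                 beams = beams, physics = physics, calibration = cal),
            class = "dose_influence")
}

#' @export
print.dose_influence <- function(x, ...) {
  cat("dose_influence:", nrow(x$D), "voxels x", ncol(x$D), "beamlets,",
      length(x$D@x), "nonzeros\n")
  invisible(x)
}

apply_col_max <- function(D) {
  cm <- numeric(ncol(D))
  dp <- diff(D@p)
  nz <- dp > 0
  cm[nz] <- vapply(which(nz), function(j)
    max(D@x[(D@p[j] + 1):D@p[j + 1]]), numeric(1))
  cm
}

drop_small_cols <- function(D, thresh) {
  # zero out entries below their column threshold
  j <- rep(seq_len(ncol(D)), diff(D@p))
  D@x[D@x < thresh[j]] <- 0
  D
}

#' Map a fluence vector to a dose grid
#'
#' The linear dose operator `d = D x`: nonnegative beamlet weights in,
#' a 3D dose array (Gy) out, zero outside the body.
#'
#' @param dij a [compute_dij()] result.
#' @param x nonnegative fluence weights, one per beamlet.
#' @return numeric 3D array on `dij$grid`.
#' @export
dose_from_fluence <- function(dij, x) {
  if (length(x) != ncol(dij$D))
    stop("fluence length does not match the number of beamlets")
  if (any(x < 0)) stop("fluence weights must be nonnegative")
  d <- array(0, dim = dij$grid$dims)
  d[dij$kept] <- as.numeric(dij$D %*% x)
  d
}

# ---- sparse on-disk container ---------------------------------------------

#' Write / read a dose-influence matrix
#'
#' MatrixMarket for the sparse matrix, CSV for the beamlet and voxel
#' index tables, JSON header for grid/beam/physics metadata.
#'
#' @param dij a [compute_dij()] result; `dir` a directory.
#' @return `load_dij()` returns a `dose_influence`.
#' @export
save_dij <- function(dij, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(dij$D, file.path(dir, "dij.mtx"))
  utils::write.csv(dij$beamlets, file.path(dir, "beamlets.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(kept = dij$kept),
                   file.path(dir, "voxels.csv"), row.names = FALSE)
  hdr <- list(grid = list(dims = dij$grid$dims, spacing = dij$grid$spacing,
                          origin = dij$grid$origin),
              beams = unclass(dij$beams),
              physics = unclass(dij$physics),
              calibration = dij$calibration)
  jsonlite::write_json(hdr, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_dij
#' @param dir directory written by `save_dij()`.
#' @export
load_dij <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "header.json"),
                             simplifyVector = TRUE)
  D <- methods::as(Matrix::readMM(file.path(dir, "dij.mtx")), "CsparseMatrix")
  structure(list(
    D = D,
    kept = utils::read.csv(file.path(dir, "voxels.csv"))$kept,
    beamlets = utils::read.csv(file.path(dir, "beamlets.csv")),
    grid = voxel_grid(hdr$grid$dims, hdr$grid$spacing, hdr$grid$origin),
    beams = make_beams(length(hdr$beams$angles), hdr$beams$isocenter,
                       hdr$beams$beamlet_size, hdr$beams$sad),
    physics = do.call(physics_params, hdr$physics[
      c("mu_cm", "sigma_mm", "step_mm", "lateral_cut_mm",
        "calibration_gy", "column_cutoff")]),
    calibration = hdr$calibration), class = "dose_influence")
}
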