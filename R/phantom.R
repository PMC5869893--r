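#' Synthetic pelvis phantom specification
#'
#' Parametric stand-in for a planning CT with contours of a whole-pelvis
#' prostate case.  The geometry emulates the anatomy that makes
#' whole-pelvis planning hard: a concave nodal target (horseshoe of
#' pelvic lymph nodes opening anteriorly around bladder and bowel), a
#' boost target (prostate) abutting rectum and bladder, lateral femoral
#' heads, and an elliptical body contour cropped by the scan extent in
#' the cranio-caudal direction.
#'
#' All lengths in mm.  A seeded uniform jitter (`+/- jitter_mm` on organ
#' centers, `+/- jitter_mm / 3` on radii) perturbs the nominal anatomy so
#' that cohorts of distinct but anatomically plausible cases can be
#' generated; the same spec and seed always reproduce the same phantom.
#'
#' @param body_semiaxes semi-axes (x, y) of the elliptic body cylinder.
#' @param prostate,bladder lists with `center` (3) and `radius` (spheres).
#' @param rectum list with `center_xy` (2), `radius`, `z_range` (2): a
#'   tube running cranio-caudally, posterior to and abutting the prostate.
#' @param bowel list with `center` (3) and `semiaxes` (3): the bowel bag,
#'   clipped cranially to `bowel_cranial_margin_mm` above the nodal target.
#' @param femoral_left,femoral_right lists with `center` and `radius`.
#' @param nodes nodal-target wrap parameters: `center_xy`, `arc_radius`,
#'   `half_width` (radial half-thickness), `opening_half_angle_deg`
#'   (anterior gap half-angle), `z_range`.
#' @param rectal_sparing_mm gap carved between rectum and the nodal
#'   horseshoe (mesorectal corridor).
#' @param ptv_margin_mm CTV-to-PTV setup margin (5 mm, daily image
#'   guidance).
#' @param bowel_cranial_margin_mm cranial extension of the delineated
#'   bowel beyond the nodal target (2 cm).
#' @param jitter_mm anatomy jitter amplitude; must stay below the
#'   smallest organ radius.
#' @param seed integer RNG seed for the jitter.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(body_semiaxes = c(92, 72),
                         prostate = list(center = c(0, -10, -25), radius = 20),
                         bladder = list(center = c(0, 20, 0), radius = 24),
                         rectum = list(center_xy = c(0, -42), radius = 12,
                                       z_range = c(-60, 10)),
                         bowel = list(center = c(0, 12, 30),
                                      semiaxes = c(50, 38, 40)),
                         femoral_left = list(center = c(-64, -12, -32),
                                             radius = 18),
                         femoral_right = list(center = c(64, -12, -32),
                                              radius = 18),
                         nodes = list(center_xy = c(0, 2), arc_radius = 46,
                                      half_width = 13,
                                      opening_half_angle_deg = 55,
                                      z_range = c(-5, 35)),
                         rectal_sparing_mm = 2,
                         ptv_margin_mm = 5,
                         bowel_cranial_margin_mm = 20,
                         jitter_mm = 3,
                         seed = 42L) {
  spec <- list(body_semiaxes = body_semiaxes, prostate = prostate,
               bladder = bladder, rectum = rectum, bowel = bowel,
               femoral_left = femoral_left, femoral_right = femoral_right,
               nodes = nodes, rectal_sparing_mm = rectal_sparing_mm,
               ptv_margin_mm = ptv_margin_mm,
               bowel_cranial_margin_mm = bowel_cranial_margin_mm,
               jitter_mm = jitter_mm, seed = as.integer(seed))
  radii <- c(prostate$radius, bladder$radius, rectum$radius,
             femoral_left$radius, femoral_right$radius, nodes$half_width)
  if (any(radii <= 0)) stop("all organ radii must be > 0")
  if (jitter_mm < 0 || jitter_mm >= min(radii))
    stop("`jitter_mm` must be nonnegative and below the smallest organ radius")
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec: pelvis, body", paste(x$body_semiaxes, collapse = " x "),
      "mm, jitter", x$jitter_mm, "mm, seed", x$seed, "\n")
  invisible(x)
}

#' Default planning grid for the packaged phantom
#'
#' 50 x 40 x 40 voxels at 4 mm isotropic spacing (200 x 160 x 160 mm),
#' centered on the world origin — the desk-scale resolution at which the
#' packaged two-phase planning runs complete in minutes.
#' @export
default_grid <- function() voxel_grid(c(50L, 40L, 40L), 4)

# solid primitives on a grid ------------------------------------------------

ball_mask <- function(grid, center, radius) {
  ax <- grid_axes(grid)
  dx2 <- (ax$x - center[1])^2
  dy2 <- (ax$y - center[2])^2
  dz2 <- (ax$z - center[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
}

ellipsoid_mask <- function(grid, center, semiaxes) {
  ax <- grid_axes(grid)
  dx2 <- ((ax$x - center[1]) / semiaxes[1])^2
  dy2 <- ((ax$y - center[2]) / semiaxes[2])^2
  dz2 <- ((ax$z - center[3]) / semiaxes[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

tube_mask <- function(grid, center_xy, radius, z_range) {
  ax <- grid_axes(grid)
  dx2 <- (ax$x - center_xy[1])^2
  dy2 <- (ax$y - center_xy[2])^2
  inplane <- outer(dx2, dy2, `+`) <= radius^2
  zin <- ax$z >= z_range[1] & ax$z <= z_range[2]
  outer(inplane, zin, `&`)
}

horseshoe_mask <- function(grid, center_xy, arc_radius, half_width,
                           opening_half_angle_deg, z_range) {
  ax <- grid_axes(grid)
  dx <- ax$x - center_xy[1]
  dy <- ax$y - center_xy[2]
  r <- sqrt(outer(dx^2, dy^2, `+`))
  # angle from the anterior (+y) direction; the gap opens anteriorly
  phi <- abs(outer(dx, dy, function(a, b) atan2(a, b))) * 180 / pi
  inplane <- r >= arc_radius - half_width & r <= arc_radius + half_width &
    phi >= opening_half_angle_deg
  zin <- ax$z >= z_range[1] & ax$z <= z_range[2]
  outer(inplane, zin, `&`)
}

# ---------------------------------------------------------------------------

#' Structure set
#'
#' Named binary masks on a common grid.  The whole-pelvis problem
#' requires `external`, `CTV-P`, `CTV-LN`, `PTV-P`, `PTV-LN`, `rectum`,
#' `bladder`, `bowel_bag`, `femoral_head_left`, `femoral_head_right`.
#'
#' @param grid a [voxel_grid()].
#' @param masks named list of logical arrays on `grid`.
#' @param check validate required names, non-emptiness and nesting
#'   (`CTV-P` within `CTV-LN`, `PTV-P` within `PTV-LN`, everything
#'   within `external`).
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(grid, masks, check = TRUE) {
  stopifnot(inherits(grid, "voxel_grid"), is.list(masks),
            !is.null(names(masks)))
  masks <- lapply(masks, as_mask, grid = grid)
  ss <- structure(list(grid = grid, masks = masks), class = "structure_set")
  if (check) validate_structure_set(ss)
  ss
}

#' @export
print.structure_set <- function(x, ...) {
  cat("structure_set on", format(x$grid), "\n")
  n <- vapply(x$masks, sum, numeric(1))
  vol <- n * voxel_volume_ml(x$grid)
  for (i in seq_along(n))
    cat(sprintf("  %-22s %6d voxels %8.1f ml\n", names(n)[i], n[i], vol[i]))
  invisible(x)
}

#' Required structure names for whole-pelvis planning
#' @export
required_structures <- function()
  c("external", "CTV-P", "CTV-LN", "PTV-P", "PTV-LN", "rectum", "bladder",
    "bowel_bag", "femoral_head_left", "femoral_head_right")

#' @keywords internal
validate_structure_set <- function(ss) {
  miss <- setdiff(required_structures(), names(ss$masks))
  if (length(miss))
    stop("structure set is missing: ", paste(miss, collapse = ", "))
  for (nm in required_structures())
    if (!any(ss$masks[[nm]])) stop("structure '", nm, "' is empty")
  ext <- ss$masks$external
  for (nm in setdiff(names(ss$masks), "external"))
    if (any(ss$masks[[nm]] & !ext))
      stop("structure '", nm, "' extends outside the body contour")
  if (any(ss$masks[["CTV-P"]] & !ss$masks[["CTV-LN"]]))
    stop("CTV-P is not contained in CTV-LN")
  if (any(ss$masks[["PTV-P"]] & !ss$masks[["PTV-LN"]]))
    stop("PTV-P is not contained in PTV-LN")
  invisible(ss)
}

#' Generate a synthetic pelvis phantom
#'
#' Builds the full whole-pelvis structure set from a [phantom_spec()]:
#' body contour, primary CTV (prostate) and secondary CTV (nodal
#' horseshoe including the prostate), their 5 mm PTV expansions, and the
#' organs at risk.  The bowel bag is delineated up to
#' `bowel_cranial_margin_mm` (2 cm) cranial of the nodal target, and
#' rectum/bladder/bowel are made disjoint from the CTVs so that
#' organ-sparing objectives act on organ tissue proper.
#'
#' @param spec a [phantom_spec()].
#' @param grid a [voxel_grid()] large enough to contain the body.
#' @return A [structure_set()].  Deterministic in `spec` (including its
#'   seed) and `grid`.
#' @examples
#' ss <- generate_phantom(phantom_spec(jitter_mm = 0), default_grid())
#' sum(ss$masks[["CTV-P"]] & !ss$masks[["CTV-LN"]])  # nesting: 0
#' @export
generate_phantom <- function(spec, grid) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(grid, "voxel_grid"))
  sp <- jitter_spec(spec)

  ax <- grid_axes(grid)
  ex2 <- outer((ax$x / sp$body_semiaxes[1])^2,
               (ax$y / sp$body_semiaxes[2])^2, `+`) <= 1
  external <- outer(ex2, rep(TRUE, grid$dims[3]), `&`)
  if (!any(external)) stop("grid does not contain the body ellipsoid")

  ctvp <- ball_mask(grid, sp$prostate$center, sp$prostate$radius)
  rectum <- tube_mask(grid, sp$rectum$center_xy, sp$rectum$radius,
                      sp$rectum$z_range)
  rectum <- rectum & !ctvp                       # abuts, never invades
  horseshoe <- horseshoe_mask(grid, sp$nodes$center_xy, sp$nodes$arc_radius,
                              sp$nodes$half_width,
                              sp$nodes$opening_half_angle_deg,
                              sp$nodes$z_range)
  rect_corridor <- expand_mask(rectum, grid, sp$rectal_sparing_mm)
  ctvln <- (horseshoe & !rect_corridor) | ctvp
  bladder <- ball_mask(grid, sp$bladder$center, sp$bladder$radius)
  bladder <- bladder & !ctvp & !rectum
  bowel <- ellipsoid_mask(grid, sp$bowel$center, sp$bowel$semiaxes)
  zmax_ln <- max(ax$z[apply(ctvln, 3, any)])
  zcut <- zmax_ln + sp$bowel_cranial_margin_mm + 1e-9
  bowel <- bowel & outer(array(TRUE, grid$dims[1:2]), ax$z <= zcut, `&`)
  # bowel loops abut the nodal PTV but stay clear of the boost region,
  # where bladder and seminal vesicles occupy the space
  bowel <- bowel & !expand_mask(ctvln, grid, sp$ptv_margin_mm) &
    !expand_mask(ctvp, grid, 3 * sp$ptv_margin_mm) & !bladder
  fem_l <- ball_mask(grid, sp$femoral_left$center, sp$femoral_left$radius)
  fem_r <- ball_mask(grid, sp$femoral_right$center, sp$femoral_right$radius)

  organs <- list(`CTV-P` = ctvp, rectum = rectum, bladder = bladder,
                 bowel_bag = bowel, femoral_head_left = fem_l,
                 femoral_head_right = fem_r, `CTV-LN` = ctvln)
  for (nm in names(organs))
    if (any(organs[[nm]] & !external))
      stop("organ '", nm, "' is placed outside the body contour")

  ptvp <- expand_mask(ctvp, grid, sp$ptv_margin_mm) & external
  ptvln <- expand_mask(ctvln, grid, sp$ptv_margin_mm) & external

  structure_set(grid, list(
    external = external, `CTV-P` = ctvp, `CTV-LN` = ctvln,
    `PTV-P` = ptvp, `PTV-LN` = ptvln, rectum = rectum, bladder = bladder,
    bowel_bag = bowel, femoral_head_left = fem_l,
    femoral_head_right = fem_r))
}

# seeded uniform perturbation of centers (+/- jitter) and radii (+/- jitter/3)
jitter_spec <- function(spec) {
  if (spec$jitter_mm == 0) return(spec)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  a <- spec$jitter_mm
  jc <- function(v) v + stats::runif(length(v), -a, a)
  jr <- function(v) v + stats::runif(length(v), -a / 3, a / 3)
  sp <- spec
  for (nm in c("prostate", "bladder", "femoral_left", "femoral_right")) {
    sp[[nm]]$center <- jc(sp[[nm]]$center)
    sp[[nm]]$radius <- jr(sp[[nm]]$radius)
  }
  sp$rectum$center_xy <- jc(sp$rectum$center_xy)
  sp$rectum$radius <- jr(sp$rectum$radius)
  sp$bowel$center <- jc(sp$bowel$center)
  sp$nodes$center_xy <- jc(sp$nodes$center_xy)
  sp$nodes$z_range <- jc(sp$nodes$z_range)
  sp
}

# ---- (de)serialization -----------------------------------------------------

#' Read/write a phantom spec as YAML
#' @param spec a [phantom_spec()]; `path` a file path.
#' @return `load_phantom_spec` returns a [phantom_spec()].
#' @export
save_phantom_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname save_phantom_spec
#' @param path file path.
#' @export
load_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(phantom_spec, x)
}

#' Write a structure set as NIfTI masks plus a JSON manifest
#'
#' One `.nii.gz` per structure and a `structures.json` sidecar listing
#' names, files, grid geometry and voxel counts.
#'
#' @param ss a [structure_set()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
save_structure_set <- function(ss, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(ss$masks)) {
    f <- paste0(gsub("[^A-Za-z0-9_]+", "_", nm), ".nii.gz")
    write_nifti_grid(ss$masks[[nm]] * 1, ss$grid, file.path(dir, f))
    files[nm] <- f
  }
  manifest <- list(
    grid = list(dims = ss$grid$dims, spacing = ss$grid$spacing,
                origin = ss$grid$origin),
    structures = lapply(names(files), function(nm)
      list(name = nm, file = files[[nm]],
           voxels = sum(ss$masks[[nm]]))))
  mpath <- file.path(dir, "structures.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' @rdname save_structure_set
#' @export
load_structure_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "structures.json"),
                                  simplifyVector = TRUE)
  grid <- voxel_grid(manifest$grid$dims, manifest$grid$spacing,
                     manifest$grid$origin)
  masks <- list()
  for (i in seq_len(nrow(manifest$structures))) {
    nm <- manifest$structures$name[i]
    arr <- read_nifti_grid(file.path(dir, manifest$structures$file[i]))$array
    masks[[nm]] <- array(arr > 0.5, dim = grid$dims)
  }
  structure_set(grid, masks, check = FALSE)
}
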