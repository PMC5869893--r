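# Shared small fixtures, built in code at test time.

small_grid <- function(n = c(20L, 20L, 16L), spacing = 4)
  wishplan::voxel_grid(n, spacing)

# large enough to hold the default pelvis at coarse resolution
phantom_grid <- function() wishplan::voxel_grid(c(34L, 28L, 24L), 6)

fine_grid <- function(n = c(15L, 15L, 15L))
  wishplan::voxel_grid(n, 1)

# small but complete pelvis phantom used where a full structure set is
# needed quickly (coarse 8 mm grid keeps it light)
tiny_phantom <- function() {
  g <- wishplan::voxel_grid(c(26L, 22L, 20L), 8)
  ss <- wishplan::generate_phantom(wishplan::phantom_spec(jitter_mm = 0), g)
  list(grid = g, ss = ss)
}

# a hand-made dose-influence object: dense matrix on explicit voxels
toy_dij <- function(D, grid = NULL, kept = NULL) {
  D <- Matrix::Matrix(D, sparse = TRUE)
  if (is.null(grid))
    grid <- wishplan::voxel_grid(c(nrow(D), 1L, 1L), 1)
  if (is.null(kept)) kept <- seq_len(nrow(D))
  structure(list(D = methods::as(D, "CsparseMatrix"), kept = kept,
                 beamlets = data.frame(beam = 1, row = 1,
                                       col = seq_len(ncol(D))),
                 grid = grid,
                 beams = wishplan::make_beams(1, c(0, 0, 0)),
                 physics = wishplan::physics_params(), calibration = 1),
            class = "dose_influence")
}

# a resolved problem assembled by hand on a toy dij
toy_problem <- function(grid, constraints = list(), objectives = list()) {
  structure(list(name = "toy", context = wishplan::prescription_context(),
                 grid = grid, masks = list(),
                 constraints = constraints, objectives = objectives),
            class = "resolved_problem")
}

toy_constraint <- function(idx, type, limit)
  list(structure = "s", type = type, limit_gy = limit, idx = idx,
       label = sprintf("s %s <= %g", type, limit))

toy_objective <- function(idx, priority, kind, goal, D_p = NULL,
                          alpha = NULL, k = NULL)
  list(priority = as.integer(priority), structure = "s",
       cost = wishplan::cost_spec(kind, D_p = D_p, alpha = alpha, k = k),
       goal = goal, idx = idx,
       label = sprintf("p%d %s", priority, kind))
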