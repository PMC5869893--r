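# Independent brute-force oracles used across the suite.  These are
# deliberately naive implementations (exhaustive enumeration, dense
# algebra, sorted arrays) kept separate from the package's optimized
# code paths.

# exhaustive Euclidean distance from every voxel center to a mask
brute_distance <- function(mask, grid) {
  xyz <- wishplan::grid_coords(grid)
  src <- xyz[as.vector(mask), , drop = FALSE]
  out <- array(Inf, dim = grid$dims)
  if (nrow(src) == 0) return(out)
  for (i in seq_len(prod(grid$dims))) {
    dif <- sweep(src, 2, xyz[i, ])
    out[i] <- sqrt(min(rowSums(dif^2)))
  }
  out
}

# sorted-array dose quantile: minimum dose to the hottest q% with linear
# interpolation between descending order statistics
brute_d_at_volume <- function(d, q) {
  s <- sort(d, decreasing = TRUE)
  n <- length(s)
  h <- 1 + (q / 100) * (n - 1)
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

brute_v_at_dose <- function(d, x) 100 * sum(d >= x) / length(d)

# exhaustive gamma on the voxel lattice (search over the whole grid)
brute_gamma <- function(ref, eval, grid, dose_pct = 3, dist_mm = 3,
                        cutoff_pct = 10) {
  xyz <- wishplan::grid_coords(grid)
  cutoff <- cutoff_pct / 100 * max(ref)
  out <- array(NA_real_, dim = grid$dims)
  rv <- as.vector(ref); ev <- as.vector(eval)
  for (i in which(rv >= cutoff)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    dd <- (ev - rv[i]) / (dose_pct / 100 * rv[i])
    out[i] <- sqrt(min(d2 / dist_mm^2 + dd^2))
  }
  out
}

# all candidate dose vectors on a regular fluence grid (vectorized)
grid_doses <- function(D, xmax = 1, step = 0.01) {
  X <- as.matrix(expand.grid(rep(list(seq(0, xmax, by = step)), ncol(D))))
  list(X = X, Dd = X %*% t(as.matrix(D)))
}

# exhaustive lexicographic search over a fluence grid.  Objectives are
# evaluated in priority order; at each level only candidates within
# `band` of the level's minimum survive.
brute_lexi <- function(D, cons, objfuns, xmax = 1, step = 0.01,
                       band = 1e-9) {
  n <- ncol(D)
  axes <- rep(list(seq(0, xmax, by = step)), n)
  X <- as.matrix(expand.grid(axes))
  Dd <- X %*% t(as.matrix(D))   # candidate doses: candidates x voxels
  ok <- rep(TRUE, nrow(X))
  for (cn in cons) {
    v <- apply(Dd[, cn$rows, drop = FALSE], 1, cn$fun)
    ok <- ok & v <= cn$limit + 1e-9
  }
  stopifnot(any(ok))
  keep <- which(ok)
  vals <- numeric(0)
  for (f in objfuns) {
    v <- apply(Dd[keep, , drop = FALSE], 1, f)
    m <- min(v)
    vals <- c(vals, m)
    keep <- keep[v <= m + band + 1e-12]
  }
  list(values = vals, x = X[keep[1], ])
}

# convenience: random strictly positive dose vectors
rand_doses <- function(n, lo = 0, hi = 70) stats::runif(n, lo, hi)
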