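# Toy problems small enough for exhaustive fluence-space search.

toy_settings <- function(...)
  solver_settings(inner_maxit = 400, outer_maxit = 25, factr = 1e7,
                  tol_gy = 0.01, ...)

test_that("a single-voxel LTCP problem drives the dose to its hard cap", {
  # dose = 10 * x on one voxel, LTCP strictly decreasing in dose, hard
  # MAX <= 63: the optimum is exactly 63 Gy (constraint active)
  dij <- toy_dij(matrix(10, 1, 1))
  prob <- toy_problem(dij$grid,
                      constraints = list(toy_constraint(1, "MAX", 63)),
                      objectives = list(toy_objective(1, 1, "LTCP",
                                                      goal = 0.65,
                                                      D_p = 60,
                                                      alpha = 0.7)))
  plan <- solve_prioritized(dij, prob, toy_settings())
  expect_equal(plan$dose[1, 1, 1], 63, tolerance = 0.02)
  expect_true(plan$trace$goal_met[1])    # exp(-2.1) = 0.12 beats the goal
  expect_equal(plan$trace$final[1], exp(-0.7 * 3), tolerance = 1e-3)
})

test_that("objectives on decoupled structures reach their independent minima", {
  # two beamlets, two voxels, diagonal coupling only; the max cap keeps
  # the coverage stage bounded
  D <- diag(c(5, 5))
  dij <- toy_dij(D)
  prob <- toy_problem(dij$grid,
    constraints = list(toy_constraint(1:2, "MAX", 45)),
    objectives = list(
      toy_objective(1, 1, "LTCP", goal = 0.5, D_p = 20, alpha = 0.5),
      toy_objective(2, 2, "MEAN", goal = 1)))
  plan <- solve_prioritized(dij, prob, toy_settings())
  # the OAR voxel is driven to (essentially) zero regardless of priority
  expect_lt(plan$dose[2, 1, 1], 0.05)
  # the target reaches its goal: LTCP 0.5 at d = 20 + log(2)/0.5
  expect_lte(plan$trace$attained_pass_a[1], 0.5 + 1e-3)
  # reversing priorities changes nothing (separable problem)
  prob2 <- prob
  prob2$objectives <- list(
    toy_objective(2, 1, "MEAN", goal = 1),
    toy_objective(1, 2, "LTCP", goal = 0.5, D_p = 20, alpha = 0.5))
  prob2$objectives <- prob2$objectives[c(2, 1)]
  prob2$objectives[[1]]$priority <- 1L
  prob2$objectives[[2]]$priority <- 2L
  plan2 <- solve_prioritized(dij, prob2, toy_settings())
  expect_equal(plan$dose[1, 1, 1], plan2$dose[1, 1, 1], tolerance = 0.05)
  expect_lt(plan2$dose[2, 1, 1], 0.05)
})

test_that("a 2x3 toy problem matches the exhaustive lexicographic oracle", {
  D <- matrix(c(30, 20,  5,
                 5, 25, 28), nrow = 3)
  dij <- toy_dij(D)
  prob <- toy_problem(dij$grid,
    constraints = list(toy_constraint(1:3, "MAX", 40)),
    objectives = list(
      toy_objective(1:2, 1, "LTCP", goal = 1e-9, D_p = 30, alpha = 0.25),
      toy_objective(3, 2, "MEAN", goal = 1e-9)))
  plan <- solve_prioritized(dij, prob, toy_settings())
  gd <- grid_doses(D, xmax = 2, step = 0.01)
  feas <- gd$Dd[, 1] <= 40 & gd$Dd[, 2] <= 40 & gd$Dd[, 3] <= 40
  f1c <- rowMeans(exp(-0.25 * (gd$Dd[, 1:2] - 30)))
  f2c <- gd$Dd[, 3]
  expect_equal(plan$trace$final[1], min(f1c[feas]), tolerance = 0.05)
  # no grid point at least as good on coverage beats the organ result
  pool <- feas & f1c <= plan$trace$final[1] * 1.02
  if (any(pool))
    expect_lte(plan$trace$final[2], min(f2c[pool]) + 0.5)
})

test_that("randomized toy instances stay lexicographically within tolerance of grid search", {
  set.seed(31)
  n_cases <- 12
  for (case in seq_len(n_cases)) {
    nb <- sample(2:3, 1)
    nv <- sample(3:6, 1)
    D <- matrix(runif(nv * nb, 0, 30), nrow = nv)
    tgt <- sort(sample(nv, 2))
    oar <- setdiff(seq_len(nv), tgt)[1]
    cap <- 45
    dij <- toy_dij(D)
    # unattainable goals: wishlist semantics reduce to strict
    # lexicographic minimization, matching the oracle
    prob <- toy_problem(dij$grid,
      constraints = list(toy_constraint(seq_len(nv), "MAX", cap)),
      objectives = list(
        toy_objective(tgt, 1, "LTCP", goal = 1e-9, D_p = 25, alpha = 0.3),
        toy_objective(oar, 2, "MEAN", goal = 1e-9)))
    plan <- solve_prioritized(dij, prob, toy_settings())
    step <- if (nb == 3) 0.02 else 0.01
    gd <- grid_doses(D, xmax = 2.5, step = step)
    feas <- do.call(pmax, asplit(gd$Dd, 2)) <= cap
    f1c <- rowMeans(exp(-0.3 * (gd$Dd[, tgt] - 25)))
    f2c <- gd$Dd[, oar]
    # level 1: at least as good as the grid optimum up to resolution
    expect_lte(plan$trace$final[1], min(f1c[feas]) * 1.05 + 1e-4)
    # level 2: no grid candidate that matches the plan's coverage level
    # does meaningfully better on the organ
    pool <- feas & f1c <= plan$trace$final[1] + 1e-9
    if (any(pool))
      expect_lte(plan$trace$final[2], min(f2c[pool]) + 0.5)
  }
})

test_that("a met goal leaves headroom for lower priorities", {
  # coupled 2 beamlets x 2 voxels: voxel 1 is the target, voxel 2 the
  # organ; sparing the organ costs coverage, so the goal semantics are
  # visible: coverage is held at its goal instead of its optimum, and
  # the organ profits
  D <- matrix(c(20, 8,
                 6, 15), nrow = 2, byrow = TRUE)
  dij <- toy_dij(D)
  prob <- toy_problem(dij$grid,
    constraints = list(toy_constraint(1:2, "MAX", 45)),
    objectives = list(
      toy_objective(1, 1, "LTCP", goal = 0.5, D_p = 25, alpha = 0.3),
      toy_objective(2, 2, "MEAN", goal = 1e-9)))
  plan <- solve_prioritized(dij, prob, toy_settings())
  expect_true(plan$trace$goal_met[1])
  # the final plan respects the goal bound
  expect_lte(plan$trace$final[1], 0.5 * 1.01)
  # goal-aware oracle: best organ mean among fluences with LTCP <= goal
  X <- as.matrix(expand.grid(seq(0, 2.5, 0.01), seq(0, 2.5, 0.01)))
  Dd <- X %*% t(D)
  ok <- Dd[, 1] <= 45 & Dd[, 2] <= 45 &
    exp(-0.3 * (Dd[, 1] - 25)) <= 0.5
  best_f2 <- min(Dd[ok, 2])
  # the delta relaxation lets pass B trade up to 3% of the organ bound
  expect_lte(plan$trace$final[2], best_f2 * 1.04 + 0.1)
  # strictly better for the organ than full lexicographic minimization
  strict <- brute_lexi(
    D, cons = list(list(rows = 1:2, fun = max, limit = 45)),
    objfuns = list(function(d) ltcp(d[1], 25, 0.3),
                   function(d) mean(d[2])),
    xmax = 2.5, step = 0.01, band = 5e-3)
  expect_lt(plan$trace$final[2], strict$values[2])
})

test_that("infeasible hard constraints are reported by name", {
  # one beamlet feeding two voxels equally: requiring mean >= coverage
  # via a GE sense constraint against a tiny MAX cap is contradictory
  D <- matrix(c(10, 10), nrow = 2)
  dij <- toy_dij(D)
  rep <- feasibility_check(dij, list(
    list(structure = "s", type = "MEAN", limit_gy = 30, idx = 1:2,
         sense = "ge", label = "s MEAN >= 30"),
    list(structure = "s", type = "MAX", limit_gy = 10, idx = 1:2,
         label = "s MAX <= 10")))
  expect_true(any(!rep$feasible))
  expect_true(any(rep$violation_gy > 1))
  # empty constraint set is trivially feasible
  rep0 <- feasibility_check(dij, list())
  expect_equal(nrow(rep0), 0)
})

test_that("hard constraints hold at the returned plan of every toy solve", {
  set.seed(32)
  for (case in 1:5) {
    D <- matrix(runif(6, 0, 20), nrow = 3)
    dij <- toy_dij(D)
    prob <- toy_problem(dij$grid,
      constraints = list(toy_constraint(1:3, "MAX", 35),
                         toy_constraint(1:2, "MEAN", 30)),
      objectives = list(
        toy_objective(1:2, 1, "LTCP", goal = 0.5, D_p = 28, alpha = 0.4),
        toy_objective(3, 2, "MEAN", goal = 0.5)))
    plan <- solve_prioritized(dij, prob, toy_settings())
    expect_true(all(plan$constraint_slacks$slack_gy > -0.05))
    expect_true(all(plan$fluence >= 0))
  }
})

test_that("appending a lowest-priority objective protects existing bounds", {
  D <- matrix(c(12, 3,
                 4, 9,
                 2, 2), nrow = 3, byrow = TRUE)
  dij <- toy_dij(D)
  base_obj <- list(
    toy_objective(1, 1, "LTCP", goal = 0.5, D_p = 20, alpha = 0.4),
    toy_objective(2, 2, "MEAN", goal = 1))
  prob1 <- toy_problem(dij$grid,
                       constraints = list(toy_constraint(1:3, "MAX", 35)),
                       objectives = base_obj)
  prob2 <- prob1
  prob2$objectives <- c(base_obj, list(toy_objective(3, 3, "MEAN",
                                                     goal = 0.1)))
  s <- toy_settings(pass_b = FALSE, tie_break = FALSE)
  p1 <- solve_prioritized(dij, prob1, s)
  p2 <- solve_prioritized(dij, prob2, s)
  expect_equal(p1$trace$bound[1:2], p2$trace$bound[1:2], tolerance = 0.02)
})

test_that("the solver trace is deterministic for fixed inputs", {
  D <- matrix(c(8, 2, 3, 7, 5, 5), nrow = 3)
  dij <- toy_dij(D)
  prob <- toy_problem(dij$grid,
    constraints = list(toy_constraint(1:3, "MAX", 30)),
    objectives = list(
      toy_objective(1:2, 1, "LTCP", goal = 0.5, D_p = 22, alpha = 0.4),
      toy_objective(3, 2, "MEAN", goal = 0.5)))
  a <- solve_prioritized(dij, prob, toy_settings())
  b <- solve_prioritized(dij, prob, toy_settings())
  expect_identical(a$trace, b$trace)
  expect_identical(a$fluence, b$fluence)
})

test_that("lexicographic bounds are consistent under truncation", {
  # deleting all priorities below p reproduces the bound recorded at p
  D <- matrix(c(10, 2, 3, 8, 4, 6), nrow = 3)
  dij <- toy_dij(D)
  objs <- list(
    toy_objective(1:2, 1, "LTCP", goal = 0.4, D_p = 24, alpha = 0.35),
    toy_objective(3, 2, "EUD", goal = 1, k = 4))
  prob_full <- toy_problem(dij$grid,
                           constraints = list(toy_constraint(1:3, "MAX", 33)),
                           objectives = objs)
  prob_trunc <- prob_full
  prob_trunc$objectives <- objs[1]
  s <- toy_settings(pass_b = FALSE, tie_break = FALSE)
  full <- solve_prioritized(dij, prob_full, s)
  trunc <- solve_prioritized(dij, prob_trunc, s)
  expect_equal(full$trace$attained_pass_a[1],
               trunc$trace$attained_pass_a[1], tolerance = 0.01)
})

test_that("joint same-priority mode solves the slot as one subproblem", {
  D <- matrix(c(6, 1, 2, 5, 3, 3), nrow = 3)
  dij <- toy_dij(D)
  prob <- toy_problem(dij$grid,
    constraints = list(toy_constraint(1:3, "MAX", 30)),
    objectives = list(
      toy_objective(1, 1, "LTCP", goal = 0.5, D_p = 18, alpha = 0.5),
      toy_objective(2, 2, "MEAN", goal = 0.5),
      toy_objective(3, 2, "MEAN", goal = 0.5)))
  pj <- solve_prioritized(dij, prob, toy_settings(joint_priority = TRUE))
  ps <- solve_prioritized(dij, prob, toy_settings())
  # both modes respect the priority-1 bound and produce feasible plans
  expect_lte(abs(pj$trace$final[1] - ps$trace$final[1]), 0.05)
  expect_true(all(pj$constraint_slacks$slack_gy > -0.05))
})
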