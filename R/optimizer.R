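#' Solver settings for prioritized planning
#'
#' @param delta relaxation factor (>= 1) applied to an objective's
#'   attained value when it misses its goal: the imposed bound is
#'   `attained * delta`, leaving the solver 3% slack by default.
#' @param tol_gy absolute constraint tolerance in Gy.
#' @param tol_rel relative constraint tolerance (fraction of the limit);
#'   the effective slack allowance is `max(tol_gy, tol_rel * limit)`.
#' @param inner_maxit L-BFGS iteration cap per augmented-Lagrangian
#'   inner solve.
#' @param outer_maxit augmented-Lagrangian multiplier updates per stage.
#' @param factr L-BFGS `factr` convergence control.
#' @param pass_b run the tightening second pass (re-minimize every
#'   objective subject to the other bounds and replace its bound by the
#'   attained value), which removes most of the `delta` slack and the
#'   goal-bound headroom so the returned plan is Pareto-consistent.
#' @param tie_break finish with a minimum-norm fluence solve at the
#'   lowest priority to select deterministically among near-degenerate
#'   optima.
#' @param joint_priority optimize rows sharing a priority slot jointly
#'   as an equal-weight sum instead of sequentially in listed order
#'   (the default is sequential, which preserves the listed row order).
#' @param verbose print per-stage progress.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(delta = 1.03, tol_gy = 0.05, tol_rel = 1e-3,
                            inner_maxit = 150L, outer_maxit = 8L,
                            factr = 1e9, pass_b = TRUE, tie_break = TRUE,
                            joint_priority = FALSE, verbose = FALSE) {
  stopifnot(delta >= 1, tol_gy > 0, tol_rel > 0, inner_maxit >= 10,
            outer_maxit >= 1)
  structure(list(delta = delta, tol_gy = tol_gy, tol_rel = tol_rel,
                 inner_maxit = as.integer(inner_maxit),
                 outer_maxit = as.integer(outer_maxit), factr = factr,
                 pass_b = pass_b, tie_break = tie_break,
                 joint_priority = joint_priority, verbose = verbose),
            class = "solver_settings")
}

# ---- internal term machinery ----------------------------------------------
# A term is a cost function bound to rows of the dose-influence matrix.
# Scalar kinds (LTCP on the log scale, EUD, MEAN) yield one constraint
# residual; MAX yields one residual per voxel.  Residuals are normalized
# by `scale` for conditioning; violations are measured in natural units.

make_term <- function(kind, rows, params = list(), limit = NA_real_,
                      label = "", type = "hard") {
  internal_limit <- limit
  if (kind == "LTCP" && !is.na(limit)) internal_limit <- log(limit)
  scale <- if (kind == "LTCP") 1 else max(1, abs(internal_limit),
                                          na.rm = TRUE)
  list(kind = kind, rows = rows, params = params, limit = internal_limit,
       natural_limit = limit, scale = scale, label = label, type = type,
       pervoxel = kind == "MAX")
}

scalar_value_grad <- function(kind, d, params) {
  switch(kind,
         LTCP = log_ltcp_grad(d, params$D_p, params$alpha),
         EUD = eud_grad(d, params$k),
         MEAN = mean_grad(d),
         stop("not a scalar term kind: ", kind))
}

# natural-scale value of a term on a full dose vector
term_value <- function(term, d) {
  ds <- d[term$rows]
  switch(term$kind,
         LTCP = exp(log_ltcp_grad(ds, term$params$D_p,
                                  term$params$alpha)$value),
         EUD = eud_grad(ds, term$params$k)$value,
         MEAN = mean(ds),
         MAX = max(ds))
}

# violation of "term <= its limit" in natural units (Gy; LTCP on log scale)
term_violation <- function(term, d) {
  v <- term_value(term, d)
  if (term$kind == "LTCP") max(0, log(v) - term$limit)
  else max(0, v - term$natural_limit)
}

term_tol <- function(term, settings) {
  if (term$kind == "LTCP") return(1e-3)
  max(settings$tol_gy, settings$tol_rel * abs(term$natural_limit))
}

# Augmented-Lagrangian solve of one convex stage:
#   minimize sum_j f_j(D x)   subject to  term_i(D x) <= limit_i, x >= 0.
# `objective` is a list of terms (one for the sequential mode, several
# for the joint same-priority mode), or "l2" (minimum-norm tie-break) or
# "feas" (minimize total squared violation, used by feasibility_check).
# Each MAX objective term is lifted with an auxiliary variable t >= 0:
#   minimize t  subject to  d_S - t <= 0  (exact, per-voxel).
solve_stage <- function(D, x0, objective, cons, settings,
                        lambda_init = NULL, rho_init = 50) {
  n <- ncol(D)
  feas_only <- identical(objective, "feas")
  l2_only <- identical(objective, "l2")
  obj_terms <- if (feas_only || l2_only) list() else objective
  t_idx <- which(vapply(obj_terms, function(t) t$kind == "MAX", logical(1)))
  n_t <- length(t_idx)

  lambda <- lapply(seq_along(cons), function(ci) {
    cn <- cons[[ci]]
    len <- if (cn$pervoxel) length(cn$rows) else 1L
    li <- lambda_init[[ci]]
    if (!is.null(li) && length(li) == len) li else numeric(len)
  })
  lambda_t <- lapply(t_idx, function(i) numeric(length(obj_terms[[i]]$rows)))
  rho <- rho_init

  par0 <- pmax(x0, 0)
  if (n_t > 0) {
    d0 <- as.numeric(D %*% par0)
    par0 <- c(par0, vapply(t_idx, function(i)
      max(c(d0[obj_terms[[i]]$rows], 0)), numeric(1)))
  }

  cache <- new.env(parent = emptyenv())
  cache$par <- NULL

  eval_at <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$val)
    x <- par[seq_len(n)]
    tvars <- if (n_t > 0) par[n + seq_len(n_t)] else numeric(0)
    d <- as.numeric(D %*% x)
    u <- numeric(nrow(D))
    f <- 0
    gt <- numeric(n_t)
    gx_extra <- numeric(0)

    if (feas_only) {
      for (cn in cons) {
        if (cn$pervoxel) {
          g <- (d[cn$rows] - cn$limit) / cn$scale
          viol <- pmax(0, g)
          f <- f + sum(viol^2)
          u[cn$rows] <- u[cn$rows] + 2 * viol / cn$scale
        } else {
          vg <- scalar_value_grad(cn$kind, d[cn$rows], cn$params)
          sense <- if (is.null(cn$sense)) 1 else cn$sense
          g <- sense * (vg$value - cn$limit) / cn$scale
          if (g > 0) {
            f <- f + g^2
            u[cn$rows] <- u[cn$rows] + 2 * g * sense * vg$grad / cn$scale
          }
        }
      }
      out <- list(f = f, grad = as.numeric(Matrix::crossprod(D, u)))
      cache$par <- par; cache$val <- out
      return(out)
    }

    if (l2_only) {
      f <- mean(x^2) / 2
      gx_extra <- x / n
    } else {
      ti <- 0L
      for (j in seq_along(obj_terms)) {
        ob <- obj_terms[[j]]
        if (ob$kind == "MAX") {
          ti <- ti + 1L
          f <- f + tvars[ti] / ob$scale
          gt[ti] <- gt[ti] + 1 / ob$scale
        } else {
          vg <- scalar_value_grad(ob$kind, d[ob$rows], ob$params)
          f <- f + vg$value / ob$scale
          u[ob$rows] <- u[ob$rows] + vg$grad / ob$scale
        }
      }
    }

    # augmented Lagrangian  psi(g) = (max(0, l + rho g)^2 - l^2) / (2 rho)
    for (ci in seq_along(cons)) {
      cn <- cons[[ci]]
      if (cn$pervoxel) {
        g <- (d[cn$rows] - cn$limit) / cn$scale
        act <- pmax(0, lambda[[ci]] + rho * g)
        f <- f + sum(act^2 - lambda[[ci]]^2) / (2 * rho)
        u[cn$rows] <- u[cn$rows] + act / cn$scale
      } else {
        vg <- scalar_value_grad(cn$kind, d[cn$rows], cn$params)
        g <- (vg$value - cn$limit) / cn$scale
        act <- max(0, lambda[[ci]] + rho * g)
        f <- f + (act^2 - lambda[[ci]]^2) / (2 * rho)
        if (act > 0) u[cn$rows] <- u[cn$rows] + act * vg$grad / cn$scale
      }
    }
    # t-lift constraints d_S - t <= 0 for MAX objective terms
    for (m in seq_along(t_idx)) {
      ob <- obj_terms[[t_idx[m]]]
      g <- (d[ob$rows] - tvars[m]) / ob$scale
      act <- pmax(0, lambda_t[[m]] + rho * g)
      f <- f + sum(act^2 - lambda_t[[m]]^2) / (2 * rho)
      u[ob$rows] <- u[ob$rows] + act / ob$scale
      gt[m] <- gt[m] - sum(act) / ob$scale
    }
    gx <- as.numeric(Matrix::crossprod(D, u))
    if (length(gx_extra)) gx <- gx + gx_extra
    out <- list(f = f, grad = c(gx, gt))
    cache$par <- par; cache$val <- out
    out
  }

  fn <- function(par) eval_at(par)$f
  gr <- function(par) eval_at(par)$grad

  par <- par0
  prev_viol <- Inf
  f_prev <- Inf
  opt <- NULL
  for (it in seq_len(settings$outer_maxit)) {
    cache$par <- NULL
    opt <- stats::optim(par, fn, gr, method = "L-BFGS-B", lower = 0,
                        control = list(maxit = settings$inner_maxit,
                                       factr = settings$factr, lmm = 10))
    par <- opt$par
    if (feas_only) break
    x <- par[seq_len(n)]
    d <- as.numeric(D %*% x)
    viols <- vapply(cons, term_violation, numeric(1), d = d)
    tols <- vapply(cons, term_tol, numeric(1), settings = settings)
    for (m in seq_along(t_idx)) {
      ob <- obj_terms[[t_idx[m]]]
      viols <- c(viols, max(0, max(d[ob$rows]) - par[n + m]))
      tols <- c(tols, settings$tol_gy)
    }
    feasible <- length(viols) == 0L || all(viols <= tols)
    # stop only when feasible AND the inner solver has genuinely
    # converged (or the augmented objective has stalled): an inner solve
    # truncated at maxit gets further outer rounds to keep descending
    stalled <- abs(opt$value - f_prev) <= 1e-7 * max(1, abs(opt$value))
    f_prev <- opt$value
    if (feasible && (opt$convergence == 0L || stalled)) break
    # multiplier update, sharpen the penalty if progress stalls
    for (ci in seq_along(cons)) {
      cn <- cons[[ci]]
      if (cn$pervoxel) {
        g <- (d[cn$rows] - cn$limit) / cn$scale
        lambda[[ci]] <- pmax(0, lambda[[ci]] + rho * g)
      } else {
        v <- scalar_value_grad(cn$kind, d[cn$rows], cn$params)$value
        lambda[[ci]] <- max(0, lambda[[ci]] + rho * (v - cn$limit) / cn$scale)
      }
    }
    for (m in seq_along(t_idx)) {
      ob <- obj_terms[[t_idx[m]]]
      g <- (d[ob$rows] - par[n + m]) / ob$scale
      lambda_t[[m]] <- pmax(0, lambda_t[[m]] + rho * g)
    }
    mv <- max(viols)
    if (mv > 0.25 * prev_viol) rho <- min(rho * 5, 1e7)
    prev_viol <- mv
  }
  x <- par[seq_len(n)]
  d <- as.numeric(D %*% x)
  list(x = x, d = d,
       violations = if (length(cons))
         vapply(cons, term_violation, numeric(1), d = d) else numeric(0),
       lambda = lambda, rho = rho,
       converged = is.null(opt) || opt$convergence %in% c(0L, 1L))
}

# ---------------------------------------------------------------------------

problem_terms <- function(dij, problem) {
  map_rows <- function(idx) {
    r <- match(idx, dij$kept)
    r[!is.na(r)]
  }
  hard <- lapply(problem$constraints, function(cn) {
    rows <- map_rows(cn$idx)
    if (length(rows) == 0L) return(NULL)
    make_term(cn$type, rows, limit = cn$limit_gy, label = cn$label,
              type = "hard")
  })
  hard <- Filter(Negate(is.null), hard)
  objs <- lapply(problem$objectives, function(ob) {
    rows <- map_rows(ob$idx)
    if (length(rows) == 0L) return(NULL)
    t <- make_term(ob$cost$kind, rows,
                   params = ob$cost[c("D_p", "alpha", "k")],
                   label = ob$label, type = "objective")
    t$priority <- ob$priority
    t$goal <- ob$goal
    t$structure <- ob$structure
    t
  })
  objs <- Filter(Negate(is.null), objs)
  # stable sort by priority: resolved problems arrive sorted, hand-built
  # ones may not
  objs <- objs[order(vapply(objs, `[[`, integer(1), "priority"))]
  list(hard = hard, objectives = objs)
}

bound_term <- function(obj_term, bound_natural) {
  make_term(obj_term$kind, obj_term$rows, params = obj_term$params,
            limit = bound_natural,
            label = paste0("bound: ", obj_term$label), type = "bound")
}

#' Feasibility check of a constraint set
#'
#' Minimizes the total squared constraint violation over nonnegative
#' fluence and reports the residual violation of every constraint at the
#' least-violating fluence found.  Constraints may carry a `sense`
#' (`"le"`, the default, or `"ge"`) so contradictory requirements can be
#' diagnosed.
#'
#' @param dij a [compute_dij()] result.
#' @param constraints list of constraints as in a `resolved_problem`
#'   (`structure`, `type`, `limit_gy`, `idx`, optional `sense`).
#' @param settings a [solver_settings()].
#' @return A data frame with one row per constraint: `label`,
#'   `limit_gy`, `violation_gy`, `feasible`.
#' @export
feasibility_check <- function(dij, constraints,
                              settings = solver_settings()) {
  terms <- lapply(constraints, function(cn) {
    rows <- match(cn$idx, dij$kept)
    rows <- rows[!is.na(rows)]
    t <- make_term(cn$type, rows, limit = cn$limit_gy, label = cn$label)
    t$sense <- if (!is.null(cn$sense) && cn$sense == "ge") -1 else 1
    t
  })
  terms <- Filter(function(t) length(t$rows) > 0, terms)
  if (length(terms) == 0L)
    return(data.frame(label = character(0), limit_gy = numeric(0),
                      violation_gy = numeric(0), feasible = logical(0)))
  x0 <- numeric(ncol(dij$D))
  res <- solve_stage(dij$D, x0, "feas", terms, settings)
  viol <- vapply(terms, function(t) {
    v <- term_value(t, res$d)
    if (t$sense < 0) max(0, t$natural_limit - v) else
      max(0, v - t$natural_limit)
  }, numeric(1))
  data.frame(label = vapply(terms, `[[`, character(1), "label"),
             limit_gy = vapply(terms, `[[`, numeric(1), "natural_limit"),
             violation_gy = viol,
             feasible = viol <= vapply(terms, term_tol, numeric(1),
                                       settings = settings))
}

#' Prioritized (lexicographic epsilon-constraint) plan optimization
#'
#' The two-pass prioritized solver.  Pass A walks the wishlist
#' objectives in priority order (rows sharing a priority in listed
#' order, or jointly when `joint_priority` is set): each objective is
#' minimized subject to the hard constraints and all previously imposed
#' objective bounds; if it reaches its goal the bound is set at the goal
#' (deliberately leaving headroom for lower priorities), otherwise at
#' `attained * delta`.  Pass B revisits every objective, re-minimizing
#' it subject to all other bounds and replacing its bound by the
#' attained value, so the remaining slack is consumed and the plan is
#' Pareto-consistent.  A final minimum-norm fluence solve breaks ties
#' among near-degenerate optima.
#'
#' Every stage subproblem is convex: the dose is linear in the fluence,
#' LTCP is handled on the log scale (log-sum-exp of affine), EUD with
#' `k >= 1` is a convex power mean, and max-dose terms are exact
#' per-voxel linear constraints via an auxiliary variable.  Subproblems
#' are solved with an augmented-Lagrangian method over projected
#' L-BFGS.
#'
#' @param dij a [compute_dij()] dose-influence matrix.
#' @param problem a [resolve_wishlist()] result on the same grid.
#' @param settings a [solver_settings()].
#' @return An object of class `plan_result`: `fluence`, `dose` (3D Gy
#'   array), `trace` (one row per objective: priority, structure,
#'   attained values in both passes, imposed bound, goal, `goal_met`),
#'   `constraint_slacks` (limit minus measured per hard constraint) and
#'   `diagnostics`.
#' @export
solve_prioritized <- function(dij, problem, settings = solver_settings()) {
  stopifnot(inherits(dij, "dose_influence"),
            inherits(problem, "resolved_problem"))
  stop_if_grid_mismatch(dij$grid, problem$grid)
  tm <- problem_terms(dij, problem)
  hard <- tm$hard
  objs <- tm$objectives
  if (length(objs) == 0L) stop("the resolved problem has no objectives")

  feas <- feasibility_check(dij, problem$constraints, settings)
  if (any(!feas$feasible)) {
    bad <- feas$label[!feas$feasible]
    stop("hard constraints are infeasible: ", paste(bad, collapse = "; "))
  }

  n <- ncol(dij$D)
  x <- numeric(n)
  # warm start: uniform fluence scaled to put the first target near its
  # prescription keeps the first LTCP stage well conditioned
  first <- objs[[1]]
  if (first$kind == "LTCP") {
    dunit <- as.numeric(dij$D %*% rep(1, n))
    m <- mean(dunit[first$rows])
    if (m > 0) x <- rep(first$params$D_p / m, n)
  }

  bounds <- rep(NA_real_, length(objs))   # natural-scale imposed bounds
  attained_a <- rep(NA_real_, length(objs))
  stage_viol <- numeric(0)

  run_stage <- function(x, objective, cons, keys, idx_label,
                        final = FALSE) {
    st <- settings
    if (final) st$outer_maxit <- 2L * st$outer_maxit
    t0 <- Sys.time()
    res <- solve_stage(dij$D, x, objective, cons, st)
    if (settings$verbose)
      message(sprintf("  [stage %s: %.1f s, max violation %.3g]",
                      idx_label, as.numeric(Sys.time() - t0, units = "secs"),
                      if (length(res$violations)) max(res$violations)
                      else 0))
    tols <- vapply(cons, term_tol, numeric(1), settings = settings)
    # stages may drift on near-equality constraints (the terminal
    # rescale removes residual hard-limit violations exactly), so only
    # gross divergence is fatal
    guard <- pmax(20 * tols, 1)
    if (length(res$violations) && any(res$violations > guard)) {
      worst <- which.max(res$violations / pmax(tols, 1e-12))
      stop("subproblem at stage ", idx_label, " did not converge: '",
           cons[[worst]]$label, "' violated by ",
           signif(res$violations[worst], 3))
    }
    res
  }

  hard_keys <- paste0("h", seq_along(hard))

  active_bounds <- function(exclude = integer(0)) {
    keep <- setdiff(which(!is.na(bounds)), exclude)
    terms <- lapply(keep, function(i) {
      b <- bounds[i]
      # small numeric slack so the next stage starts feasible
      bound_term(objs[[i]], if (objs[[i]]$kind == "LTCP")
        b * (1 + 1e-4) else b + 0.25 * settings$tol_gy)
    })
    list(terms = terms, keys = paste0("b", keep))
  }

  impose_bound <- function(i, att) {
    goal_met <- att <= objs[[i]]$goal
    bounds[i] <<- if (goal_met) objs[[i]]$goal else att * settings$delta
    goal_met
  }

  # stage groups: one objective per stage (sequential, default) or all
  # rows of a priority slot at once (joint)
  groups <- if (settings$joint_priority) {
    split(seq_along(objs), vapply(objs, `[[`, integer(1), "priority"))
  } else {
    as.list(seq_along(objs))
  }

  # ---- Pass A ----
  for (grp in groups) {
    ab <- active_bounds()
    res <- run_stage(x, objs[grp], c(hard, ab$terms),
                     c(hard_keys, ab$keys),
                     sprintf("A/p%d", objs[[grp[1]]]$priority))
    x <- res$x
    for (i in grp) {
      att <- term_value(objs[[i]], res$d)
      attained_a[i] <- att
      met <- impose_bound(i, att)
      if (settings$verbose)
        message(sprintf("pass A p%-2d %-44s attained %.4g%s",
                        objs[[i]]$priority, objs[[i]]$label, att,
                        if (met) " (goal met)" else ""))
    }
    stage_viol <- c(stage_viol, if (length(res$violations))
      max(res$violations) else 0)
  }

  # ---- Pass B (tighten) ----
  attained_b <- rep(NA_real_, length(objs))
  if (settings$pass_b) {
    for (grp in groups) {
      ab <- active_bounds(exclude = grp)
      res <- run_stage(x, objs[grp], c(hard, ab$terms),
                       c(hard_keys, ab$keys),
                       sprintf("B/p%d", objs[[grp[1]]]$priority))
      # accept the re-minimization only if it actually improved the
      # slot (inexact subsolves on near-equality constraint sets can
      # drift); otherwise keep the incoming fluence and bounds
      att_new <- vapply(grp, function(i) term_value(objs[[i]], res$d),
                        numeric(1))
      tol_b <- vapply(grp, function(i)
        if (objs[[i]]$kind == "LTCP") 1e-3 * bounds[i] else
          settings$tol_gy, numeric(1))
      accepted <- all(att_new <= bounds[grp] + tol_b)
      if (accepted) x <- res$x
      for (m in seq_along(grp)) {
        i <- grp[m]
        attained_b[i] <- att_new[m]
        # tighten-only: an inexact re-minimization never loosens a bound
        bounds[i] <- min(bounds[i], att_new[m])
        if (settings$verbose)
          message(sprintf("pass B p%-2d %-44s attained %.4g%s",
                          objs[[i]]$priority, objs[[i]]$label, att_new[m],
                          if (accepted) "" else " (reverted)"))
      }
    }
  }

  # ---- minimum-norm tie-break / feasibility polish ----
  # the last solve carries a doubled multiplier budget so the returned
  # plan meets every hard constraint and bound within tolerance
  if (settings$tie_break) {
    ab <- active_bounds()
    res <- run_stage(x, "l2", c(hard, ab$terms), c(hard_keys, ab$keys),
                     "tie-break", final = TRUE)
    x <- res$x
  }

  d <- as.numeric(dij$D %*% x)

  # rescue: every hard constraint is an upper limit on a quantity that is
  # positively homogeneous in the fluence, so a residual violation can
  # always be removed exactly by scaling the plan down
  rescale <- 1
  if (length(hard)) {
    over <- vapply(hard, function(h) {
      v <- term_value(h, d)
      if (h$kind == "LTCP") 1 else v / h$natural_limit
    }, numeric(1))
    tolf <- vapply(hard, function(h)
      1 + term_tol(h, settings) / max(h$natural_limit, 1e-9), numeric(1))
    if (any(over > tolf)) {
      rescale <- min(1 / over[over > tolf])
      x <- x * rescale
      d <- d * rescale
    }
  }

  dose <- array(0, dim = dij$grid$dims)
  dose[dij$kept] <- d

  slacks <- data.frame(
    structure = vapply(problem$constraints, `[[`, character(1), "structure"),
    type = vapply(problem$constraints, `[[`, character(1), "type"),
    limit_gy = vapply(problem$constraints, `[[`, numeric(1), "limit_gy"),
    measured_gy = vapply(hard, term_value, numeric(1), d = d))
  slacks$slack_gy <- slacks$limit_gy - slacks$measured_gy

  trace <- data.frame(
    priority = vapply(objs, `[[`, integer(1), "priority"),
    structure = vapply(objs, `[[`, character(1), "structure"),
    kind = vapply(objs, `[[`, character(1), "kind"),
    goal = vapply(objs, `[[`, numeric(1), "goal"),
    attained_pass_a = attained_a,
    attained_pass_b = attained_b,
    bound = bounds)
  trace$goal_met <- trace$attained_pass_a <= trace$goal
  trace$final <- vapply(objs, term_value, numeric(1), d = d)

  structure(list(fluence = x, dose = dose, trace = trace,
                 constraint_slacks = slacks,
                 diagnostics = list(stage_max_violation = stage_viol,
                                    final_rescale = rescale,
                                    settings = settings),
                 problem = problem$name),
            class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  cat("plan_result for '", x$problem, "'\n", sep = "")
  cat(" hard constraints (measured / limit Gy):\n")
  s <- x$constraint_slacks
  for (i in seq_len(nrow(s)))
    cat(sprintf("   %-28s %-4s %7.2f / %7.2f  %s\n", s$structure[i],
                s$type[i], s$measured_gy[i], s$limit_gy[i],
                if (s$slack_gy[i] >= -0.05) "ok" else "VIOLATED"))
  cat(" objective trace:\n")
  t <- x$trace
  for (i in seq_len(nrow(t)))
    cat(sprintf("   p%-2d %-24s %-4s goal %8.3g attained %8.3g%s\n",
                t$priority[i], t$structure[i], t$kind[i], t$goal[i],
                t$final[i], if (t$goal_met[i]) " (goal met)" else ""))
  invisible(x)
}

#' Write the per-priority solver trace as JSON
#'
#' @param plan a `plan_result`.
#' @param path output JSON path.
#' @export
save_plan_trace <- function(plan, path) {
  jsonlite::write_json(
    list(problem = plan$problem, trace = plan$trace,
         constraints = plan$constraint_slacks),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
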