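#' Prescription context
#'
#' The two-phase whole-pelvis prescription: phase 1 delivers
#' `D_high` = 60 Gy to the prostate PTV and `D_low` = 50 Gy to the nodal
#' PTV in 25 fractions as a simultaneous integrated boost; phase 2 is a
#' sequential boost of `D_boost` = 13 Gy to the prostate PTV in 5
#' fractions.  Wishlist limits and goals quoted as percentages resolve
#' against these reference doses (`"D_p"` refers to the boost dose in
#' the phase-2 wishlist).
#'
#' @param D_high,D_low,D_boost reference doses (Gy, > 0).
#' @param fractions integer vector: fractions in phase 1 and phase 2.
#' @return An object of class `prescription_context`.
#' @export
prescription_context <- function(D_high = 60, D_low = 50, D_boost = 13,
                                 fractions = c(25L, 5L)) {
  stopifnot(D_high > 0, D_low > 0, D_boost > 0, all(fractions >= 1))
  structure(list(D_high = D_high, D_low = D_low, D_boost = D_boost,
                 fractions = as.integer(fractions)),
            class = "prescription_context")
}

reference_dose <- function(ref, context) {
  switch(ref,
         D_high = context$D_high,
         D_low = context$D_low,
         D_p = context$D_boost,
         stop("unknown dose reference '", ref, "'"))
}

resolve_quantity <- function(q, context) {
  if (!is.null(q$gy)) return(q$gy)
  if (!is.null(q$percent)) return(q$percent / 100 * reference_dose(q$of,
                                                                   context))
  stop("a limit/goal needs either `gy` or `percent` + `of`")
}

# ---- wishlist data model ---------------------------------------------------

wishlist_fields <- c("name", "phase", "auxiliary", "constraints",
                     "objectives")

#' Load, save and validate wishlists
#'
#' A wishlist is the planning protocol driving automated plan
#' generation: an ordered list of hard constraints that must never be
#' violated, plus prioritized objectives, each with a cost function
#' (LTCP / EUD / max / mean), a goal, and the recipes for the auxiliary
#' planning structures it refers to (fall-off shells, skin ring,
#' transition region, structure unions, unspecified tissue).  Wishlists
#' are stored as YAML; [builtin_wishlist()] returns the two packaged
#' whole-pelvis protocols.
#'
#' @param path a YAML file.
#' @return A validated object of class `wishlist`.
#' @export
load_wishlist <- function(path) {
  w <- yaml::read_yaml(path)
  validate_wishlist(w, where = path)
}

#' @rdname load_wishlist
#' @param w a `wishlist`.
#' @export
save_wishlist <- function(w, path) {
  stopifnot(inherits(w, "wishlist"))
  yaml::write_yaml(unclass(w), path)
  invisible(path)
}

wl_fail <- function(where, path, msg)
  stop("wishlist validation error at ", where, "$", path, ": ", msg,
       call. = FALSE)

validate_quantity <- function(q, where, path, unitless_ok = FALSE) {
  if (is.numeric(q)) {
    if (!unitless_ok)
      wl_fail(where, path, "expected {gy: ...} or {percent: ..., of: ...}")
    if (q <= 0) wl_fail(where, path, "must be > 0")
    return(invisible(TRUE))
  }
  if (!is.list(q)) wl_fail(where, path, "expected a mapping")
  if (!is.null(q$gy)) {
    if (q$gy <= 0) wl_fail(where, path, "gy must be > 0")
  } else if (!is.null(q$percent)) {
    if (q$percent <= 0) wl_fail(where, path, "percent must be > 0")
    if (is.null(q$of) || !q$of %in% c("D_high", "D_low", "D_p"))
      wl_fail(where, path, "percent needs of: D_high|D_low|D_p")
  } else wl_fail(where, path, "needs gy or percent")
  invisible(TRUE)
}

validate_wishlist <- function(w, where = "wishlist") {
  if (!is.list(w)) wl_fail(where, "", "not a mapping")
  for (f in c("name", "constraints", "objectives"))
    if (is.null(w[[f]])) wl_fail(where, f, "missing")
  for (i in seq_along(w$auxiliary)) {
    a <- w$auxiliary[[i]]
    p <- sprintf("auxiliary[%d]", i)
    if (is.null(a$name)) wl_fail(where, p, "missing name")
    if (is.null(a$recipe) ||
        !a$recipe %in% c("union", "expand", "subtract", "shell", "ring",
                         "unspecified"))
      wl_fail(where, p, "unknown recipe")
  }
  for (i in seq_along(w$constraints)) {
    cn <- w$constraints[[i]]
    p <- sprintf("constraints[%d]", i)
    if (is.null(cn$structure)) wl_fail(where, p, "missing structure")
    if (is.null(cn$type) || !cn$type %in% c("MAX", "MEAN"))
      wl_fail(where, p, "type must be MAX or MEAN")
    validate_quantity(cn$limit, where, paste0(p, "$limit"))
  }
  for (i in seq_along(w$objectives)) {
    ob <- w$objectives[[i]]
    p <- sprintf("objectives[%d]", i)
    if (is.null(ob$structure)) wl_fail(where, p, "missing structure")
    if (is.null(ob$priority) || ob$priority != round(ob$priority) ||
        ob$priority < 1)
      wl_fail(where, p, "priority must be a positive integer")
    if (is.null(ob$kind) || !ob$kind %in% c("LTCP", "EUD", "MAX", "MEAN"))
      wl_fail(where, p, "unknown cost kind")
    if (ob$kind == "LTCP") {
      if (is.null(ob$params$alpha) || ob$params$alpha <= 0)
        wl_fail(where, p, "LTCP needs params$alpha > 0")
      if (is.null(ob$params$D_p))
        wl_fail(where, p, "LTCP needs params$D_p")
      validate_quantity(ob$params$D_p, where, paste0(p, "$params$D_p"))
      if (!is.numeric(ob$goal) || ob$goal <= 0)
        wl_fail(where, p, "LTCP goal must be a positive number")
    } else {
      validate_quantity(ob$goal, where, paste0(p, "$goal"))
    }
    if (ob$kind == "EUD" && (is.null(ob$params$k) || ob$params$k < 1))
      wl_fail(where, p, "EUD needs params$k >= 1")
  }
  structure(w, class = "wishlist")
}

#' @export
print.wishlist <- function(x, ...) {
  cat("wishlist '", x$name, "': ", length(x$constraints),
      " hard constraints, ", length(x$objectives),
      " objective rows (priorities ",
      paste(range(vapply(x$objectives, `[[`, numeric(1), "priority")),
            collapse = "-"), ")\n", sep = "")
  invisible(x)
}

#' Packaged whole-pelvis wishlists
#'
#' The two planning protocols shipped with the package: phase 1
#' (whole-pelvis simultaneous integrated boost, 60/50 Gy) and phase 2
#' (13 Gy prostate boost).  Phase 1 carries 7 hard constraints and 14
#' objective rows over priorities 1-12 (priorities 4 and 6 hold two rows
#' each); phase 2 carries 5 constraints and 10 rows over priorities 1-8
#' (priority 5 holds three rows).
#'
#' @param phase 1 or 2.
#' @return A `wishlist`.
#' @export
builtin_wishlist <- function(phase) {
  if (!phase %in% c(1, 2)) stop("`phase` must be 1 or 2")
  f <- system.file("extdata", "wishlists",
                   sprintf("wprt_phase%d.yaml", phase),
                   package = "wishplan", mustWork = TRUE)
  load_wishlist(f)
}

# ---- resolution ------------------------------------------------------------

materialize_auxiliary <- function(w, ss) {
  grid <- ss$grid
  masks <- ss$masks
  get_mask <- function(nm) {
    if (is.null(masks[[nm]]))
      stop("unresolvable structure '", nm, "' in wishlist '", w$name, "'")
    masks[[nm]]
  }
  unspecified_at <- NULL
  for (a in w$auxiliary) {
    m <- switch(a$recipe,
      union = Reduce(function(x, y) mask_union(x, y, grid),
                     lapply(a$of, get_mask)),
      expand = expand_mask(get_mask(a$of), grid, a$margin_mm),
      subtract = mask_subtract(get_mask(a$of), get_mask(a$minus), grid),
      shell = shell_mask(get_mask(a$of), grid, a$distance_mm,
                         if (is.null(a$thickness_mm)) 5 else a$thickness_mm,
                         external = masks$external,
                         exclude = if (!is.null(a$exclude))
                           get_mask(a$exclude)),
      ring = inner_ring(masks$external, grid, a$depth_mm,
                        exclude = if (!is.null(a$exclude))
                          get_mask(a$exclude)),
      unspecified = { unspecified_at <- a$name; NULL })
    if (!is.null(m)) masks[[a$name]] <- m
  }
  if (!is.null(unspecified_at))
    masks[[unspecified_at]] <-
      unspecified_tissue(masks$external,
                         masks[setdiff(names(masks), "external")], grid)
  masks
}

#' Resolve a wishlist against a prescription and structure set
#'
#' Materializes every auxiliary planning structure (expansions, shells,
#' skin ring, transition region, unspecified tissue), converts all
#' percent-of-reference limits, goals and LTCP prescriptions to absolute
#' Gy, and binds each constraint and objective row to the voxel index
#' list of its structure.  Empty auxiliary structures are dropped with a
#' warning; rows referring to them are removed from the problem.
#'
#' @param w a `wishlist`.
#' @param context a [prescription_context()].
#' @param ss a [structure_set()].
#' @return An object of class `resolved_problem` with `masks`,
#'   `constraints` (absolute Gy limits) and `objectives` (absolute
#'   parameters, listed in priority order, stable within a priority).
#' @export
resolve_wishlist <- function(w, context, ss) {
  stopifnot(inherits(w, "wishlist"),
            inherits(context, "prescription_context"),
            inherits(ss, "structure_set"))
  masks <- materialize_auxiliary(w, ss)
  nonempty <- function(nm) {
    if (is.null(masks[[nm]]))
      stop("unresolvable structure '", nm, "'")
    any(masks[[nm]])
  }
  idx_of <- function(nm) which(as.vector(masks[[nm]]))

  constraints <- list()
  for (cn in w$constraints) {
    if (!nonempty(cn$structure)) {
      warning("dropping constraint on empty structure '", cn$structure, "'")
      next
    }
    limit <- resolve_quantity(cn$limit, context)
    constraints[[length(constraints) + 1L]] <- list(
      structure = cn$structure, type = cn$type, limit_gy = limit,
      idx = idx_of(cn$structure),
      label = sprintf("%s %s <= %.4g Gy", cn$structure, cn$type, limit))
  }

  objectives <- list()
  for (ob in w$objectives) {
    if (!nonempty(ob$structure)) {
      warning("dropping objective on empty structure '", ob$structure, "'")
      next
    }
    if (ob$kind == "LTCP") {
      spec <- cost_spec("LTCP",
                        D_p = resolve_quantity(ob$params$D_p, context),
                        alpha = ob$params$alpha)
      goal <- ob$goal
      lab <- sprintf("%s LTCP(D_p=%.4g, a=%.3g) goal %.3g", ob$structure,
                     spec$D_p, spec$alpha, goal)
    } else {
      spec <- switch(ob$kind,
                     EUD = cost_spec("EUD", k = ob$params$k),
                     MAX = cost_spec("MAX"),
                     MEAN = cost_spec("MEAN"))
      goal <- resolve_quantity(ob$goal, context)
      lab <- sprintf("%s %s%s goal %.4g Gy", ob$structure, ob$kind,
                     if (ob$kind == "EUD") sprintf("(k=%g)", spec$k) else "",
                     goal)
    }
    objectives[[length(objectives) + 1L]] <- list(
      priority = as.integer(ob$priority), structure = ob$structure,
      cost = spec, goal = goal, idx = idx_of(ob$structure), label = lab)
  }
  ord <- order(vapply(objectives, `[[`, integer(1), "priority"))
  objectives <- objectives[ord]

  structure(list(name = w$name, context = context, grid = ss$grid,
                 masks = masks, constraints = constraints,
                 objectives = objectives),
            class = "resolved_problem")
}

#' @export
print.resolved_problem <- function(x, ...) {
  cat("resolved_problem '", x$name, "'\n", sep = "")
  cat(" hard constraints:\n")
  for (cn in x$constraints) cat("   ", cn$label, "\n")
  cat(" objectives:\n")
  for (ob in x$objectives)
    cat(sprintf("   p%-2d %s\n", ob$priority, ob$label))
  invisible(x)
}
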