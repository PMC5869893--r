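#' Wishlist cost functions
#'
#' The four cost-function types a planning wishlist is built from, all
#' convex in the voxel doses (the property the prioritized solver relies
#' on):
#'
#' * **LTCP** (logarithmic tumor control probability), the target
#'   coverage surrogate: `LTCP = mean(exp(-alpha * (d - D_p)))` over the
#'   target voxels.  Equal to 1 for a uniform dose at the prescription
#'   `D_p`, it decreases toward 0 as the target dose rises and penalizes
#'   cold spots exponentially; `alpha` (1/Gy) is the cell-sensitivity
#'   parameter.
#' * **EUD** (equivalent uniform dose), the organ-at-risk surrogate: the
#'   generalized power mean `(mean(d^k))^(1/k)` with volume-effect
#'   exponent `k >= 1`; `k = 1` is the mean dose, large `k` approaches
#'   the maximum dose.
#' * **max** and **mean** dose over the masked voxels.
#'
#' @name cost-functions
NULL

#' @rdname cost-functions
#' @param d numeric vector of voxel doses (Gy) on a structure mask.
#' @param D_p prescription dose (Gy, > 0).
#' @param alpha cell sensitivity (1/Gy, > 0).
#' @return `ltcp()`: a positive scalar (unitless).
#' @examples
#' ltcp(rep(60, 100), 60, 0.7)        # uniform at prescription -> 1
#' eud(c(60, 0), k = 4)               # generalized mean
#' @export
ltcp <- function(d, D_p, alpha) {
  check_doses(d)
  if (!is.numeric(D_p) || D_p <= 0) stop("`D_p` must be > 0")
  if (!is.numeric(alpha) || alpha <= 0) stop("`alpha` must be > 0")
  exp(log_ltcp(d, D_p, alpha))
}

# log-sum-exp form: convex, and finite even at zero dose where the
# natural-scale value overflows double precision
log_ltcp <- function(d, D_p, alpha) {
  a <- -alpha * (d - D_p)
  m <- max(a)
  m + log(mean(exp(a - m)))
}

#' @rdname cost-functions
#' @param k volume-effect exponent (>= 1).
#' @return `eud()`: equivalent uniform dose in Gy, between the mean and
#'   the maximum of `d`.
#' @export
eud <- function(d, k) {
  check_doses(d)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1)
    stop("`k` must be >= 1 (organ volume-effect regime)")
  if (any(d < 0)) stop("doses must be nonnegative")
  if (k == 1) return(mean(d))
  m <- max(d)
  if (m == 0) return(0)
  # evaluate in units of the max to avoid overflow for large k
  m * mean((d / m)^k)^(1 / k)
}

#' @rdname cost-functions
#' @return `max_dose()` / `mean_dose()`: Gy.
#' @export
max_dose <- function(d) {
  check_doses(d)
  max(d)
}

#' @rdname cost-functions
#' @export
mean_dose <- function(d) {
  check_doses(d)
  mean(d)
}

check_doses <- function(d) {
  if (length(d) == 0L) stop("empty structure mask: no doses to evaluate")
  if (!is.numeric(d) || anyNA(d)) stop("doses must be numeric and non-NA")
  invisible(TRUE)
}

#' Cost-function specification
#'
#' @param kind one of `"LTCP"`, `"EUD"`, `"MAX"`, `"MEAN"`.
#' @param D_p prescription dose in Gy (LTCP only).
#' @param alpha cell sensitivity in 1/Gy (LTCP only).
#' @param k volume-effect exponent, >= 1 (EUD only).
#' @return An object of class `cost_spec`.
#' @export
cost_spec <- function(kind, D_p = NULL, alpha = NULL, k = NULL) {
  kind <- match.arg(kind, c("LTCP", "EUD", "MAX", "MEAN"))
  if (kind == "LTCP") {
    if (is.null(D_p) || D_p <= 0) stop("LTCP needs `D_p` > 0")
    if (is.null(alpha) || alpha <= 0) stop("LTCP needs `alpha` > 0")
  }
  if (kind == "EUD") {
    if (is.null(k) || k < 1) stop("EUD needs `k` >= 1")
  }
  structure(list(kind = kind, D_p = D_p, alpha = alpha, k = k),
            class = "cost_spec")
}

#' Evaluate a cost spec on a dose vector
#' @param spec a [cost_spec()].
#' @param d voxel doses (Gy).
#' @export
eval_cost <- function(spec, d) {
  switch(spec$kind,
         LTCP = ltcp(d, spec$D_p, spec$alpha),
         EUD = eud(d, spec$k),
         MAX = max_dose(d),
         MEAN = mean_dose(d))
}

# ---- smooth value/gradient pairs used by the solver -----------------------
# Internally LTCP is handled on the log scale (a monotone transform that
# preserves minimizers and sublevel sets) and MAX via an auxiliary
# variable, so every solver term below is smooth and convex.

# value and gradient w.r.t. d of log(LTCP)
log_ltcp_grad <- function(d, D_p, alpha) {
  a <- -alpha * (d - D_p)
  m <- max(a)
  e <- exp(a - m)
  s <- sum(e)
  list(value = m + log(s / length(d)), grad = -alpha * e / s)
}

# value and gradient w.r.t. d of EUD(k)
eud_grad <- function(d, k) {
  n <- length(d)
  if (k == 1) return(list(value = mean(d), grad = rep(1 / n, n)))
  m <- max(d)
  if (m <= 0) return(list(value = 0, grad = rep(0, n)))
  r <- pmax(d, 0) / m
  mk <- mean(r^k)
  val <- m * mk^(1 / k)
  # dE/dd_j = (1/n) * d_j^(k-1) * (mean(d^k))^(1/k - 1)
  g <- (r^(k - 1)) * mk^(1 / k - 1) / n
  list(value = val, grad = g)
}

mean_grad <- function(d) list(value = mean(d), grad = rep(1 / length(d),
                                                          length(d)))
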