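#' Dose-volume histograms and DVH metrics
#'
#' Cumulative DVHs and the quantile-type dose metrics used for plan
#' evaluation.  `d_at_volume()` implements the dose-ranked quantile
#' `D_q%` — the minimum dose received by the hottest q% of a structure —
#' with linear interpolation between the sorted order statistics so the
#' values are reproducible bit-for-bit; `v_at_dose()` is the fraction of
#' the structure receiving at least a dose threshold.
#'
#' @param dose 3D dose array (Gy).
#' @param mask logical array selecting the structure.
#' @param bin_gy DVH bin width in Gy.
#' @return `dvh()`: a data.frame with `dose_gy` (bin edges) and
#'   `volume_fraction` (cumulative, 1 at 0 Gy, non-increasing).
#' @export
dvh <- function(dose, mask, bin_gy = 0.1) {
  d <- masked_doses(dose, mask)
  edges <- seq(0, max(d) + bin_gy, by = bin_gy)
  vol <- vapply(edges, function(e) mean(d >= e), numeric(1))
  data.frame(dose_gy = edges, volume_fraction = vol)
}

masked_doses <- function(dose, mask) {
  if (!identical(dim(dose), dim(mask))) stop("dose/mask dims differ")
  d <- dose[mask]
  if (length(d) == 0L) stop("empty structure mask")
  d
}

#' @rdname dvh
#' @param q volume percentage in (0, 100): `d_at_volume(dose, mask, 2)`
#'   is the near-maximum dose `D_2%`.
#' @return `d_at_volume()`: dose in Gy.
#' @export
d_at_volume <- function(dose, mask, q) {
  d <- masked_doses(dose, mask)
  if (!is.numeric(q) || q <= 0 || q >= 100) stop("`q` must be in (0, 100)")
  # linear interpolation between descending order statistics
  s <- sort(d, decreasing = TRUE)
  n <- length(s)
  if (n == 1L) return(s)
  h <- 1 + (q / 100) * (n - 1)
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

#' @rdname dvh
#' @param threshold_gy dose threshold in Gy.
#' @return `v_at_dose()`: percent of the structure volume at or above
#'   `threshold_gy`.
#' @export
v_at_dose <- function(dose, mask, threshold_gy) {
  d <- masked_doses(dose, mask)
  100 * mean(d >= threshold_gy)
}

#' Total irradiated volume at a fraction of the prescription
#'
#' The patient volume (ml) receiving at least `fraction * rx_gy`,
#' measured over the whole body — the quantity entering the conformity
#' indices.
#'
#' @param dose 3D dose array (Gy).
#' @param external body mask.
#' @param grid the [voxel_grid()].
#' @param rx_gy prescription dose (Gy).
#' @param fraction fraction of the prescription (0.95 or 0.5).
#' @return volume in ml.
#' @export
v_total_at_fraction <- function(dose, external, grid, rx_gy,
                                fraction = 0.95) {
  if (rx_gy <= 0) stop("`rx_gy` must be > 0")
  d <- masked_doses(dose, external)
  sum(d >= fraction * rx_gy) * voxel_volume_ml(grid)
}

#' Homogeneity index
#'
#' `HI = (D_2% - D_98%) / D_50%`: 0 for a perfectly uniform dose,
#' invariant under dose rescaling.
#'
#' @inheritParams dvh
#' @export
hi <- function(dose, mask) {
  d50 <- d_at_volume(dose, mask, 50)
  if (d50 <= 0) stop("median dose is zero; HI undefined")
  (d_at_volume(dose, mask, 2) - d_at_volume(dose, mask, 98)) / d50
}

#' Conformity indices
#'
#' `CI = V_95% / V_PTV` and `CI_50% = V_50% / V_PTV`, where `V_95%` and
#' `V_50%` are the total patient volumes irradiated with 95% and 50% of
#' the prescribed dose (measured over the whole body, not the PTV).
#'
#' @inheritParams v_total_at_fraction
#' @param ptv_mask target mask.
#' @export
ci <- function(dose, ptv_mask, external, grid, rx_gy) {
  v95 <- v_total_at_fraction(dose, external, grid, rx_gy, 0.95)
  v95 / (sum(ptv_mask) * voxel_volume_ml(grid))
}

#' @rdname ci
#' @export
ci50 <- function(dose, ptv_mask, external, grid, rx_gy) {
  v50 <- v_total_at_fraction(dose, external, grid, rx_gy, 0.50)
  v50 / (sum(ptv_mask) * voxel_volume_ml(grid))
}

#' Sum two phase doses
#' @param a,b 3D dose arrays of identical dims.
#' @export
sum_plans <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("dose grids do not match")
  a + b
}

#' Equi-effective dose in 2 Gy fractions (linear-quadratic model)
#'
#' `EQD2 = D * (d + a/b) / (2 + a/b)` with per-fraction dose
#' `d = D / n`; the identity map where the fraction dose is 2 Gy.  Used
#' to adjust hypofractionated summed doses before evaluating rectal
#' V70/V55.
#'
#' @param dose_total total dose (scalar, vector or 3D array, Gy).
#' @param n_fractions number of fractions (>= 1).
#' @param alpha_beta tissue fractionation sensitivity (Gy; 3 for late
#'   rectal toxicity).
#' @return same shape as `dose_total`.
#' @export
eqd2 <- function(dose_total, n_fractions, alpha_beta = 3) {
  if (n_fractions < 1) stop("`n_fractions` must be >= 1")
  if (alpha_beta <= 0) stop("`alpha_beta` must be > 0")
  dose_total * (dose_total / n_fractions + alpha_beta) / (2 + alpha_beta)
}

# ---- clinical protocol -----------------------------------------------------

#' Clinical organ-at-risk protocol for the summed dose
#'
#' The packaged protocol lists the clinically applied constraints on the
#' total (phase 1 + phase 2) dose: maximum dose and V_xGy limits for
#' rectum, bowel bag, bladder and femoral heads.
#'
#' @return An object of class `clinical_protocol`: data.frame with
#'   `structure`, `metric` (`D_max` or `V_xGy`), `dose_gy` (threshold
#'   dose for V metrics), `limit` (Gy for `D_max`, percent volume for
#'   `V_xGy`).
#' @export
clinical_protocol <- function() {
  path <- system.file("extdata", "protocol", "oar_constraints.yaml",
                      package = "wishplan", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  rows <- do.call(rbind, lapply(y$constraints, function(cn)
    data.frame(structure = cn$structure, metric = cn$metric,
               dose_gy = if (is.null(cn$dose_gy)) NA_real_ else cn$dose_gy,
               limit = cn$limit)))
  structure(rows, class = c("clinical_protocol", "data.frame"))
}

#' Check a summed dose against the clinical protocol
#'
#' @param summed_dose total dose array (Gy).
#' @param ss a [structure_set()] containing every protocol structure
#'   (`femoral_heads` is taken as the union of left and right).
#' @param protocol a [clinical_protocol()].
#' @return data.frame ledger: one row per constraint with `measured`,
#'   `limit` and `pass`; overall acceptability is `all(pass)`.
#' @export
check_protocol <- function(summed_dose, ss, protocol = clinical_protocol()) {
  grid <- ss$grid
  get_mask <- function(nm) {
    if (nm == "femoral_heads")
      return(mask_union(ss$masks$femoral_head_left,
                        ss$masks$femoral_head_right, grid))
    if (is.null(ss$masks[[nm]]))
      stop("protocol structure '", nm, "' missing from the structure set")
    ss$masks[[nm]]
  }
  out <- protocol
  out$measured <- NA_real_
  for (i in seq_len(nrow(out))) {
    m <- get_mask(out$structure[i])
    out$measured[i] <- if (out$metric[i] == "D_max")
      max_dose(masked_doses(summed_dose, m))
    else v_at_dose(summed_dose, m, out$dose_gy[i])
  }
  out$pass <- out$measured <= out$limit
  class(out) <- "data.frame"
  out
}

# ---- target metrics --------------------------------------------------------

#' Target dose metrics for the two-phase plan
#'
#' Computes, per target and per dose distribution (phase 1, phase 2,
#' summed), coverage `V_95%` against the relevant prescription, `D_2%`,
#' `D_98%`, `D_50%`, `D_mean`, `D_max`, HI, CI and `CI_50%`.  Nodal-PTV
#' dose statistics are reported on `PTV-LN` minus the boost volume
#' expanded by 20 mm, so the simultaneous-boost gradient region does not
#' contaminate the nodal homogeneity; nodal coverage is still measured
#' on the full `PTV-LN`.  Summed coverage prescriptions: 73 Gy for
#' `PTV-P` (60 + 13) and 50 Gy for `PTV-LN`.
#'
#' @param dose_phase1,dose_phase2 phase dose arrays (Gy); either may be
#'   `NULL`.
#' @param ss a [structure_set()].
#' @param context a [prescription_context()].
#' @param sib_margin_mm margin around the boost volume excluded from
#'   nodal reporting (mm).
#' @return data.frame with one row per (distribution, target, metric).
#' @export
target_metrics <- function(dose_phase1, dose_phase2, ss,
                           context = prescription_context(),
                           sib_margin_mm = 20) {
  grid <- ss$grid
  ext <- ss$masks$external
  ptvp <- ss$masks[["PTV-P"]]
  ptvln <- ss$masks[["PTV-LN"]]
  report_ln <- mask_subtract(ptvln, expand_mask(ptvp, grid, sib_margin_mm),
                             grid)
  ln_stats_mask <- if (any(report_ln)) report_ln else NULL
  if (is.null(ln_stats_mask))
    warning("nodal reporting mask is empty; PTV-LN dose statistics omitted")

  doses <- list()
  if (!is.null(dose_phase1)) doses$phase1 <- dose_phase1
  if (!is.null(dose_phase2)) doses$phase2 <- dose_phase2
  if (!is.null(dose_phase1) && !is.null(dose_phase2))
    doses$summed <- sum_plans(dose_phase1, dose_phase2)

  rx <- list(
    phase1 = list(`PTV-P` = context$D_high, `PTV-LN` = context$D_low),
    phase2 = list(`PTV-P` = context$D_boost),
    summed = list(`PTV-P` = context$D_high + context$D_boost,
                  `PTV-LN` = context$D_low))

  rows <- list()
  add <- function(dist, target, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      distribution = dist, target = target, metric = metric, value = value)

  for (dist in names(doses)) {
    dgrid <- doses[[dist]]
    for (target in names(rx[[dist]])) {
      rx_gy <- rx[[dist]][[target]]
      cov_mask <- ss$masks[[target]]
      stats_mask <- if (target == "PTV-LN" && !is.null(ln_stats_mask))
        ln_stats_mask else cov_mask
      add(dist, target, "V95_pct", v_at_dose(dgrid, cov_mask, 0.95 * rx_gy))
      add(dist, target, "D2_gy", d_at_volume(dgrid, stats_mask, 2))
      add(dist, target, "D98_gy", d_at_volume(dgrid, stats_mask, 98))
      add(dist, target, "D50_gy", d_at_volume(dgrid, stats_mask, 50))
      add(dist, target, "Dmean_gy", mean_dose(masked_doses(dgrid,
                                                           stats_mask)))
      add(dist, target, "Dmax_gy", max_dose(masked_doses(dgrid, cov_mask)))
      add(dist, target, "HI", hi(dgrid, stats_mask))
      add(dist, target, "CI", ci(dgrid, cov_mask, ext, grid, rx_gy))
      add(dist, target, "CI50", ci50(dgrid, cov_mask, ext, grid, rx_gy))
    }
  }
  do.call(rbind, rows)
}

#' Rectal V70/V55 on the fractionation-adjusted summed dose
#'
#' Converts the summed dose grid to EQD2 (`alpha/beta` = 3, total
#' fraction number of the two phases) and evaluates rectal V_70Gy and
#' V_55Gy on it.  Set `convert = "threshold"` to instead convert the
#' dose thresholds and evaluate on the physical dose.
#'
#' @param summed_dose total dose array (Gy).
#' @param ss a [structure_set()].
#' @param context a [prescription_context()].
#' @param alpha_beta Gy.
#' @param convert `"dose"` (default) or `"threshold"`.
#' @return data.frame with V70 and V55 (percent of rectum volume).
#' @export
rectum_v70_v55 <- function(summed_dose, ss,
                           context = prescription_context(),
                           alpha_beta = 3, convert = c("dose", "threshold")) {
  convert <- match.arg(convert)
  n <- sum(context$fractions)
  rect <- ss$masks$rectum
  if (convert == "dose") {
    deq <- eqd2(summed_dose, n, alpha_beta)
    data.frame(metric = c("V70Gy_pct", "V55Gy_pct"),
               value = c(v_at_dose(deq, rect, 70), v_at_dose(deq, rect, 55)))
  } else {
    # invert EQD2(th) = D (th + ab) / (2 + ab) with d = th / n
    inv <- function(target) {
      ab <- alpha_beta
      # solve D^2/n + ab D - target (2 + ab) = 0 for D >= 0
      (-ab + sqrt(ab^2 + 4 * target * (2 + ab) / n)) * n / 2
    }
    data.frame(metric = c("V70Gy_pct", "V55Gy_pct"),
               value = c(v_at_dose(summed_dose, rect, inv(70)),
                         v_at_dose(summed_dose, rect, inv(55))))
  }
}
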