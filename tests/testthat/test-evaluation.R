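test_that("DVH quantile metrics match the sorted-array oracle", {
  g <- wishplan::voxel_grid(c(10L, 10L, 10L), 2)
  mask <- array(TRUE, dim = g$dims)
  set.seed(10)
  dose <- array(runif(1000, 0, 80), dim = g$dims)
  for (q in c(2, 25, 50, 75, 98))
    expect_equal(d_at_volume(dose, mask, q), brute_d_at_volume(dose, q))
  for (x in c(10, 40, 66))
    expect_equal(v_at_dose(dose, mask, x), brute_v_at_dose(dose, x))
  # quantile ordering invariant
  expect_lte(d_at_volume(dose, mask, 98), d_at_volume(dose, mask, 50))
  expect_lte(d_at_volume(dose, mask, 50), d_at_volume(dose, mask, 2))
  expect_lte(d_at_volume(dose, mask, 2), max(dose))
  # uniform dose: all quantiles coincide
  u <- array(60, dim = g$dims)
  expect_equal(d_at_volume(u, mask, 2), 60)
  expect_equal(d_at_volume(u, mask, 98), 60)
  expect_equal(v_at_dose(u, mask, 60), 100)
  expect_equal(v_at_dose(array(50, dim = g$dims), mask, 60), 0)
  # linear ramp over 100 voxels: agrees with the oracle everywhere
  g1 <- wishplan::voxel_grid(c(100L, 1L, 1L), 1)
  ramp <- array(seq(50, 70, length.out = 100), dim = g1$dims)
  m1 <- array(TRUE, dim = g1$dims)
  for (q in c(2, 50, 98))
    expect_equal(d_at_volume(ramp, m1, q), brute_d_at_volume(ramp, q))
  expect_error(d_at_volume(dose, array(FALSE, dim = g$dims), 2), "empty")
})

test_that("DVH curves are proper cumulative distributions", {
  g <- wishplan::voxel_grid(c(8L, 8L, 8L), 4)
  mask <- array(TRUE, dim = g$dims)
  set.seed(11)
  dose <- array(runif(512, 0, 70), dim = g$dims)
  h <- dvh(dose, mask, bin_gy = 0.5)
  expect_equal(h$volume_fraction[1], 1)
  expect_true(all(diff(h$volume_fraction) <= 0))
  # at vanishing bin width the curve reproduces exact V_xGy
  h2 <- dvh(dose, mask, bin_gy = 0.01)
  at <- function(x) h2$volume_fraction[which.min(abs(h2$dose_gy - x))]
  for (x in c(10.0, 35.0, 60.0))
    expect_equal(100 * at(x), v_at_dose(dose, mask, x), tolerance = 0.2)
})

test_that("homogeneity index is zero for uniform dose and scale-invariant", {
  g <- wishplan::voxel_grid(c(100L, 1L, 1L), 1)
  m <- array(TRUE, dim = g$dims)
  expect_equal(hi(array(60, dim = g$dims), m), 0)
  ramp <- array(seq(50, 70, length.out = 100), dim = g$dims)
  expected <- (brute_d_at_volume(ramp, 2) - brute_d_at_volume(ramp, 98)) /
    brute_d_at_volume(ramp, 50)
  expect_equal(hi(ramp, m), expected)
  expect_equal(hi(ramp * 1.7, m), hi(ramp, m))
  expect_error(hi(array(0, dim = g$dims), m), "zero")
})

test_that("conformity indices count volume over the whole patient", {
  g <- wishplan::voxel_grid(c(12L, 12L, 12L), 4)
  ext <- array(TRUE, dim = g$dims)
  ptv <- array(FALSE, dim = g$dims); ptv[5:8, 5:8, 5:8] <- TRUE
  dose <- array(0, dim = g$dims)
  dose[ptv] <- 60
  expect_equal(ci(dose, ptv, ext, g, 60), 1)
  # 95% isodose volume exactly twice the PTV
  dose2 <- dose
  dose2[5:8, 5:8, 1:4] <- 60
  expect_equal(ci(dose2, ptv, ext, g, 60), 2)
  # brute-force voxel count on a random field
  set.seed(12)
  dr <- array(runif(12^3, 0, 70), dim = g$dims)
  expect_equal(ci(dr, ptv, ext, g, 60),
               sum(dr >= 57) / sum(ptv))
  expect_equal(ci50(dr, ptv, ext, g, 60),
               sum(dr >= 30) / sum(ptv))
  # invariant under relabeling of organs: depends on dose/external/PTV only
  expect_error(ci(dr, ptv, ext, g, 0), "rx_gy")
})

test_that("plan summation is voxelwise and commutative", {
  a <- array(runif(27), dim = c(3, 3, 3))
  b <- array(runif(27), dim = c(3, 3, 3))
  expect_equal(sum_plans(a, array(0, dim = dim(a))), a)
  expect_equal(sum_plans(a, b), sum_plans(b, a))
  expect_equal(sum_plans(array(60, dim = dim(a)), array(13, dim = dim(a))),
               array(73, dim = dim(a)))
  expect_error(sum_plans(a, array(0, dim = c(2, 3, 3))), "match")
})

test_that("EQD2 follows the linear-quadratic model", {
  # 2 Gy per fraction is the fixed point
  expect_equal(eqd2(60, 30, 3), 60)
  # 73 Gy in 30 fractions at alpha/beta 3
  expect_equal(eqd2(73, 30, 3), 73 * (73 / 30 + 3) / 5)
  expect_equal(round(eqd2(73, 30, 3), 1), 79.3)
  expect_equal(eqd2(0, 30, 3), 0)
  # voxelwise on arrays
  d <- array(c(0, 40, 73), dim = c(3, 1, 1))
  expect_equal(eqd2(d, 30, 3),
               array(c(0, 40 * (40 / 30 + 3) / 5, 73 * (73 / 30 + 3) / 5),
                     dim = c(3, 1, 1)))
  expect_error(eqd2(60, 0), "fractions")
})

test_that("the packaged clinical protocol reproduces the summed-dose constraint list", {
  p <- clinical_protocol()
  expect_equal(nrow(p), 16)
  sig <- paste(p$structure, p$metric,
               ifelse(is.na(p$dose_gy), "", p$dose_gy), p$limit)
  expect_equal(sig, c(
    "rectum D_max  78", "rectum V_xGy 65 20", "rectum V_xGy 60 40",
    "rectum V_xGy 55 45", "rectum V_xGy 50 50",
    "bowel_bag D_max  56", "bowel_bag V_xGy 50 10",
    "bowel_bag V_xGy 45 15", "bowel_bag V_xGy 40 20",
    "bladder D_max  78", "bladder V_xGy 65 20", "bladder V_xGy 55 40",
    "bladder V_xGy 50 50", "bladder V_xGy 35 80",
    "femoral_heads D_max  55", "femoral_heads V_xGy 45 5"))
})

test_that("protocol checking flags the right violations", {
  tp <- tiny_phantom()
  ss <- tp$ss
  zero <- array(0, dim = tp$grid$dims)
  led0 <- check_protocol(zero, ss)
  expect_true(all(led0$pass))
  # rectum uniform 50 Gy: V65 passes, V50 fails (100% > 50%)
  d <- zero; d[ss$masks$rectum] <- 50
  led <- check_protocol(d, ss)
  r65 <- led$structure == "rectum" & !is.na(led$dose_gy) & led$dose_gy == 65
  r50 <- led$structure == "rectum" & !is.na(led$dose_gy) & led$dose_gy == 50
  expect_equal(led$measured[r65], 0)
  expect_true(led$pass[r65])
  expect_equal(led$measured[r50], 100)
  expect_false(led$pass[r50])
  # femoral head uniform 56 Gy: D_max 55 fails
  d2 <- zero; d2[ss$masks$femoral_head_left] <- 56
  led2 <- check_protocol(d2, ss)
  fmax <- led2$structure == "femoral_heads" & led2$metric == "D_max"
  expect_equal(led2$measured[fmax], 56)
  expect_false(led2$pass[fmax])
  # missing structure errors by name
  ss2 <- ss; ss2$masks$bladder <- NULL
  expect_error(check_protocol(zero, ss2), "bladder")
})

test_that("target metrics use the nodal reporting mask and summed prescriptions", {
  tp <- tiny_phantom()
  g <- tp$grid
  ss <- tp$ss
  report_ln <- mask_subtract(ss$masks[["PTV-LN"]],
                             expand_mask(ss$masks[["PTV-P"]], g, 20), g)
  expect_equal(sum(report_ln & expand_mask(ss$masks[["PTV-P"]], g, 20)), 0)
  d1 <- array(0, dim = g$dims)
  d1[ss$masks[["PTV-LN"]]] <- 50
  d1[ss$masks[["PTV-P"]]] <- 60
  d2 <- array(0, dim = g$dims)
  d2[ss$masks[["PTV-P"]]] <- 13
  mt <- target_metrics(d1, d2, ss)
  get <- function(dist, target, metric)
    mt$value[mt$distribution == dist & mt$target == target &
               mt$metric == metric]
  # uniform 73 Gy on PTV-P in the sum: full coverage
  expect_equal(get("summed", "PTV-P", "V95_pct"), 100)
  expect_equal(get("summed", "PTV-P", "Dmean_gy"), 73)
  expect_equal(get("phase2", "PTV-P", "V95_pct"), 100)
  # nodal statistics come from the reporting mask (all at 50 Gy)
  expect_equal(get("summed", "PTV-LN", "D2_gy"), 50)
  expect_equal(get("summed", "PTV-LN", "HI"), 0)
  # random dose: V95 equals the voxel-count oracle
  set.seed(13)
  dr <- array(runif(prod(g$dims), 0, 80), dim = g$dims)
  mtr <- target_metrics(dr, NULL, ss)
  vr <- mtr$value[mtr$distribution == "phase1" & mtr$target == "PTV-P" &
                    mtr$metric == "V95_pct"]
  expect_equal(vr, brute_v_at_dose(dr[ss$masks[["PTV-P"]]], 57))
  # D_mean is additive across phases
  expect_equal(get("summed", "PTV-P", "Dmean_gy"),
               get("phase1", "PTV-P", "Dmean_gy") +
                 get("phase2", "PTV-P", "Dmean_gy"))
})

test_that("rectal V70/V55 evaluates on the EQD2-adjusted sum", {
  tp <- tiny_phantom()
  g <- tp$grid
  ss <- tp$ss
  d <- array(0, dim = g$dims)
  d[ss$masks$rectum] <- 68   # EQD2(68, 30 fx) = 71.6 > 70
  out <- rectum_v70_v55(d, ss)
  expect_equal(out$value[out$metric == "V70Gy_pct"], 100)
  # threshold conversion is the inverse mapping
  out2 <- rectum_v70_v55(d, ss, convert = "threshold")
  expect_equal(out$value, out2$value, tolerance = 1e-9)
})
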