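---
title: "Prioritized wishlist planning for whole-pelvis radiotherapy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritized wishlist planning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The planning problem

Whole-pelvis prostate radiotherapy (WPRT) treats two nested targets: the
prostate (primary clinical target volume, CTV-P) and the pelvic lymph
nodes plus the prostate (secondary CTV, CTV-LN), a large concave volume
wrapping around bowel and bladder.  The packaged prescription is a
two-phase protocol: phase 1 delivers 60 Gy to the prostate PTV and
50 Gy to the nodal PTV in 25 fractions as a simultaneous integrated
boost; phase 2 adds a sequential boost of 13 Gy in 5 fractions to the
prostate PTV.  Setup margins of 5 mm expand each CTV to its PTV.

`wishplan` re-implements the *a priori* multi-criteria approach to this
problem: the planning protocol is written down once as a **wishlist** —
an ordered list of inviolable hard constraints plus prioritized
objectives with goals — and a lexicographic optimizer turns the wishlist
into a fluence plan with no per-patient tweaking.

# The optimization model

## Dose model

Dose is linear in the beamlet fluence weights: `d = D x`, `x >= 0`,
where `D` is the sparse dose-influence matrix.  Rotational delivery is
approximated, as in fluence pre-optimization practice, by 20
equi-angular static beams.  Each beamlet deposits dose along its
divergent ray through a homogeneous water-equivalent body:

* exponential depth attenuation, `mu` = 0.04/cm by default (a
  broad-beam effective value for high-energy photons);
* a Gaussian lateral profile with `sigma` = 5 mm measured in the
  isocenter plane;
* no buildup region, no scatter kernels, no inverse-square factor.

The surrogate is deliberately minimal: its role is to provide a linear,
qualitatively realistic `D` that exercises the optimizer, not to
reproduce a commercial dose engine.  The matrix is calibrated so unit
uniform fluence delivers 2 Gy at the isocenter; entries below `1e-4` of
their column maximum are dropped.  Beamlets are 10 mm at the isocenter
plane — the pre-optimization resolution is not dictated by the protocol,
so it is a documented assumption, configurable in `physics_params()` /
`make_beams()`.

## Cost functions

All four wishlist cost types are convex in dose, which is what makes the
lexicographic bounds globally valid:

* **LTCP** (logarithmic tumor control probability), the coverage
  surrogate: `LTCP = mean(exp(-alpha (d - D_p)))` over target voxels.
  It equals 1 at a uniform prescription dose and penalizes cold spots
  exponentially.  Two non-obvious choices: the normalization is a *mean*
  over voxels (not a sum) so that the goal values in the packaged
  wishlists (0.65, 0.5) are volume-independent; and the solver operates
  on `log(LTCP)` (a log-sum-exp of affine functions — still convex, and
  a monotone transform, so minimizers and sublevel sets are unchanged)
  because the natural-scale value overflows double precision at zero
  dose.
* **EUD**, the organ surrogate: the power mean `(mean(d^k))^(1/k)`,
  `k >= 1`; `k = 1` is the mean dose, large `k` approaches the maximum.
  Large-`k` evaluation is done in units of the vector maximum to avoid
  overflow.  Note the finite-voxel limit: `EUD(k) >= max * n^(-1/k)`,
  so on a 1000-voxel structure EUD(64) is only guaranteed within ~10%
  of the max for arbitrary dose vectors; within the ±5% homogeneity
  window of a target it is within 2%.
* **max** and **mean** dose.  Maximum-dose constraints are enforced
  per voxel (exactly, not via a smooth softmax); maximum-dose
  *objectives* are lifted with an auxiliary variable `t`
  (`min t` s.t. `d_i <= t`), which keeps the stage subproblem smooth
  and the constraint exact.

## The wishlists

The two packaged YAML configs (`wprt_phase1.yaml`, `wprt_phase2.yaml`)
encode the full WPRT planning protocol: 7 hard constraints and 14
objective rows over priorities 1–12 for phase 1 (priorities 4 and 6
carry two rows each), 5 constraints and 10 rows over priorities 1–8 for
phase 2 (priority 5 carries three).  Limits and goals are stored as
percentages of the named reference doses (`D_high` = 60 Gy,
`D_low` = 50 Gy, `D_p` = 13 Gy) and resolved to absolute Gy against a
`prescription_context()`.

The wishlists refer to auxiliary planning structures, each shipped as a
recipe and materialized at resolve time:

* a 5 mm **transition region** `PTV-P+5mm` around the boost target, and
  the nodal ring `PTV-LN - PTV-P+5mm` that carries the phase-1 nodal
  dose limits — without the transition, the 105%-of-50-Gy cap would
  collide with the 60 Gy boost gradient;
* **fall-off shells** at 5/15/25/50 mm driving dose compactness.  The
  protocol names only a distance ("shell 5 mm"); whether such shells
  are thin bands or everything beyond a distance is not recoverable
  from it, so both are provided and the default is a 5 mm-thick band
  (`shell_mask(thickness_mm = 5)`), the conventional fall-off
  construction.  Shells and the skin ring exclude the phase PTV (and
  only the PTV) so that fall-off objectives can never fight coverage;
  whether they should also exclude OARs is likewise unstated, and they
  do not — organ sparing has its own prioritized rows;
* the 20 mm **skin ring** suppressing superficial dose;
* **unspecified tissue** — body voxels in no named or auxiliary
  structure — carrying its own 105% maximum constraint.

Empty auxiliaries (possible on small grids or unusual anatomies) are
dropped with a warning rather than an error, and rows referring to them
are removed.

## The prioritized solver

`solve_prioritized()` implements the two-pass lexicographic
epsilon-constraint method:

* **Pass A** walks the objectives in priority order.  Each objective is
  minimized subject to the hard constraints and every previously
  imposed bound.  If the attained value reaches the goal, the bound is
  imposed *at the goal* — deliberately leaving headroom for lower
  priorities, which is what the protocol's "goal" column implies; if
  not, the bound is `attained * delta` with `delta = 1.03`.  The
  relaxation constant is not prescribed by the protocol, so it is a
  logged setting.
* **Pass B** revisits each objective, re-minimizing it subject to all
  *other* bounds and tightening its own bound to the attained value.
  This consumes the pass-A slack and is what makes the final plan
  Pareto-consistent.  Two safeguards matter in floating point: bounds
  are tighten-only (`min(old, attained)`), and a pass-B stage that
  fails to improve its slot (possible when the incoming iterate sits on
  a near-equality constraint set) leaves the fluence untouched.
* A terminal **minimum-norm solve** (`l2` tie-break) selects
  deterministically among near-degenerate optima, and a final linear
  **rescale** removes any residual hard-limit violation exactly — every
  hard constraint is an upper limit on a positively homogeneous
  function of the fluence, so scaling down by `min(limit/measured)` is
  always a valid projection.

Rows sharing a priority are handled sequentially in listed order by
default (deterministic, faithful to the table ordering); a joint
equal-weight mode is available via
`solver_settings(joint_priority = TRUE)` since the protocol does not
state which the reference optimizer uses.

Each stage subproblem is convex and solved by an augmented-Lagrangian
method over projected L-BFGS (`stats::optim`, `L-BFGS-B`, `lower = 0`).
Numerical choices: constraint residuals are normalized by their limits;
the outer loop stops only when the iterate is feasible *and* the inner
solver converged or the augmented objective stalled (stopping on
feasibility alone silently truncates objective descent); the penalty
parameter starts at 50 and is multiplied by 5 whenever the worst
violation fails to drop by 4x.  Constraint tolerance is
`max(0.05 Gy, 0.1% of the limit)` per constraint (LTCP bounds: `1e-3`
on the log scale).

## Evaluation and QA

The evaluation module computes cumulative DVHs, `D_q%` quantiles
(linear interpolation between descending order statistics, so values
are bit-reproducible), `V_xGy`, homogeneity `HI = (D2% - D98%)/D50%`,
conformity `CI = V95%/V_PTV` and `CI50% = V50%/V_PTV` measured over the
whole patient, plan summation, and EQD2 conversion
(`alpha/beta` = 3 Gy, identity at 2 Gy per fraction).  Nodal-target
dose statistics are reported on PTV-LN minus the boost volume expanded
by 20 mm, so the boost gradient does not contaminate nodal homogeneity;
nodal *coverage* is still measured on the full PTV-LN.  Because the
summed plan has two dose levels, summed coverage is checked per target
against 73 Gy (boost target) and 50 Gy (nodal target).

The packaged organ-at-risk protocol for the summed dose (16 constraints
on rectum, bowel bag, bladder and femoral heads) is checked verbatim by
`check_protocol()`; its `D_max` rows are evaluated as the true voxel
maximum, with a near-max (`D_2%`-style) variant available through
`d_at_volume()` since protocols differ on this point.  Rectal V70/V55
are evaluated on the EQD2-converted summed dose grid by default; the
protocol wording would also admit converting the thresholds instead,
which is exposed as `convert = "threshold"` (the two agree to within
the inverse LQ mapping).

Gamma QA implements the 3% local / 3 mm criterion with a 10% low-dose
cutoff (a standard QA default; the protocol does not state one).  The
search lattice steps at half a voxel with trilinear interpolation of
the evaluated dose and is capped at 3x the distance criterion — any
voxel beyond the cap has gamma > 3 and cannot affect pass/fail.

# The synthetic phantom

`generate_phantom()` builds a seeded pelvis: an elliptical body
cylinder (92 x 72 mm semi-axes, cropped cranio-caudally by the scan
extent like a real planning CT), a spherical prostate abutting a
rectal tube posteriorly, a bladder anterior-superior to it, a nodal
horseshoe (annular sector, opening anteriorly) wrapping around bladder
and bowel with a 2 mm mesorectal corridor carved around the rectum, a
bowel bag clipped exactly 20 mm cranial of the nodal target, and
femoral heads placed laterally and caudally to the nodal volume —
pelvic nodes run along the iliac vessels cranial to the femoral heads,
and this separation is what makes 50 Gy nodal coverage compatible with
the 70% femoral hard limit.  Default volumes are realistic for the
site (CTV-LN ≈ 250 ml, PTV-LN ≈ 390 ml, bladder ≈ 50 ml).

Anatomy jitter adds seeded uniform perturbations (± 3 mm on centers,
± 1 mm on radii) for cohort generation; the same spec and seed always
reproduce the same masks.  What the phantom does *not* emulate: CT
densities and heterogeneity, organ deformation, hip prostheses,
intra-patient motion.  Tests passing on the phantom therefore
demonstrate the optimizer/evaluator machinery, not clinical dosimetric
accuracy.

# Problem sizes and defaults

The packaged desk-scale setup is a 50 x 40 x 40 grid at 4 mm
(~52,000 body voxels), 20 beams of 10 mm beamlets with the aperture
shaped to the phase target plus 12 mm (~4,500 beamlets in phase 1,
~1,000 in phase 2), giving a dose-influence matrix with ~5 million
nonzeros.  A full phase-1 solve (14 objective rows, two passes and the
tie-break — 30 convex subproblems) runs in minutes on one CPU; phase 2
is several times faster.  Oracle tests run at much smaller sizes: toy
fluence problems with 2–3 beamlets and up to 6 voxels are compared
against exhaustive lexicographic grid search, and geometry/gamma
operators are verified against brute-force oracles on fine 1–3 mm
grids.

# Worked example

```{r}
library(wishplan)

cfg <- run_config(seed = 42L)
res <- run_pipeline(cfg)

print(res$phase1$plan)            # constraint slacks + objective trace
subset(res$evaluation$metrics,
       metric == "V95_pct")       # coverage per phase and summed
all(res$evaluation$protocol$pass) # clinical OAR protocol on the sum

g <- gamma_index(res$phase1$plan$dose, res$phase1$plan$dose, cfg$grid)
g$pass_rate                       # 100 for a plan against itself
```

# Known limitations

* The dose surrogate ignores buildup, scatter and heterogeneity; its
  absolute dose scale is set by a single calibration point.
* The terminal product is the optimized fluence plan; arc sequencing,
  aperture generation and monitor-unit computation are out of scope.
* The augmented-Lagrangian stages are inexact by design (iteration
  caps); bounds carry a 3% relaxation and tolerances of 0.05 Gy, so
  the lexicographic trace is reproducible to those tolerances rather
  than to machine precision.
* The phantom's hard geometric idealizations (spheres, tubes and
  ellipsoids on a 4 mm grid) make target-edge penumbra effects coarser
  than on clinical CT resolutions.  One visible consequence: bowel-bag
  voxels abutting the nodal PTV sit inside the 4 mm-scale penumbra of a
  50 Gy region, so the summed-dose organ protocol's bowel maximum
  (56 Gy) can be exceeded by 1-2 Gy on the default phantom even though
  every wishlist hard constraint is met — on clinical-resolution
  anatomy the gradient between PTV edge and bowel is sharper.
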