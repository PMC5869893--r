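# wishplan

Automated, wishlist-driven treatment planning for whole-pelvis prostate
radiotherapy (WPRT), in R.

Planning a WPRT case means covering two nested targets — the prostate
(boost target, PTV-P) and the large concave pelvic-node volume (PTV-LN)
wrapping around bowel and bladder — while sparing rectum, bladder, bowel
bag and femoral heads.  Done by hand, this is hours of iterative
parameter tweaking per patient.  `wishplan` implements the *a priori*
multi-criteria alternative: the planning protocol is written once as a
**wishlist** — an ordered list of inviolable hard constraints plus
prioritized objectives with goals — and a lexicographic optimizer turns
it into a Pareto-consistent fluence plan with no per-case interaction.
The package is aimed at medical-physics researchers studying automated
planning algorithms; it ships a seeded synthetic pelvis phantom so the
whole pipeline runs with no patient data.

## The method

Dose is linear in the beamlet fluence weights, `d = D x` with `x >= 0`;
`D` is a sparse dose-influence matrix for 20 equi-angular coplanar
beams over a water-equivalent body (exponential depth attenuation,
Gaussian lateral beamlet profile).  A wishlist row is one of four
convex cost functions on a structure's voxel doses:

- `LTCP = (1/m) Σ_j exp(−α (d_j − D_p))` — target-coverage surrogate
  (1 at uniform prescription dose; cold spots penalized exponentially),
- `EUD_k = ((1/m) Σ_j d_j^k)^{1/k}` — organ-at-risk surrogate
  (k = 1 is the mean dose, large k approaches the max),
- maximum and mean dose.

`solve_prioritized()` minimizes the objectives in priority order
(ε-constraint method): each stage minimizes one objective subject to
the hard constraints and all previously imposed bounds; an objective
that reaches its goal is bounded *at the goal* (leaving headroom for
lower priorities), otherwise at `attained × δ` (δ = 1.03).  A second
pass re-minimizes every objective under the other bounds and tightens
its bound to the attained value, and a minimum-norm tie-break selects
deterministically among near-degenerate optima.  Every subproblem is
convex and solved by an augmented-Lagrangian method over projected
L-BFGS.

The two packaged wishlists encode the full two-phase WPRT protocol
(60/50 Gy simultaneous integrated boost in 25 fractions, then a 13 Gy
prostate boost in 5 fractions), including the auxiliary planning
structures they reference: a 5 mm transition region around the boost
volume, dose fall-off shells at 5/15/25/50 mm, a 20 mm skin ring and
"unspecified tissue".  Evaluation covers DVHs, D_q% quantiles, V_xGy,
homogeneity (`HI = (D2% − D98%)/D50%`) and conformity
(`CI = V95%/V_PTV`, `CI50% = V50%/V_PTV`) indices, EQD2 conversion
(α/β = 3), a packaged clinical organ-at-risk protocol for the summed
dose, and 3%-local/3 mm gamma-index QA.

## Worked example

```r
library(wishplan)

cfg <- run_config(seed = 42L)        # 4 mm grid, 20 beams, packaged wishlists
res <- run_pipeline(cfg)             # phantom -> phase-1 -> phase-2 -> report
```

`print(res$phase1$plan)` shows the phase-1 hard-constraint ledger
(measured / limit, Gy):

```
   PTV-P                        MAX    62.49 /   63.00  ok
   PTV-P                        MEAN   60.59 /   60.60  ok
   PTV-LN - PTV-P+5mm           MAX    52.11 /   52.50  ok
   PTV-LN - PTV-P+5mm           MEAN   50.50 /   50.50  ok
   femoral_heads                MAX    28.68 /   42.00  ok
   PTV-LN shell 50 mm           MAX    27.07 /   30.00  ok
   Unspecified tissues          MAX    60.98 /   63.00  ok
```

Both target-dose caps sit at their limits (coverage pushes up to them)
while the organ and tissue limits keep comfortable slack.  The summed
plan reaches `V95% = 98.0%` for PTV-P (against 73 Gy) and `99.3%` for
PTV-LN (against 50 Gy) — above the 96% clinical coverage criterion —
with phase-1 `HI = 0.086` and `CI = 1.47` for the boost target:

```r
summed <- sum_plans(res$phase1$plan$dose, res$phase2$plan$dose)
v_at_dose(summed, res$structures$masks[["PTV-P"]],  0.95 * 73)  # 97.98
v_at_dose(summed, res$structures$masks[["PTV-LN"]], 0.95 * 50)  # 99.33
```

A full two-phase run takes about 13 minutes on one CPU.  A thin
command-line front end over the same functions is installed at
`inst/cli/wishplan.R` (`phantom`, `plan --phase`, `evaluate`, `gamma`,
`report` subcommands).

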