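# ependyflow

Quantification of planar cell polarity and near-wall flow for
multiciliated epithelia — the ependymal lining of the brain ventricles
in particular — plus the small cohort-genetics arithmetic that such
studies report.

Multiciliated ependymal cells drive cerebrospinal-fluid flow along the
ventricular wall through coordinated ciliary beating. That coordination
shows up as measurable polarity: the basal-body (BB) patch of each cell
is displaced off-center in a tissue-wide direction, the patch is
elongated along a shared axis, each basal body's basal foot points in
the beat direction, and tracer microspheres over the wall move in a
common direction. This package computes all of it from labeled
cell-boundary images and point tables:

* **Translational polarity** — distance `TD = |C - BC|` and angle `TA`
  of the vector from the cell centroid `C` to the BB patch centroid
  `BC` (with `TD_norm = TD / r_eq`, the offset as a fraction of the
  equivalent cell radius).
* **Patch orientation** — Feret's angle `FA` and longest diameter `LD`
  of the BB point set (axial, on `[0, 180)`).
* **Rotational polarity** — one-to-one gated nearest-neighbour vectors
  from basal-foot markers to basal-body markers.
* **Flow directionality** — spot detection, greedy gated
  nearest-neighbour track linking, per-track net-displacement
  directions.
* **Circular statistics** — circular mean and resultant length `R`,
  Rayleigh uniformity test (`Z = nR²`), and Watson's two-sample U²
  homogeneity test
  `U² = (nm/N²)[Σ d_k² − (Σ d_k)²/N]`
  with a permutation p-value (default) or the asymptotic
  critical-point bracket.
* **Cohort statistics** — cohort minor allele frequency and the 2×2 χ²
  test with Yates continuity correction.

A synthetic-epithelium and flow generator (`generate_mosaic()`,
`generate_flow_video()`) produces ground-truthed inputs with the exact
statistical structure the analysis assumes (von Mises-distributed
offsets, axes, and foot directions around a global polarity direction;
coherent versus disorganized advection), so every stage of the pipeline
is verifiable without microscopy data. See the vignette in
`vignettes/quantifying-ependymal-polarity.Rmd` for the model, the
conventions, and the design decisions.

## Worked example

Contrast a coordinated ("wildtype-like") synthetic field with an
uncoordinated ("mutant-like") one, end to end:

```r
library(ependyflow)

wt  <- generate_mosaic(scene_preset("wildtype", seed = 1))
mut <- generate_mosaic(scene_preset("mutant",   seed = 2))

res <- run_polarity(list(
  list(label = wt$label,  points = wt$points,  name = "wildtype"),
  list(label = mut$label, points = mut$points, name = "mutant")))
print(res$summary, digits = 3)
#>      group   n td_mean td_sem td_norm_mean td_norm_sem ta_mean   ta_R fa_mean  fa_R
#> 1 wildtype 150    9.06 0.0677        0.351     0.00161    91.1 0.9424    89.5 0.913
#> 2   mutant 150    2.62 0.0373        0.102     0.00127   132.5 0.0716    78.1 0.144
```

The wildtype-like group recovers the generating conditions: mean
`TD_norm` 0.351 against a true patch offset of 0.35, patch-angle
circular mean 91.1° against a global polarity direction of 90°, with a
high resultant length (`ta_R` 0.94). The mutant-like group shows the
decohered phenotype: patches near the cell center (`TD_norm` 0.10) and
patch angles spread over the circle (`ta_R` 0.07 — the 132.5° "mean" of
a near-uniform sample is meaningless, which is why `R` is reported next
to it). The translational-distance contrast is formally tested:

```r
res$t_test
#> Welch t-test on TD: t = -83.3, df = 232, p = 1e-174
```

Flow analysis from rendered microsphere videos, through detection and
tracking to the circular comparison:

```r
coh <- generate_flow_video(flow_config("coherent",     seed = 3))
dis <- generate_flow_video(flow_config("disorganized", seed = 4))
flow <- run_flow(list(list(stack = coh$frames, name = "wildtype"),
                      list(stack = dis$frames, name = "mutant")),
                 max_disp = 6, seed = 5)
flow$watson
#> Watson's two-sample U2 test of homogeneity
#>   groups: wildtype (n = 106) vs mutant (m = 105)
#>   U2 = 4.28394
#>   p = 0.001 (permutation, 999 relabelings, seed 5)
```

And the cohort worked example — one heterozygous carrier among 53
sequenced diploid individuals:

```r
allele_frequency(1, 53)
#> [1] 0.009433962   # 0.0094 at two significant figures
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/ependyflow` (subcommands `simulate`, `polarity`,
`rotational`, `flow`, `cohort`).

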