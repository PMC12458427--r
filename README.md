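# rotastat

Statistical analysis of per-particle rotational states of mitochondrial ATP
synthase from in situ cryo-electron tomography.

Subtomogram averaging with heterogeneity analysis assigns every ATP synthase
monomer in a tomogram a rotation angle of its F1 head and of its central
stalk about the complex axis (z), plus a displacement coordinate of the upper
peripheral stalk (UPS, ASA2/4). `rotastat` implements the statistics that
turn those per-particle states into biological conclusions, for structural
biologists analysing rotary-machine heterogeneity:

* **Rotational-state distributions** — the unimodal F1-head distribution
  (95% of particles within ±19°) and the trimodal central-stalk distribution
  with pseudo-c3 dwells at 120°, 0°, −120°.
* **Stalk–head coupling test** — F1 angles grouped into 20 bins of 18° of
  central-stalk state, each compared to the F1 reference distribution
  (n = 22,630) by a two-sample Kolmogorov–Smirnov test, combined with a
  tri-periodic sinusoid fit *a*·sin(3*x* − *b*) whose amplitude is assessed
  by a permutation test; plus a power analysis showing 20–30° coupling would
  be detected with power ≈ 1.
* **Angular resolution bound** — the smallest detectable rotation at radius
  *r* given local resolution (chord) *d*: θ = 2·arcsin(*d*/2*r*); for
  *d* ≈ 10 Å at *r* ≈ 30 Å, θ ≈ 19°.
* **c-ring symmetry inference** — a c1..c15 symmetry-imposition similarity
  scan and a per-degree rotational self-correlation curve, combined into an
  order call (c10 for the modelled ring).
* **Intradimer tests** — KS comparisons of partner-monomer distributions
  across sign/mode groups, testing whether dimer monomers move together.
* **UPS trajectory analysis** — 1 Å displacement buckets with box-plot
  statistics and the coupled mean F1 rotation (7 Å over 6.5°, middle-95%
  5 Å over 6°).
* **Volume primitives** — minimal MRC (mode 2) I/O, bicubic z-rotation,
  masked Pearson similarity, symmetry imposition, and z-contrast
  ice-thickness estimation for tomogram ranking (<150 nm selection).
* **Synthetic data** — calibrated particle-ensemble and phantom-volume
  generators so the whole pipeline is testable without any raw data.

See the methods vignette (`vignettes/rotastat-methods.Rmd`) for the model,
calibration constants, and design decisions.

## Worked example

```r
library(rotastat)

# synthetic ensemble at the study scale: 11,315 dimers = 22,630 monomers
tab <- make_particle_table(n_dimers = 11315, seed = 1)

quantile(tab$theta_f1, c(.025, .975))   # -19.1, 19.0  -> 95% within ~±19 deg
find_angle_modes(tab$theta_stalk)       # -120.0, 0.0, 119.7 -> stalk dwells

res <- coupling_test(tab, n_perm = 999, seed = 2)
res$sinusoid$a                          # 1.22 deg  (fitted coupling amplitude)
res$sinusoid$permutation_p              # 0.099     (not significant)
min(res$bin_p, na.rm = TRUE)            # 0.077     (no bin deviates from reference)
res$decision                            # "not_detected"

intradimer_tests(tab)$f1_sign_p         # 0.13      (monomers independent)

tr <- trajectory_bin_stats(tab)
tr$full_span                            # 6.98 A, 6.88 deg
tr$middle95_span                        # 4.88 A, 5.33 deg

angular_resolution_deg(10, 30)          # 19.19 deg
```

The ensemble is drawn under the null (no stalk–head coupling), and the
pipeline reproduces the headline findings on it: the F1 and stalk
distributions match their calibration, the coupling detectors stay at their
nominal level (`"not_detected"`), monomers within dimers are independent,
and the UPS trajectory spans ~7 Å (middle 95%: ~5 Å) for ~6.5° of coupled F1
rotation.

A c-ring symmetry call on a phantom:

```r
ph <- make_cring_phantom(n_sub = 10, radius = 30, blob_sd = 4,
                         box = 64, voxel = 2, noise_sd = 0.05, seed = 1)
m <- ring_mask(radius = 30, blob_sd = 4)
inf <- infer_order(symmetry_order_scan(ph, mask = m),
                   self_rotation_curve(ph, mask = m))
inf$order         # 10
inf$minima_count  # 10 evenly spaced self-correlation minima
```

A thin CLI over the same functions ships in `inst/scripts/rotastat`
(subcommands `simulate`, `symmetry`, `couple`, `dimer`, `trajectory`,
`power`, `angres`, `report`).

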