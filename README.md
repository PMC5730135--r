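# dispquant

Area-based quantification of hard- and soft-tissue displacement between two
rigidly superimposed 3D scans.

## The problem

After orthognathic (jaw) surgery, outcome studies ask two questions of a
pre-surgical scan (T1) and a follow-up scan (T2): how far did the bone move,
and how far did the overlying soft tissue follow? `dispquant` implements the
area-based closest-point protocol used to answer them with cone-beam CT:

* **voxel-based rigid superimposition** of T2 onto T1 by maximizing mutual
  information over the surgically unaltered cranial base (6 degrees of
  freedom, T1 always the reference frame);
* **label-separated surface extraction**: maxilla + upper teeth,
  mandible + lower teeth, and soft tissue are distinct labels, each meshed
  separately, so a closest-point search can never match a lip against teeth
  (the *label firewall*);
* **painted surface regions**: signed closest-point displacement statistics
  (minimum, maximum, mean) over operator-selected areas of the reference
  mesh — for each region vertex `v` with outward normal `n` and closest
  target point `c`,

  `d(v) = sign(⟨c − v, n⟩) · ‖c − v‖`,

  and the region mean of `d` is the study quantity;
* the **statistical layer** of such studies: intra-rater ICC(A,1)
  repeatability with between-session difference tables, descriptive
  statistics, and Spearman rank correlation matrices (exact permutation
  p-values at n ≤ 9) split into maxillary and mandibular area sets.

Because no patient data are available, the package ships a first-class
**phantom generator**: primitive skulls with flat anterior jaw faces, known
per-label rigid "surgery", a soft-tissue shell displaced as a noisy scaled
copy of its jaw's displacement, an uncoupled nose shell, a rigid nuisance
head pose, and an analytic scanner PSF imaging model. Every validation claim
is made against this known ground truth.

The package also quantifies the method's failure modes: measuring 100% of a
surface grossly underestimates displacement wherever surfaces overlap (the
area-size effect, with a closed-form reference in
`analytic_box_advance_mean()`), and regions mixing inward/outward change
trigger an explicit sign-mixing warning.

## Worked example

A box jaw with a 40 × 40 mm flat anterior face is advanced 5 mm; the painted
anterior region must read exactly 5 mm while the full-surface mean collapses
toward zero:

```r
library(dispquant)

spec <- box_jaw_spec()                      # 40x40 face, 20 mm deep, 0.5 mm voxels
ph   <- make_phantom(spec)
t2   <- apply_surgery(ph$volume, ph$labels, surgical_plan(maxilla_advance_mm = 5))

m1 <- extract_surface(ph$labels, "maxilla_upper_teeth")
m2 <- extract_surface(t2$labels, "maxilla_upper_teeth")

region <- paint_region(m1, c(28, 27.75, 28), radius_mm = 6, name = "anterior")
region_summary(region, m1, m2)
#>     region n_vertices min_mm max_mm mean_mm unsigned_mean_mm negative_fraction
#> 1 anterior       1793      5      5       5                5                 0

full_surface_summary(m1, m2)[, c("region", "mean_mm", "unsigned_mean_mm")]
#>           region mean_mm unsigned_mean_mm
#> 1 <full surface> -0.5837            2.561
```

The region mean recovers the planned 5 mm advancement exactly; the
full-surface signed mean (−0.58 mm) and unsigned mean (2.56 mm) show how
badly an unrestricted average misses it.

Cohort-level analysis mirrors the study tables:

```r
co  <- make_cohort(8, seed = 42)            # 8 subjects, U[1,5]/U[5,15] mm advancements
rep <- run_cohort(co, pipeline_config())    # register, extract, measure twice, correlate
rep$cor_mandibular                          # r below / p above, '*' = p < 0.05
tidy(rep$cor_mandibular)                    # long tibble of pairs
autoplot(rep$cor_maxillary)                 # ggplot heatmap
```

And the statistics layer is usable standalone:

```r
spearman(c(2.9, 4.4, 1.3, 5.0, 3.6, 2.2, 4.1, 1.8), ...)
#> Spearman rho = 0.976, two-sided p = 0.0003968 (n = 8, exact permutation)
```

A command-line front end (`exec/dispquant`) exposes
`simulate | register | extract | measure | correlate | run` over NIfTI,
binary STL (mm), JSON transforms/regions and CSV tables.

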