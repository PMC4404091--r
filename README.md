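# coilwatch

Quantitative longitudinal volumetry for coil-embolized cerebral aneurysms.

When a coiled aneurysm recurs, the conventional explanation is *coil
compaction* — the coil mass packing down and letting blood re-enter. The
competing explanation is *sac growth*: the aneurysm wall enlarges and the
intact coil mass shifts deeper into the sac. Telling them apart needs
objective 3D measurements across treatment and follow-up, not side-by-side
2D angiograms. `coilwatch` implements that measurement chain for paired 3D
rotational angiography sessions, plus a phantom generator with programmed
ground truth to validate every stage, and the statistical layer used to
compare cohorts.

## What it measures

Each 3DRA session contributes a *subtracted* volume (contrast-filled lumen)
and a *baseline* bone volume (coil mass). Across the four study time points
(pre/post first coiling `1-`/`1+`, pre/post second coiling `2-`/`2+`) the
package measures sac volumes V<sub>S1-</sub>, V<sub>S1+</sub>,
V<sub>S2-</sub>, V<sub>S2+</sub> and coil-mass volumes V<sub>C1+</sub>,
V<sub>C2-</sub>, then derives:

* **Sac growth** V<sub>SG</sub> under four prioritized definitions
  (V<sub>SG1</sub> = V<sub>S2+</sub> − V<sub>S1-</sub>,
  V<sub>SG2</sub> = V<sub>S2+</sub> − V<sub>S1+</sub>,
  V<sub>SG3</sub> = V<sub>S2-</sub> − V<sub>S1-</sub>,
  V<sub>SG4</sub> = V<sub>S2-</sub> − V<sub>S1+</sub>), the
  highest-priority computable one being reported; V<sub>SG</sub> > 0 means
  growth.
* **Coil growth** V<sub>CG</sub> = V<sub>C2-</sub> − V<sub>C1+</sub>;
  V<sub>CG</sub> < 0 means compaction.
* **Coil-center translation** δ: the Euclidean distance between the
  volume-weighted coil-mass centroids at 1+ and 2- — a candidate
  recurrence biomarker measurable on non-angiographic (bone) scans alone.

The segmentation chain is grayscale opening → Otsu threshold over a volume
of interest → seeded connected component → morphological level set for
subtracted scans, and grayscale closing → Otsu → internal-hole filling
(through-tunnels retained) → level set for the coil. Surfaces come from
marching tetrahedra (watertight by construction); volumes and centroids
are exact divergence-theorem integrals; the aneurysm sac is isolated from
its parent vessel by centerline tube subtraction, yielding a non-planar
neck surface. One-tailed exact Wilcoxon signed-rank and Mann–Whitney
tests, ROC/AUC with a Youden-optimal cutoff, and investigator-agreement
R² complete the analysis.

## A worked example

```r
library(coilwatch)

# one phantom: +20% programmed sac growth, 2 mm programmed coil translation
scn <- scenario(
  sac_semiaxes = list(`1m` = c(3, 3, 3), `1p` = c(3, 3, 3),
                      `2m` = c(3, 3, 3) * 1.2^(1/3),
                      `2p` = c(3, 3, 3) * 1.2^(1/3)),
  coil_center_offset = c(2, 0, 0),
  grid_shape = c(72, 72, 72), seed = 7)
subj <- make_subject(scn)
sv   <- run_subject(subj, seg = list(levelset = levelset_params(iterations = 20)))
growth_result(sv)[, c("vsg", "vsg_definition", "pct_vsg", "pct_vcg", "delta")]
#>          vsg vsg_definition  pct_vsg    pct_vcg    delta
#> 1 0.02243656              1 19.83106 -0.1301905 1.992621
```

The measured growth (19.8%) recovers the programmed +20%, the coil volume
is stable (−0.13%, no programmed compaction), and the coil-center
translation (1.99 mm) recovers the programmed 2 mm to within a tenth of a
voxel. Definition 1 was used because all four time points were available.

At cohort level:

```r
coh   <- make_cohort(15, 12, seed = 1)   # 15 recurrence, 12 control phantoms
study <- run_study(coh, seg = list(levelset = levelset_params(iterations = 20)))
study
#> recurrence VSG: p = 3.1e-05 (n=15)   control VSG: p = 0.38 (n=12)
#> VCG: p = 0.49 / 0.52 (no compaction in either cohort)
#> delta Mann-Whitney one-tailed p = 5.8e-08, ROC AUC = 1.0, cutoff 1.38 mm
```

Growth is detected in the recurrence cohort only, compaction in neither,
and δ separates the cohorts — the qualitative fingerprint of sac growth,
not coil compaction, as the recurrence mechanism.

The packaged demographics table is available via `read_table1()` and
`demographics_summary()` (cohort sizes, median clinical sac sizes 10 vs
6.5 mm, counts ≥ 10 mm, per-patient follow-up, and the between-cohort size
comparison).

A thin command-line wrapper lives at `inst/cli/coilwatch.R`
(`simulate`, `measure`, `analyze`, `demographics` subcommands).

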