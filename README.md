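# psoctfib

Automatic detection, segmentation and quantification of subretinal
fibrotic lesions in 3D polarization-sensitive OCT (PS-OCT) volumes.

Subretinal fibrosis is a major cause of irreversible vision loss in
neovascular age-related macular degeneration, and no conventional
imaging modality quantifies it objectively: on OCT it hides inside
subretinal hyperreflective material, on fundus photography grading is
subjective.  Fibrotic tissue, however, is *birefringent*, and — unlike
every other posterior tissue once anterior birefringence is removed —
shows a **locally uniform optic axis orientation**.  `psoctfib`
implements the full processing chain that turns this into a lesion
area in mm², plus a layered digital eye phantom that makes the chain
testable end-to-end without clinical data.

## The method

For a single-input-state PS-OCT system (vertical input, quarter-wave
plate at 45°), each voxel's two complex detection channels yield

- reflectivity *R* ∝ A²_H + A²_V,
- double-pass retardation δ = arctan(A_V/A_H) ∈ [0°, 90°],
- axis orientation θ = (π − ΔΦ)/2 ∈ [−90°, 90°),

and the degree of polarization uniformity (DOPU) from kernel-averaged
Stokes vectors.  The pipeline then:

1. **Compensates anterior birefringence** (cornea, RNFL, Henle's fiber
   layer).  In double pass the whole anterior stack is a single
   effective linear retarder (Jones reversibility), measured directly
   at a reference surface below the HFL; a compensator
   J(−δ_R, θ_R) applied on both sides of each voxel's reconstructed
   joint retarder removes it.  The single-step approximation errs by at
   most ≈1.2° in axis for a 20° cornea + 14° HFL (an exact two-step
   variant is included), adding < 10⁻⁵ circular variance in a 5×5
   kernel — negligible against the segmentation thresholds.
2. **Builds a depth-averaged axis map** between the reference surface
   and a lower boundary (100 px deep centrally, 50 px at the edges,
   Gaussian transition) that excludes the birefringent sclera, masking
   out depolarizing RPE voxels (DOPU < 0.8) and voxels below 2× the
   intensity noise floor.  Angles are averaged as exp(i2θ) because
   axes are π-periodic.
3. **Segments by axis uniformity**: circular variance
   v = 1 − |mean(exp(i2θ))| in 5×5 kernels; seeds are connected
   regions of v < 0.21 larger than 100 px; seeded region growing adds
   neighbors with v < 0.36; pixel counts convert to mm²
   (187.5 µm²/px at the standard 1024×250 / 8×6 mm geometry).
   A threshold sweep (th₁ = 0…0.85, th₂ = th₁+0.15) yields per-pixel
   likelihood maps L_h = 1 − th₂*, and 41×41 variance B-scans
   visualize the depth columns of uniform axis in severe fibrosis.

## Worked example

```r
library(psoctfib)

# simulate the default desk-scale eye: 256 x 64 x 512 voxels over
# 8 x 6 mm, cornea 20 deg, HFL doughnut 14 deg, one 3.8 mm^2 lesion
sim  <- generate_phantom(phantom_spec(), seed = 1)
pol  <- extract_polarization(sim$tomogram)
noise <- estimate_noise_floor(pol)
surf <- find_surfaces(pol, noise = noise)
comp <- compensate(pol, sample_reference(pol, surf$reference, smooth = c(1, 1)))
amap <- depth_averaged_axis(comp, surf, dopu = compute_dopu(pol),
                            noise_floor = noise)
mask <- segment_fibrosis(amap)
mask$area_mm2
#> [1] 3.47168
lesion_area(sim$truth$lesion_mask, pitch = amap$pitch)  # ground truth
#> [1] 3.820312
```

The segmented area is within ~10% of the ground truth (the variance
kernel erodes roughly one pixel at the lesion boundary); across three
speckle seeds the areas are 3.472, 3.445 and 3.448 mm² (seed-to-seed
SD 0.3%), with Dice overlap ≈ 0.95 against the true lesion mask.  The same chain runs
from the command line via `inst/cli/psoctfib.R` (`simulate` and `run`
subcommands) or in one call with `run_pipeline(pipeline_config())`,
which writes axis/variance/mask/likelihood maps (PNG), a per-lesion
`report.csv` and the effective configuration (YAML, hash-stamped file
names).

Repeated measurements are summarized with
`lesion_repeatability(c(7.94, 8.57, 7.05))`, giving mean 7.853 mm²,
population SD 0.624 mm² (8%).

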