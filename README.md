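# heartnc

Reconstruction of patient-specific **3D heart volumes from 2D planar
radiotherapy planning images**, for retrospective cardiac dosimetry in
patients who were planned on simulator films and therefore have no CT.

The package implements the navigator-channel (NC) adaptation technique
end to end:

1. **Population heart model** — voxelwise OR of several patients' binary
   heart masks, watertight surface extraction (`mask_union()`,
   `mask_to_mesh()`).
2. **Reference matching** — thorax measurements `(W1, W2, L)` on the
   anterior radiograph, compared within gender/group by the least-squares
   difference
   `LSD = sqrt((W1t-W1r)^2 + (W2t-W2r)^2 + (Lt-Lr)^2)`
   (`measure_thorax()`, `lsd()`, `select_matches()`).
3. **Edge shifts** — six rectangular navigator channels on the matched
   DRR pair (4 horizontal at the chamber circumflexes, 2 vertical at the
   superior/inferior edges); each yields a 1D intensity profile whose
   point of inflection (zero crossing of the smoothed second derivative at
   the maximum rate of intensity change) marks the organ edge; the
   per-channel shift is the POI difference (`place_channels()`,
   `extract_profile()`, `detect_poi()`, `compute_shift()`).
4. **Adaptation** — the population-to-Reference displacement field
   `Delta` is rescaled per node by the channel ratios
   `(DeltaNC + dNC) / DeltaNC`, blended linearly (upper/lower regions,
   superior-inferior) or bilinearly (middle region) by the node's
   normalized position, leaving anterior-posterior displacements
   untouched; applying the adapted field to the population model yields
   the Test-specific 3D heart (`adapt_field()`, `reconstruct()`).
5. **Evaluation** — Dice volume overlap
   `Dice = 2|V1 ^ V2| / (|V1| + |V2|) x 100` after center-of-mass
   alignment, cohort summaries, paired t-tests (`dice()`, `paired_t()`).

A deterministic phantom module (synthetic hearts in an attenuating thorax
with ribs, spine and graticule-equivalent geometry) makes the whole
pipeline testable with known ground truth; see the methods vignette
(`vignettes/navigator-channel-adaptation.Rmd`) for the model, parameter
choices, and what the phantom world does and does not establish.

## Worked example

Matching two patients by thorax measurements:

```r
library(heartnc)
ref  <- thorax_measurements("ref_M1", "M", W1 = 15.0, W2 = 24.8, L = 14.3)
test <- thorax_measurements("M1",     "M", W1 = 14.7, W2 = 25.3, L = 14.4)
round(lsd(ref, test), 2)
#> [1] 0.59
```

`0.59` cm is the root-sum-of-squares distance between the two measurement
triples; the matched Reference for a Test patient is the same-group
candidate minimizing it.

Full pipeline on the seeded phantom cohort (15 Reference/Test pairs,
composite scale + translate + bend ground-truth deformations, ~1 min on
one CPU):

```r
cohort <- make_phantom_cohort(n_pairs = 15, seed = 1)
results <- run_cohort(cohort)
report <- run_evaluate(results)
sprintf("with NC %.2f +/- %.2f%%, without %.2f +/- %.2f%%, paired p = %.2g",
        report$with_nc$avg, report$with_nc$sd,
        report$without_nc$avg, report$without_nc$sd, report$paired$p)
#> [1] "with NC 95.98 +/- 2.16%, without 92.19 +/- 3.94%, paired p = 0.00011"
```

Read: reconstructing each Test heart from its 2D radiograph via
NC adaptation overlaps the true Test volume at 96.0% mean Dice, against
92.2% for the un-adapted Reference model — a significant improvement
(paired t), with a smaller spread. The same run is reproduced bit-for-bit
under the same seed.

## Command line

```sh
inst/cli/heartnc fixtures    --out runs/demo --seed 1 --n-pairs 15
inst/cli/heartnc match       --out runs/demo
inst/cli/heartnc shifts      --out runs/demo
inst/cli/heartnc reconstruct --out runs/demo
inst/cli/heartnc evaluate    --out runs/demo
```

Exit codes: 0 success, 2 validation error, 1 stage failure. All artifacts
are plain text (ASCII VTK/PLY meshes, PGM + JSON radiographs, CSV fields,
JSON provenance records with config echo and md5 digests).

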