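# nmpquant

Single-cell quantification of Sox2/T co-expression in 3D confocal stacks of
the caudal mouse embryo.

Neuromesodermal progenitors (NMPs) — the bipotent axial progenitors that
feed both the spinal cord and the paraxial mesoderm — are operationally
identified as nuclei co-expressing the neural factor Sox2 and the
mesodermal factor T (Brachyury). Turning a wholemount immunostained
z-stack into per-embryo NMP counts takes a chain of steps, each with its
own failure modes, and `nmpquant` implements that chain end to end:

1. **3D nuclear instance segmentation** of the DAPI counterstain —
   Gaussian smoothing, global (Otsu or fixed) foreground threshold, exact
   Euclidean distance transform, distance-maxima seeds, seeded watershed —
   plus the debris filter that discards objects of volume ≤ 2000 voxels,
   and a manual seed-and-grow control route for estimating the automated
   method's error as |K_auto − K_manual| / K_manual.
2. **Per-nucleus measurement**: arithmetic mean Sox2 and T intensity (8-bit
   arbitrary units, AU) over each nucleus's voxels, with centroid and
   volume.
3. **Per-sample threshold calibration** on four internal control regions
   (only-Sox2+, only-T+, mixed single positives, all-negative): an
   exhaustive grid search maximising agreement with the controls' expected
   statuses, midpoint tie-break.
4. **Four-way classification** (Sox2+T+, Sox2-only, T-only, negative;
   positivity is mean ≥ threshold) and **T-intensity level binning**
   (negative i < 7 AU; level 1, 7 ≤ i < 12; level 2, 12 ≤ i < 24; level 3,
   24 ≤ i < 36; level 4, 36 ≤ i < 48; level 5, i ≥ 48), with coordinate/
   class export for 3D rendering.
5. **Per-embryo statistics**: mean ± s.d., unpaired Student's t-test
   (pooled, df = nₐ + n_b − 2) and Welch-corrected test
   (Welch–Satterthwaite df), strict p < 0.05 significance, fold changes
   reported to 2 significant figures.
6. **Graft scoring**: donor-cell position on a neural-tube section
   expressed as a percentage of the NT perimeter (0% dorsal-right, 50%
   ventral, 100% dorsal-left), positional histograms split by axis vs
   tail-bud context, and cohort tissue-contribution percentages.

Because the reference imaging data are not publicly deposited, the package
includes a first-class **synthetic embryo-stack generator**
(`embryo_model()` / `generate_embryo_stack()`): ellipsoidal nuclei at
tissue density with a spatially structured double-positive domain flanked
by Sox2-high (rostral) and T-high (caudal, plus notochord stripe) domains,
rostrocaudal intensity gradients, additive noise and depth attenuation —
with exact ground truth, so every stage is validated by parameter
recovery.

## Worked example

```r
library(nmpquant)

model   <- embryo_model(n_nuclei = 300L, seed = 42L)   # ground-truthed stack
emb     <- generate_embryo_stack(model)
labels  <- segment_nuclei(emb$stack[, , , "dapi"],
                          segmentation_params(debris_volume_threshold = 20))
n_labels(labels)
#> [1] 300

records  <- quantify_nuclei(labels, emb$stack[, , , "sox2"],
                            emb$stack[, , , "t"])
controls <- control_records(generate_control_rois(emb), records)
thr      <- calibrate_thresholds(controls)
#> calibrated thresholds: Sox2 10.5 AU, T 10.5 AU (control agreement 100%)

cl <- classify_populations(records, thr)
cl$counts
#>   n_total n_double n_sox2_only n_t_only n_negative
#> 1     300       88          74       80         58

bin_t_levels(cl$records)$level_counts
#> NEG  L1  L2  L3  L4  L5
#> 131   5 136  17  10   1
```

All 300 synthetic nuclei are recovered, and the pipeline's 88 double
positives sit one nucleus away from the generator's ground truth of 89.
The classified table can be written for any 3D viewer with
`export_3d(records, "records.csv")` (fixed four-population colour legend
via `population_colours()`).

Statistics follow the field's reporting conventions:

```r
welch_t(c(98, 105, 91, 110), c(230, 241, 218, 236))
#> Welch two-sample t-test: t = -20.1631, df = 5.817, p = 1.32e-06 *

fold_change(2338, 960)$rounded   # late vs early double-positive counts
#> [1] 2.4
```

Whole runs are driven by a YAML config through `run_pipeline()` /
`read_run_config()` (or the CLI in `inst/cli/nmpquant.R`, subcommands
`generate`, `segment`, `quantify`, `classify`, `stats`, `score-graft`,
`run-all`); every intermediate is persisted and the run manifest records
the seed, all calibrated thresholds, debris-removal counts and MD5
checksums of every output, so reruns are bit-reproducible.

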