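# radialcells

Cell-type classification and sub-cellular fluorescence quantification for
confocal images of radially organized plant sections.

## The problem

Transverse sections of stem-like plant organs (hypocotyl, stem) show a
radial anatomy: rings of xylem vessels and parenchyma, cambium, phloem and
cortex around a central origin. Cell-wall chemistry — probed with
fluorescently visualized monoclonal antibodies against wall epitopes — is
a stable marker of cell differentiation, but extracting it from laser
scanning confocal images has traditionally meant drawing regions of
interest by hand: slow, subjective, and hopeless at the scale of mutant
screens. `radialcells` automates the whole chain for two-channel images in
which channel 1 is a cell-wall counterstain (e.g. calcofluor white) and
channel 2 the immunofluorescence signal:

1. **Segmentation** of the counterstain into per-cell regions — whole cell
   (ROIC), lumen (ROIL), wall (ROIW = ROIC ∖ ROIL);
2. **Morphometrics** — 22 features per cell (position, shape, intensity);
3. **Classification** of every cell into user-defined cell types with a
   Random Forest and a per-cell confidence score;
4. **Quantification** of the signal channel per cell, per sub-cellular
   region, and per radial quadrant, with derived polarity and total-signal
   measures and per-class summaries.

A ground-truthed synthetic tissue generator makes every stage testable
without microscopy data.

## The method in brief

Cells are recovered by a minima-seeded **watershed** on the smoothed
counterstain (Gaussian variance 1 px² by default): basins grow from dark
lumens, dams form on bright walls. Over-segmentation is corrected by
merging adjacent regions whose **dam saliency**

S(a, b) = min<sub>p∈D<sub>ab</sub></sub> I(p) − max(m<sub>a</sub>, m<sub>b</sub>)

(dam minimum minus the higher of the two basin minima) falls below 10
intensity units, iteratively, lowest saliency first. Within each cell,
**Otsu's threshold** over the cell's own histogram splits lumen from wall.
Each ROI is divided into four 90° quadrants about the radial axis from a
user-supplied tissue center: quadrants 3/4 are the outer/inner periclinal
sectors, 1/2 the anticlinal ones. A Breiman **Random Forest** (500 trees,
untransformed features, mandatory seed) classifies cells; the confidence
score of a cell is the fraction of trees voting for its winning class,
and filtering at 50/70/90 % trades coverage against misclassification.
Per-quadrant signal statistics yield derived measures such as
`Wallsignal` (total wall signal) and `WallRPA` (periclinal : anticlinal
wall signal ratio).

## Worked example

Generate a synthetic six-ring hypocotyl-like tissue, segment it, train a
classifier on the ground-truth classes, and quantify a wall-restricted
signal:

```r
library(radialcells)
library(dplyr)

gen <- generate_radial_tissue(default_tissue_spec(seed = 1))
seg <- segment_cells(gen$image, segmentation_params(1, 10))
seg
#> <cell_segmentation> 512 x 512 px, 152 cells

frame    <- tissue_frame(gen$truth$spec$center_xy, pixel_size_um = 0.7)
features <- compute_feature_table(seg, attr(seg, "smoothed"), frame)
features |> select(cell_id, radialV, s.area, m.eccentricity, MedianROIW) |> head(4)
#> # A tibble: 4 × 5
#>   cell_id  radialV s.area m.eccentricity MedianROIW
#>     <int>    <dbl>  <dbl>          <dbl>      <dbl>
#> 1       1   0.0205 32073.        0.00810       61.8
#> 2       2 164.       810.        0.885         66.6
#> 3       3 164.       654.        0.819         70.0
#> 4       4 165.       735.        0.862         76.3
```

Cell 1 is the central pith basin (radius ≈ 0, huge area); the rest are
cells with areas in micrometres squared and their radial position. Train
on ground-truth labels matched by intersection-over-union, then rank
features and summarize the signal channel per class:

```r
matches <- match_segmentation(seg$roic, gen$truth$label_map)
annotations <- matches$matches |>
  filter(iou >= 0.7) |>
  inner_join(gen$truth$cells |> select(true_id = cell_id, class),
             by = "true_id") |>
  transmute(cell_id = pred_id, class)

model <- train_random_forest(features, annotations, n_trees = 500, seed = 7)
model
#> <cell_classifier> 500 trees, 18 features, 6 classes, 150 training cells
#>   OOB error: 0.027; seed 7
tidy(model) |> head(3)
#> # A tibble: 3 × 3
#>   feature    permutation impurity
#>   <chr>            <dbl>    <dbl>
#> 1 radialV           37.7     34.0
#> 2 MeanROIW          22.9     19.1
#> 3 MedianROIW        21.3     14.7

preds     <- predict_with_confidence(model, features)
corrected <- background_correct(gen$image$signal, seg$roic)
quad      <- assign_quadrants(seg, frame)
qm        <- quantify_roi_quadrants(corrected, seg, quad, frame)
summary   <- summarize_by_class(derive_measures(qm), preds, threshold = 0.7)
summary |> filter(measure == "Wallsignal") |> arrange(desc(mean))
#> # A tibble: 6 × 6
#>   class             measure    n_cells     n   mean    sd
#>   <chr>             <chr>        <int> <int>  <dbl> <dbl>
#> 1 xylem_vessel      Wallsignal      14    14 13387. 3085.
#> 2 xylem_parenchyma  Wallsignal      24    24   116.  186.
#> 3 cambium           Wallsignal      30    30     0     0
#> 4 cortex            Wallsignal      24    24     0     0
#> 5 phloem_fiber      Wallsignal      28    28     0     0
#> 6 phloem_parenchyma Wallsignal      30    30     0     0
```

The generator placed channel-2 signal only in the xylem-vessel ring's
walls; the quantification recovers exactly that: `radialV` dominates the
importance ranking, vessels carry a wall signal two orders of magnitude
above every other class, and the small parenchyma signal is boundary
bleed at the vessel–parenchyma interface. `autoplot(seg)`,
`autoplot(model)`, `plot_feature_map()` and `plot_class_summary()` render
the corresponding diagnostics.

For batch work, `build_experiment_catalog()` catalogues a folder of
images named `plate_antibody_genotype_age_tissue_replicate.tif`,
`run_training()` / `run_quantification()` / `run_assembly()` drive the
three pipeline stages, and `export_compiled_data()` writes the compiled
per-cell CSV (`DataRawCompile.csv`: metadata, class, confidence, the 22
features, the per-quadrant block in C/L/W order, the derived measures).
A thin command-line wrapper with `catalog` / `synth` / `segment` /
`train` / `quantify` / `assemble` subcommands ships in `inst/exec/`.

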