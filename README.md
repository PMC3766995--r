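# minkograde

Minkowski-functional texture analysis and symbolic classification of AFM
tissue height maps.

## What this is for

Grading astrocytic brain tumors from histology is subjective enough that
experienced pathologists disagree. Atomic force microscopy (AFM) of
unstained sections offers an objective alternative signal: low-grade
(WHO II) tissue shows a dense meshwork of fine neuropil fibres with small
cavities, while glioblastoma (WHO IV) degenerates into a pulpy mass with
irregular large cavities. That difference is *topological*, and this package
quantifies it.

A height map is flattened (global first-order plane fit), rank-equalized to
256 gray levels, and thresholded at every level `t = 0..255` into a stack of
binary level sets (foreground = gray ≥ t). For each level set the three 2-D
Minkowski functionals are computed:

* area `A(t)` — foreground pixel count,
* contour length `P(t)` — foreground/background pixel-edge count
  (exterior counts as background),
* Euler characteristic `χ(t)` — number of 8-connected foreground objects
  minus number of 4-connected interior holes, computed by 2×2 quad
  counting: `χ = (Q₁ − Q₃ − 2·Q_d)/4`.

The Euler and contour curves are reduced to 15 geometric descriptors
(extremum values/positions, zero crossing, smoothed maximum slope, areas
under the curves, width, centroid), which feed a strongly typed
genetic-programming classifier — Boolean expression trees over arithmetic,
comparison and logical operators — evaluated with stratified, repeated
cross-validation and a 24-cell parameter grid. Group mean curves with 1σ
bands, extreme-value ratios and non-overlap gray-level bands (single-feature
classification) are produced along the way. A synthetic tissue-texture
generator emulates both morphologies so the whole chain is testable without
clinical data.

## Worked example

Simulate the two texture classes at the reference class sizes, run the full
pipeline, and cross-validate the classifier:

```r
library(minkograde)

cfg <- pipeline_config(
  out_dir = "run",
  simulate = list(n_gradeII = 54, n_gradeIV = 59, image_size = 256),
  gp = gp_config(max_generations = 70, max_tree_length = 50,
                 n_runs = 10, n_folds = 10),
  seed = 11)
rep <- run_pipeline(cfg)

print(rep$stats$gradeII)
#> Group 'gradeII' (n = 54 curves)
#>   mean Euler minimum -2350 at gray level 42
#>   mean Euler maximum 308 at gray level 245
#>   mean contour-length maximum 28500 at gray level 91
print(rep$stats$gradeIV)
#> Group 'gradeIV' (n = 59 curves)
#>   mean Euler minimum -1570 at gray level 77
#>   mean Euler maximum 368 at gray level 215
#>   mean contour-length maximum 21800 at gray level 129
print(rep$stats$band)
#>   start end
#> 1     3  39
#> 2   133 156
#> 3   238 251
```

The grade II group has the deeper Euler minimum (−2350 vs −1570: more
enclosed dark cavities between the dense fibres) and the larger contour
maximum (28 500 vs 21 800 pixel edges: more fine-structure boundary), the
same ordering the method exploits on real tissue. Three gray-level bands
separate the groups by more than one standard deviation; the mean Euler
value over the widest band alone cross-validates at 0.99, and the evolved
15-feature model reaches a best-run CV accuracy of 0.975:

```r
print(rep$classification$result)
#> GP cross-validation: 10 runs x 10 folds
#>   mean accuracy 0.9500 +/- 0.0176 (sd across runs)
#>   best run 4: accuracy 0.9750
```

All artifacts (equalized PNGs, `curves.csv`, `features.csv`, `stats.csv`,
`band_report.json`, `classification.json`, the resolved `config.json`) are
written under `out_dir`; rerunning the same configuration reproduces them
byte for byte.

A thin CLI wraps the same functions
(`exec/minkograde simulate|preprocess|curves|features|stats|classify|run`).

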