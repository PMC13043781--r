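# cultimap

Unsupervised pixel-based mapping of cultivated land from 4-band (blue, green,
red, near-infrared) multispectral digital-number rasters.

Agencies and agronomists who need the cultivated share of a region — for crop
inventory, irrigation planning or land management — often have high-resolution
imagery but no labeled training data. `cultimap` segments each pixel into
**background** (zero-padded frame), **bare soil** or **crops** and reports the
cultivated-area percentage, using four classifiers:

* **NIR threshold** — NIR = 0 → background, (0, 700] → soil, > 700 → crops;
* **NDVI threshold** — NDVI = (NIR − Red)/(NIR + Red); ≤ 0.2 → soil,
  > 0.2 → crops;
* **K-means on raw bands** — (NIR, Red, Blue), min-max normalized to [0, 1],
  k = 3;
* **Spectral K-means** — (NDVI, MNDWI, NIR) with
  MNDWI = (Green − NIR)/(Green + NIR), normalized, k = 3: vegetation
  greenness, a green/NIR contrast and raw NIR brightness jointly separate the
  three classes better than any single band or index.

The K-means is a from-scratch, seeded Lloyd's algorithm (Forgy
initialization, Euclidean assignment with deterministic tie-breaks,
mean updates, empty-cluster repair, logged inertia trajectory, multi-start).
Accuracy against a binary ground-truth mask is scored by the relative error
|detected − actual| / actual × 100.

Because sub-meter imagery of this kind is usually access-restricted, the
package includes a synthetic scene generator with known truth
(`benchmark_scene_spec()`: 512×512, 71.19% cultivated, calibrated spectral
overlap) so the whole pipeline is testable end-to-end. All eight common
vegetation/water indices (NDVI, EVI, SAVI, GCI, CVI, DVI, NDWI, MNDWI) are
provided; rasters travel as 16-bit multiband TIFF with plain-text `.tfw`
world files.

## Worked example

```r
library(cultimap)

gen <- generate_scene(benchmark_scene_spec(seed = 0))
gen$true_cultivated_percent
#> [1] 71.19141

cm <- classify_kmeans(build_spectral_stack(gen$scene), gen$scene, seed = 0)
area_report(cm, mask = gen$mask)
#> <area_report> [spectral-kmeans]
#>   pixels: background 31744, soil 46341, crops 184059 (0.25 m2/px)
#>   cultivated: 70.21% detected vs 71.19% reference -> relative error 1.37%
```

The spectral K-means recovers the known 71.19% cultivated share to within
about 1.4%, while on the same scene the NIR threshold errs by 8.1% (it loses
the crop pixels whose NIR noise dips below 700) and the NDVI threshold by
3.1%. Per-pixel agreement beyond the area-level score:

```r
agreement_table(cm, gen$mask)
#>            mask
#> prediction  cultivated uncultivated
#>   crops         183682          377
#>   non_crops       2942        75143
```

From the shell, via the bundled CLI (`inst/cli/cultimap.R`):

```sh
Rscript inst/cli/cultimap.R simulate --scene s.tif --mask m.tif --benchmark --seed 0
Rscript inst/cli/cultimap.R compare  --scene s.tif --mask m.tif --seed 0
Rscript inst/cli/cultimap.R classify --scene s.tif --classifier spectral-kmeans \
        --out-labels labels.tif --out-png labels.png --out-report report.json
```

`compare` prints a method/error table; `classify` writes the label raster
(codes 0/1/2), a white/brown/green composite and a JSON area report. Exit
codes: 0 success, 1 input error, 2 computation error.

See `vignettes/cultivated-land-mapping.Rmd` for the model, the numerical
conventions (degenerate-denominator handling, normalization, cluster
labeling) and the design of the synthetic benchmark.

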