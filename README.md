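# ciseg

Segmentation of grayscale images contaminated by **speckle noise** — the
signal-dependent multiplicative noise (`J = I + u·I`) typical of
ultrasound and SAR imagery — using a statistical pre-filter followed by
multi-level Otsu thresholding.

Plain histogram thresholding degrades badly under speckle: the noise
spreads each tissue/material level into a wide, signal-dependent lobe and
the threshold search fragments homogeneous regions. `ciseg` inserts a
cheap, single-pass pre-stage built on the confidence interval for a
sample mean:

1. compute the population standard deviation σ of all pixel intensities;
2. split the image into `np` sub-images (tiles) of `ia × ja` pixels;
3. compute each tile's sample mean x̄;
4. keep a pixel `A_k(i,j)` only if it lies strictly inside the band

       x̄ − z·σ/√(ia·ja)  <  A_k(i,j)  <  x̄ + z·σ/√(ia·ja)

   (default `z = 1.96`, the two-sided 95 % standard-normal quantile),
   otherwise replace it by x̄ (tile min/max are options);
5. recompose the tiles and segment the result with multi-level **Otsu**:
   the `m` thresholds (default `m = 3`, four classes) that maximize the
   between-class variance σ_B² = Σ_k ω_k (μ_k − μ_T)² of the 256-bin
   intensity histogram, found exactly and deterministically.

The band contains the high-information content of a locally homogeneous
tile; pixels outside it are predominantly speckle excursions, and
replacing them with the tile mean suppresses the noise while leaving
in-band structure untouched. By the Central Limit Theorem the normal
band is appropriate for tile sample sizes of a few dozen pixels or more
even though speckle itself is far from Gaussian (defaults use
`8 × 8 = 64`).

The package also provides synthetic piecewise-constant phantoms with
ground-truth labels, speckle/Gaussian noise generators, Jaccard–Dice and
label-accuracy evaluation, PNG/TIFF/PGM input and output, and a CLI.

## Worked example

```r
library(ciseg)

ph    <- make_phantom(256, 256, n_classes = 4, seed = 1)  # truth labels
noisy <- add_speckle(ph$image, variance = 0.12, seed = 2) # sigma ~ 0.23
fit   <- ci_otsu_segment(noisy)                            # CI + Otsu
ref   <- ci_otsu_segment(noisy, prefilter = FALSE)         # plain Otsu
fit
#> CI + Otsu segmentation of a 256 x 256 image
#>   pre-filter: tile 8x8, z = 1.96, sigma = 0.22998, np = 1024, retention = 0.7717
#>   Otsu: 3 thresholds over 256 bins -> 57, 122, 181 (intensities 0.223, 0.477, 0.707)

label_accuracy(fit$labels, ph$labels)   #> 0.9616852
label_accuracy(ref$labels, ph$labels)   #> 0.91745

b <- binarize(ph$image, 0.5)            # binary protocol at level 0.5
jaccard(binarize(labels_to_gray(fit$labels, noisy), 0.5), b)
#> Jaccard = 0.8767, Dice = 0.9343
jaccard(binarize(labels_to_gray(ref$labels, noisy), 0.5), b)
#> Jaccard = 0.7209, Dice = 0.8378
```

The pre-filter keeps 77 % of the pixels of this noisy phantom and lifts
per-pixel accuracy from 0.917 to 0.962 (Jaccard at the 0.5 binarization
level from 0.72 to 0.88) relative to running Otsu directly on the noisy
image. `plot(fit)` displays the label map; `summary(fit)` adds class
pixel counts.

The same chain from a shell:

```sh
ciseg=$(Rscript -e 'cat(system.file("cli", "ciseg", package = "ciseg"))')
Rscript $ciseg simulate phantom --size 256x256 --classes 4 --seed 1 \
        --out ph.png --truth truth.png
Rscript $ciseg simulate noise --kind speckle --variance 0.12 --seed 2 \
        --in ph.png --out noisy.png
Rscript $ciseg segment --in noisy.png --out labels.png --levels 3
Rscript $ciseg evaluate --pred labels.png --truth truth.png --image ph.png
```

Every run logs its parameters, image shape, tile count `np`, σ, the
retention fraction and the chosen thresholds to standard error, so runs
are reproducible from their logs.

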