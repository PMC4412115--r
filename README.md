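# phenoscope

Automated single-cell phenotype classification for cyanobacterial
fluorescence micrographs.

Ethanol-producing strains of *Synechocystis* sp. PCC6803 and *Synechococcus*
sp. PCC7002 down-regulate phycocyanin, which changes how single cells look
under a fluorescence microscope: wild-type and revertant cells fluoresce
**red**, producing cells appear **orange** (red ≈ green signal, dimmer), and
dead cells show only an unspecific **green** fluorescence. Counting these
three classes per cell is a fast way to monitor producer cultures for
revertants — something bulk absorption spectroscopy (the PC/Chl ratio,
A(620)/A(680)) can only see as a population average. This package is aimed
at people running or simulating such strain-stability assays.

## What it does

The analysis chain, per micrograph:

1. **Flat-field correction** against a blank (no-sample) image:
   `I' = I · mean(B)/B` per channel, blank median-smoothed 5×5
   (`correct_illumination()`).
2. **Segmentation**: maximum-entropy (Kapur) thresholding of the red and
   green channels separately — the threshold t maximizes
   H(levels ≤ t) + H(levels > t), the summed Shannon entropies of the
   background and foreground intensity distributions — mask union,
   8-connected particle registration, exclusion of particles < 10 px or
   touching the image edge (`kapur_threshold()`, `segment_cells()`).
3. **Features**: per-particle normalized hue histogram (32 bins over the
   hexcone hue, red ≈ 0, green ≈ 1/3) plus mean brightness
   (`particle_features()`).
4. **Classification**: a one-hidden-layer feed-forward network (sigmoid,
   default 10 hidden units) trained by resilient propagation with a
   genetic-algorithm phase whenever the error rate stalls (< 1% relative
   change over 20 epochs), run until 0% training error (`phenonet()`).
5. **Reporting**: per-sample counts and fractions of the three classes with
   exclusion tallies (`analyze_sample()`).

Because no annotated micrographs of these strains are deposited anywhere,
the package includes a synthetic micrograph generator with ground truth
(`render_scene()`) and an in-silico reconstruction of the wild-type/producer
mixing validation (`mixing_experiment()`). Culture-level spectrum utilities
(`normalize_spectrum()`, `pc_chl_ratio()`) round out the toolkit.

## Worked example

Train a network on synthetic pure-phenotype samples, then analyze a
simulated sample of 1000 cells mixed at 23% wild type / 72% producer / 5%
dead:

```r
library(phenoscope)

ts <- synthetic_training_set(n_per_class = 100, seed = 1)
model <- phenonet(ts$x, ts$y, seed = 1)
print(model)
#> Phenotype network: 33 -> 10 -> 3 (sigmoid)
#> training error 0.00% after 5 epochs, 0 GA phase(s)

scenes <- lapply(1:20, function(j)
  render_scene(scene_config(n_cells = 50,
                            class_fractions = c(0.23, 0.72, 0.05),
                            seed = 100 + j)))
report <- analyze_sample(lapply(scenes, `[[`, "image"),
                         scenes[[1]]$blank, model)
print(report)
#> Sample report: 20 of 20 image(s) analyzed
#>   registered particles : 6479
#>   excluded             : 5479 ( 5479 by size, 88 touching border )
#>   WT_RED          :   218 ( 21.8%)
#>   PRODUCER_ORANGE :   722 ( 72.2%)
#>   DEAD_GREEN      :    60 (  6.0%)
```

The 5479 size-excluded "particles" are read-noise specks removed by the
10-px area filter; the 1000 true cells all survive, and the recovered
fractions (21.8 / 72.2 / 6.0%) match the simulated mixture (23 / 72 / 5%)
to within binomial sampling error of a 1000-cell draw.

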