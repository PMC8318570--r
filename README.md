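# modalseg

Anatomical segmentation of 3D brain volumes across imaging modalities —
T1-weighted MRI, FLAIR, DWI and CT — with a quality gate that tells you
when not to trust the result.

Conventional segmentation suites are built around T1-weighted scans, where
gray/white-matter contrast is strong. Clinically important contrasts (FLAIR,
DWI) and CT are typically unsupported, even though they carry substantial
anatomical soft-tissue information. `modalseg` implements the
learning-based alternative end to end, for users who want a complete,
inspectable CPU implementation of the method in R:

1. **Coregistration.** The input scan is affinely registered to a reference
   volume by maximizing normalized mutual information (cross-modal capable),
   with a deterministic multi-resolution Nelder–Mead search over 12 affine
   parameters.
2. **Resampling + normalization.** The registered scan is resampled with
   cubic splines to the network grid and intensities are mapped to
   *I* = [0, 100] by percentile clipping.
3. **Segmentation.** A 3D U-Net (depth *D*, base width *F*, kernel 3³;
   encoder/decoder blocks of two conv–batchnorm–ReLU operations with
   dropout after each block but not in the bottleneck) produces a softmax
   map *P\_s(x)* per class; the hard segmentation is
   *S(x) = argmax\_s P\_s(x)*. The convolution kernels are
   Rcpp/RcppArmadillo (im2col + BLAS); training uses Adam on the combined
   loss *L = −Σ\_s Dice\_s + CE* with early stopping on validation loss.
4. **Uncertainty gating.** At inference, dropout stays active and *N* = 15
   Monte-Carlo samples are drawn; the final mask is
   *argmax\_s Σ\_i P\_s^i(x)* and the coefficient of variation of each
   structure's volume across samples, *CV\_s = σ\_s/μ\_s*, is averaged into
   a single *CV* that flags corrupted inputs or low-quality segmentations.
5. **Back-projection.** The mask returns to the scan's native grid through
   the inverse affine with nearest-neighbour sampling.
6. **Evaluation.** Per-structure Dice *D\_s*, average Dice *D\_A*,
   volume-weighted Dice *D\_V*, and the average symmetric surface distance
   (ASSD, mm) — each validated in the tests against independent brute-force
   oracles.

Because clinical databases of paired multi-modal scans are rarely shareable,
the package includes a synthetic multi-modal head-phantom generator (nested
wobbly ellipsoids, per-modality contrast tables, noise, misalignment,
degradation) so that every stage — including training — runs and is tested
without any data download.

## Worked example

```r
library(modalseg)

# synthetic study: 8 training subjects, 4 held-out, shared 3-structure anatomy
spec     <- phantom_spec(grid_shape = c(24, 24, 24), n_structures = 3,
                         structures = coarse_phantom_structures())
contrast <- modality_contrast("t1", n_structures = 3)
train    <- phantom_dataset(8,  spec, contrast, seed = 1)
heldout  <- phantom_dataset(4,  spec, contrast, seed = 500)

net <- unet(input_shape = c(24, 24, 24), n_classes = 4, depth = 2,
            n_filters = 8, seed = 4)
fitted <- fit(net, train, heldout,
              unet_control(learning_rate = 0.003, max_epochs = 60,
                           patience = 60, seed = 9, augment = NULL,
                           min_val_dice = 0.95))
fitted
#> <unet_fit> 35 epoch(s); best epoch 35 (val loss 401.5548, val Dice 0.9652)
#> <unet> input 24x24x24, C=4 classes, D=2, F=8, kernel 3x3x3, dropout r=0.20
#>   encoder channels: 8/16 | bottleneck: 32 (no dropout)
#>   trainable parameters: 85,364

# segment a new subject with the MC-dropout quality gate
scan <- phantom_dataset(1, spec, contrast, seed = 700)[[1]]
res <- segment_volume(scan$image, fitted, reference = NULL,
                      config = inference_config("t1", n_samples = 15,
                                                seed = 3, cv_threshold = 0.05,
                                                input_shape = c(24, 24, 24)))
res$qc
#> <qc_report> aggregate CV = 0.0314 (threshold 0.0500) -> ok [N = 15]

evaluate_segmentation(res$labels, scan$labels)
#> <ms_metrics> average Dice 0.9838 | weighted Dice 0.9860 | mean ASSD 0.044 mm
#>  id            name   dice assd_mm volume_mm3
#>   1 cerebral_cortex 0.9862 0.03210       1571
#>   2    white_matter 0.9863 0.05415       1169
#>   3       ventricle 0.9789 0.04459        117
```

The validation Dice is the mean per-structure overlap on the held-out
phantoms (1 = perfect); the QC report's *CV* is the mean relative spread of
structure volumes across the 15 stochastic forward passes — on degraded
inputs it rises sharply while Dice falls, which is what makes it a usable
quality gate. The ASSD is the symmetrized mean distance between predicted
and true structure surfaces in mm.

A command-line wrapper with the subcommands `phantom`, `train`, `register`,
`segment` (exit status 2 = segmented but QC-flagged) and `evaluate` is
installed at `inst/cli/modalseg`.

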