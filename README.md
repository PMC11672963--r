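# bladderseg

Semi-supervised multi-region segmentation of the bladder wall and tumor
for 2D grayscale (T2-weighted-like) images, with wall-enhanced
self-supervised pre-training and anatomically informed post-processing.

## The problem

Staging bladder cancer hinges on whether the tumor infiltrates the
muscular bladder wall, so clinicians need accurate delineation of four
regions: background, urine (the bright lumen), the thin dark wall, and
the wall-attached tumor. Two things make this hard: wall and tumor have
similar intensity distributions with blurred boundaries, and high-quality
expert annotations are scarce. This package implements a pipeline that
squeezes signal out of limited labels plus unlabeled images:

1. **Self-supervised pre-training.** An encoder-decoder reconstruction
   network (nine conv blocks / three max-pooling stages in the encoder,
   four conv blocks / three index-preserving unpooling stages in the
   decoder) is trained to restore randomly hole-masked patches. Two
   differently masked views `X1, X2` of the same patch `X` are
   reconstructed as `X̂1, X̂2`, minimizing

   `L_self = L_con + L_rec`,
   `L_con = mean |X̂1 − X̂2|`,  `L_rec = mean |X̂1 − X| + mean |X̂2 − X|`.

2. **Semi-supervised segmentation.** The same trunk, capped by a softmax
   head and regularized by a variational (VAE) branch at the bottleneck,
   is fine-tuned on labeled + unlabeled images with

   `L_semi = DFL + VAL`, where
   `DFL = FL + DL` is the Dice-focal loss
   (`FL = mean −α_t (1−P_t)^γ log P_t` with α = 0.1 / 0.6 / 0.8 for
   urine / wall / tumor; `DL = 1 − (2|x∩y|+e)/(|x|+|y|+e)`) computed on
   labeled pixels, and `VAL = MSE + KL(N(μ1, σ1²) ‖ N(0, 1))` is the VAE
   loss computed on every sample. Trunk layers initialized from
   pre-training train at rate `LR1`; randomly initialized layers at
   `LR2 = β(n)·LR1`, where `β` follows the anchor table
   (n, β) = (42, 0.02), (21, 0.2), (12, 2), (4, 10), (1, 20)
   with log-linear interpolation between anchors.

3. **Inference.** Test-time augmentation over exactly invertible
   transforms (flips, 90° rotations) with probability-mean merging, then
   segmentation correction: keep the largest foreground connected
   component and fill interior holes, enforcing the prior of one
   hole-free bladder region per image.

Because the clinical MRI cohort behind the method is private, the package
ships a synthetic phantom generator that reproduces the statistical
structure the method assumes (bright lumen, thin dark wall ring,
wall-attached tumor of intermediate intensity, boundary blur, noise) and
exercises the full pipeline on it.

## Worked example

```r
library(bladderseg)

cfg <- default_config()
cfg$seed <- 1L
dir <- tempfile("phantoms")
generate_dataset(60, 40, 20, phantom_config(), seed = 1, out_dir = dir)
m <- read_manifest(dir)

pm <- pretrain(m, cfg)               # stage 1: ~1 min on one CPU core
sm <- train_semisupervised(m, checkpoint = pm, config = cfg)  # stage 2
print(sm)
#> <bws_seg_model> pre-trained trunk, n_labeled = 60, beta = 0.02, best val DSC = 0.8509

ts <- bladderseg:::.load_split(m, "test")
preds <- predict(sm, ts$images, tta = TRUE, correct = TRUE)
evaluate(preds, ts$labels)
#> Segmentation evaluation (per-class means over cases)
#>            class    dsc    sen    spe    hd
#>            tumor 0.7820 0.8979 0.9878 4.462
#>            urine 0.9625 0.9292 0.9997 2.656
#>             wall 0.8429 0.9824 0.9688 4.900
#>  foreground_mean 0.8625 0.9365 0.9855 4.006
```

The table gives per-class means over the 20 held-out phantoms: Dice
similarity (overlap with the ground truth), sensitivity/specificity
(pixel-level recall on the class and on its complement), and the
Hausdorff distance between predicted and true boundaries in pixels. The
thin wall ring and the wall/tumor boundary are the hard parts; urine is
nearly saturated, as expected.

The same pipeline is scriptable from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "bwseg", package = "bladderseg"))')
Rscript $CLI make-data --out ds --n-labeled 60 --n-unlabeled 40 --n-test 20 --seed 1
Rscript $CLI pretrain  --data ds --out ckpt.rds
Rscript $CLI train     --data ds --ckpt ckpt.rds --out model.rds
Rscript $CLI predict   --model model.rds --data ds --out preds
Rscript $CLI evaluate  --pred preds --data ds --out metrics
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the model,
its assumptions, every tunable parameter with its default and rationale,
what the phantom generator does and does not emulate, and known
limitations.
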