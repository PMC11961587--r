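# scaleformer

An R package implementing a grouped multi-scale attention network for 2D
medical image segmentation, end to end: encoder, decoder, compound loss,
evaluation metrics, significance testing, a synthetic multi-scale dataset
generator, and a training/evaluation pipeline with a command-line interface.
The network layers run on a self-contained reverse-mode automatic
differentiation core with C++ (Rcpp/Armadillo) convolution kernels, so the
package needs no deep-learning framework.

## Who this is for

Researchers and students who want a fully inspectable, CPU-scale
implementation of channel-grouped multi-scale self-attention for
segmentation — to study the mechanism, verify its complexity claims, or
prototype on small 2D datasets — rather than a production training system.

## The model

**GMSA (grouped multi-scale attention).** The channels of a feature map
`X ∈ R^{h×w×c}` are split into `G` groups. Group `i` projects its pixels to
`Q_i, K_i, V_i = x_i W_i^Q, x_i W_i^K, x_i W_i^V`, average-pools each onto an
`s_i × s_i` token grid (patch size `(h/s_i, w/s_i)`, sequence length
`N_i = s_i²`), runs multi-head `softmax(QKᵀ/√d_h)V` over the tokens,
broadcasts the result back over the patches and applies an output
projection; the groups are concatenated. One layer thus mixes several
receptive granularities, with attention-score cost `Σ_i s_i⁴ d_i` —
a law the package *measures* via instrumented multiply counters rather than
assumes.

**ISA (inter-scale attention).** After GMSA, per-group channel affinities
`CA_i = softmax_tokens(k_i)ᵀ v_i` (cost linear in the pixel count) are
pooled, gated through a small sigmoid network, mixed across the group axis
into a shared map `A`, and applied to each group's channel-softmaxed
queries — cross-scale information exchange at linear cost.

These sit in a four-stage encoder (convolutional local perception unit +
residual GMSA/FFN/ISA/FFN blocks per stage, pyramid at strides 4/8/16/32)
and a context-perception decoder (SE-gated encoder/decoder fusion, Inception
refinement, channel+spatial attention, low-level stem fusion). Training
minimizes `0.3·CE + 0.7·Dice` deep-supervised over four branches with
weights `0.7/0.1/0.1/0.1`. Evaluation: per-class Dice, HD95, mIoU, accuracy,
sensitivity, specificity, and paired t-tests with 95% confidence intervals.

See the methods vignette (`vignettes/multiscale-attention.Rmd`) for every
design decision and the generator's rationale.

## Worked example

Train the packaged desk-scale study: 200 synthetic 64×64 scenes whose two
foreground classes (one large "organ" ellipse, several small "lesions")
share the same intensity distribution, so only object *scale* separates
them:

```r
library(scaleformer)

ds <- generate_dataset(scene_spec(seed = 42L), 200)   # 70/10/20 split
model <- scaleformer(input_size = 64, in_channels = 1, num_classes = 3,
                     stage_channels = c(16, 32, 64, 128),
                     stage_depths = c(1, 1, 1, 1), seed = 1)
cfg <- run_config("adam", lr = 1e-3, batch_size = 12, epochs = 8,
                  seed = 1, early_stop_dsc = 95)
model <- train_scaleformer(model, ds, cfg)
#> epoch 1/8  loss 0.6562  branches [0.660, 0.613, 0.541, 0.787]  val DSC 23.39%
#> epoch 2/8  loss 0.4783  branches [0.496, 0.342, 0.356, 0.613]  val DSC 47.52%
#> ...
#> epoch 7/8  loss 0.3044  branches [0.281, 0.197, 0.301, 0.581]  val DSC 90.66%
#> epoch 8/8  loss 0.2788  branches [0.246, 0.189, 0.295, 0.580]  val DSC 93.64%

ev <- evaluate_model(model, ds, split = "test")
attr(ev, "aggregate")[1:4, ]
#>      metric      mean          sd
#> 1  dsc_mean 93.098430 1.702655254    # mean foreground Dice, percent
#> 2    class1 98.404521 0.819691408    # the large "organ" class
#> 3    class2 87.792338 2.940885650    # the small "lesion" class
#> 4 hd95_mean  1.499316 2.224663603    # boundary error, pixels
```

The epoch lines report the training loss and its four deep-supervision
branches (main, 1/8, 1/16, 1/32); `dsc_mean` is the held-out mean foreground
Dice in percent — above 90 means both the large organ and the small lesions
are segmented well, and an HD95 of ~1.5 pixels means predicted boundaries
sit essentially on the true ones. Passing a second model to
`evaluate_model()` attaches a paired t-test on per-case Dice (here against a
single-scale ablation, which on this easy synthetic task converges slightly
faster — see the vignette's discussion of why the scaled-down study cannot
reproduce a multi-scale advantage):

```r
ev2 <- evaluate_model(model, ds, split = "test", compare = ablated_model)
attr(ev2, "ttest")
#> Paired t-test (n = 40): t = -7.9828, p = 9.978e-10, significant: yes
#>   mean A = 93.0984, 95% CI (92.5539, 93.6430)
#>   mean B = 95.6435, 95% CI (95.1534, 96.1337)
```

Command-line equivalents (thin wrapper over the same functions):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/scaleformer.R", package="scaleformer"))')
Rscript $CLI generate --out data/ --n 200 --seed 42
Rscript $CLI train    --data data/ --out run/ --epochs 8 --lr 1e-3
Rscript $CLI eval     --data data/ --checkpoint run/checkpoint.rds --out run/
Rscript $CLI predict  --checkpoint run/checkpoint.rds --images img.png --out preds/
```

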