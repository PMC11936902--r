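# lungreg

Deformable registration of dynamic lung fields in chest radiograph (CXR)
sequences, as a fully automatic three-stage pipeline:

1. **Segmentation** — a seeded U-Net-style encoder–decoder predicts a
   binary lung-field mask per frame;
2. **Lung-field extraction** — the mask multiplies the frame pixel-wise,
   zeroing everything outside the lungs;
3. **Registration** — a deformation predictor ("VectorCNN") maps a
   (source, target) lung-field pair to a dense displacement field `T`,
   applied by a differentiable warper with backward bilinear sampling.

Registration training is unsupervised, minimising the composite loss

```
L = -λ_NCC · NCC(I∘T, J) + λ_TV · TV(T) + λ_BCE · BCE(S_I∘T, S_J)
    + λ_L2 · mean‖enc(S_I∘T) − enc(S_J)‖²
```

with λ_NCC = 1, λ_TV = 5·10⁻⁵, λ_BCE = 1, λ_L2 = 0.1 and ε = 10⁻⁵
guarding the NCC denominator. `enc` is the frozen encoder of a denoising
autoencoder pretrained on lung masks — an anatomical prior that forces
warped masks to encode like plausible lung shapes. Training follows a
three-step scheme on *static* frames only: initial training on all
ordered image pairs (n² − n of them; 787 images give 618,582 pairs),
enhanced training on image → affine-image pairs, and final training on
extracted lung-field pairs, yielding the models V1, V2 and V3. Image and
mask always share one affine draw, the consistency the mask-dependent
loss terms require.

Because clinical dynamic sequences cannot ship with a package, `lungreg`
includes a seeded analytic breathing phantom — two super-elliptic lungs
on a rib-textured thorax with a diaphragm-dominant, analytically
invertible motion model — that provides frames, masks and ground-truth
dense displacement fields for every test. Evaluation uses the four
standard metrics (Dice similarity coefficient, Hausdorff distance,
average symmetric surface distance, mean squared intensity distance) with
paired Wilcoxon significance testing.

## Worked example

```r
library(lungreg)

## one breathing cycle: 11 frames of 96 px, ground-truth motion included
seq <- generateBreathingSequence(phantomConfig(seed = 1))

## desk-scale end-to-end study: simulate 60 static training subjects,
## train autoencoder + segmenter + registration steps 1-3, evaluate
study <- runStudy(seed = 1, verbose = TRUE)

reportAggregates(study$ablation$baseline)[1, ]
#   metric      mean         sd       min       max
# 1    dsc 0.9627174 0.02291156 0.9073821 0.999187
reportAggregates(study$ablation$V3)[1, ]
#   metric      mean         sd       min       max
# 1    dsc 0.9792428 0.01340866 0.9377787 0.9975775
attr(study$translation, "meanError")
# [1] 0.8731023
```

The mean Dice over the 110 ordered test-frame pairs improves from 0.963
(unregistered baseline) to 0.979 after the final training step, while
the initial model V1 *drops below* the baseline (0.932) — the ordering
reported for this three-step scheme: only the final model improves every
metric. The translation probe registers lung fields shifted by known
integer translations of at most 4 px; the mean predicted displacement
inside the lung mask lands within about 0.9 px of truth.

A thin command-line wrapper covers the same stages
(`inst/scripts/lungreg`): `simulate`, `extract`, `warp`, `train`,
`register`, `evaluate`.

```sh
Rscript inst/scripts/lungreg simulate --out seq/ --size 96 --frames 11 --seed 1
Rscript inst/scripts/lungreg evaluate --data seq/ --out report.csv
```

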