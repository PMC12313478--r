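# smfnet

Text-guided multimodal image segmentation with semi-supervised
dual-student adversarial training, in R.

## The problem

Small, low-contrast lesions inside a larger organ are hard to delineate
from grayscale images alone, and expert pixel annotations are scarce.
Short clinical reports, however, routinely state how many findings there
are and roughly where. `smfnet` implements, end to end on CPU:

* **A dual U-shaped segmentation network** fusing a CNN image encoder with
  a multi-granularity text encoder. At every resolution level the pooled
  text embedding is projected, broadcast and multiplied into the image
  features (Hadamard gating), then refined by a transformer encoder block
  over spatial patch tokens; a pooling-based attention gate (average + max
  pooling streams, sigmoid squash) sits at each skip connection. The
  decoder emits per-pixel class probabilities
  `softmax(logits)` over background / organ / lesion.
* **A dual-student adversarial training framework** for semi-supervised
  learning: two independently initialized students exchange
  stability-gated consistency constraints on unlabeled images,

  `L = L_seg + lambda1 L_cons + lambda2 L_sta + lambda3 L_adv`,

  with weights (0.5, 0.2, 0.05), a Gaussian ramp
  `exp(-5 (1 - I)^2)` on the unsupervised terms, per-student adversarial
  discriminators, and an EMA teacher (`alpha = 0.999`). Supervised loss is
  `(CE + Dice loss) / 2`. A mean-teacher variant is included.
* **Evaluation metrics**: per-class Dice, mIoU, 95th-percentile Hausdorff
  distance on 4-connectivity boundaries, and probability MAE.
* **A synthetic phantom generator** producing paired images, masks and
  templated reports ("1 lesion in the upper left of the organ") whose text
  is causally tied to the mask, so every stage is testable without
  external data.

Because no deep-learning framework is available for R in this
environment, the package includes a compact reverse-mode autodiff engine
with compiled kernels (im2col convolution, pooling, fused multi-head
attention); every primitive's gradient is finite-difference checked in the
test suite.

## Worked example

```r
library(smfnet)

# 8 labeled + 32 unlabeled phantoms and a small validation corpus
cmd_synthesize("corpus", n_labeled = 8, n_unlabeled = 32, grid = 32, seed = 1)
cmd_synthesize("val",    n_labeled = 8, n_unlabeled = 0,  grid = 32, seed = 2)

# dual-student semi-supervised training, tiny preset
run <- cmd_train("corpus", "run", framework = "dual_student",
                 lambda = c(0.5, 0.2, 0.05), epochs = 20, lr = 1e-3,
                 val_dir = "val", seed = 1)

# evaluate on the validation corpus
cmd_eval(run$checkpoint, "val")
```

This toy run takes a few CPU minutes and prints:

```
metric report (n = 8)
  dice per class: 1=0.4544 2=0.0000
  mean dice 0.2272 | mIoU 0.1483 | HD95 13.597 | MAE 0.4316
```

i.e. after twenty epochs the organ (class 1) is partially segmented
(Dice 0.45) while the small lesion class (2) has not yet been learned -
lesions at these default settings need the longer schedules used in the
acceptance benchmarks, where mean validation Dice reaches ~0.7. `mean
dice` averages the foreground classes; HD95 is in pixels.

A shell interface wrapping the same functions ships at
`inst/cli/smfnet` (`smfnet synthesize | train | eval | predict`).

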