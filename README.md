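# compressnet

Teacher–student compression of convolutional image classifiers, for
settings where a model must run on weak hardware without giving up the
accuracy of a heavy network — the motivating application being herb
(medicinal plant material) image recognition on low-cost smartphones, or
any folder-per-class image task of similar shape.

## The method

Let `X_i` be an RGB image with one-hot label `Y_i`, `phi(X_i)` a network's
softmax output, and `H` the D-dimensional **hidden vector** (the output of
the fully connected layer before the classifier head). The pipeline has
three steps:

1. **Pre-train + fine-tune.** Teacher and student are trained separately
   with mini-batch cross-entropy `sum_i -Y_i log phi(X_i) / B` (SGD,
   batch B = 32, momentum 0.9, weight decay 5e-4, step-decay learning-rate
   ladders), optionally starting from weights pre-trained on a larger
   source task.
2. **Transfer.** The teacher is frozen; the student minimizes

   ```
   sum_i ( -Y_i log phi(X_i)  +  lambda * || H_S - H_L ||_2^2 ) / B ,    lambda = 1
   ```

   where both hidden vectors are computed on the same augmented view of
   each image.
3. **Top-down cut.** For each prunable layer t, from the deepest (T) down
   to 1: each filter i of the bank `P_t` is scored by the reconstruction
   error it induces in the next layer's feature map over M subset images,

   ```
   Score_i = sum_m || F_{t+1}^{(i)}(X_m) - F_{t+1}(X_m) ||_2^2 / M ,
   ```

   the `ceiling(C_t * alpha)` lowest-scoring filters are removed
   structurally (default cut ratio `alpha = 0.5`), and the network is
   retrained with the step-2 objective before the next layer is cut.

Training augmentation is the four-step pipeline: random area scaling
(log-uniform on [0.08, 1], aspect kept), random aspect ratio (log-uniform
on [3/4, 4/3], area kept), random crop, resize; testing is a deterministic
resize + center crop (256 → 224 at full scale). Evaluation is macro
(per-class averaged) top-k accuracy over repeated stratified 70/30 splits.

A deterministic synthetic glyph-image generator (`generate_dataset()`)
with controllable class count, scarcity, inter-class similarity, geometric
jitter and pixel noise makes the whole pipeline testable end to end with
no external data. See the methods vignette
(`vignettes/compression-methods.Rmd`) for every modeling choice.

## Worked example

```r
library(compressnet)

cfg   <- synth_config(n_classes = 10, n_per_class = 30, image_size = 64,
                      noise_sd = 0.05, seed = 5)
train <- generate_dataset(cfg)
test  <- generate_dataset(synth_config(10, 10, image_size = 64, noise_sd = 0.05,
                                       seed = 6, prototype_seed = cfg$prototype_seed))
aug <- aug_config(train_out = 32, test_resize = 36, test_crop = 32)

teacher <- build_network(spec_desk_teacher(n_classes = 10), seed = 2)
teacher <- train_crossentropy(teacher, train, aug,
  train_config(lr_schedule = list(c(0.05, 100), c(0.005, 40)), batch = 16, seed = 1))

student <- build_network(spec_desk_student(n_classes = 10), seed = 3)
student <- train_crossentropy(student, train, aug,
  train_config(lr_schedule = list(c(0.05, 100), c(0.005, 40)), batch = 16, seed = 2))
wsk <- transfer_train(student, teacher, train, aug,
  transfer_config(lambda = 1, train = train_config(
    lr_schedule = list(c(0.001, 250), c(0.0001, 80)), batch = 16, seed = 3)))

res <- compress(wsk, teacher, train, aug,
  cut_config(alpha = 0.5, subset_size = 32, subset_seed = 1,
             retrain = transfer_config(lambda = 1, train = train_config(
               lr_schedule = list(c(0.001, 120)), batch = 16, seed = 4))),
  eval_data = test)
print(res$report)

acc <- function(m) topk_macro_accuracy(predict_logits(m, test$images, aug), test$labels, 1)
cat(sprintf("teacher %.1f%% | transferred student %.1f%% | compressed student %.1f%%\n",
            acc(teacher), acc(wsk), acc(res$model)))
```

Output (R 4.3, single CPU):

```
<compression_report> alpha=0.50, 3 stages, params 5650 -> 3626
  block 4: removed 16, reserved 16, held-out top1 99.0
  block 3: removed 16, reserved 16, held-out top1 99.0
  block 2: removed 8, reserved 8, held-out top1 100.0
teacher 99.0% | transferred student 100.0% | compressed student 100.0%
```

Reading it: the cut walks the student's three prunable bottleneck blocks
top-down (blocks 4, 3, 2), halves each expansion filter bank (16 → 8 of
32/32/16 filters reserved), shrinks the model from 5650 to 3626
parameters, and the held-out macro top-1 after each retrain stays at the
transferred student's level — compression at `alpha = 0.5` with no
accuracy loss on this task.

## Command line

Every stage is scriptable through a YAML config:

```sh
Rscript -e 'compressnet::cli_main()' --config run.yaml
```

with `stage:` one of `synth`, `train`, `transfer`, `cut`, `evaluate`,
`sweep` (the accuracy-vs-ratio curve). Each run echoes its effective
configuration and writes TSV logs and JSON reports; checkpoints are plain
text (`spec.yaml`, `params.json`, `cut_history.json`). See
`?compressnet_run`.

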