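# nmfdecode

Real-time-oriented decoding of four hand/wrist movements (key grip, power
grip, wrist extension, wrist flexion) from multichannel motor EEG, built
around two ideas:

1. **Segment-wise spatial factorization.** Each 100 ms decoding block is
   split into five 20 ms segments; the absolute-valued segment
   `X ∈ R₊^{C×20}` is factorized at rank 2 by non-negative matrix
   factorization, `min_{W,H≥0} ‖X − WH‖²_F`, with multiplicative updates
   (`ε = 1e−9` in the denominators). The spatial factors `W ∈ R₊^{C×2}` of
   the five segments are concatenated into a `C × 10` block feature
   `F = concat(W⁽¹⁾ … W⁽⁵⁾)`, then z-scored.
2. **Contrastive representation learning with joint refinement.** A
   residual 1-D convolutional encoder (stem → stages 32/64/128 with strides
   1/2/2 → pooling → latent dimension 32) is pre-trained with a contrastive
   loss using the negative squared Euclidean similarity
   `ψ(z, z′) = −‖z − z′‖²`,
   `L = E[ −ψ(z, z⁺) + log Σⱼ exp ψ(z, zⱼ⁻) ]`,
   and then refined jointly with a linear classifier head under
   cross-entropy, giving calibrated class probabilities per 100 ms block.

Around this core the package provides: a 10–10 montage model with the six
nested channel-reduction sets (60/36/29/22/13/7 electrodes) for robustness
studies, band-pass filtering and sliding-window epoching, a fully seeded
synthetic 4-class motor-EEG generator (focal sensorimotor topographies,
8–30 Hz amplitude-modulated sources, spatially correlated 1/f noise at a
controllable SNR), evaluation metrics (accuracy, macro-F1, Cohen's κ,
confusion matrices, one-way ANOVA + Tukey HSD across methods), channel
drop/shift perturbations, and a CLI driver. Recordings are read and written
as delimited array fixtures with a JSON sidecar or minimal 16-bit EDF.

It is aimed at BCI methods researchers who want a tested, reproducible
reference implementation of this decoding pipeline that runs end-to-end on
synthetic data without any restricted recordings.

## Worked example

Simulate a 13-channel (central + centro-parietal) session, extract NMF
block features, train the two-stage model, and score held-out blocks:

```r
library(nmfdecode)

labs <- get_channel_set("set5")$labels
cfg <- default_config(seed = 42)
cfg$synth <- utils::modifyList(cfg$synth, list(
  n_channels = 13, channels = labs, trials_per_class = 8,
  trial_s = 2, rest_s = 0.5, snr = 4))
cfg$montage$set <- "set5"
cfg$preprocess$n_train <- 6
cfg$preprocess$n_test <- 2
cfg$training <- utils::modifyList(cfg$training, list(
  pretrain_epochs = 5, joint_epochs = 10))

res <- run_pipeline(cfg)
print(res$metrics)
#> <metrics_report: n=312 acc=1.0000 macro-F1=1.0000 kappa=1.0000>
#>      predicted
#> truth KG PG WE WF
#>    KG 78  0  0  0
#>    PG  0 78  0  0
#>    WE  0  0 78  0
#>    WF  0  0  0 78
```

Each of the 16 held-out trials (4 per class, 2 s each) contributes 39
sliding 100 ms blocks, hence 312 scored blocks; at SNR 4 the synthetic
topographies are fully separable, so block accuracy, macro-F1 and κ all
reach 1. `res$trial_metrics` aggregates blocks by trial majority vote.
Lower the SNR (`cfg$synth$snr`), drop channels
(`perturb_channels(rec, "drop", k)`), or switch to a smaller montage
(`cfg$montage$set <- "set6"`) to watch the metrics degrade.

The same pipeline is scriptable from a shell via the installed CLI:

```sh
Rscript inst/cli/nmfdecode run --seed 42 --outdir runs/demo
Rscript inst/cli/nmfdecode ablate-channels --seed 42 --outdir runs/demo
Rscript inst/cli/nmfdecode run --seed 42 --outdir runs/nojoint --no-joint-refinement
```

`ablate-channels` retrains per channel set and writes a six-row
set-versus-metrics table; `--no-nmf` and `--no-joint-refinement` wire the
two ablation variants (raw `C × 100` blocks into the encoder, and a frozen
pre-trained encoder with a head-only fit).

See `vignettes/nmfdecode-methods.Rmd` for the model, its assumptions, all
tunable parameters, and what the synthetic benchmark does and does not
demonstrate.

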