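# schnetr

Detection of pathological (schizophrenic) speech from audio recordings,
end to end: the **Sch-net** convolutional neural network operating on
spectrogram images, the classical acoustic-feature + classifier pipeline
it is compared against, Grad-CAM interpretation of what the network
attends to, and a source-filter speech synthesizer that generates
labelled two-class data with ground-truth annotations so every stage can
be exercised at desk scale without clinical recordings.

The package is aimed at speech-pathology and machine-learning researchers
who want a fully inspectable, dependency-light reference implementation
of this detection pipeline in R.

## What is implemented

**The network.** Sch-net consumes a 128 x 256 log-magnitude STFT image
(one recording = one image, standardized per image). A VGG-style backbone
of four blocks (2 x [3x3 conv] each; 64/128/256/512 filters; BN + ReLU;
2x2 max pool) feeds three *skip connections* that average-pool the
outputs of blocks 1–3 to 8 x 16, project each with a 3x3 convolution to
512 channels, and concatenate them with the block-4 output into a
2048-channel map. A *convolutional block attention module* (CBAM) applies
channel attention (shared MLP over spatial average/max descriptors,
sigmoid-gated) then spatial attention (7x7 convolution over channel
mean/max maps). A 512-filter fusion convolution, global average pooling
and an FC 512 -> 2 head with softmax finish the graph — 12 convolutional
layers in total. Forward and reverse passes are hand-authored on
compiled im2col + GEMM kernels (RcppArmadillo); no deep-learning
framework is involved, and the backward pass is verified against
numerical gradients in the test suite.

**Training and evaluation.** Two-class cross-entropy, Adam at 3e-4
dropped tenfold at epoch 25, batch size 16; repeated stratified ten-fold
cross-validation (30 iterations at full scale) reporting accuracy,
precision, recall, F1, sensitivity, specificity and rank-statistic AUC
with 95% confidence intervals; subject-disjoint folds whenever speaker
identifiers exist. Ablation variants (backbone / +SC / +CBAM / full)
come from the same configuration object via `run_ablation()`.

**Interpretation.** `grad_cam()` computes class-activation heatmaps from
the fusion convolution; `band_energy_share()` and `gradcam_band_study()`
quantify how much heat falls above a frequency cutoff (5 kHz by
default), the axis along which healthy and pathological speech differ.

**Classical baselines.** Ten per-clip feature sets — short-term energy,
pitch, five fluency/pause statistics, LTAS, pooled spectrogram, MFCC,
GTCC, and linear prediction with its weighted variants (LP/SWLP/XLP,
order 38) — benchmarked with random forest, KNN, SVM and LDA under the
same CV protocol (`benchmark_grid()`).

**Synthetic data.** `generate_dataset()` synthesizes balanced,
subject-grouped clips whose classes differ the way the clinical classes
are reported to differ: patients get reduced F0 variability (sd 4 Hz vs
30 Hz), energy confined below 5 kHz (vs 16 kHz), three times the pause
rate at twice the duration, and voiced realizations of unvoiced
segments. Ground truth (segments, voicing, F0 contour) is recorded
exactly.

## A worked example

```r
library(schnetr)

# 40 labelled clips (10 simulated speakers), with ground truth
ds   <- generate_dataset(n_per_class = 20, duration_s = 3, seed = 11)
prep <- prepare_inputs(ds)          # STFT -> 128 x 256 standardized images

# hold out two speakers, train a quarter-width Sch-net for 4 epochs
te  <- which(ds$subjects %in% c("S0_01", "S1_01"))
tr  <- setdiff(seq_along(ds$labels), te)
fit <- train_schnet(build_schnet(schnet_config(width_scale = 1/8, seed = 42)),
                    prep$images[tr], prep$labels[tr],
                    train_config(epochs = 4, seed = 42), verbose = TRUE)
#> epoch   1  loss 0.6977  acc 0.469  lr 0.0003
#> epoch   2  loss 0.3933  acc 1.000  lr 0.0003
#> epoch   3  loss 0.2334  acc 1.000  lr 0.0003
#> epoch   4  loss 0.1560  acc 1.000  lr 0.0003

pr <- predict_schnet(fit$model, prep$images[te])
mean((pr[, "patient"] >= 0.5) == (ds$labels[te] == 1))
#> [1] 0.875
```

The loss curve shows the planted spectral contrast is learned within two
epochs; held-out accuracy is 7/8 on the two unseen speakers. Where the
network looks:

```r
study <- gradcam_band_study(fit$model, prep$images, ds$labels, cutoff_hz = 5000)
c(control = study$mean_control, patient = study$mean_patient, p = study$p_value)
#>      control      patient            p 
#> 8.125266e-01 7.130828e-01 4.146208e-05
```

For this lightly trained model, heat above 5 kHz is larger for control
clips. (The methods vignette discusses why a fully converged model can
invert this ordering on synthetic data: the strongest patient-class
evidence is the *absence* of high-band energy, and Grad-CAM marks
evidence, not energy.) Classical features on the same clips:

```r
f <- fluency_features(vad_segment(ds$clips[[1]]))
round(f, 3)
#> total_time  voiced_time  voiced_ratio  max_pause  mean_syllable
#>      3.000        3.000         1.000      0.000          0.214
```

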