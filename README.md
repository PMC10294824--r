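# melpcg

Classify phonocardiogram (heart-sound) recordings as **normal** or
**abnormal** from STFT-based **MelSpectrum** and **Log-MelSpectrum**
feature maps, and study which of the two representations survives a
change of acquisition device.

## Who this is for

Researchers in biomedical signal processing who want a self-contained,
seeded laboratory for the domain-shift question in heart-sound
classification: public heart-sound corpora combine sub-datasets recorded
with different stethoscopes, and a classifier trained on some devices
often degrades on an unseen one.

## The model at the core

A recorded heart sound is modelled as

```
y(n) = (s(n) + a(n)) * h(n)
```

with `s` the cardiac source, `a` additive background noise, `h` the
stethoscope impulse response and `*` convolution. After STFT and a
triangular Mel filterbank (band `m`, frame `l`):

* MelSpectrum: `Mel_y[m,l] ≈ (S²[m,l] + A²[m,l]) · H²[m]` — the device
  acts **multiplicatively**;
* Log-MelSpectrum: `log Mel_y[m,l] ≈ log H²[m] + log(S²[m,l] + A²[m,l])`
  — the device becomes a frame-constant **additive** per-band offset,
  which a CNN tolerates far more readily.

The package implements the full chain: WAV input → 25–950 Hz Butterworth
band-pass (zero phase) → Savitzky–Golay smoothing → 2.5 s segments →
240/60/512 Hanning STFT → 128 triangular Mel filters → optional log →
128×128 standardised maps → a compact VGG-style CNN (7 conv / 3 pool /
4 FC, Kaiming init, Adam, cross-entropy) → leave-one-domain-out (LODO)
evaluation reporting sensitivity, specificity and their mean (MAcc).
A seeded simulator generates six-domain datasets with realistic size and
class imbalance, per-domain channel coloration and additive noise.

## Worked example

```r
library(melpcg)

# a clean abnormal (murmur-bearing) heart sound and its acquisition
p <- heart_sound_params(murmur_present = TRUE, murmur_band = c(50, 900),
                        murmur_gain = 0.6)
s <- synth_clean_pcg(p, duration = 5, fs = 2000, seed = 7)
y <- acquire(s, noise_params(snr_db = Inf),
             channel_model("t", c(1, 0.4), "first-order channel"), seed = 1)

st <- logmel_shift_stats(s, y)
round(c(bands = nrow(st$bands), max_sd_ratio = st$max_sd_ratio,
        mel_diff_cv = st$mel_diff_cv_median), 3)
#>        bands max_sd_ratio  mel_diff_cv
#>      128.000        0.048        1.139
```

All 128 Mel bands are retained; the frame-wise SD of the log-Mel channel
shift never exceeds 4.8% of the mean absolute shift (the offset is
frame-constant, i.e. additive), while the Mel-domain difference varies
across frames with a median coefficient of variation above 1 (clearly
not frame-constant).

The end-to-end comparison on a simulated six-domain dataset (162
records, domain *e* holding 66% of them and never tested):

```r
res <- cmd_evaluate(run_config(seed = 1, seeds = c(1, 2, 3)))
round(res$across_seeds, 3)
#>     macc_mel macc_log_mel       d_macc
#>        0.532        0.990        0.458
```

The Mel-trained classifier converges in-domain (validation accuracy
around 68%) yet drops to near-chance mean accuracy on held-out devices,
while the log-Mel-trained one stays near-perfect across domains — the
domain-robustness tendency the package exists to demonstrate. Exact
values depend on the seed.

## Command line

A thin CLI over the same drivers is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/melpcg_cli.R", package="melpcg"))')" \
    simulate --seed 1 --out data_out
```

Subcommands: `simulate`, `extract`, `evaluate`, `reproduce-metrics`.

## Layout

- `R/`, `src/` — implementation (preprocessing, features, simulator,
  CNN, evaluation, drivers)
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/domain-robust-features.Rmd` — the methods vignette: model,
  assumptions, parameter choices, simulator scope, limitations
- `scripts/acceptance.R` — end-to-end reproduction script
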