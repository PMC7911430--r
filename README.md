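# bovocal

Acoustic monitoring and behavioral classification of cattle vocalizations.

Livestock welfare monitoring increasingly relies on sound: cows vocalize
differently in estrus, when feeding is delayed, and when coughing, so a barn
instrumented with sound sensors can alert the farmer to conditions that need
attention. `bovocal` implements the full monitoring chain as a reusable R
toolkit:

1. **Event capture** — a stream is recorded for 5 s whenever its calibrated
   level reaches 60 dB (`detectEvents()`); among co-located sensors in one
   zone that capture the same sound, only the loudest recording is kept
   (`deduplicateZone()`).
2. **Noise removal** — short-time Fourier transform (STFT) spectral gating
   (`denoise()`): per frequency bin *k*, a noise reference yields the mean
   μ_k and standard deviation σ_k of the dB magnitudes, and a
   time–frequency bin passes when its magnitude exceeds the threshold
   μ_k + n·σ_k (default n = 1.5). The binary mask is smoothed by a 2
   (frequency) × 4 (time) equal-weight kernel to avoid musical-noise
   artifacts, applied to the STFT, and inverted by weighted overlap-add.
3. **Features** — Mel-frequency cepstral coefficients (`mfccFeatures()`):
   one-sided power spectrum, a bank of M = 128 triangular filters equally
   spaced on the Mel scale m(f) = 2595·log10(1 + f/700), floored log, and
   the unnormalized cosine transform
   MFCC(n) = Σ_m E_log(m)·cos(n(m−½)π/M), padded/truncated to a fixed
   2000 time frames.
4. **Classification** — two small CNNs built and trained in-package
   (`buildBinaryCnn()`, `buildBehaviorCnn()`, `train()`): a binary
   cattle-voice/noise gate, then a four-class behavioral classifier
   (0 estrus, 1 food anticipating, 2 cough, 3 normal). Optimization uses a
   from-scratch **Adadelta** rule (`adadeltaStep()`), element-wise, with no
   global learning rate:

       E[g²]_t  = γ·E[g²]_{t−1}  + (1−γ)·g_t²
       Δθ_t     = −( RMS[Δθ]_{t−1} / RMS[g]_t ) · g_t,   RMS[v] = √(E[v²]+ε)
       E[Δθ²]_t = γ·E[Δθ²]_{t−1} + (1−γ)·Δθ_t²
       θ_{t+1}  = θ_t + Δθ_t

   with γ = 0.95 and ε = 1e−7.
5. **Evaluation & reporting** — confusion-matrix rates (`accuracy()`,
   `trueRecognitionRate()` = TP/(TP+FP), `falseRecognitionRate()` =
   TN/(TN+FN), truncated to two decimals), four-class confusion matrices
   (`confusionFromPredictions()`), and a monitoring pipeline
   (`runPipeline()`) that emits one JSON/CSV record per event with the
   predicted class, its probability and an alert flag for the three
   actionable classes.

A synthetic generator (`generateCall()`, `addNoise()`, `makeDataset()`)
produces labeled corpora with the structure the pipeline assumes — harmonic
cattle calls of four distinct signatures embedded 2–3 s into 5 s clips,
continuous sub-400 Hz background hum, broadband microphone noise, and
non-cattle transients (metal clangs, speech-like chatter) — so every stage
is testable without field recordings.

## Worked example

```r
library(bovocal)

# evaluation of the binary gate from its confusion counts
cm <- ConfusionMatrix2(tp = 141, fp = 11, fn = 10, tn = 199)
writeLines(evaluationReport(cm, format = "text"))

# one synthetic estrus call, noisy at 0 dB SNR, denoised
g <- generateCall(CallSpec(0, seed = 1), sampleRate = 8000)
clean <- samples(g$segment)
noise <- local({ set.seed(2); rnorm(length(clean)) })
noise <- noise * sqrt(mean(clean^2) / mean(noise^2))
noisy <- AudioSegment(clean + noise, 8000)
den <- denoise(noisy)
snr <- function(ref, x) 10 * log10(mean(ref^2) / mean((ref - x)^2))
cat(sprintf("SNR before: %.1f dB, after: %.1f dB\n",
            snr(clean, samples(noisy)), snr(clean, samples(den))))

f <- mfccFeatures(g$segment, M = 64, tFixed = 128,
                  config = STFTConfig(nFft = 1024, hop = 512))
f
```

prints

```
True positive                     141
False positive                     11
True negative                     199
False negative                     10
True recognition rate (%)       92.76
False recognition rate (%)      95.21
Accuracy (%)                    94.18
SNR before: 0.0 dB, after: 7.8 dB
MFCCMatrix (mfcc): 64 coefficients x 128 frames
```

The first block is the standard binary evaluation: of 152 sounds recognized
as cattle voice, 92.76% really were; of 209 recognized as other sounds,
95.21% really were; 94.18% of all 361 clips were classified correctly
(rates are truncated, not rounded, to two decimals). The denoising block
shows spectral gating lifting a 0 dB-SNR clip by about 8 dB, and the last
line is the fixed-size feature matrix a classifier consumes.

A command-line interface wrapping the same functions (subcommands
`simulate`, `denoise`, `featurize`, `train`, `evaluate`, `predict`,
`monitor`) is installed at `inst/cli/bovocal.R`.

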