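# otoseg

Denoising, segmentation and evaluation for otoscope-style tympanic-membrane
images, aimed at computer-aided otitis media (OM) image analysis.

Otoscopic frames are routinely corrupted by impulse noise, and quantitative
OM analysis needs the eardrum segmented from the ear-canal background.
`otoseg` implements the full pipeline with a synthetic phantom generator in
place of clinical data, so every stage is testable against exact ground
truth:

* **HE/ACWM filter** — a switching impulse-noise filter: histogram
  equalization (CDF remapping `y = round((L−1)(CDF(v) − c_min)/(n − c_min))`),
  impulse detection by the rank-ordered absolute difference statistic
  (ROAD: sum of the k = 4 smallest neighbour differences, threshold 40)
  combined with an adaptive-window fixed-valued test, then replacement of
  flagged pixels only, by a center-weighted median (weight 3) over the
  non-flagged pixels of an adaptive window.  Baselines: sliding weighted
  median and the two-stage adaptive median.
* **Three segmenters** — a Chan–Vese level-set active contour minimizing
  `E_T = w1·E1 + w2·E2 + w3·E3` (region + shape-prior + edge energies, the
  prior under a similarity transform of a template signed-distance field);
  the GrowCut cellular automaton (attack rule `g(d)·θ_q`, `g(d) = 1 − d/255`,
  Von Neumann or Moore neighbourhoods); and Haar-wavelet multiscale
  histogram thresholding (coarse-to-fine valley search on an approximation
  pyramid of the 256-bin histogram).
* **Evaluation metrics** — PSNR (`10·log10(255²/MSE)` dB), Rand index,
  global consistency error and variation of information (bits), all
  verified against brute-force definitions.
* **Benchmark harness** — seeded 10-phantom suite (IM1–IM10), PSNR tables
  over noise densities 0.30/0.40/0.50 and RI/GCE/VI tables over the three
  segmenters, deterministic down to CSV bytes.

## Worked example

```r
library(otoseg)

ph <- make_phantom(phantom_spec(rng_seed = 1))          # image + ground truth
nz <- add_impulse_noise(ph$image, noise_spec(0.3, "fixed", rng_seed = 42))
f  <- acwm_filter(nz$image)                             # HE/ACWM
cat(sprintf("flagged %d of %d corrupted pixels (recall %.3f, FPR %.4f)\n",
    sum(f$mask & nz$mask), sum(nz$mask),
    sum(f$mask & nz$mask) / sum(nz$mask),
    sum(f$mask & !nz$mask) / sum(!nz$mask)))
cat(sprintf("PSNR: noisy %.2f dB -> filtered %.2f dB\n",
    psnr(ph$image, nz$image), psnr(ph$image, f$image)))

seg <- dwt_threshold_segment(f$image)                   # wavelet threshold
sc  <- evaluate_segmentation(seg$labels, ph$truth)
cat(sprintf("DWT threshold %d; RI %.4f, GCE %.4f, VI %.4f\n",
    seg$threshold, sc$ri, sc$gce, sc$vi))
```

prints

```
flagged 19661 of 19661 corrupted pixels (recall 1.000, FPR 0.0165)
PSNR: noisy 9.58 dB -> filtered 31.55 dB
DWT threshold 96; RI 0.9970, GCE 0.0030, VI 0.0314
```

At 30% salt-and-pepper density the detector recovers every injected
impulse while flagging under 2% of clean pixels; filtering lifts PSNR by
~22 dB; the wavelet segmenter then separates membrane from background with
near-perfect pair agreement (RI) and near-zero consistency error and
information distance against the phantom truth.

A command-line front end over the same functions ships in
`inst/cli/otoseg` (verbs: `phantoms`, `denoise`, `segment`, `evaluate`,
`bench-denoise`, `bench-seg`).

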