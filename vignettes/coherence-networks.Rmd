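---
title: "Resting-state EEG coherence networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG coherence networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coherenet)
```

## The model

coherenet quantifies resting-state EEG functional connectivity as
magnitude-squared coherence (MSC) between channel pairs,

$$C_{xy}(f) \;=\; \frac{|P_{xy}(f)|^2}{P_{xx}(f)\,P_{yy}(f)} \;\in\; [0, 1],$$

where $P_{xx}, P_{yy}$ are auto-spectral densities and $P_{xy}$ the
cross-spectral density, all estimated by Welch's method: the signal is
cut into tapered, overlapping segments, each segment is Fourier
transformed, and (cross-)periodograms are averaged over the $K$
segments. MSC measures linear synchronisation at each frequency; a
shared oscillatory source drives it toward 1, independent noise toward
0. Per-frequency coherence is averaged within canonical frequency bands
(delta 1–4 Hz through beta2 20–35 Hz, including the alpha1/alpha2/alpha3
sub-bands of the alpha rhythm), and each band's channels × channels
coherence matrix is the subject's connectivity profile for one
recording condition (eyes-open, EO, or eyes-closed, EC).

Group inference is edge-wise and nonparametric: for every unordered
channel pair, band, and condition, case and control subjects' band
coherences are compared with a two-sided Mann–Whitney U test, and
p-values are corrected with the Benjamini–Hochberg (BH) step-up
procedure within each band × condition family of all pairs. Group-level
topology is summarised two ways: median-coherence graphs per group at
fixed thresholds (0.5, and 0.7 for robust connections), and
significant-difference graphs containing the FDR-significant pairs
whose case median is below the control median (case-deficit
direction). Region tags on the montage turn difference graphs into
region-pair edge densities.

## Estimator settings and why

* **Welch segments: 2 s, Hann taper, 50% overlap, constant detrend.**
  At 250 Hz this gives a 0.5-Hz grid, which resolves every band
  boundary used here (all are multiples of 0.5 Hz), and the narrowest
  band (alpha2, 1.5 Hz) holds three bins. Over a condition of
  3 × 56-s epochs, $K \approx 165$, so the independent-noise bias of
  MSC ($\mathbb{E}[\hat{C}] \approx 1/K$ for unrelated Gaussian
  channels) is about 0.006 — negligible against any effect of
  interest. Segments are tiled **within** epochs and never straddle an
  epoch boundary.
* **Band membership is half-open** $[low, high)$: each boundary bin
  (e.g. 13 Hz) belongs to exactly one band, so sub-bands partition
  their parent and nothing is counted twice.
* **Coherence is computed on segments pooled across a condition's
  epochs** (equivalent to concatenating the epochs), not per epoch and
  then averaged.
* **MSC is clipped to [0, 1]** against floating-point rounding; the
  Cauchy–Schwarz inequality guarantees the bound analytically, and the
  test suite checks it on a thousand random signal pairs. Bins where a
  channel has zero power have undefined coherence; they are returned
  as `NA` and excluded from band means.
* **$K \ge 2$ is enforced**: a single-segment estimate is identically
  1 and meaningless.

## Preprocessing chain

`preprocess_recording()` applies, in order: zero-phase band-pass
filtering, kurtosis-based bad-channel rejection, channel removal,
average re-referencing, an optional cleaning hook, and condition
segmentation.

* **Filter**: Butterworth band-pass 0.5–35 Hz designed with a
  4th-order low-pass prototype (`signal::butter(4, ...)`, an 8th-order
  band-pass transfer function) and applied forward–backward
  (`filtfilt`), so phase — and therefore cross-spectra — is
  undistorted. The steeper prototype keeps a 50-Hz mains tone below 3%
  of its input RMS after zero-phase application; an order-2 prototype
  would leave ~15%.
* **Bad channels**: Fisher excess kurtosis per channel, z-scored
  across channels; |z| > 5 rejects, in a single pass. A property worth
  knowing: the largest |z| a single outlying channel can attain among
  $n$ channels is $(n-1)/\sqrt{n}$, so this rule *cannot* fire below
  27 channels — it is a dense-montage rule. On the 32-channel fixture
  montage a genuinely spiky channel reaches z ≈ 5.48 and is caught.
  Rejected channels are dropped, not interpolated: interpolation would
  fabricate connectivity for the reconstructed channel, which is worse
  than an honestly missing row.
* **Re-referencing** subtracts the instantaneous channel mean
  (average reference). Coherence is always computed on
  average-referenced data.
* **Cleaning hook**: interactive artifact removal (e.g. ICA) is out of
  scope; `clean_fun` is an identity-default `recording -> recording`
  stage where such a step can plug in.
* **Segmentation**: annotated condition intervals lose their first 4 s
  (auditory-cue transient) and are capped at 56 s; a shorter remainder
  is kept with a message rather than discarded, which maximises data
  while staying auditable.

## The synthetic cohort generator

Because raw resting-state recordings of the emulated design are not
distributable, the generator is a first-class, tested module. Each
subject is a sum of (i) shared band-limited sources — white Gaussian
noise, zero-phase Butterworth band-passed, mixed into a chosen channel
subset with per-source gains — and (ii) independent $1/f$ background
noise per channel, synthesised by frequency-domain shaping (exact
target slope). The recording is organised as alternating 60-s EO/EC
annotated intervals, three per condition, at 250 Hz — six minutes per
subject, matching the emulated protocol; the preprocessing defaults
then yield the 3 × 56-s analysis epochs.

For a pair sharing one source with gains $g_x, g_y$, source PSD $S$
and noise PSDs $N_x, N_y$, the population coherence is the closed form

$$C_{xy} = \frac{(g_x g_y S)^2}{(g_x^2 S + N_x)(g_y^2 S + N_y)},$$

implemented as `analytic_coherence()` and used as the generator's
oracle: empirical Welch MSC of generated pairs converges to it (the
suite checks agreement within ±0.05 at ten minutes of signal).
Subjects are not identical replicates — each subject × source draws a
lognormal gain jitter (sd 0.1 on the log scale, ≈ ±10%) — and every
subject's signal derives deterministically from
(master seed, subject index, group), so cohorts are exactly
reproducible and subjects independent.

### The planted deficit, and two lessons from building it

The demo cohort (`demo_config()`) plants the connectivity effect to be
recovered: a 12-Hz source over right-frontal and frontal-midline
channels, present only with eyes open, whose gain is multiplied by 0.4
in the case group — a 60% reduction of upper-alpha coupling. Two
background sources (occipital alpha, stronger with eyes closed;
fronto-midline theta) are identical across groups so that null bands
contain genuine coherence, not just noise. Defaults: 32 channels,
12 subjects per group.

Two design points are worth recording because they are generic to
band-limited connectivity simulation:

1. **Keep planted sources well inside their band.** A source occupying
   the full 11–13 Hz band has half its edge power exactly at 13 Hz,
   and the Hann mainlobe (±1 Hz at 2-s segments) leaks coherent power
   into the 13-Hz bin — which belongs to beta under the half-open
   convention. With a full-width source the beta/beta1 families showed
   hundreds of spurious "significant" edges; confining the source to
   12 ± 0.25 Hz (order-8 skirts) restores the intended pattern:
   significant edges only in alpha3 × EO and its parent alpha × EO
   cell (whose 7.5–13 Hz range contains the planted bins by
   construction).
2. **Average reference spreads a strong localised source.** With 7 of
   32 channels carrying the source at gain 4.5, the common mode
   subtracted by the average reference injects the source into every
   channel, so within the alpha3 × EO cell the group difference is
   detectable montage-wide, not only on targeted pairs. This is
   faithful reference physics, not a bug — and it shrinks ~7× at 224
   channels. Tests that assert *concentration* of difference edges on
   targeted pairs therefore compute profiles without re-referencing,
   where coupling exists only where planted.

What the generator deliberately does **not** model: volume conduction
and leadfields (so neighbouring channels lack the high broadband
coherence of real scalp EEG, and 0.5-threshold median graphs are much
sparser than on real data), ocular/muscle artifacts, and
nonstationarity. Passing tests therefore validate the estimator and
inference chain, not the realism of scalp topographies.

## Statistical choices

* **Mann–Whitney U**: rank-sum with midranks; exact p-value when
  $n_1 n_2 \le 100$ with no ties (the exact path is verified against
  exhaustive enumeration over all such group sizes), otherwise the
  normal approximation with tie and continuity corrections. The
  statistic reported is U for the case sample, so
  $U_{case} + U_{control} = n_1 n_2$.
* **BH families** are one band × condition set of all channel pairs
  (22 families for 11 bands × 2 conditions); `family = "global"` is
  available for sensitivity analysis. With discrete Mann–Whitney
  p-values at small n the procedure is conservative — at 6 + 6
  subjects the smallest attainable two-sided exact p
  ($2/\binom{12}{6}$) cannot clear the rank-1 BH threshold in a
  496-pair family, which is why desk-scale power simulations use at
  least 8 + 8.
* **Significance cutoff** defaults to q ≤ 0.05 and is recorded in the
  run provenance.
* **Group medians** use the midpoint convention for even counts, and
  "above threshold" is implemented as ≥, making graphs
  bit-reproducible.
* **Summary-statistic t-tests** (`t_from_summary()`) use the pooled
  variance and df $= n_1 + n_2 - 2$, matching the df = 96 reported for
  the questionnaire contrasts; the sign convention is control minus
  case. Recomputing from rounded published means/SDs reproduces
  printed |t| values to ±0.05 for exhaustion, depression and age; the
  cynicism row differs by 0.08, which rounding of its inputs cannot
  close — an apparent inconsistency in the published table, as is the
  sign of its age row (negative although the control mean is larger).

## Problem sizes used in validation

All validation is desk-scale and seeded: the recovery run uses the
full study shape at reduced n (32 channels, 12 + 12 subjects, 2 × 3 ×
60-s intervals — about 90 s of compute); FDR-control runs use 20 null
cohorts of 8 + 8 subjects on a 16-channel montage with 2 × 30-s
intervals; estimator oracles run on seconds-long signals. A
224-channel, 49 + 49 "fullscale" profile is expressible through the
same configuration objects but is not exercised by the test suite.

## Known limitations

* Coherence is a linear, undirected measure; no imaginary-part or
  phase-lag variants are provided, so volume-conduction-driven zero-lag
  coherence on real data is not suppressed.
* Bad-channel rejection is per recording; subjects with differing
  retained channels cannot currently be pooled into one edge-wise
  comparison (the tests require aligned channel lists and fail loudly
  otherwise).
* The EDF writer/reader covers the continuous one-rate EDF+C subset
  this pipeline produces, not the full standard.
* The kurtosis rule's z-score ceiling (above) makes it inert on sparse
  montages; that is a property of the published rule itself, preserved
  deliberately.
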