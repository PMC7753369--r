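---
title: "Multi-resolution SVD fusion for hybrid EEG-fNIRS signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution SVD fusion for hybrid EEG-fNIRS signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msvdfuse)
```

## The problem

A hybrid brain-computer interface records electroencephalography (EEG, fast
electrical activity, hundreds of Hz) and functional near-infrared
spectroscopy (fNIRS, slow cortical hemodynamics, ~10 Hz) at the same time.
Each modality alone supports only modest task-classification accuracy; the
promise of the hybrid system lies in *fusing* them. `msvdfuse` implements a
fusion operator based on the multi-resolution singular value decomposition
(MSVD) and the full pipeline around it — filtering, Modified Beer-Lambert
conversion, synchronization, correlation-based channel selection, wavelet
and statistical feature extraction, and cross-validated classification —
together with a synthetic paired-signal generator so that every stage can be
verified without access to recording hardware or external datasets.

## The MSVD transform

Given a matrix $X \in \mathbb{R}^{2n \times 2m}$ (channels $\times$ samples,
or a reshaped feature vector), each non-overlapping $2 \times 2$ block is
stacked as one column of a data matrix $A \in \mathbb{R}^{4 \times nm}$ in
the order (upper-left, upper-right, lower-left, lower-right); blocks are
enumerated block-row-major. The full SVD $A = U S V^\top$ yields the scatter
matrix $T = U^\top A = S V^\top$, whose four rows — reshaped back to
$n \times m$ — are the subbands $\Gamma_1, \ldots, \Gamma_4$: $\Gamma_1$
(the dominant singular direction) is the approximation, $\Gamma_2..\Gamma_4$
are details. Because $U$ is orthogonal the transform is exactly invertible
($A = U T$, then undo the blocking), row $i$ of $T$ has norm $S_i$, and
$\sum_i S_i^2 = \lVert X \rVert_F^2$. Recursing on $\Gamma_1$ gives an
$L$-level pyramid; only the details and $U$ are kept per level, plus the
approximation at the coarsest level.

Two same-shape pyramids are fused rule-wise:

* details: element-wise maximum magnitude, sign preserved (the larger detail
  is taken to carry the dominant signal power); exact ties keep the first
  argument (the EEG stream by pipeline convention);
* singular-vector matrices: averaged, $U^{fused} = (U^a + U^b)/2$;
* coarsest approximation: averaged.

Fusing a pyramid with itself therefore reproduces the source exactly — the
self-fusion identity that the test suite asserts at pyramid, feature and
system level at $10^{-10}$.

### Numerical conventions

* **SVD sign**: each left singular vector's first non-negligible component
  (|.| > 1e-12) is made non-negative, compensating in $T$. This pins down an
  otherwise backend-dependent sign and makes decompositions byte-stable.
* **Degenerate singular values**: the backend's ordering is accepted and
  then sign-stabilized; subband identity under exact ties is not contractual
  (the round-trip identity still is).
* **Odd shapes**: matrices are padded by edge replication up to the next
  multiple of $2^L$; the padding is recorded and cropped on reconstruction,
  so 6-channel matrices work at any depth. Depth is bounded by
  $2^L \le 4\,\max(\dim X)$ to keep the padded shape proportionate.
* **Default depth** $L = 1$ for both fusion schemes: the 6-row signal
  matrices and $2 \times 4$ feature matrices admit little more structure,
  and every additional level operates on an increasingly padded
  approximation.

## Fusion schemes

**Feature-based fusion** reduces each trial to one 6-vector per modality —
EEG: the mean of each selected channel's level-4 approximation coefficients;
fNIRS: the six statistics (mean, peak, skewness, kurtosis, SD, variance) of
the spatially averaged selected HbO channels. Each 6-vector is rescaled per
feature to [0, 1] across trials, reshaped row-major into a $2 \times 4$
matrix (zero-padded by two entries, since 6 does not factor into two even
dimensions), MSVD-decomposed, fused, reconstructed, cropped and flattened.
Note the pre-fusion rescaling uses all-trial column ranges — a mild
train/test coupling inherent to fusing normalized features before
cross-validation; the classifier-stage scaling, by contrast, is fit on
training folds only.

**System-based fusion** fuses the synchronized $6 \times S$ signal matrices
themselves (EEG stream and HbO stream per trial) and extracts features —
wavelet, statistical, or both — from the fused signal.

## The pipeline

1. **Filtering.** Butterworth IIR per the dataset presets: 1–50 Hz order 4
   (EEG) and 0.01–0.2 Hz order 4 (HbO/HbR) for the motor-execution protocol;
   1–40 Hz order 6 zero-phase with 200 Hz downsampling (EEG) and 0.2 Hz
   low-pass order 6 zero-phase with 10 Hz downsampling (NIRS) for the n-back
   protocol. The synthetic preset applies the first set of bands
   *zero-phase*: offline analysis has no causality constraint, and the
   causal narrow-band filter's group delay (seconds at 0.08 Hz) would
   misalign the hemodynamic response with the trial windows. Causal
   filtering warm-starts the filter state at the signal's initial value
   (steady-state initialization), so constants pass at DC gain without
   start-up transients; zero-phase filtering uses odd-reflection padding of
   3x the filter length and a forward-backward pass.
2. **MBLL.** Raw dual-wavelength intensities convert to HbO/HbR
   concentration changes by $\Delta OD_\lambda = -\log_{10}(I_\lambda /
   \bar I_\lambda^{baseline})$ and a per-optode $2 \times 2$ linear solve
   with tabulated extinction coefficients (760/850 nm defaults), DPF 6 and
   3 cm source-detector distance — all overridable. The synthetic generator
   emits HbO/HbR directly, so MBLL sits in the pipeline only for intensity
   data.
3. **Standardization.** Per channel, subtract the mean and divide by the
   population (divide-by-n) standard deviation; the convention is fixed and
   documented because skewness/kurtosis-style comparisons depend on it.
4. **Synchronization.** Both modalities are placed on a common 10 Hz grid by
   a 1-s sliding mean followed by resampling. For EEG the synchronized
   stream is the *band-power envelope* (squared signal, 1-s mean): the raw
   oscillation averages to nearly zero under a 1-s window, whereas its
   envelope is the quantity that co-varies with the hemodynamics. A raw
   mode exists behind the `envelope` flag of `rank_channels()`.
5. **Channel selection.** Pearson correlation of every EEG-envelope x HbO
   channel pair on the common grid; pairs ranked by |rho| (neurovascular
   coupling can invert sign across chromophores); greedy selection of pairs
   with both channels still unused until `k = 6` per modality. Ties break
   toward lower channel indices, making selection deterministic and the
   top-k sets nested. Selection runs once per recording — matching the
   once-per-subject practice — rather than on the first rest block, which
   contains no task structure and would rank channels by noise; a strict
   per-fold mode is the obvious extension for leakage-sensitive studies.
6. **fNIRS epoch lag.** HbO trial windows are shifted by `nirs_lag_s = 3` s:
   the boxcar x HRF response averages 0.12 of its peak over [0, 6) s after
   onset but 0.52 over [3, 9) s, while the previous trial's leakage drops
   from 0.24 to below zero. Standard practice for slow hemodynamics; set it
   to 0 to reproduce strictly onset-locked windows.
7. **Features and classification.** Wavelet features use the sym4 symlet
   (filter length 8, quadrature-mirror high-pass derived in code as
   $h_k = (-1)^k g_{F-1-k}$) under periodic boundary extension, which makes
   the filter bank exactly orthonormal — energy conservation is a test, not
   a hope. The decomposition depth is capped at
   $\lfloor \log_2(N/(F-1)) \rfloor$; the target is 4 levels where the trial
   length allows it (native-rate EEG), 3 on the 60-sample synchronized
   grid. The [0, 1] feature rescaling is applied per feature across trials,
   fit on training folds only inside the stratified 10-fold CV. KNN (k = 5,
   Euclidean, vote-fraction scores, distance and vote ties broken by lower
   index) and a Gini-impurity CART-style tree (unlimited depth, minimum
   leaf 1; zero-gain splits on impure nodes are taken so XOR-type
   interactions remain solvable) produce accuracy, macro one-vs-rest
   specificity, and macro one-vs-rest rank-sum AUC, all in percent.

## The synthetic generator

`gen_hybrid()` emulates a motor-execution-style block protocol: trials of
6 s rest + 6 s task, four active classes against a rest class, EEG at 250 Hz
and fNIRS at 10.42 Hz, 12 channels per modality of which 6 are informative.
Class $k$ has task amplitude 0 for the rest class and $2 + \text{fine}_k$
otherwise, where the fine structure differs between modalities: EEG levels
(0, 3, 3, 4, 4) and fNIRS levels (0, 3, 4, 3, 4). The shared dominant gain
keeps the planted EEG-envelope/HbO correlations strong (the quantity channel
selection recovers), while the complementary fine structure means EEG alone
separates {2,3} from {4,5}, fNIRS alone separates {2,4} from {3,5}, and only
the fused system can separate all five — the qualitative signature of a
useful multimodal fusion.

Informative EEG channels carry the class amplitude on 10 Hz and 20 Hz
oscillations with random phase per trial (induced activity, not phase-locked
potentials) over 1/f background noise; informative HbO channels carry the
class-amplitude boxcar convolved with a canonical double-gamma hemodynamic
response (peak 6 s, undershoot 16 s, ratio 1/6), contaminated by Mayer-wave
(0.1 Hz), respiratory (0.3 Hz) and cardiac (1.2 Hz) sinusoids plus white
noise; HbR is a negatively scaled HbO copy with independent noise. Noise
amplitude scales as 1/SNR with both SNRs defaulting to 1 (order-unity
amplitude signal-to-noise, typical of averaged task responses);
`trials_per_class` defaults to 10 so the default session supports 10-fold
stratified CV. Every channel draws from its own seeded substream, so the
arrays are byte-reproducible and adding channels does not perturb existing
ones.

What the generator does *not* emulate: phase-locked event-related
potentials, motion artifacts, optode-skin coupling drift, spatial channel
correlations, subject variability, or any biophysical forward model. Two
consequences matter when reading the test results:

* Raw wavelet-coefficient features of unimodal EEG sit near chance on this
  data — with random oscillation phase the coefficient vectors decorrelate
  across trials, and only power-like quantities discriminate. The hybrid
  pipeline succeeds because its synchronized EEG stream is the band-power
  envelope. On phase-locked ERP-dominated recordings the deep approximation
  coefficients would instead be the strong unimodal EEG feature, and deeper
  levels would be expected to beat shallower ones.
* Because every class signal is a *scaled copy of one waveform*, the trial
  mean and peak are near-sufficient statistics, and the six statistical
  features of the fused signal outperform the wavelet-coefficient features
  (the suite computes both; the wavelet-vs-statistics ordering check is
  expected to fail on this generator). On real recordings, where classes
  differ in temporal shape and phase rather than pure scale, the six global
  statistics discard most of the discriminative structure and the ordering
  reverses. This is the main caveat when extrapolating synthetic results to
  real data.

## Problem sizes and runtimes

The classification-level checks run on 5 classes x 40 trials (200 trials,
seed 42) with 10-fold stratified CV — large enough for stable fold metrics,
small enough to keep the whole suite under a minute. Channel-selection
recovery is evaluated over 20 generator seeds at the default 12-channel /
6-informative configuration. Algebraic checks (reconstruction, oracle
equivalence, energy conservation) use 50-200 random matrices or signals per
property. The structural tolerances are 1e-10 (exact algebra), 1e-9 (energy
accumulation) and 1e-8 (eigenvalue-oracle agreement).

## Known limitations

* The printed-formula depth bound for the wavelet filter bank is implemented
  as the standard $\lfloor \log_2(N/(F-1)) \rfloor$; signals shorter than
  112 samples cannot reach 4 levels, so short synchronized trials use the
  admissible maximum (3).
* Only two-modality fusion is supported; the rule set has no weights to
  learn.
* The MBLL constants are literature defaults; for quantitative concentration
  units they must be matched to the actual optode geometry.
* `fuse_details` ties (exactly equal magnitudes) break toward the first
  argument, so fusion is commutative only off that measure-zero set.
* Feature-based fusion normalizes feature columns over all trials before
  fusing (see above); studies requiring strict fold isolation should prefer
  the system scheme, whose per-trial fusion uses no cross-trial statistics.
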