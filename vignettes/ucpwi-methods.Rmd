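---
title: "Methods: deep-learning post-processing for contrast-agent plane-wave imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep-learning post-processing for contrast-agent plane-wave imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Plane-wave insonification images the whole field with a single
unfocused transmit, which buys frame rate and keeps the mechanical
index low enough not to destroy microbubble contrast agents — but it
pays with poor contrast: without a transmit focus, tissue clutter
competes with the microbubble signal. `ucpwi` implements a three-stage
post-processing chain that attacks the clutter in the channel-domain RF
before an image is ever formed:

1. a 1-D **U-net** classifies short RF segments as *microbubble* or
   *tissue* and zeroes the tissue;
2. the **bubble-approximated wavelet transform (BAWT)** replaces the
   surviving RF with matched-filter coefficients against a simulated
   bubble echo, and a **maximum-eigenvalue threshold** removes residual
   tissue patches;
3. **eigenspace-based minimum-variance (ESBMV)** beamforming forms the
   final image inside the detected bubble area.

Because no public channel-RF recordings accompany this problem, the
package ships a plane-wave simulator that generates the study
conditions synthetically, with per-sample ground truth. Everything the
tests and the acceptance script assert is computed on those synthetic
conditions.

# The microbubble model

Stage 2's mother wavelet is the far-field pressure scattered by a
single shelled microbubble, obtained by integrating a Doinikov-type
shell model for the bubble wall radius $R(t)$:

$$\rho_l \left(R\ddot R + \tfrac32 \dot R^2\right) =
  \left(P_0 + \frac{2\sigma(R_0)}{R_0}\right)\left(\frac{R_0}{R}\right)^{3\gamma}
  - \frac{2\sigma(R_0)}{R} - 4\chi\left(\frac1{R_0} - \frac1R\right)
  - P_0 - P_\mathrm{drive}(t) - 4\eta_l\frac{\dot R}{R}
  - 4\left(\frac{k_0}{1 + \alpha\left|\dot R/R\right|} + k_1\frac{\dot R}{R}\right)\frac{\dot R}{R^2}$$

with the SonoVue-like constants carried by `bubble_params()`
($\rho_l = 1000$ kg/m³, $P_0 = 101$ kPa, $\gamma = 1.07$,
$R_0 = 1.7\,\mu$m, $\sigma(R_0) = 0.072$ N/m, $\chi = 0.25$ N/m,
$\eta_l = 2$ mPa·s, $k_0 = 4\times10^{-8}$, $k_1 = 7\times10^{-15}$,
$\alpha = 4\,\mu$s). The scattered pressure at distance $d$ is
$P(d) = \rho_l (R/d)(2\dot R^2 + R\ddot R)$, exactly $\propto 1/d$.

Numerical choices:

* The ODE is integrated with an adaptive Dormand–Prince 4(5)
  Runge–Kutta scheme (`deSolve::ode(method = "ode45")`, rtol $10^{-8}$,
  atol $10^{-12}$) in **log-radius** coordinates $u = \log(R/R_0)$, so
  trial steps can never evaluate the right-hand side at a non-physical
  $R \le 0$. $\ddot R$ is recovered by evaluating the right-hand side
  on the solution, never by finite differences.
* **Drive amplitude.** With the shell-viscosity term implemented
  exactly as written above, the $k_1$ contribution is quadratic in the
  wall velocity with a collapse-accelerating sign during compression,
  and the equation has a finite-time blow-up for a 4 MHz two-cycle
  drive at roughly 70 kPa and above (lower at 3–3.5 MHz). The package
  therefore drives the wavelet bubble at **50 kPa** by default —
  mechanical index $0.05/\sqrt{4} = 0.025$, safely in the low-MI regime
  contrast imaging requires — and the corpus generator varies the drive
  over 30–50 kPa, all verified inside the stability envelope. A
  `solve_bubble_dynamics()` call outside that envelope fails loudly
  rather than returning a diverged trajectory.
* The wavelet is the scattered pressure trimmed to the window holding
  99.9% of its energy, mean-subtracted (zero-mean admissibility) and
  normalized to unit continuous energy; it is stored oversampled at
  100 MHz so that dilation onto a 25 MHz RF grid interpolates from a
  fine source grid. Its measured spectral peak $f_c$ (≈ 3.8 MHz at the
  defaults) defines the optimal scale $s = f_c / (2 f_0)$ that places
  the dilated passband on the second harmonic $2f_0$.

# The synthetic study conditions

`simulate_plane_wave_rx()` emulates a 0° plane-wave acquisition on a
128-element, 0.3 mm-pitch linear array sampled at 25 MHz, 2100 samples
per line, 4 MHz two-cycle transmit — the acquisition geometry the
method targets. Echoes are delayed by $z/c_0$ plus the per-element
return path with linear-interpolated fractional delays; amplitude falls
as reflectivity over return distance; $c_0 = 1540$ m/s (standard
soft-tissue value; the source conditions do not state one). Tissue
scatterers echo the transmit pulse (linear); bubble scatterers echo the
Doinikov scattered-pressure waveform (nonlinear, second-harmonic-rich).
A per-sample `truth_mask` records which samples each echo type covers,
with bubble taking precedence where they overlap.

Deliberate emulation choices, and what they mean for the tests:

* **Tissue is dense speckle.** Corpus phantoms draw 150–250 tissue
  scatterers so element lines are densely covered; with sparse point
  targets nearly every 60-sample window is majority-background and the
  tissue class starves.
* **Training corpora are single-class acquisitions.** The corpus
  alternates frames of pure microbubble solution (bubbles throughout
  the field, as in a beaker recording) and frames of pure tissue
  speckle, which is how such training data is collected in practice;
  per-sample truth on *mixed* frames still drives every inference-time
  evaluation. With mixed-frame training windows, tissue and bubble
  echoes superpose inside single windows and cap attainable accuracy
  near 80%; single-class acquisitions restore a well-posed
  classification problem (a linear spectral probe alone reaches ≈ 98%).
* **Omitted physics:** element directivity, attenuation, transducer
  impulse response (4–11 MHz band), multiple scattering, bubble motion,
  and angle compounding. The chain operates on RF statistics, not
  absolute calibration, so these affect realism but not the contracts
  under test. Passing tests therefore demonstrate the pipeline's
  internal correctness and its behavior under the stated statistical
  structure (tissue centered at $f_0$, bubbles carrying a
  second-harmonic excess ≥ 10 dB measured on Hann-tapered averaged
  segment periodograms) — not field performance on a clinical scanner.
* Segmentation follows the study conditions: length-60 windows, step 5
  (409 windows per 2100-sample line), majority-vote labels with ties
  going to bubble, windows more than 50% background excluded from
  training, 45/55 bubble/tissue balance, 80/20 train/test split. The
  split is applied at the *frame* level so heavily overlapping windows
  never straddle it.

# The classifiers

The U-net reads a length-60 segment (per-segment RMS-normalized, so
classification rests on waveform shape rather than depth-dependent
amplitude) and emits a 2-class softmax. The hidden stack is 14
convolutions (kernel 3×1, stride 1, zero-padded), three 2×1 max-pool
downsamplings, three nearest-neighbour upsamplings, three fusion
concatenations, four dropout layers (rate 0.5) and one dense layer.
Encoder widths 32/64/128 are fixed by the design; the remaining widths
are not, and were chosen as bottleneck 197 and decoder 150/93/32 — the
integer plan whose total trainable parameter count is exactly
**607,112**, the published architectural checksum
(`count_parameters(build_unet())` reproduces it). Length bookkeeping:
60 → 30 → 15 → 7 through the pools (the odd trailing sample of 15 is
dropped), then 7 → 14 → zero-pad to 15 → 30 → 60 through the decoder,
with the pad making the fusion alignment deterministic. Dropout sits
after each encoder conv pair and after the bottleneck, matching the
stated "conv + activation + dropout + downsample" block structure.

The CNN baseline is conv128×2 → pool → conv64×2 → pool → dropout →
two dense layers; the RNN baseline is four stacked 100-unit tanh
recurrent layers → dropout → three dense layers. All three share one
`train_classifier()` / `predict_proba()` / `predict_mask()` interface,
and all three backward passes are verified against central finite
differences in the test suite.

Training uses Adam (β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁸) on softmax
cross-entropy, batch 100. The `"paper"` profile is 150 epochs at step
10⁻⁵; the `"fast"` profile used by the desk-scale checks is 12 epochs
at 10⁻³ — on the synthetic corpus the problem is far easier than field
data, and held-out accuracy typically saturates (> 0.99) within a few
epochs; the extra epochs buy margin on seeds where the
feature-learning transition arrives late.
The engine is hand-written on BLAS matrix operations with the
convolution im2col/GEMM kernels in C++ (RcppArmadillo); no
deep-learning framework is required.

At inference, `predict_mask()` scores all sliding windows and assigns
each RF sample the *mean* bubble probability of every window covering
it (an order-invariant aggregation; the source flow classifies segments
but does not state how overlaps combine), thresholded at 0.5.
Background samples inherit whatever the two-class network assigns —
at training time they are excluded rather than given a third class.

# BAWT and the eigenvalue threshold

`cwt_line()` correlates an RF line with the dilated,
energy-renormalized wavelet in "same" mode (zero-padded edges, so
coefficients within half a wavelet of the line ends are attenuated).
The L2 (1/√s) normalization convention is adopted; the discrete dilated
kernel has unit sum of squares, so a line equal to the kernel itself
correlates to a peak of 1. Only the single optimal scale enters the
pipeline; other scales remain available as a library call.
`apply_bawt()` replaces classifier-flagged samples with coefficients
and **zeroes** tissue-flagged samples — the flow replaces classified
signal only, and residual tissue must be suppressed before beamforming.

Beamforming conventions (`beamform_frame()`):

* one scan line per element position, pixels gathered with the 0°
  plane-wave delay law and linear interpolation;
* subarray covariance averaged over the $M - L + 1 = 97$ sliding
  subarrays of length $L = 32$;
* diagonal loading $\varepsilon = \delta\,\mathrm{trace}(R)$ with
  $\delta = 1/(10L)$ by default — the source bounds $\delta \le 1/L$
  without fixing it, and $1/(10L)$ is a conventional mid-range choice;
* signal subspace from the eigenvectors with
  $\lambda_i \ge \alpha \lambda_1$, $\alpha = 0.4$ (the alternative
  noise-floor rule for choosing the subspace dimension is not
  implemented, since the reference flow states only the α-rule);
* steering vector all-ones (delays already applied), MV weight
  $w = \tilde R^{-1} d / (d^H \tilde R^{-1} d)$ computed **once per
  pixel** and shared across the subarray outputs, as the printed
  subarray-sum equations read; ESBMV projects that weight onto the
  signal subspace before the same sum;
* a singular system (possible only for pathological inputs — loading
  guarantees positive definiteness whenever the pixel has energy)
  falls back to uniform DAS weights with a warning; a zero-energy pixel
  is left silent.

The detection rule flags a pixel as bubble when its largest eigenvalue
reaches `c_frac = 0.15` of the maximum on its own scan line; every
non-silent line therefore flags at least its own argmax, which is the
per-line normalization the rule is defined with. Detection is
per-pixel; no connected-component cleanup is applied.

# Metrics and display

The display is the analytic-signal envelope per line, log-compressed to
$[-60, 0]$ dB. Detection removes signal: outside the detection mask the
envelope is zero, which the dB display clips to the −60 dB floor. A
perfectly cleaned tissue region therefore yields an undefined (infinite)
CTR, reported as `+Inf` with a warning — a true statement of complete
suppression rather than a number to average. CTR and CNR are computed
on the linear (pre-log) envelope:
$\mathrm{CTR} = 20\log_{10}(I_\mathrm{UCA}/I_\mathrm{tissue})$,
$\mathrm{CNR} = 20\log_{10}(|I_\mathrm{UCA}-I_\mathrm{tissue}|/
\sqrt{\sigma^2_\mathrm{UCA}+\sigma^2_\mathrm{tissue}})$. The absolute
value in the CNR numerator keeps the logarithm defined when tissue
outshines contrast (plain plane-wave images of a strong tissue layer
routinely have $I_\mathrm{tissue} > I_\mathrm{UCA}$); with this
convention CTR is positive when the contrast region dominates, and
*improvement* is reported as the difference against plain DAS.
Computing the means on dB-clipped images would saturate at the floor,
which is why the linear envelope is used.

# Problem sizes used by the checks

The shipped checks run at desk scale, chosen so the whole suite
completes comfortably on a single CPU: a 20,000-segment corpus from 16
simulated frames for classifier training (fast profile); a single
2100 × 128 tube-phantom fixture (pork-like speckle layer with three
strong scatterers over a 3 mm bubble tube at 26 mm) beamformed over
6–30 mm at depth decimation 2 for the end-to-end ablation ladder; and
small algebraic fixtures (L ≤ 32) for the beamformer oracles.

# Known limitations

* The shell-model blow-up above ~60 kPa is a property of the equation
  as printed; amplitudes near the envelope edge produce increasingly
  stiff (slow) solves.
* The classifier generalizes across the simulated drive grid
  (3.5–4.5 MHz, 30–50 kPa) but has never seen a physical transducer's
  impulse response; trained weights are not transferable to real
  recordings.
* BAWT edge attenuation biases coefficients within half a dilated
  wavelet of the line ends.
* The per-line eigenvalue threshold guarantees at least one detection
  per non-silent scan line, including lines with no bubble content;
  downstream metrics must tolerate such isolated false positives, as
  the tables here do.
* MV/ESBMV assume the delayed data are coherent across the subarray;
  gross sound-speed errors (not modeled) would degrade them before
  they degrade DAS.
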