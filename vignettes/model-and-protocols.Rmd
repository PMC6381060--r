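---
title: "A recurrent V1-MT circuit with depressing synapses: model, protocols and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A recurrent V1-MT circuit with depressing synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skewadapt)
```

## The scientific problem

Prolonged viewing of geometrically skewed scenes — the everyday experience of
progressive-lens wearers — biases the motion-direction statistics of the
retinal input. After such exposure, the direction of a moving test pattern is
misperceived away from the adapted direction: a motion aftereffect (MAE)
measurable as a shift of the point of subjective equality (PSE), the test
direction reported "upward" on half the trials. `skewadapt` implements a
mesoscopic model of this adaptation: direction-tuned populations in V1 and MT
coupled by a driving feedforward (FF) projection and a modulatory re-entrant
feedback (FB) projection, with short-term synaptic depression in both
streams, plus the stimulus generators, simulated psychophysical protocols and
psychometric analysis needed to reproduce the phenomenon end to end.

## Model

Each area holds `n = 37` units with direction preferences on the half circle
from $-90^\circ$ (down) to $+90^\circ$ (up) in $5^\circ$ steps. A unit's mean
membrane potential $v \in [-1, 1]$ follows shunting single-compartment
dynamics

$$\tau \dot v = -v + (1 - v)\,I_{ex} - (1 + v)\,I_{inh}, \qquad
\tau = 30\ \mathrm{ms},$$

whose fixed point under constant drives is
$(I_{ex} - I_{inh})/(1 + I_{ex} + I_{inh})$ — saturating, and bounded in
$(-1, 1)$ for non-negative drives. The drives are

* V1 excitation: $(G * R_\theta)\,(1 + \lambda\, y^{FB} [v^{MT}]_+)$ — the
  direction-filtered input, multiplicatively enhanced where MT predicts
  signal ($\lambda = 20$);
* MT excitation: $y^{FF} (G * [v^{V1}]_+)$ — the FF drive, gated by the FF
  synaptic efficacy;
* inhibition: the mean excitatory drive across the population (pool
  normalization), identical in both areas. A featureless (uniform) input is
  therefore exactly balanced and evokes no response.

$[v]_+ = \max(v, 0)$ is used wherever a potential acts presynaptically
(firing rates are non-negative, and the modulation factor must not invert
sign); the raw potential remains the state variable. Higher-order modulation
into MT (MST, attention) is held at zero.

Synaptic efficacies $y \in [0, 1]$ are vesicle occupancies gating each
stream, depleted by presynaptic activity and tonically replenished:

$$\tau_{syn}\,\dot y = \alpha\,(1 - y) - \beta\, y\,[v]_+ , \qquad
\tau_{syn} = 1\ \mathrm{s},$$

with fixed point $\alpha / (\alpha + \beta v)$. The published rate pairs
make the FF synapse fast (depletion time constant tens of milliseconds under
drive, recovery $\sim 1$ s) and the FB synapse slow (recovery
$1/\alpha = 25$ s) — the two adaptation time-scales of the model. The five
model variants (`variant_params(1:5)`) cross circuit complexity (FF-only
versus FF–FB) with these rate regimes; variant 5 carries both.

Decisions are read from MT by two Gaussian channels centered at
$\pm 90^\circ$ and a softmax with temperature `temp`
(`readout()`), giving the probability of an "upward" report. The readout
uses the time-averaged rectified MT response of the test interval — more
robust than an instantaneous sample and the natural model of an observer
integrating over the 0.3–0.5 s test.

### Width conventions

The published circuit constants name a "width" of $45^\circ$ for the
direction kernels and readout channels, and $15^\circ$ for the test-stimulus
direction signal, without fixing the convention. We resolve them as follows
(all configurable via `width_as` arguments):

* Direction kernel: **span** — $45^\circ$ is the full $\pm 2$ SD tuning
  extent, SD $= 11.25^\circ$. A kernel with SD $45^\circ$ (or even FWHM
  $45^\circ$, SD $19^\circ$) smooths so heavily on the $180^\circ$ grid that
  the no-feedback V1 response to skewed statistics could never remain
  bimodal, contradicting the published response patterns; the span reading
  leaves a window in which one convolution stage (V1) preserves the
  bimodality and the second (MT) merges it, which is the published
  disambiguation behavior.
* Readout channels: **SD** $= 45^\circ$. The two channels are broad
  integrators for the up/down decision; with a narrow reading a
  near-horizontal test response would be invisible to both channels and the
  decision would be at chance.
* Test signal: **SD** $= 15^\circ$, following the description of the test
  input as direction noise of that width.

### Operating point

The reference parameterization fixes the synaptic rate constants but not
the absolute scale of the direction signal $R_\theta$ that they were fitted
against; the two are mutually calibrated. The package fixes the adapting signal's dominant
peak at 1 and the random-dot test signal at amplitude 0.05 of that. The
weak-probe regime matters: the test stimulus must probe the adapted state,
not re-adapt the circuit. With order-of-unity probes the tests themselves
deplete the synapses, null-protocol PSEs reach several tenths of a degree
and the ordering bias of the PSE sum is dominated by test-history effects.
At 0.05 the null-protocol PSEs of the randomized designs are
$\sim 0.01^\circ$ and all aftereffect signs are stable across seeds.

## Stimuli and the synthetic-data generators

`apply_skew()` implements the shear $(x, y) \mapsto (x + \tan\Psi\, y,\,
\tan\Psi\, x + y)$ about the image center, in pixel-matrix coordinates
(x rightward, y downward), resampled by inverse mapping with bilinear
interpolation and cropped to the central square (650/720 of the short side,
matching the full-scale stimulus proportions). `hanning_window()` applies
the circular raised-cosine aperture $w(r) = \cos^2(\pi r / N)$.
`synth_movie()` builds a desk-scale surrogate for natural movie input: a
random-phase $1/f$ texture translating coherently, with piecewise-constant
direction and speed, shifted by Fourier phase ramps (periodic, deterministic
per seed). Passing such movies through the Reichardt front-end shows the
signature the full-scale stimuli are reported to have: an un-skewed
horizontally drifting sequence pools to a direction signal peaked at
$0^\circ$, and per-frame skew shifts the dominant direction in the skew
direction — by substantially more than the $\pm 25^\circ$ velocity rotation,
because the shear also stretches the texture along one diagonal and the
resulting orientation anisotropy biases correlation detectors toward the
perpendicular. This aperture effect is presumably why the full-scale skewed
sequences are dominated by $\pm 50^\circ$ rather than $\pm 25^\circ$.

Because the recurrent stage consumes only the pooled direction signal, the
protocols use a parametric surrogate of those statistics
(`direction_stats_model()`): a broadband baseline (0.1) plus Gaussian
components — down-skew: dominant mode at $-50^\circ$ (SD $12^\circ$,
amplitude 1) and a horizontal remnant at $0^\circ$ (SD $12^\circ$, amplitude
0.7); up-skew is the exact mirror. The surrogate reproduces the
bimodal-over-baseline shape of skewed natural statistics but none of their
trial-to-trial variability, spatial structure, or up/down asymmetries of
real scenes; model results under it are statements about the circuit, not
about any particular movie. In particular, with exactly mirrored adaptors
the ordering bias of the PSE sum can only arise from state carry-over, not
from adaptor-strength asymmetry (both mechanisms are conceivable in the
human data).

`dot_field()`/`update_dots()` generate the random-dot test stimulus itself
(2000 dots, 0.14$^\circ$, 3$^\circ$/s, 17.6$^\circ$ aperture — the display
geometry of the psychophysical setup at 57 cm); the printed per-frame update
rule is dimensionally a projection and cannot produce coherent translation,
so the update advances positions by speed $\times\ dt$ along the motion
direction, with out-of-aperture dots redrawn uniformly inside.

## Protocols

`build_schedule()` encodes three session designs, all down-skew (DSK) block
first, then up-skew (USK), with no state reset anywhere in a session:

1. **Short exposure**: 0.3 s top-up / 0.3 s blank / 0.3 s test / 0.3 s
   blank; 12 test directions $-6.6^\circ..6.6^\circ$ in $1.2^\circ$ steps
   (the printed endpoints and step admit exactly 12 values only without
   $0^\circ$), 5 repetitions, randomized order; 60 responses per block.
2. **Long exposure**: 180 s initial adaptation opening the session, then
   0.5 s blank / 0.5 s test / 15 s top-up per trial. The USK block switches
   directly to top-ups: a fresh 3-min USK re-adaptation would, by the
   model's own synaptic time constants, fully erase the DSK trace and with
   it the ordering bias that the carry-over interpretation requires.
3. **Sequential (hysteresis)**: as (1) but 14 directions
   $-13^\circ..13^\circ$ in $2^\circ$ steps, swept ascending in the DSK
   block and descending in the USK block, 4 cycles (56 responses per block).

In the randomized designs the USK block presents the negated DSK order
(mirror-yoked). The order is still random, but the two blocks are exact
reflections of each other, so order-sampling noise — which otherwise swamps
the PSE sum at $\pm 0.7^\circ$ — cancels exactly in the no-memory limit, and
any non-zero PSE sum isolates the deterministic carry-over of the DSK-first
design. Consequently the pass criterion on the PSE sum defaults to a strict
sign test (`evaluate_variant_pattern(sum_min = 0)`).

Per-cell validity additionally requires both fitted PSEs to lie inside the
tested direction range: a psychometric function that never crosses 50%
within the measured levels is not a valid constant-stimuli measurement
(this is how the degenerate hard-choice variant 1 fails, with the maximal
deviation — the tested-range width — per summary).

## Psychometrics

`fit_psychometric()` fits
$\psi(\theta) = \gamma + (1 - 2\gamma)\,\Phi((\theta - \mu)/\sigma)$ with a
shared lower/upper asymptote $\gamma \in [0, 0.25]$, by binomial maximum
likelihood for k-of-n data and least squares for real-valued model outputs,
using bounded L-BFGS-B from a deterministic 6-point start grid ($\mu$ at the
extreme and central levels $\times$ $\sigma$ at a quarter and half span),
with a polish restart when a line search terminates abnormally at an
optimum; ties break by objective, then smallest $|\mu|$. $\mu$ is the PSE.
`aftereffect_summary()` forms $\Delta PSE = PSE_{USK} - PSE_{DSK}$ (the MAE
magnitude; positive for repulsion) and $\Sigma PSE = PSE_{USK} + PSE_{DSK}$
(the ordering bias; negative when the first-adapted DSK state carries over).

## Numerical choices

* Forward Euler at `dt = 1 ms` ($\tau/30$); `step()` is the readable R
  reference and `run_segment()` the identical compiled loop (they agree to
  $10^{-13}$; a consistency test enforces this). Updates use the pre-update
  rectified potentials; values may leave their invariant ranges only by
  $<10^{-6}$ (clipped), larger excursions raise an error naming the bound.
* The direction kernel is truncated at the grid boundary (no wraparound on
  the half-circle) and row-renormalized to unit sum, which makes the
  balanced-input null exact.
* The softmax exponent is max-subtracted, so the hard-choice temperature of
  variant 1 ($10^{-5}$, effectively a step) is safe.
* Population peak locations are refined by a quadratic fit through the
  argmax and its neighbours (`response_peak()`), giving sub-grid resolution
  of repulsion shifts; modality is classified by topographic prominence
  (`find_peaks()`, 5% of the curve maximum).
* Problem sizes: protocol simulations integrate the full published session
  lengths (the long-exposure session is $\sim$2,100 s of model time, 2.1M
  Euler steps); surrogate movies default to 50–64 px frames and tens of
  frames, with full-scale sizes available through the same arguments.

## What the model does and does not reproduce

Under the frozen defaults (seed-robust, recomputed by
`scripts/acceptance.R` and the test suite):

* Repulsive MAEs with the correct signs in all three protocols for the
  two-rate FF–FB model (variant 5): $\Delta PSE > 0$, $\Sigma PSE < 0$, with
  the long-exposure $\Delta PSE$ the largest — and variant 5 is the only
  variant passing all three protocols, with the smallest average prediction
  error.
* Feedback disambiguation: without FB the V1 response to the bimodal skewed
  statistics is bimodal and MT unimodal in between; with FB both are
  unimodal at the dominant direction (argmax coincident to grid
  resolution — exact coincidence is impossible because the fast FF
  depression already repels MT's peak during the exposure).
* Sub-second adaptation repels both V1 and MT responses to a horizontal
  test under FB, and MT only without FB.

Known mismatches with the published account, left visible as failing
expectations rather than patched:

* The comparative repulsion size: here the FF-only variant shows the larger
  MT shift. With multiplicative resonance feedback the recurrent loop
  re-anchors the test response to the bottom-up input and corrects the
  repulsion; the published larger shift under feedback is not attainable
  with this modulation form on a clean unimodal test signal.
* The full five-variant pass/fail pattern: sign-based criteria cannot
  express failures that were overshoots of the human numeric ranges (the
  slow-FF variant 2 saturates within 0.3 s at any input scale — its
  depletion rate $\beta v$ exceeds its recovery rate — so its sub-second
  MAE is large, not absent), and $\Sigma PSE$ criteria discriminate memory,
  not time-scale: only slow-FB variants carry the bias, and no variant can
  carry it through a 3-min re-adaptation.
* The sequential protocol retains genuine hysteresis ($\sim 0.2^\circ$) even
  with adaptors removed — the phenomenon that protocol was designed to
  elicit — so its null-adaptation PSEs do not vanish like the randomized
  protocols' do.

## Limitations

Space is pooled out before the recurrent stage (as in the source
architecture); there are no lateral intra-areal connections, no spiking, no
observer lapses or reaction times, and the decision stage is a steady-state
softmax rather than an accumulation process. The surrogate statistics are
stationary within a block; real movie statistics fluctuate. Conclusions
about absolute effect sizes (in degrees) therefore depend on the operating
point above; the sign structure and time-scale dissociations are the robust
content.
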