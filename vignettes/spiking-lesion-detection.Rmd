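---
title: "Rate-coded spiking networks for lesion detection: models, conversion and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate-coded spiking networks for lesion detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(spikelesion)
```

# The problem

Single-stage convolutional detectors locate and classify breast lesions in
grayscale medical images (ultrasound, film mammography). Spiking neural
networks (SNNs) promise the same inference at a fraction of the arithmetic
energy, because an event-driven network performs one *accumulate* (AC) per
spike per synapse instead of one *multiply-accumulate* (MAC) per weight per
output. Training deep SNNs directly is hard (spike generation is
non-differentiable), so this package follows the conversion route: train a
conventional ReLU network, then re-express it as a rate-coded spiking
network whose firing rates approximate the original activations.

The package implements the full chain on synthetic data: a
leaky integrate-and-fire (LIF) neuron simulator with its closed-form
solutions, a layer-graph container with batch-norm folding and
ANN-to-SNN conversion, a small multi-scale saliency-fusion detection
network with desk-scale training, PASCAL-VOC detection metrics, a MAC/AC
energy model, per-scanner optical-density calibration for film mammograms,
and a synthetic lesion image generator so that nothing requires an
external dataset.

# Leaky integrate-and-fire neurons

The membrane potential obeys
$$\tau \frac{dV_m}{dt} = -(V_m - V_{rest}) + R_m I(t), \qquad \tau = R_m C_m .$$
Under constant drive $I_0$ from rest the solution is the charging curve
$$V_m(t) = R_m I_0\,(1 - e^{-t/\tau}) + V_{rest},$$
and the neuron first reaches threshold $V_{th}$ after
$$\Delta T = \tau \ln \frac{R_m I_0}{R_m I_0 - (V_{th} - V_{rest})},$$
provided the asymptote $R_m I_0$ exceeds the distance to threshold;
otherwise it never fires, which `first_spike_interval()` reports as `NA`
rather than an error.

Defaults (all in mV/ms): $V_{rest} = 0$, $V_{th} = 1$, $V_{reset} = 0$,
$\tau = 10$ ms, refractory period 1 ms, step $\Delta t = 0.01$ ms. Because
the drive always enters as the voltage $R_m I_0$, the individual values of
$R_m$ and $C_m$ are never needed and are not parameters.

Numerical choices: integration is explicit Euler at $\Delta t$ (first
order; the convergence test halves the step and checks the error halves
within ±20%). A spike is emitted at the first *sampled* step where
$V \ge V_{th}$, with no sub-step interpolation — consistent with the
discrete-time update used for conversion. During the refractory window the
membrane is clamped at $V_{reset}$ and the drive is ignored; the full
period between spikes is therefore $\Delta T + \tau_{ref}$.

```{r}
p <- lif_params()
first_spike_interval(2, p)          # tau * ln 2
sim <- simulate_constant_current(2, 40, p)
head(sim$spikes)
```

# ANN-to-SNN conversion

## Batch-norm folding

Inference-time batch normalization $y = \frac{\gamma}{\sigma}(x-\mu)+\beta$
after a convolution with weights $W$ and bias $b$ is absorbed as
$$\tilde W = \frac{\gamma}{\sigma} W, \qquad
  \tilde b = \frac{\gamma}{\sigma}(b - \mu) + \beta,$$
per output channel. `fold_batchnorm()` performs this graph rewrite; it is
idempotent and the folded forward pass agrees with the unfolded one to
floating tolerance (checked on random graphs).

## Rate coding

Each ReLU becomes an integrate-and-fire unit with *subtractive reset*:
$$V(t) = V(t-1) + z - V_{th}\,\theta_t,$$
firing $\theta_t = 1$ whenever the updated membrane reaches $V_{th}$.
Summing the update over $T$ steps and dividing by $T V_{th}$ gives the
firing rate
$$f = x - \frac{V_T - V_0}{T\,V_{th}}, \qquad z = V_{th}\,x,$$
so for a single unit with constant drive $|f - x| \le 1/T$, exactly; in the
limit $T \to \infty$, $f = x$. The subtractive reset is essential for this
identity (reset-to-zero discards residual charge and breaks it).

Design choices, and why:

* **Input encoding** is constant injection of the analog pixel value at
  every timestep, not Poisson spikes. This makes the residual bound exact
  and every simulation deterministic.
* **Biases** are injected as a constant per-timestep current.
* **Activation scaling.** Rates live in $[0,1]$, so each ReLU layer is
  rescaled by a calibration statistic $\lambda$ of its activations
  (`norm_percentile` of `rate_code_config()`). The general default is the
  99.9th percentile, which is robust to stray outliers. The *detection*
  conversion (`convert_msf()`) uses the exact maximum instead: in a
  detector the largest activations sit on the lesions, and clipping them
  would selectively distort exactly the evidence the head needs. A
  residual branch whose two inputs carry different scales is handled with
  per-edge gains so that every IF unit still sees correctly normalised
  current.
* **Non-ReLU graph pieces** (the saliency masks and the detection head,
  which sit after the last ReLU) are executed once, in full precision, on
  the decoded rates. Spiking them would require rate-coding non-monotone
  operations for no accuracy benefit.
* **Threshold comparison** uses a relative tolerance of $10^{-9}$ so that
  firing patterns match exact arithmetic (ten summands of $0.3$ must reach
  $3.0$).

The simulator exploits the fact that the converted network is feedforward
*within* a timestep: each linear layer processes all $T$ timesteps as one
batched matrix product, and only the membrane update iterates over $T$.
Spike tensors of layers that no longer feed anything are freed as the
evaluation proceeds.

```{r}
if_rate(c(0, 0.3, 0.7, 1), timesteps = 10)   # |f - x| <= 1/T, here exact
```

`equivalence_audit()` reports per-layer mean/max $|f - \hat a|$ for a list
of horizons; the single-layer bound $1/T$ applies to the first spiking
layer, deeper layers accumulate their inputs' quantisation and are
reported, not bounded.

# The detection network

A four-stage residual backbone (stride-2 stem, then four stages of
stride-2 downsampling plus residual blocks) emits feature maps
$C_2..C_5$ at strides 4/8/16/32. Lateral $1\times1$ convolutions reduce
each to a common width $d$ and a top-down path fuses them:
$$P_5 = \mathrm{lat}_5(C_5), \qquad
  P_k = \mathrm{lat}_k(C_k) + \mathrm{up}_2(P_{k+1}),\; k = 4, 3, 2,$$
with nearest-neighbour upsampling (conversion-friendly: replication is
exact on spike trains). Each fused map passes a $3\times3$ convolution,
batch norm and ReLU.

**Saliency.** Before each detection head the feature map is summed over
channels, min-max normalised to $[0,1]$ (a uniform map yields an all-ones
mask, i.e. pass-through), and multiplied back onto every channel. This is
the spatial attention component; an optional per-channel global-average
gate exists behind an off-by-default switch, since the spatial sum-mask is
the documented mechanism and the channel gate is an interpretation.
During training the gradient flows through the mask's channel sum but the
min/max positions are treated as constants — a cheap, almost-everywhere
correct approximation.

**Head.** The heads attach to $P_3$ and $P_4$ by default (configurable):
at 96 px input these are $12\times12$ and $6\times6$ grids, which match
the synthetic lesion sizes; adding $P_2$ mostly adds cost. Decoding is the
standard grid scheme: sigmoid centre offsets, exponential size terms on
k-means anchor priors (3 per level, clustered from the training boxes),
sigmoid objectness and class scores, confidence filtering and greedy
per-class NMS at IoU 0.5.

**Training.** SGD with momentum 0.9, weight decay 5e-4 and learning rate
1e-3 — batch 64 in 8 subdivisions at full scale; the desk default is batch
16 in 2 subdivisions so each accumulation chunk still holds 8 images.
The loss combines box-offset squared error (weight 5), objectness
cross-entropy (positives upweighted 10:1 against background, which
outnumbers them by about two orders of magnitude; predicted boxes
overlapping a ground truth above the 0.5 ignore threshold receive no
background penalty), and per-class logistic terms. `train_detector()` runs
a main phase and then a polish phase at a tenth of the learning rate: the
polish phase sharpens confidence margins, which matters downstream because
near-tied objectness scores flip under the $\pm 1/T$ rate quantisation of
the spiking execution. Batch-norm uses batch statistics forward, gradients
through them, and an EMA (rate 0.1) for the running statistics that
inference and folding use. All training is deterministic given the seed.

# Synthetic data

The generator emulates the two study modalities at a configurable size
(96 px desk default; 500 px matches the source imagery):

* **ultrasound**: a smooth multiplicative background field, *hypointense*
  (dark) lesions, and multiplicative speckle (gamma, shape 14 — strong
  enough to be clearly speckled, weak enough that a tiny network can
  learn from 64 images);
* **mammogram**: a dim additive-texture background with *hyperintense*
  (bright) masses and Gaussian pixel noise.

Lesion boundaries are radial harmonic perturbations of an ellipse: benign
lesions use low-order harmonics at 5% amplitude (smooth margins),
malignant ones harmonics up to order 8 at 32% (spiculated margins).
Boxes are exact by construction — the tight bounding box of the rendered
mask. The default class mix is the study's 437:210 benign:malignant
ratio; lesion-free "normal" images can be generated but are excluded from
detection training and evaluation by convention. The malignant class can
be doubled exactly by 90° clockwise rotation (`augment_malignant()`).

What passing tests on these images do **not** show: robustness to real
acoustic shadowing, operator variability, breast density, calcifications,
or any physical image formation — the generator is a statistical stand-in
that exercises the *pipeline*, not a clinical claim.

Annotations round-trip through two dialects: VOC XML (LabelImg
convention, 1-based inclusive pixel corners) and YOLO text (normalised
centre/size, six decimals, sub-half-pixel round-trip). Internally boxes
are 0-based half-open — the conversion happens only at the file boundary.

# Evaluation

Detections are matched greedily in descending confidence to the
highest-IoU unmatched ground truth at IoU ≥ 0.5 (the ignore threshold
reused as the match threshold); each ground truth matches at most once.
AP integrates the precision envelope over recall at every recall change
(the modern all-point convention; the 11-point variant is available via a
flag and agrees within 0.05 on small cases). mAP averages the two classes
unweighted. Reported precision/recall scalars are computed at the
detector's operating point (confidence 0.25 after NMS).

# Energy accounting

`count_flops()` counts one MAC per multiply-add pair (convolution:
$H W C_{out} \cdot k^2 C_{in}$; the published figures confirm this
convention — $6.97\times10^9$ MACs at 4.6 pJ is 0.032 J). Bias additions,
elementwise adds and upsampling copies are tallied separately and excluded
from the MAC total. `count_synaptic_ops()` counts one AC per spike per
outgoing synapse, with exact per-neuron fan-outs derived from the graph
geometry (border neurons feed fewer windows). Energy is
$\mathrm{count} \times \mathrm{cost_{pJ}} \times 10^{-12}$ J, with default
costs 4.6/0.9 pJ (32-bit float MAC/AC) and 3.2/0.1 pJ (32-bit integer).

# Film-mammography calibration

The four DDSM digitizers map gray value to optical density by
$OD = a + b\,\log_{10}(GV)$ (DBA M2100) or $OD = a + b\,GV$ (Howtek 960,
Lumisys 200, Howtek MultiRad850), with coefficients stored at full
printed precision and validated against each scanner's bit depth (16-bit
DBA, 12-bit others). All slopes are negative: brighter film reads lower
density. `volume_summary()` reproduces the archive's case bookkeeping
(2620 examinations across four severity volumes).

# Problem sizes and determinism

The shipped tests and the acceptance script run everything at desk scale,
as a deliberate design point: 96×96 images, 64 training images, 700
optimizer steps (500 + 200 polish), 12 held-out images, spiking simulation
at $T = 512$. Every stochastic step takes an explicit seed: dataset
generation, weight initialisation, batch sampling and anchor clustering
are bitwise reproducible, and the spiking simulator is deterministic by
construction.

# Known limitations

* The ANN→SNN error bound is exact only for the first spiking layer;
  depth compounds quantisation, so detection-level agreement is validated
  empirically (fraction of images with identical post-NMS decisions), not
  proved.
* The saliency-mask gradient ignores the min/max positions; training
  treats the normalisation range as locally constant.
* The tiny backbone trained for a few hundred steps on synthetic images
  is a pipeline surrogate — its absolute mAP on 64 images (~0.3 at the
  0.25 operating point) is far from what full-scale training on real
  data achieves, and is asserted only as a smoke floor.
* Energy figures model arithmetic only: no memory traffic, leakage or
  hardware-specific overheads.
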