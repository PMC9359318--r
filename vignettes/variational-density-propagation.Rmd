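---
title: "Variational density propagation and predictive-variance failure detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variational density propagation and predictive-variance failure detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`vdpnet` implements Bayesian convolutional classifiers by *variational
density propagation* (VDP). Every weight and bias is given a factorized
Gaussian variational posterior $q_\phi(\theta)$ — a mean and an elementwise
variance per scalar parameter — and, instead of sampling weights at test
time, the first two moments of the signal are propagated *analytically*
through every layer. The network's output is a Gaussian predictive
distribution on the class-probability simplex: its mean is the decision, and
the covariance quantifies the uncertainty attached to that decision. No
Monte-Carlo forward passes are needed at training or test time.

The per-layer moment algebra:

* **First convolution** (deterministic input $X$, random kernel): with
  $\tilde X$ the im2col matrix of the input (one row per output location),
  $\mu_z = \tilde X m$ and $\Sigma_z = \tilde X\,\mathrm{diag}(\sigma^2)\,
  \tilde X^\top$ per output channel. Kernels of different output channels are
  independent, so cross-channel covariance is exactly zero.
* **Nonlinearities** use a first-order Taylor expansion at the mean:
  $\mu \mapsto f(\mu)$, $\Sigma \mapsto \Sigma \odot \nabla f(\mu)\,\nabla
  f(\mu)^\top$.
* **Max-pooling** pools the mean and *co-pools* the covariance: the rows and
  columns at the argmax indices of the mean are retained. Argmax ties break
  to the first index in row-major order, so results are bit-reproducible.
* **Flattening** concatenates means; the covariance is block-diagonal because
  distinct kernels are independent.
* **Fully-connected layers** multiply two independent Gaussian vectors:
  $\mu_{d_i} = m_i^\top \mu_b$,
  $\Sigma_{d_{ii}} = \mathrm{tr}(\Sigma_i \Sigma_b) + m_i^\top \Sigma_b m_i +
  \mu_b^\top \Sigma_i \mu_b$, and $\Sigma_{d_{ij}} = m_i^\top \Sigma_b m_j$
  off the diagonal.
* **Intermediate convolutions** apply the same product-of-Gaussians moments
  patchwise. One subtlety: outputs at different spatial locations of a
  channel share one kernel, so their exact cross-covariance carries two
  additional terms, $\mu_{b_l}^\top \Sigma_w \mu_{b_{l'}} +
  \mathrm{tr}(\Sigma_w \Sigma_{b_{l'l}})$, beyond the
  independent-weights off-diagonal. The full-mode implementation includes
  them; dropping them is detectable by the package's Monte-Carlo oracle at
  its 5% covariance tolerance, and the formula reduces exactly to the
  fully-connected case when no outputs share weights.
* **Softmax** is linearized through its Jacobian $J = \mathrm{diag}(g) -
  g g^\top$: $\Sigma_{\tilde y} = J \Sigma_d J^\top$. Because the rows of $J$
  sum to zero, $1^\top \Sigma_{\tilde y} 1 = 0$: the output covariance is
  degenerate along the simplex normal, which the tests assert.
* **Batch normalization** is a diagonal affine map
  $D = \mathrm{diag}(\gamma/\sqrt{\sigma_B^2+\epsilon})$:
  mean $D(\mu-\mu_B)+\beta$, covariance $D\Sigma D$. Batch statistics are
  supplied externally.
* **Residual connections**: mean $\mu + F(\mu)$, covariance $J \Sigma
  J^\top$ with $J$ the Jacobian of the summed map. `propagateResidual`
  obtains $J$ by central finite differences of the block's mean map (step
  $10^{-5}\max(1,|\mu_j|)$ per coordinate); R has no automatic
  differentiation for arbitrary closures, and at these toy sizes the central
  difference is accurate to well below the tolerances the oracle checks
  enforce.

## Two covariance backends

Full per-activation covariance is the reference representation and the one
the closed-form and Monte-Carlo tests exercise, but it is quadratic in the
feature-map size and infeasible beyond toy inputs. The package therefore has
a dual backend:

* `propagate*()` functions operate on single `GaussianActivation` objects in
  **full** or **diagonal** mode — the reference path.
* The trainable `VDPNetwork` propagates batches of diagonal variances only —
  the scalable path used for training and prediction.

For transforms that do not mix off-diagonal mass into the diagonal
(activation, batch norm, pooling, flattening), the diagonal output equals
the diagonal of the full output exactly, and the tests assert identity. For
the fully-connected, intermediate-convolution, softmax, and residual
transforms, diagonal mode is an approximation: it drops the off-diagonal
input covariance that those transforms would fold into output variances. In
the residual layer the diagonal backend adds branch variances as if the
identity and residual branches were uncorrelated; the full-mode Jacobian
form is the reference.

## The training objective

Training minimizes the negative evidence lower bound: the expected
log-likelihood of one-hot targets under the propagated output Gaussian, plus
the closed-form KL divergence of the factorized posterior from an isotropic
$N(0, 1)$ prior, weighted by `klWeight` (default $1/N$, so the KL is counted
once per epoch under mini-batch scaling). Variational variances are stored
as log-variances so gradient descent keeps them positive without clipping.
The optimizer is SGD with a fixed learning rate and global gradient-norm
clipping (default norm 2). Clipping is load-bearing: the likelihood's early
phase is stiff, and unclipped fixed-rate SGD collapses to chance on a
substantial fraction of seeds at learning rates that otherwise train well.
Seeds control initialization and shuffling, and two runs with the same seed
are bit-identical.

**The variance floor.** The Gaussian likelihood is applied to one-hot
targets whose propagated covariances are nearly singular (the softmax
covariance is degenerate by construction), so a floor (`jitter`) is added to
the variance before the log-determinant and quadratic form. The floor's size
matters for plain SGD: gradients of the quadratic term scale with its
inverse, and floors near $10^{-3}$ make the objective so stiff that fixed-
learning-rate SGD cannot descend it. The trainer's default is `jitter =
0.25`, which keeps likelihood gradients on the same scale as cross-entropy
gradients and trains stably in a few epochs; the floor enters only the loss,
never the reported predictive variances. `expectedLogLik()` accepts any
floor, and the exactness tests use a negligible one.

## The synthetic benchmark

The generator produces MedMNIST-shaped data: K-class (4–11) images of
28×28 pixels, 1 or 3 channels, values in [0,1], balanced labels, three
disjoint-seeded splits. Each class is a parametric prototype — a positioned
geometric shape (disk, frame, bars, cross, stripe, ring, checker patch,
triangle, X, dot pattern) plus a weak class-specific intensity gradient —
jittered per sample in position (±4 px), size (±30%), and amplitude, then
overlaid with i.i.d. Gaussian texture noise of standard deviation
1/`separability`. Shapes-plus-gradient prototypes were chosen over Gaussian
blobs so that pixel noise degrades accuracy *gradually*: classification
depends on mid-frequency shape features that additive noise erodes smoothly,
which is what makes the noise-bin trends reproducible at desk scale. The
prototype amplitude and jitter were calibrated once so that a small
deterministic CNN reaches more than 85% but less than 100% test accuracy in
ten epochs at the default `separability = 3`.

What the generator does *not* emulate: medical image content and class
semantics, inter-class label noise, intensity calibration artifacts, or
class imbalance. Passing trends on this benchmark show that the machinery
behaves as designed under controlled conditions, not that the specific
thresholds transfer to clinical data.

The benchmark conditions used by the tests and the acceptance script: the
small residual architecture (one 8-channel residual block; the default
`networkSpec` is the larger two-block 16/32 variant), $n = 2000$ training
images, 10 epochs, SGD with learning rate 0.15, batch 50. The Gaussian noise
bins target SNRs of 15/7/2 dB (energy-ratio definition) for low/medium/high
noise — within the span of SNRs the evaluation protocol is designed around —
chosen so that test accuracy declines gradually from the clean bin to the
high-noise bin. Five seeds are averaged for every trend assertion.

## Failure detection

Both mechanisms threshold the scalar predictive variance, which by default
is the diagonal entry of the propagated softmax covariance at the predicted
class — uncertainty about the decision actually made (`trace` and `maxdiag`
reductions are available). A record abstains when its variance strictly
exceeds the threshold; a sample exactly at the threshold is retained.
Post-threshold accuracy over zero retained samples is reported as
undefined (`NA`), never 100%.

* **Fixed threshold**: the median predictive variance of correct decisions
  at the minimum tested noise level. The alternative selections (combined
  median; manual value) are exposed because the remaining thresholds in
  practice are chosen by inspecting the variance trends, which no closed
  rule captures.
* **Learned threshold**: a small regression network (raw pixels in; fully
  connected by default, conv+fc preset available) trained with MSE or MAE to
  predict the *clean-image* predictive variance from either the clean image
  or a noise-corrupted copy. Its output is compared to the observed variance
  directly (no margin), clamped at zero. Regression targets are standardized
  internally for conditioning and unstandardized at prediction.

## Attacks and the SNR protocol

SNR is computed as an energy ratio, $10\log_{10}(\sum x^2/\sum n^2)$; the
source formula divides "signal" by "noise" without stating squares, and the
energy reading is the one under which dB values behave conventionally (a
10× noise amplitude change is exactly 20 dB). Noise is scaled per image to
hit the target SNR exactly before clipping to [0,1], and achieved SNR is
reported pre-clip.

FGSM and PGD attack the cross-entropy of the *predictive mean* — the
decision surface the detector must protect. The predictive mean of a VDP
network is exactly the deterministic forward pass through the weight means,
so input gradients are taken through the mean path. PGD uses a seeded random
start in the $\epsilon$-ball and projects after every step; with one step,
$\alpha = \epsilon$ and no random start it reproduces FGSM bit-for-bit.

**A known limitation.** Under attacks strong enough to drive a small model
to zero accuracy, the first-order softmax covariance *collapses* rather than
grows: the attacked logit margin saturates the softmax, the Jacobian factors
decay exponentially in that margin, and they outrun the modest growth of the
pre-softmax variance. At this package's toy scale, converged
$\epsilon = 0.1$ attacks therefore produce median predictive variances
*below* the clean median even though the pre-softmax variance rises — very
deep networks amplify off-manifold variance by orders of magnitude more, and
moderate attacks that leave substantial accuracy behave differently. The
attack harness reports both accuracies and variance medians so this regime
is visible rather than hidden.

## Numerical choices

* Diagonal variances are clamped at zero (tolerance $-10^{-10}$); full
  covariances are symmetrized as $(\Sigma + \Sigma^\top)/2$ after every
  transform.
* Flattening order is channel-major, then row-major spatial, fixed
  everywhere and recorded in each activation's `layout`.
* Convolution geometry: zero padding, unit dilation, cross-correlation
  convention, output size $\lfloor (n + 2p - k)/s \rfloor + 1$.
* The Monte-Carlo oracle (`mcOracle`) draws weight (and, when the input is a
  `GaussianActivation`, input) realizations and runs the deterministic
  forward pass per draw; it is the independent check of every propagation
  rule and never a substitute for it.
* Checkpoints, manifests, and the learned regressor serialize to plain JSON;
  dataset fixtures use the MedMNIST npz dialect (a zip of NumPy arrays named
  `train_images`, `train_labels`, ..., written uncompressed with a CRC-32
  taken from a gzip stream), so real PathMNIST/DermaMNIST/OrganAMNIST
  archives load through the same reader.

## Limitations

* First-order Taylor propagation ignores curvature: softmax means are taken
  at the logit mean, ReLU moments are exact only away from the kink, and the
  attack-saturation collapse described above is the extreme case.
* The tensor-normal prior over kernels is realized as its standard
  factorized reduction (elementwise Gaussians); no structured covariance
  between weights is modeled.
* Diagonal-mode training drops cross-feature covariance inside feature maps;
  the full-mode reference exists precisely to measure what that loses on
  small cases.
* The benchmark is synthetic; thresholds calibrated on it say nothing
  quantitative about clinical data.
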