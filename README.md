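# vdpnet

Bayesian convolutional classifiers by **variational density propagation
(VDP)**, with **predictive-variance failure detection**.

Deep classifiers deployed in settings without ground-truth labels — medical
imaging being the motivating case — cannot track their own accuracy, and raw
softmax probabilities are overconfident, increasingly so on noisy or
out-of-distribution inputs. `vdpnet` addresses this by (1) training networks
whose weights carry a factorized Gaussian variational posterior
$q_\phi(\theta) = \prod_i N(m_i, \sigma_i^2)$ and propagating the mean and
covariance of that posterior *analytically* through every layer —
convolution, ReLU (first-order Taylor), max-pool/co-pool, flatten,
fully-connected, batch norm, residual connections, and the softmax Jacobian —
so each prediction arrives with a calibrated predictive covariance, without
any test-time sampling; and (2) turning the scalar predictive variance into a
*failure detector*: the model abstains ("no decision") whenever the variance
exceeds a threshold, either a **fixed** cutoff (the median variance of
correct decisions at minimum noise) or a **learned** per-image cutoff
(a regression network trained to predict the clean-image variance).

Training minimizes the negative evidence lower bound
$\mathcal{L} = -\mathbb{E}_{q_\phi(\theta)}[\log p(\mathcal{D}\mid\theta)]
+ \mathrm{KL}(q_\phi(\theta)\,\|\,p(\theta))$, with the expected
log-likelihood evaluated in closed form on the propagated output moments.
The package includes a deterministic twin (same architecture, weights =
posterior means, cross-entropy training) for accuracy–probability-gap
comparisons, Gaussian/speckle corruption at exact target SNRs, FGSM/PGD
adversarial attacks, a Monte-Carlo oracle that independently verifies every
propagation rule, a synthetic MedMNIST-shaped image generator so the whole
pipeline runs without external data, and a CLI for scripted experiments.

Audience: researchers in uncertainty quantification / selective prediction,
and developers who need a self-contained, fully testable reference
implementation of moment propagation through CNNs.

## Worked example

```r
library(vdpnet)

## closed-form check: w ~ N(2, 0.5) times b ~ N(3, 1)
b <- gaussianActivation(3, matrix(1, 1, 1))
w <- randomParameter(2, 0.5)
out <- propagateFC(b, list(w))
cat("mean:", actMean(out), " variance:", actCovariance(out)[1, 1], "\n")
#> mean: 6  variance: 9

## train a small residual VDP classifier on the synthetic benchmark
dataset <- generateDataset(syntheticSpec(seed = 1))
spec <- networkSpec(architecturePreset("small", 4), numClasses = 4, seed = 1)
net <- trainNetwork(buildNetwork(spec), dataset, epochs = 10, lr = 0.15,
                    batchSize = 50,
                    config = lossConfig(N = 2000, H = 4, jitter = 0.25),
                    seed = 1)

## evaluate the four Gaussian-noise bins and summarize the variance trends
records <- NULL
for (b in defaultNoiseBins(seed = 7)) {
  Xb <- applyBin(b, dataset$test$images)
  records <- rbind(records,
                   predictBatch(net, Xb, dataset$test$labels, bin = b$label))
}
vs <- summarizeVariance(records, c("none", "low", "medium", "high"))
print(vs, digits = 3)
#>      bin medianCorrect medianIncorrect medianCombined accuracy    n
#> 1   none      1.33e-05          0.0759       2.68e-05     92.0 1000
#> 2    low      1.95e-05          0.0450       4.28e-05     92.0 1000
#> 3 medium      2.85e-05          0.0678       9.51e-05     87.7 1000
#> 4   high      1.37e-04          0.0660       1.14e-03     77.1 1000

tau <- selectFixedThreshold(vs, "correct-at-min-noise")
cat("fixed threshold:", signif(tau, 3), "\n")
#> fixed threshold: 1.33e-05
print(applyThreshold(records[records$bin == "high", ], tau), digits = 3)
#>   threshold preAccuracy abstainedPct postAccuracy
#> 1  1.33e-05        77.1         67.7           96
```

Reading the output: the median predictive variance rises monotonically with
noise while accuracy falls; at every noise level incorrect decisions carry
orders-of-magnitude higher variance than correct ones; and abstaining on
variances above the clean correct-decision median lifts the high-noise
accuracy from 77.1% to 96.0% at the cost of abstaining on 67.7% of samples —
the accuracy / abstention trade-off the failure detector is built around.

## Command line

```sh
inst/cli/vdp all --config experiment.yaml      # or train / evaluate /
                                               # curves / attack /
                                               # threshold-fit /
                                               # threshold-apply / report
```

Every stage writes CSV artifacts plus a manifest (config hash, seeds,
versions) to the configured output directory; re-runs with an unchanged
config are no-ops unless `--force`.

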