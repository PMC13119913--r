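---
title: "Dynamic gene-gene interaction modeling for driver-gene prioritization"
author: "driverDyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic gene-gene interaction modeling for driver-gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driverDyn)
```

# The scientific problem

Most driver-gene discovery methods rank genes by mutation recurrence,
which misses rare regulators whose influence shows up in expression
dynamics rather than in DNA variant counts. driverDyn takes the
complementary, functional view: given single-cell RNA-seq data collected
at ordered disease stages (for example normal tissue, primary tumor,
metastasis), it models each gene's cluster-level mean expression
trajectory as a latent stochastic process, infers gene-gene interaction
effects from the joint posterior, and ranks genes by a *driver
coefficient* -- the squared posterior signal-to-noise ratio of the gene's
effect size. Genes that exert strong and *reliably estimated* influence
on the expression dynamics rank highly; genes with weak or uncertain
effects do not.

The pipeline has four stages:

1. **Aggregation.** Cells annotated with a cluster (cell type) and an
   ordered stage are averaged into a genes x stages x clusters mean
   expression tensor.
2. **Progenitor selection.** The cancer-originating cluster is the one
   whose stage abundance trends monotonically across progression *and*
   whose cancer cell fraction (fraction of cells with non-zero
   expression of a tumor marker such as *EPCAM*) is maximal.
3. **Temporal model and inference.** The progenitor cluster's
   trajectories are modeled with a time-varying ARMA state-space prior
   driven by fractional Gaussian noise; latent states and
   gamma-distributed interaction effects are inferred by mean-field
   variational Bayes, refined by posterior sampling.
4. **Driver scoring.** Posterior effect-size distributions per gene are
   summarized into driver coefficients, 95% highest-density intervals,
   and a ranked table.

# The model

## State-space prior

For each gene the latent stage trajectory follows a finite-order,
time-varying ARMA recursion

$$x_k = \sum_{i=1}^{m} a_{i,k}\, x_{k-i} + \sum_{j=1}^{n} b_{j,k}\, u_{k-j} + u_k,$$

whose innovations $u_k$ are fractional Gaussian noise with
autocorrelation

$$\rho_u(\tau) = \tfrac12\left(|\tau+1|^{2H} - 2|\tau|^{2H} + |\tau-1|^{2H}\right),$$

so a single Hurst exponent $H \in (0.5, 1)$ controls the long-range
dependence of the stage series ($H = 0.5$ is the white-noise limit;
values above 0.5 give persistent correlations). Stacking stages gives
`x = Theta u` with a block lower-triangular transfer matrix `Theta`
(`transferMatrix()`), the Toeplitz innovation covariance
`Cuk = sigma_u^2 R(H)` (`innovationCovariance()`), and the state
covariance `Cxk = Theta Cuk Theta^T` (`stateCovariance()`). Stacked
vectors are ordered gene-major, time-minor, and innovations are
independent across genes: the cross-gene structure is carried entirely
by the interaction matrix below.

With only $K = 3$ stages a free coefficient per time point is not
identifiable, so `estimateArma()` fits time-constant AR(1)/MA(1)
coefficients per gene by least squares (full lag-by-time tables are
accepted). The Hurst exponent is either fixed (default 0.6) or selected
on a grid by `fitHurst()`, which minimizes the Frobenius error between
the model innovation covariance and an empirical covariance with the
innovation variance profiled out. The default grid is
$\{0.55, 0.60, \ldots, 0.95\}$; the default lag window for a single
series is 5, because the autocorrelation curves of different $H$
separate most at short lags, where sample autocovariances are also least
noisy. A calibration caveat: at series length 200 the grid estimate
lands within one grid step of a generating $H = 0.7$ in roughly
three-quarters of simulations. That is close to the information limit --
an exact Gaussian maximum-likelihood grid search does no better at this
length -- so single-series Hurst estimates at these lengths should be
read as indicative, not precise.

## Interaction model and posterior

Observed trajectories are modeled as latent states plus noise,
$z_k = x_k + v_k$ with $v_k \sim N(0, \sigma_v^2 I)$, and gene-gene
interaction effects enter as a non-negative matrix $\phi$ whose entries
carry elementwise Gamma$(a_0, b_0)$ priors. Conditional on the expected
interaction matrix $\langle\phi\rangle$, the state posterior is the
Gaussian prior times an exponential interaction tilt,

$$q(x \mid \phi) \propto N(x; 0, C_{x}) \exp\!\Big[-\sum_k (z_k - x_k)^\top \langle\phi\rangle (z_k - x_k)\Big] \, N(z; x, \sigma_v^2 I),$$

which stays Gaussian with precision
$C_x^{-1} + 2\,\Phi_{\mathrm{sym}} \otimes I_K + I/\sigma_v^2$
(`tiltedGaussian()`). Coordinate ascent alternates this state update
with conjugate gamma updates whose rates accumulate the expected
residual cross-moments $S_{ij} = \sum_k E[(z-x)_i (z-x)_j]$
(`vbFit()`). The evidence lower bound is reported per sweep and is
non-decreasing; `mcmcSample()` then draws from the closed-form
posterior (exactly by default, or with a random-walk Metropolis chain
for diagnostic cross-checks).

Three numerical guards keep the scheme well-posed, and each is part of
the model definition rather than a silent patch:

* **Symmetrization and lazy PSD projection.** The tilt is only a proper
  density under a PSD matrix, so $\langle\phi\rangle$ is symmetrized,
  and eigenvalue-clipped to the PSD cone only when the joint precision
  actually loses definiteness. With a finite noise anchor the
  projection never triggers, and the ascent is then exactly monotone in
  the reported objective.
* **Rate floor.** A negative residual cross-moment carries no evidence
  of positive coupling; the gamma rate term is floored at $10^{-6}$,
  which is the boundary-constrained maximizer of the objective.
* **Observation-noise anchor.** $\sigma_v$ is the generative model's
  observation noise. The pipeline supplies the pooled standard error of
  the cluster/stage means (the aggregation step's own uncertainty);
  standalone fits estimate it from first-sweep residuals. Without the
  anchor the coupled updates drift to a prior-dominated fixed point in
  which the posterior mean carries no gene-amplitude information.

A structural property of this family worth stating plainly: because the
tilt penalizes residual *co*-movement, a large $\phi_{ij}$ encodes
residual anti-correlation. Genes that genuinely co-move therefore end up
with interaction entries *suppressed below* the floored baseline -- the
informative signature is suppression, not elevation -- and positively
coupled data cannot raise an off-diagonal entry above its prior mean.

## Driver coefficient

For each gene a scalar effect-size distribution $\delta_g$ is formed
from posterior draws and summarized as

$$\mathrm{DrCoef}_g = \left(\frac{\mu_g}{\sigma_g}\right)^2,$$

with $\mu_g, \sigma_g$ the mean and standard deviation of the draws:
large when the effect is both strong and precisely estimated, zero for
a gene with no effect. Three effect definitions are available in
`geneEffectSamples()`:

* `"state"` (pipeline default): the root-mean-square of the gene's
  latent stage trajectory per posterior draw. This is the literal
  posterior-signal-to-noise reading of the driver coefficient and the
  definition under which planted drivers are reliably recovered (see
  below).
* `"centered_rowsum"` (function default): the gene's outgoing
  interaction row sum, centered at its prior expectation, so a gene
  whose interactions never moved from the prior scores zero.
* `"rowsum"`: the uncentered row sum.

The row-sum variants are retained for interpretability of the
interaction posterior itself, but note the structural property above:
at three stages the row sums of the gamma posterior are nearly flat
across genes, and simulation shows they do not separate planted drivers
from passengers. The latent-state definition does, which is why the
pipeline uses it.

The 95% HDI attached to each gene is the shortest contiguous interval
of the effect draws (`hdi()`); ranking ties break lexicographically so
results never depend on input order.

## Model comparison

`compareModels()` contrasts the independence baseline (interaction
matrix constrained to its diagonal, genes decoupled) with the full
interaction-aware model, reporting the MSE of the posterior-predictive
mean against the observations and a negative log posterior (the
negative log joint at the posterior mean, with the tilt normalized as a
Gaussian observation density). Users should know what this comparison
can and cannot show here: since the tilt encodes anti-correlation and
observation-referenced MSE mechanically favors the less-regularized
model, the full model does *not* systematically win this comparison on
positively coupled synthetic data. We examined several alternative
formulations (truth-referenced metrics, interaction-structured state
priors estimated by gated factor analysis) and none achieved a robust
directional advantage at three stages, where any data-driven coupling
estimate is noise-dominated; the comparison is therefore reported as a
diagnostic, not as evidence for the interaction term. The evidence that
the interaction machinery matters comes from the planted-driver
recovery experiments instead.

# The synthetic-data generator

`simulationConfig()`, `generateInteractionMatrix()`,
`simulateTrajectories()` and `simulateCellDataset()` generate complete
stage-ordered datasets with known ground truth, so every downstream
stage is testable without external downloads.

* **Planted interaction structure.** Drivers form a strongly
  interacting module (gamma-distributed driver-driver entries scaled by
  `strength`, default 30) and each driver additionally pushes a
  disjoint set of target genes at `targetWeight` (default 0.3) of the
  module strength, with a fixed out-degree of
  `round(sparsity * (nGenes - 1))` entries per driver row. The module
  design is deliberate: with three stages, independently sprinkled
  interaction entries leave driver identification hopeless for *any*
  estimator (the best oracle statistic we measured recovers all planted
  drivers about a third of the time), whereas mutual amplification of a
  driver module concentrates trajectory variance on the drivers and
  makes the planted structure recoverable (oracle about 92%). Driver
  rows always have strictly larger off-diagonal row sums than the
  all-zero passenger rows, and `strength = 0` yields a fully decoupled
  null dataset.
* **Latent recursion.** Since the per-gene ARMA recursion leaves gene
  coupling to the interaction matrix, the generator couples genes as
  $x_k = a_1 x_{k-1} + \epsilon\, \Phi_{\mathrm{off}}\, x_{k-1} + u_k$
  with $a_1 = 0.5$ and $\epsilon = 0.1$, driven by fGn innovations at
  the configured $H$ (default 0.6) and unit innovation sd; observations
  add Gaussian noise of sd 0.1.
* **Cell-level realization.** Per-cell expression is the cluster/stage
  mean plus Gaussian noise (sd 0.25), truncated at zero; a baseline
  offset raised to the trajectory range keeps the truncation away from
  the means. The designated progenitor cluster follows the trajectory
  itself and expresses the marker gene in every cell; other clusters
  carry fixed offsets and express the marker only at the contamination
  rate (default 1%). Cell counts realize the configured abundance trend
  (default fractions 0.1, 0.2, 0.4 across three stages of 300 cells)
  exactly.

What the generator does *not* emulate: scRNA-seq count noise (dropout,
library-size variation), doublets, batch effects, or ambient RNA. A
green closed loop on this generator shows that the inference recovers
the model's own planted structure under idealized noise; it does not
certify performance on real droplet data, where upstream QC and
normalization remain the caller's responsibility.

# Worked example

```{r example, eval = FALSE}
library(driverDyn)

config <- runConfig(
  simulation = list(nGenes = 30, cellsPerStage = 300),
  scoring = list(topK = 5),
  seed = 1
)
res <- runPipeline(config)

res$progenitor$cluster     # "epithelial": the designated cluster
head(res$driverTable, 5)   # planted drivers at the top
res$fitMetrics             # predicted vs observed expression
```

The problem sizes used throughout the examples and tests -- 15 to 30
genes, 3 stages, a few hundred cells per stage, 300 to 2000 posterior
draws -- were chosen so that a complete closed-loop experiment
(generate, fit, rank, score) runs in seconds and a 25-replicate
recovery study in about a minute, while still operating the model in
the regime it was designed for (short stage series, many more genes
than stages per cluster). For real data the gene-set cap `topG`
(default 300 most-variable genes) bounds the stacked covariance at a
workable size; the stacked precision grows as the square of
`topG * K`.

# Known limitations

* At three stages, interaction *structure* (which gene drives which) is
  only weakly identifiable; the package's ranking rests on the latent
  state magnitudes, and the interaction posterior should be read as a
  coupling diagnostic, not a network estimate.
* Single-series Hurst estimation at moderate lengths is accurate to
  about one grid step three-quarters of the time (see above); for the
  pipeline this matters little because the fitted covariance enters
  only as a prior.
* The model-comparison diagnostic does not demonstrate a predictive
  advantage of the interaction term (see the model-comparison section
  for why that is structural).
* Expression values are used as provided; normalization choices,
  including whether to `log1p`-transform on load, are the caller's.
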