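# driverDyn

Driver-gene prioritization from stage-ordered single-cell RNA-seq data
by dynamic gene-gene interaction modeling.

## What it does, and for whom

Mutation-recurrence methods for finding cancer driver genes miss rare
regulators whose influence is visible in expression *dynamics* rather
than in variant counts. driverDyn is for computational biologists with
single-cell expression data sampled at ordered disease stages (e.g.,
normal tissue → primary tumor → metastasis) who want a ranked list of
candidate functional driver genes, with uncertainty, from those
dynamics alone — no mutation calls required.

The pipeline: (1) aggregate annotated cells into a genes × stages ×
clusters mean-expression tensor; (2) select the cancer-originating
(progenitor) cluster by its monotone stage-abundance trend and maximal
marker-positive cancer cell fraction
`CCF(C) = #\{cells with marker > 0\} / #cells`; (3) model the
progenitor's trajectories with a time-varying ARMA state-space prior
driven by fractional Gaussian noise,

```
x_k = Σ_i a_i x_{k-i} + Σ_j b_j u_{k-j} + u_k,
ρ_u(τ) = ½(|τ+1|^{2H} − 2|τ|^{2H} + |τ−1|^{2H}),   0.5 < H < 1,
```

and infer latent states `x` and a gamma-distributed interaction matrix
`φ` by mean-field variational Bayes on the tilted posterior

```
q(x|φ) ∝ N(x; 0, C_x) · exp[− Σ_k (z_k − x_k)ᵀ ⟨φ⟩ (z_k − x_k)] · N(z; x, σ_v² I),
```

refined by posterior sampling; (4) rank genes by the driver coefficient

```
DrCoef_g = (μ_g / σ_g)²,
```

the squared posterior signal-to-noise ratio of the gene's effect size,
with 95% highest-density intervals. A Moran's I module
(`knnWeights()`, `moransI()`) provides the standard
graph-autocorrelation comparison statistic, and a synthetic-data module
generates complete stage-ordered datasets with known planted driver
structure so the whole loop is testable offline.

## Worked example

```r
library(driverDyn)

config <- runConfig(
  simulation = list(nGenes = 30, cellsPerStage = 300),
  scoring = list(topK = 5),
  seed = 1
)
res <- runPipeline(config)

res$progenitor$cluster
#> [1] "epithelial"
head(res$driverTable, 5)
#>     gene     drCoef hdiLower hdiUpper rank
#> 1  gene8 125919.712 6.799404 6.873476    1
#> 2  gene5 123655.480 6.995493 7.074121    2
#> 3 gene26  17796.447 2.621268 2.699433    3
#> 4 gene10  11931.181 2.073195 2.150064    4
#> 5 gene14   3687.352 1.153586 1.229124    5
```

This simulated dataset planted three driver genes (gene5, gene8,
gene26 at this seed); they occupy the top three ranks, separated from
the first passenger by an order of magnitude in DrCoef. The `hdiLower`
/ `hdiUpper` columns bound each gene's posterior effect size (here the
root-mean-square latent trajectory per draw): the drivers' effects are
both large and tightly determined, which is exactly what the squared
signal-to-noise ratio rewards. `res$fitMetrics` reports the Pearson
correlation between observed and posterior-predicted expression
(pooled ρ ≈ 1.00 on this near-noiseless synthetic data), and
`res$ccf` / `res$trend` document why the progenitor cluster was
selected. All outputs are also written as TSV plus a JSON run manifest
under `config$outdir`.

A thin command-line wrapper for shell use ships in
`inst/scripts/driverdyn-pipeline.R`:

```sh
Rscript inst/scripts/driverdyn-pipeline.R \
  --config inst/extdata/example-run.yaml --seed 1 --outdir out/
```

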