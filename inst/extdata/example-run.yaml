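# Example configuration for the full pipeline on bundled synthetic data.
# Top-level keys are the arguments of driverDyn::runConfig().
simulation:
  nGenes: 30
  cellsPerStage: 300
inference:
  nSamples: 2000
scoring:
  topK: 5
seed: 1
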