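# Shared fixtures: small synthetic objects built in code at test time.

makeTrajectories <- function(seed = 1, nGenes = 10, nDrivers = 2, ...) {
  cfg <- simulationConfig(nGenes = nGenes, seed = seed, ...)
  phi <- generateInteractionMatrix(nGenes, nDrivers, seed = seed)
  list(
    traj = simulateTrajectories(phi, cfg),
    phi = phi, cfg = cfg
  )
}

makeCovSet <- function(z, H = 0.6) {
  spec <- estimateArma(z)
  su <- max(fitHurst(z, input = "replicates")$sigmaU, 1e-3)
  buildCovarianceSet(spec, K = ncol(z), nGenes = nrow(z),
    H = H, sigmaU = su)
}

# brute-force log of the unnormalized prior-times-tilt density
logTiltDensity <- function(xvec, z, Cxk, phiBar) {
  N <- nrow(z)
  K <- ncol(z)
  lp <- -0.5 * sum(xvec * solve(Cxk, xvec))
  xm <- matrix(xvec, N, K, byrow = TRUE)
  for (k in seq_len(K)) {
    r <- z[, k] - xm[, k]
    lp <- lp - sum(r * (phiBar %*% r))
  }
  lp
}
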