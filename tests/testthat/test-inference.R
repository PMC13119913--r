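test_that("the tilted Gaussian matches hand-computed posteriors", {
  # no tilt: posterior equals the prior
  Cxk <- diag(c(1, 2, 3, 4))
  g0 <- tiltedGaussian(matrix(rnorm(4), 2, 2), Cxk, matrix(0, 2, 2))
  expect_equal(stateMean(g0), rep(0, 4))
  expect_equal(stateCov(g0), Cxk)

  # scalar case: precision 1 + 2 = 3, mean 2 * 2 / 3
  g1 <- tiltedGaussian(matrix(2), matrix(1), matrix(1))
  expect_equal(stateMean(g1), 4 / 3)
  expect_equal(stateCov(g1)[1, 1], 1 / 3)

  # dominance limit: a huge tilt pins the posterior at the observations
  z <- matrix(c(1.5, -0.4, 2, 0.3, 1, -2), 2, 3)
  gBig <- tiltedGaussian(z, diag(6), diag(1e6, 2))
  expect_lt(max(abs(stateMean(gBig) - driverDyn:::stackVector(z))), 1e-3)
})

test_that("tilted Gaussian density equals the brute-force tilt on a grid", {
  set.seed(5)
  for (case in 1:5) {
    N <- sample(2:4, 1)
    K <- 3
    z <- matrix(rnorm(N * K), N, K)
    cs <- buildCovarianceSet(
      armaSpec(1, 0, ar = runif(1, -0.5, 0.5)), K, N,
      H = runif(1, 0.55, 0.9), sigmaU = runif(1, 0.5, 2)
    )
    phiBar <- crossprod(matrix(rnorm(N * N, sd = 0.5), N)) / N + diag(N)
    g <- tiltedGaussian(z, cs@Cxk, phiBar)
    P <- driverDyn:::invPsd(stateCov(g))
    pts <- matrix(rnorm(12 * N * K), 12)
    diffs <- apply(pts, 1, function(x) {
      logTiltDensity(x, z, cs@Cxk, phiBar) -
        (-0.5 * sum((x - stateMean(g)) * (P %*% (x - stateMean(g)))))
    })
    expect_lt(max(diffs) - min(diffs), 1e-8)
  }
})

test_that("coordinate ascent is deterministic with a monotone ELBO", {
  fx <- makeTrajectories(seed = 6, nGenes = 8)
  cs <- makeCovSet(fx$traj$observed)
  f1 <- vbFit(fx$traj$observed, cs, settings = list(sigmaV = 0.1))
  f2 <- vbFit(fx$traj$observed, cs, settings = list(sigmaV = 0.1))
  expect_identical(elboTrace(f1), elboTrace(f2))
  expect_true(all(diff(elboTrace(f1)) >= -1e-8))
  expect_true(f1@converged)

  # hitting maxIter warns and flags non-convergence
  expect_warning(
    fLow <- vbFit(fx$traj$observed, cs,
      settings = list(sigmaV = 0.1, maxIter = 2)),
    "maxIter"
  )
  expect_false(fLow@converged)
})

test_that("planted interaction pairs are systematically suppressed", {
  # interacting genes co-move, so their residual cross-moments stay
  # positive and the gamma posterior pushes their entries below the
  # floored baseline: planted entries rank low among off-diagonals
  planted <- c()
  nullEntries <- c()
  for (s in 1:20) {
    fx <- makeTrajectories(seed = s, nGenes = 15, nDrivers = 2)
    cs <- makeCovSet(fx$traj$observed)
    fit <- suppressWarnings(vbFit(fx$traj$observed, cs))
    pm <- interactionMean(fit)
    truthSym <- (fx$phi$matrix + t(fx$phi$matrix)) / 2
    diag(truthSym) <- 0
    offdiag <- row(pm) != col(pm)
    planted <- c(planted, pm[truthSym > 0])
    nullEntries <- c(nullEntries, pm[truthSym == 0 & offdiag])
  }
  p <- stats::wilcox.test(planted, nullEntries,
    alternative = "less")$p.value
  expect_lt(p, 0.05)
})

test_that("direct sampling reproduces the closed-form moments", {
  fx <- makeTrajectories(seed = 8, nGenes = 3)
  cs <- makeCovSet(fx$traj$observed)
  fit <- vbFit(fx$traj$observed, cs, settings = list(sigmaV = 0.1))

  s1 <- mcmcSample(fit, nSamples = 2000, seed = 4)
  s2 <- mcmcSample(fit, nSamples = 2000, seed = 4)
  expect_identical(posteriorDraws(s1), posteriorDraws(s2))

  mu <- stateMean(fit)
  sdv <- sqrt(diag(stateCov(fit)))
  se <- sdv / sqrt(2000)
  expect_true(all(abs(colMeans(posteriorDraws(s1)) - mu) < 3.5 * se))
  # variances within Monte-Carlo error (chi-square spread)
  v <- apply(posteriorDraws(s1), 2, stats::var)
  expect_true(all(abs(v - sdv^2) < 3.5 * sdv^2 * sqrt(2 / 1999)))
})

test_that("Metropolis sampling agrees with direct sampling", {
  fx <- makeTrajectories(seed = 9, nGenes = 3)
  cs <- makeCovSet(fx$traj$observed)
  fit <- vbFit(fx$traj$observed, cs, settings = list(sigmaV = 0.1))
  dm <- mcmcSample(fit, nSamples = 4000, seed = 1)
  mm <- mcmcSample(fit, nSamples = 4000, seed = 2,
    method = "metropolis", burnIn = 2000, thin = 5)
  expect_true(mm@acceptanceRate > 0.05 && mm@acceptanceRate < 0.95)
  sdv <- sqrt(diag(stateCov(fit)))
  # effective sample size of the thinned walk is well below nominal
  seWalk <- sdv / sqrt(150)
  expect_true(all(abs(colMeans(posteriorDraws(mm)) -
    colMeans(posteriorDraws(dm))) < 3.5 * seWalk))
})

test_that("the HDI is the shortest interval with the requested mass", {
  expect_equal(as.numeric(hdi(rep(3, 10))), c(3, 3))
  x <- c(5, 1, 4, 2, 3)
  expect_equal(as.numeric(hdi(x, mass = 1)), c(1, 5))
  expect_error(hdi(numeric(0)), "invalid-input")

  set.seed(12)
  z <- rnorm(1e5)
  iv <- hdi(z, 0.95)
  expect_lt(abs(iv["lower"] + 1.95996), 0.05)
  expect_lt(abs(iv["upper"] - 1.95996), 0.05)
})

test_that("fit metrics follow the textbook correlation formula", {
  makeFit <- function(obs, pred) {
    N <- nrow(obs)
    K <- ncol(obs)
    gp <- new("GaussianPosterior",
      mean = driverDyn:::stackVector(pred),
      cov = diag(N * K), nGenes = as.integer(N), K = as.integer(K))
    new("VbFit",
      statePosterior = gp,
      interactionPosterior = new("GammaPosterior",
        shape = matrix(1, N, N), rate = matrix(1, N, N)),
      elbo = 0, converged = TRUE, iterations = 1L, sigmaV = 1,
      settings = list(a0 = 1, b0 = 1), observations = obs)
  }
  obs <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  fitPerfect <- makeFit(obs, obs)
  m <- evaluateFit(obs, fitPerfect)
  expect_equal(m$rho, 1)
  expect_equal(m$r2, 1)

  fitNeg <- makeFit(obs, -obs)
  expect_equal(evaluateFit(obs, fitNeg)$rho, -1)

  # three-point toy against cor() directly
  obs3 <- matrix(c(1, 2, 3), 1, 3)
  pred3 <- matrix(c(2, 2, 5), 1, 3)
  m3 <- evaluateFit(obs3, makeFit(obs3, pred3))
  expect_equal(m3$rho, stats::cor(c(1, 2, 3), c(2, 2, 5)))
  expect_equal(m3$pValue,
    stats::cor.test(c(1, 2, 3), c(2, 2, 5))$p.value)

  expect_error(
    evaluateFit(obs3, makeFit(obs3, matrix(1, 1, 3))),
    "undefined-correlation"
  )
})

test_that("model comparison reports four finite numbers deterministically", {
  fx <- makeTrajectories(seed = 10, nGenes = 6)
  cs <- makeCovSet(fx$traj$observed)
  mc <- suppressWarnings(compareModels(fx$traj$observed, cs))
  expect_equal(nrow(mc), 2)
  expect_equal(mc$model, c("baseline", "interaction"))
  expect_true(all(is.finite(mc$mse)))
  expect_true(all(is.finite(mc$negLogPosterior)))
  mc2 <- suppressWarnings(compareModels(fx$traj$observed, cs))
  expect_identical(mc, mc2)
})
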