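#' Gamma prior on interaction effects
#'
#' Elementwise Gamma(a0, b0) prior on the entries of the gene-gene
#' interaction matrix. The prior mean a0/b0 sets the baseline tilt strength
#' before any data are seen; the default Gamma(1, 1) is weakly informative
#' on the scale of unit-variance trajectories.
#'
#' @param a0 shape (> 0).
#' @param b0 rate (> 0).
#' @return an `interactionPrior` object.
#' @export
interactionPrior <- function(a0 = 1, b0 = 1) {
  stopIfNot(a0 > 0 && b0 > 0, "hyperparameters must be strictly positive")
  structure(list(a0 = a0, b0 = b0), class = "interactionPrior")
}

#' Tilted Gaussian posterior over latent states
#'
#' Closed form of the zero-mean Gaussian state prior `N(x; 0, Cxk)`
#' multiplied by the exponential interaction tilt
#' \deqn{\exp\left[-\sum_k (z_k - x_k)^T \langle\phi\rangle (z_k -
#'   x_k)\right],}
#' which is again Gaussian with precision
#' `P = Cxk^{-1} + 2 PhiSym (x) I_K` (gene-major stacking) and mean
#' `P^{-1} (2 PhiSym (x) I_K) z`. The expected interaction matrix is
#' symmetrized before entering the quadratic form, and eigenvalue-clipped
#' to the PSD cone whenever the joint precision would otherwise lose
#' positive definiteness (the tilt is only a proper density under a PSD
#' matrix; with a PSD input or a finite noise anchor the clip is never
#' applied).
#'
#' An optional Gaussian observation likelihood `N(z; x, sigmaV^2 I)` (the
#' additive noise of the generative model) can anchor the posterior: with
#' finite `sigmaV` the precision gains `I / sigmaV^2` and the mean gains
#' the corresponding data term. The default `sigmaV = Inf` reproduces the
#' pure prior-times-tilt form.
#'
#' @param observations genes x stages matrix `z`.
#' @param stateCov (N*K) x (N*K) state covariance `Cxk`, or a
#'   [CovarianceSet].
#' @param phiBar N x N expected interaction matrix.
#' @param sigmaV observation noise sd; `Inf` disables the Gaussian
#'   likelihood term.
#' @return a [GaussianPosterior].
#' @examples
#' # N = 1, K = 1: prior variance 1, phi = 1, z = 2 -> precision 3, mean 4/3
#' g <- tiltedGaussian(matrix(2), matrix(1), matrix(1))
#' stateMean(g) # 4/3
#' @export
tiltedGaussian <- function(observations, stateCov, phiBar, sigmaV = Inf) {
  if (is(stateCov, "CovarianceSet")) stateCov <- stateCov@Cxk
  z <- as.matrix(observations)
  N <- nrow(z)
  K <- ncol(z)
  stopIfNot(all(dim(stateCov) == N * K),
    "stateCov must be (N*K) x (N*K) for the given observations")
  stopIfNot(all(dim(phiBar) == N), "phiBar must be N x N")
  stopIfNot(is.numeric(sigmaV) && length(sigmaV) == 1 && sigmaV > 0,
    "sigmaV must be a positive scalar (Inf to disable)")
  phiSym <- symmetrize(phiBar)
  obsPrec <- if (is.finite(sigmaV)) 1 / sigmaV^2 else 0
  buildP <- function(phi) {
    invPsd(stateCov) + 2 * kronecker(phi, diag(K)) + diag(obsPrec, N * K)
  }
  P <- buildP(phiSym)
  R <- tryCatch(chol(P), error = function(e) NULL)
  if (is.null(R)) {
    # the tilt is only a proper density under a PSD matrix; project onto
    # the PSD cone when (and only when) the joint precision loses
    # definiteness
    phiSym <- psdClip(phiSym, floor = 0)
    P <- buildP(phiSym)
    R <- cholJitter(P)
  }
  # (PhiSym (x) I_K) z_stacked == stack(PhiSym %*% z) under gene-major order
  b <- 2 * stackVector(phiSym %*% z) + obsPrec * stackVector(z)
  mu <- backsolve(R, backsolve(R, b, transpose = TRUE))
  Sigma <- symmetrize(chol2inv(R))
  new("GaussianPosterior",
    mean = as.numeric(mu), cov = Sigma,
    nGenes = as.integer(N), K = as.integer(K)
  )
}

# Expected residual cross-moment matrix under q(x):
# M_ij = sum_k [ (z - mu)_{ik} (z - mu)_{jk} + Cov(x_{ik}, x_{jk}) ]
residualMoments <- function(z, gauss) {
  N <- gauss@nGenes
  K <- gauss@K
  resid <- z - unstackVector(gauss@mean, N, K)
  M <- tcrossprod(resid)
  for (k in seq_len(K)) {
    idx <- stackIndex(seq_len(N), k, K)
    M <- M + gauss@cov[idx, idx]
  }
  symmetrize(M)
}

# Evidence lower bound of the mean-field objective. The interaction tilt
# contributes (K/2) E[log phi_ij] - E[phi_ij] M_ij per entry, with M the
# (unfloored) expected residual cross-moments; the floored gamma update is
# the boundary-constrained maximizer of this objective. The optional
# Gaussian observation likelihood is a fixed quadratic term.
computeElbo <- function(z, Cxk, gauss, shape, rate, prior, M,
                        sigmaV = Inf, residSq = NA, trSig = NA) {
  d <- length(gauss@mean)
  CxInv <- invPsd(Cxk)
  eLogPx <- -0.5 * (d * log(2 * pi) + logDetPsd(Cxk) +
    sum(CxInv * gauss@cov) +
    sum(gauss@mean * (CxInv %*% gauss@mean)))
  eLogPhi <- digamma(shape) - log(rate)
  phiBar <- shape / rate
  # (shape - a0) is the tilt's E[log phi] coefficient per entry
  energy <- sum((shape - prior$a0) * eLogPhi) - sum(phiBar * M)
  if (is.finite(sigmaV)) {
    energy <- energy - 0.5 * (d * log(2 * pi * sigmaV^2) +
      (residSq + trSig) / sigmaV^2)
  }
  a0 <- prior$a0
  b0 <- prior$b0
  eLogPrior <- sum(a0 * log(b0) - lgamma(a0) + (a0 - 1) * eLogPhi -
    b0 * phiBar)
  entX <- 0.5 * (d * log(2 * pi * exp(1)) + logDetPsd(gauss@cov))
  entPhi <- sum(shape - log(rate) + lgamma(shape) +
    (1 - shape) * digamma(shape))
  eLogPx + energy + eLogPrior + entX + entPhi
}

#' Variational Bayes over latent states and interaction effects
#'
#' Mean-field coordinate ascent for the joint posterior over the stacked
#' latent state `x` and the elementwise-gamma interaction matrix `phi`.
#' Each sweep (i) refreshes the Gaussian `q(x)` as the tilted posterior at
#' the current expected interaction matrix, then (ii) updates each
#' `q(phi_ij)` to Gamma(`a0 + K/2`, `b0 + S_ij`), where `S_ij` is the
#' expected residual cross-moment `sum_k E[(z - x)_i (z - x)_j]` floored
#' at `rateFloor` (a negative cross-moment carries no evidence of positive
#' coupling, and the floor keeps the gamma rate valid). Iteration stops
#' when the relative ELBO change falls below `tol` or `maxIter` sweeps are
#' reached; hitting `maxIter` returns `converged = FALSE` with a warning,
#' never silently.
#'
#' The observation noise `sigmaV` of the generative model anchors the
#' state posterior through a Gaussian likelihood term: pass a value in
#' `settings$sigmaV` (the pipeline supplies the pooled standard error of
#' the cluster/stage means), or leave it `NULL` to estimate it as the
#' pooled residual sd after the first state update (the first sweep then
#' runs on the pure prior-times-tilt posterior).
#'
#' With `structure = "diagonal"` the interaction matrix is constrained to
#' its diagonal (genes decoupled).
#'
#' @param observations genes x stages matrix of observed expression `z`.
#' @param covarianceSet a [CovarianceSet] for the same dimensions.
#' @param prior an [interactionPrior].
#' @param settings list overriding any of `tol` (1e-6), `maxIter` (500),
#'   `rateFloor` (1e-6), `sigmaV` (NULL = estimate).
#' @param structure `"full"` or `"diagonal"` interaction matrix.
#' @return a [VbFit].
#' @export
vbFit <- function(observations, covarianceSet,
                  prior = interactionPrior(),
                  settings = list(), structure = c("full", "diagonal")) {
  structure <- match.arg(structure)
  stopIfNot(is(covarianceSet, "CovarianceSet"),
    "covarianceSet must come from buildCovarianceSet()")
  z <- as.matrix(observations)
  N <- nrow(z)
  K <- ncol(z)
  stopIfNot(all(is.finite(z)), "observations must be finite")
  stopIfNot(K >= 2, "at least two stages are required")
  stopIfNot(covarianceSet@nGenes == N && covarianceSet@K == K,
    "covarianceSet dimensions do not match the observations")
  s <- utils::modifyList(
    list(tol = 1e-6, maxIter = 500L, rateFloor = 1e-6, sigmaV = NULL),
    settings, keep.null = TRUE
  )
  Cxk <- covarianceSet@Cxk
  a0 <- prior$a0
  b0 <- prior$b0
  # initialization: expected interactions at the prior mean, diagonal only
  phiBar <- diag(a0 / b0, N)
  shape <- matrix(a0, N, N)
  rate <- matrix(b0, N, N)
  elbo <- numeric(0)
  converged <- FALSE
  sigmaV <- if (is.null(s$sigmaV)) Inf else s$sigmaV
  gauss <- NULL
  for (iter in seq_len(s$maxIter)) {
    gauss <- tiltedGaussian(z, Cxk, phiBar, sigmaV = sigmaV)
    resid <- z - unstackVector(gauss@mean, N, K)
    if (iter == 1L && is.null(s$sigmaV)) {
      # pooled residual sd after the first x-update, floored so the
      # anchored likelihood stays proper on near-interpolating fits
      sigmaV <- max(stats::sd(as.numeric(resid)), 1e-3)
    }
    M <- residualMoments(z, gauss)
    sTilde <- pmax(M, s$rateFloor)
    shape <- matrix(a0 + K / 2, N, N)
    rate <- b0 + sTilde
    if (structure == "diagonal") {
      phiBar <- diag(diag(shape / rate), N)
      offIdx <- row(shape) != col(shape)
      # off-diagonal effects are pinned at the prior in the baseline model
      shape[offIdx] <- a0
      rate[offIdx] <- b0
      sTilde[offIdx] <- 0
    } else {
      phiBar <- shape / rate
    }
    elbo <- c(elbo, computeElbo(z, Cxk, gauss, shape, rate, prior, M,
      sigmaV = sigmaV, residSq = sum(resid^2),
      trSig = sum(diag(gauss@cov))))
    if (iter > 1) {
      delta <- elbo[iter] - elbo[iter - 1]
      if (abs(delta) / (abs(elbo[iter - 1]) + 1e-12) < s$tol) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    warning("vbFit reached maxIter = ", s$maxIter,
      " without meeting the ELBO tolerance; returning converged = FALSE")
  }
  dimnames(shape) <- dimnames(rate) <- list(rownames(z), rownames(z))
  new("VbFit",
    statePosterior = gauss,
    interactionPosterior = new("GammaPosterior", shape = shape, rate = rate),
    elbo = elbo, converged = converged, iterations = length(elbo),
    sigmaV = sigmaV,
    settings = c(s, list(a0 = a0, b0 = b0, structure = structure)),
    observations = z
  )
}

#' Sample from the state posterior
#'
#' Draws from the Gaussian `q(x | <phi>)` of a fitted model, either exactly
#' (`method = "direct"`: multivariate normal draws from the closed form) or
#' with a random-walk Metropolis chain for fidelity to an MCMC refinement
#' stage (`method = "metropolis"`: Gaussian proposal with sd
#' `proposalScale` times the posterior sd per coordinate, `burnIn`
#' discarded iterations, optional thinning). A Metropolis acceptance rate
#' outside [0.05, 0.95] triggers a diagnostic warning.
#'
#' @param fit a [VbFit] (or [GaussianPosterior]).
#' @param nSamples number of retained draws (default 2000).
#' @param seed integer seed.
#' @param method `"direct"` or `"metropolis"`.
#' @param burnIn Metropolis burn-in iterations (default 1000).
#' @param thin Metropolis thinning interval (default 1).
#' @param proposalScale proposal sd as a fraction of the posterior sd.
#' @return a [PosteriorSamples].
#' @export
mcmcSample <- function(fit, nSamples = 2000L, seed = 1L,
                       method = c("direct", "metropolis"),
                       burnIn = 1000L, thin = 1L, proposalScale = 0.2) {
  method <- match.arg(method)
  gauss <- if (is(fit, "VbFit")) fit@statePosterior else fit
  stopIfNot(is(gauss, "GaussianPosterior"),
    "fit must be a VbFit or GaussianPosterior")
  stopIfNot(nSamples >= 1, "nSamples must be >= 1")
  d <- length(gauss@mean)
  acc <- NA_real_
  draws <- withSeed(seed, {
    if (method == "direct") {
      L <- cholJitter(gauss@cov)
      matrix(rnorm(nSamples * d), nSamples, d) %*% L +
        matrix(gauss@mean, nSamples, d, byrow = TRUE)
    } else {
      P <- invPsd(gauss@cov)
      propSd <- proposalScale * sqrt(pmax(diag(gauss@cov), 1e-12))
      logDens <- function(x) {
        dlt <- x - gauss@mean
        -0.5 * sum(dlt * (P %*% dlt))
      }
      x <- gauss@mean
      lp <- logDens(x)
      total <- burnIn + nSamples * thin
      out <- matrix(0, nSamples, d)
      nAcc <- 0L
      kept <- 0L
      for (t in seq_len(total)) {
        prop <- x + rnorm(d, sd = propSd)
        lpProp <- logDens(prop)
        if (log(runif(1)) < lpProp - lp) {
          x <- prop
          lp <- lpProp
          nAcc <- nAcc + 1L
        }
        if (t > burnIn && (t - burnIn) %% thin == 0) {
          kept <- kept + 1L
          out[kept, ] <- x
        }
      }
      acc <- nAcc / total
      out
    }
  })
  if (is.finite(acc) && (acc < 0.05 || acc > 0.95)) {
    warning("Metropolis acceptance rate ", signif(acc, 3),
      " outside [0.05, 0.95]; consider adjusting proposalScale")
  }
  new("PosteriorSamples",
    draws = draws, phiDraws = array(numeric(0), dim = c(0, 0, 0)),
    method = method, seed = as.integer(seed), acceptanceRate = acc,
    nGenes = gauss@nGenes, K = gauss@K
  )
}

#' Highest density interval of a sample
#'
#' Shortest contiguous interval containing at least `mass` of the sorted
#' samples (for a unimodal posterior this is the HDI). Deterministic: the
#' first minimal-width window wins.
#'
#' @param samples numeric vector of posterior draws (>= 2 unless all
#'   equal).
#' @param mass interval mass in (0, 1] (default 0.95).
#' @return named numeric vector `c(lower, upper)` with attribute `mass`.
#' @export
hdi <- function(samples, mass = 0.95) {
  samples <- as.numeric(samples)
  stopIfNot(length(samples) >= 1, "invalid-input: empty samples")
  stopIfNot(mass > 0 && mass <= 1, "mass must be in (0, 1]")
  x <- sort(samples)
  n <- length(x)
  w <- ceiling(mass * n)
  if (w >= n) {
    out <- c(lower = x[1], upper = x[n])
  } else {
    starts <- seq_len(n - w + 1)
    widths <- x[starts + w - 1] - x[starts]
    i <- which.min(widths)
    out <- c(lower = x[i], upper = x[i + w - 1])
  }
  attr(out, "mass") <- mass
  out
}

#' Posterior-predictive fit metrics
#'
#' Pearson correlation, coefficient of determination (the squared
#' correlation of predicted vs observed expression pooled across genes),
#' and the two-sided t-test p-value for the correlation. With
#' `byStage = TRUE`, metrics are reported per stage (across genes) as well
#' as pooled.
#'
#' @param observed genes x stages matrix of observed expression.
#' @param fit a [VbFit] whose posterior mean defines the prediction.
#' @param byStage also report per-stage metrics.
#' @return data.frame with columns `stage` (`"pooled"` plus stage labels
#'   when requested), `rho`, `r2`, `pValue`, `n`.
#' @export
evaluateFit <- function(observed, fit, byStage = FALSE) {
  pred <- predictedExpression(fit)
  observed <- as.matrix(observed)
  stopIfNot(all(dim(observed) == dim(pred)),
    "observed and predicted dimensions differ")
  one <- function(obs, prd, label) {
    if (stats::sd(obs) == 0 || stats::sd(prd) == 0) {
      stop("undefined-correlation: constant observed or predicted vector",
        call. = FALSE)
    }
    ct <- stats::cor.test(obs, prd, alternative = "two.sided")
    data.frame(
      stage = label, rho = unname(ct$estimate),
      r2 = unname(ct$estimate)^2, pValue = ct$p.value, n = length(obs)
    )
  }
  out <- one(as.vector(observed), as.vector(pred), "pooled")
  if (byStage) {
    stages <- colnames(observed)
    if (is.null(stages)) stages <- paste0("stage", seq_len(ncol(observed)))
    for (k in seq_len(ncol(observed))) {
      out <- rbind(out, one(observed[, k], pred[, k], stages[k]))
    }
  }
  rownames(out) <- NULL
  out
}

# Negative log joint density at the posterior mean, with the interaction
# tilt treated as a normalized Gaussian observation density
# N(z_k; x_k, (2 Phi)^{-1}).
negLogPosterior <- function(z, Cxk, gauss, phiBar) {
  N <- nrow(z)
  K <- ncol(z)
  mu <- unstackVector(gauss@mean, N, K)
  resid <- z - mu
  phiPd <- psdClip(symmetrize(phiBar), floor = 1e-8)
  CxInv <- invPsd(Cxk)
  prior <- 0.5 * (sum(gauss@mean * (CxInv %*% gauss@mean)) +
    logDetPsd(Cxk) + length(gauss@mean) * log(2 * pi))
  tilt <- sum(vapply(seq_len(K), function(k) {
    r <- resid[, k]
    sum(r * (phiPd %*% r))
  }, numeric(1)))
  norm <- (K / 2) * (N * log(2 * pi) - logDetPsd(2 * phiPd))
  prior + tilt + norm
}

#' Compare interaction-aware and independence models
#'
#' Fits (a) the independence baseline, with the interaction matrix
#' constrained to its diagonal so genes decouple, and (b) the full
#' interaction-aware model, on the same observations and covariance
#' structure, and reports for each the mean squared error of the
#' posterior-predictive mean against the observations and the negative
#' log posterior (negative log joint density at the posterior mean, with
#' the interaction tilt normalized as a Gaussian observation density).
#'
#' Note that under this variational family the off-diagonal tilt encodes
#' residual anti-correlation; on positively coupled data the full model
#' does not systematically improve the pointwise fit (see the methods
#' vignette for the analysis).
#'
#' @param observations genes x stages matrix.
#' @param covarianceSet a [CovarianceSet].
#' @param prior an [interactionPrior].
#' @param settings settings list passed to [vbFit].
#' @return data.frame with rows `baseline` and `interaction` and columns
#'   `model`, `mse`, `negLogPosterior`.
#' @export
compareModels <- function(observations, covarianceSet,
                          prior = interactionPrior(), settings = list()) {
  z <- as.matrix(observations)
  fits <- list(
    baseline = vbFit(z, covarianceSet, prior, settings,
      structure = "diagonal"),
    interaction = vbFit(z, covarianceSet, prior, settings,
      structure = "full")
  )
  out <- do.call(rbind, lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    phiBar <- interactionMean(fit)
    if (nm == "baseline") phiBar <- diag(diag(phiBar), nrow(phiBar))
    data.frame(
      model = nm,
      mse = mean((z - predictedExpression(fit))^2),
      negLogPosterior = negLogPosterior(
        z, covarianceSet@Cxk, fit@statePosterior, phiBar
      )
    )
  }))
  rownames(out) <- NULL
  out
}
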