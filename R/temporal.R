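#' Fractional Gaussian noise autocorrelation
#'
#' Autocorrelation of a fractional-Gaussian-noise increment process at
#' integer lag `tau` for Hurst exponent `H`:
#' \deqn{\rho_u(\tau) = \tfrac12 (|\tau+1|^{2H} - 2|\tau|^{2H} +
#'   |\tau-1|^{2H}).}
#' At `H = 0.5` the process degenerates to white noise (`rho = 0` for all
#' `tau >= 1`); for `0.5 < H < 1` correlations are positive and decay
#' slowly, encoding long-range dependence. The full `(0, 1)` range is
#' accepted here so the white-noise limit can be exercised; the state-space
#' constructors restrict to `(0.5, 1)`.
#'
#' @param tau non-negative integer lag (vectorized).
#' @param H Hurst exponent in (0, 1).
#' @return autocorrelation value(s) in `[-1, 1]`.
#' @examples
#' fgnAutocorrelation(0, 0.7) # 1
#' fgnAutocorrelation(1, 0.6) # 0.5 * (2^1.2 - 2)
#' @export
fgnAutocorrelation <- function(tau, H) {
  stopIfNot(
    is.numeric(H) && length(H) == 1 && H > 0 && H < 1,
    "H must lie strictly inside (0, 1) (invalid-argument)"
  )
  stopIfNot(
    is.numeric(tau) && all(tau >= 0) && all(tau == round(tau)),
    "tau must be a non-negative integer (invalid-argument)"
  )
  0.5 * (abs(tau + 1)^(2 * H) - 2 * abs(tau)^(2 * H) + abs(tau - 1)^(2 * H))
}

#' Innovation correlation and covariance matrices
#'
#' Builds the K x K symmetric Toeplitz correlation matrix `Ruk` with entries
#' `rho_u(|i - j|)` and the innovation covariance `Cuk = sigmaU^2 * Ruk`.
#' Both are positive semidefinite for any Hurst exponent in (0, 1).
#'
#' @param K number of stages (>= 1).
#' @param H Hurst exponent in (0, 1).
#' @param sigmaU innovation standard deviation (>= 0).
#' @return list with elements `Ruk` and `Cuk`.
#' @examples
#' innovationCovariance(3, H = 0.5, sigmaU = 1)$Ruk # identity
#' @export
innovationCovariance <- function(K, H, sigmaU = 1) {
  stopIfNot(K >= 1 && K == round(K), "K must be a positive integer")
  stopIfNot(sigmaU >= 0, "sigmaU must be non-negative")
  Ruk <- stats::toeplitz(fgnAutocorrelation(0:(K - 1), H))
  list(Ruk = Ruk, Cuk = sigmaU^2 * Ruk)
}

#' ARMA coefficient specification
#'
#' Container for the autoregressive and moving-average coefficients of the
#' time-varying ARMA recursion
#' \deqn{x_k = \sum_{i=1}^m a_{i,k} x_{k-i} + \sum_{j=1}^n b_{j,k} u_{k-j}
#'   + u_k.}
#' Coefficients may be supplied as a single vector (time-constant, shared
#' across genes), an `m x K` (resp. `n x K`) matrix (time-varying, shared),
#' or an `nGenes`-row matrix of per-gene time-constant values.
#'
#' @param m AR order (>= 0).
#' @param n MA order (>= 0).
#' @param ar AR coefficients: `NULL` (all zero), length-`m` vector,
#'   `m x K` matrix, or `nGenes x m` matrix (`perGene = TRUE`).
#' @param ma MA coefficients, same conventions with order `n`.
#' @param perGene logical; when `TRUE`, `ar`/`ma` rows are genes.
#' @return an object of class `armaSpec`.
#' @export
armaSpec <- function(m = 1L, n = 1L, ar = NULL, ma = NULL, perGene = FALSE) {
  stopIfNot(m >= 0 && n >= 0, "orders must be non-negative")
  if (is.null(ar) && m > 0) ar <- rep(0, m)
  if (is.null(ma) && n > 0) ma <- rep(0, n)
  structure(
    list(m = as.integer(m), n = as.integer(n), ar = ar, ma = ma,
      perGene = isTRUE(perGene)),
    class = "armaSpec"
  )
}

# Resolve the (lag x time) coefficient table for one gene.
# coef: NULL | length-m vector | m x K matrix | nGenes x m matrix (perGene)
coefTable <- function(coef, order, K, gene, perGene) {
  if (order == 0 || is.null(coef)) {
    return(matrix(0, nrow = max(order, 0), ncol = K))
  }
  if (perGene) {
    v <- if (is.matrix(coef)) coef[gene, ] else coef[gene]
    return(matrix(rep(v, K), nrow = order, ncol = K))
  }
  if (is.matrix(coef)) {
    stopIfNot(nrow(coef) == order && ncol(coef) == K,
      "time-varying coefficient table must be (order x K)")
    return(coef)
  }
  stopIfNot(length(coef) == order,
    "coefficient vector length must equal the order")
  matrix(rep(coef, K), nrow = order, ncol = K)
}

#' Estimate time-constant ARMA coefficients per gene
#'
#' Least-squares estimates of an AR(1) (and optionally MA(1)) coefficient
#' per gene from its K-length stage trajectory. With only K stages a free
#' coefficient per time point is not identifiable, so time-constant values
#' are fitted: `a_g` regresses `x_k` on `x_{k-1}`, and `b_g` regresses the
#' AR residual on its own lag. Coefficients are clamped to (-0.99, 0.99).
#'
#' @param trajectories genes x K numeric matrix.
#' @param m AR order (0 or 1).
#' @param n MA order (0 or 1).
#' @return an [armaSpec] with per-gene coefficients.
#' @export
estimateArma <- function(trajectories, m = 1L, n = 1L) {
  stopIfNot(is.matrix(trajectories) && ncol(trajectories) >= 2,
    "trajectories must be a genes x K matrix with K >= 2")
  stopIfNot(m <= 1 && n <= 1,
    "per-gene least-squares estimation supports orders <= 1")
  K <- ncol(trajectories)
  N <- nrow(trajectories)
  clamp <- function(x) pmin(pmax(x, -0.99), 0.99)
  ar <- NULL
  resid <- trajectories
  if (m == 1) {
    num <- rowSums(trajectories[, -1, drop = FALSE] *
      trajectories[, -K, drop = FALSE])
    den <- rowSums(trajectories[, -K, drop = FALSE]^2)
    a <- clamp(ifelse(den > 0, num / den, 0))
    ar <- matrix(a, ncol = 1)
    resid <- trajectories -
      cbind(0, a * trajectories[, -K, drop = FALSE])
  }
  ma <- NULL
  if (n == 1) {
    num <- rowSums(resid[, -1, drop = FALSE] * resid[, -K, drop = FALSE])
    den <- rowSums(resid[, -K, drop = FALSE]^2)
    ma <- matrix(clamp(ifelse(den > 0, num / den, 0)), ncol = 1)
  }
  armaSpec(m = m, n = n, ar = ar, ma = ma, perGene = TRUE)
}

# K x K transfer block for a single gene: theta_g = A^{-1} B with
# A[k, k] = 1, A[k, k - i] = -a_{i,k}; B[k, k] = 1, B[k, k - j] = +b_{j,k}.
transferBlock <- function(arTab, maTab, K) {
  A <- diag(K)
  B <- diag(K)
  m <- nrow(arTab)
  n <- nrow(maTab)
  for (k in seq_len(K)) {
    if (m > 0) {
      for (i in seq_len(min(m, k - 1))) A[k, k - i] <- -arTab[i, k]
    }
    if (n > 0) {
      for (j in seq_len(min(n, k - 1))) B[k, k - j] <- maTab[j, k]
    }
  }
  # A is unit lower-triangular, hence invertible by construction.
  forwardsolve(A, B)
}

#' Transfer matrix of the stacked state-space model
#'
#' Builds the (N*K) x (N*K) transfer matrix `Theta` such that the stacked
#' latent state is `x = Theta u` for stacked innovations `u`, equivalent to
#' unrolling the ARMA recursion. With the gene-major, time-minor stacking
#' and gene coupling carried entirely by the interaction matrix, `Theta` is
#' block-diagonal over genes; each K x K block is lower-triangular with unit
#' diagonal, so `Theta` is always invertible.
#'
#' @param spec an [armaSpec].
#' @param K number of stages.
#' @param nGenes number of genes.
#' @return (N*K) x (N*K) transfer matrix.
#' @examples
#' transferMatrix(armaSpec(m = 1, n = 0, ar = 0.5), K = 2, nGenes = 1)
#' @export
transferMatrix <- function(spec, K, nGenes) {
  stopIfNot(inherits(spec, "armaSpec"), "spec must come from armaSpec()")
  d <- nGenes * K
  theta <- matrix(0, d, d)
  for (g in seq_len(nGenes)) {
    arTab <- coefTable(spec$ar, spec$m, K, g, spec$perGene)
    maTab <- coefTable(spec$ma, spec$n, K, g, spec$perGene)
    idx <- stackIndex(g, seq_len(K), K)
    theta[idx, idx] <- transferBlock(arTab, maTab, K)
  }
  theta
}

#' Lift the innovation covariance to the stacked space
#'
#' Expands the K x K innovation covariance to the (N*K) x (N*K) stacked
#' space as `I_N (x) Cuk`: innovations are correlated over time through the
#' fGn structure and independent across genes.
#'
#' @param Cuk K x K innovation covariance.
#' @param nGenes number of genes.
#' @return (N*K) x (N*K) block-diagonal covariance.
#' @export
expandInnovationCovariance <- function(Cuk, nGenes) {
  kronecker(diag(nGenes), Cuk)
}

#' State covariance of the stacked model
#'
#' `Cxk = Theta Cuk_lifted Theta^T`, symmetrized and clipped to the PSD cone
#' when floating-point asymmetry exceeds 1e-10.
#'
#' @param theta (N*K) x (N*K) transfer matrix.
#' @param cukExpanded (N*K) x (N*K) lifted innovation covariance.
#' @return symmetric PSD state covariance matrix.
#' @export
stateCovariance <- function(theta, cukExpanded) {
  stopIfNot(
    is.matrix(theta) && is.matrix(cukExpanded) &&
      all(dim(theta) == dim(cukExpanded)) && nrow(theta) == ncol(theta),
    "theta and cukExpanded must be square matrices of equal size"
  )
  Cxk <- theta %*% cukExpanded %*% t(theta)
  if (max(abs(Cxk - t(Cxk))) > 1e-10) {
    Cxk <- psdClip(Cxk, floor = 0) + diag(1e-8, nrow(Cxk))
  } else {
    Cxk <- symmetrize(Cxk)
  }
  Cxk
}

#' Assemble the full covariance structure
#'
#' Convenience constructor running [innovationCovariance],
#' [transferMatrix] and [stateCovariance] and returning a validated
#' [CovarianceSet].
#'
#' @param spec an [armaSpec].
#' @param K number of stages.
#' @param nGenes number of genes.
#' @param H Hurst exponent, constrained to (0.5, 1) here.
#' @param sigmaU innovation sd.
#' @return a [CovarianceSet].
#' @export
buildCovarianceSet <- function(spec, K, nGenes, H = 0.6, sigmaU = 1) {
  stopIfNot(H > 0.5 && H < 1,
    "H must lie strictly inside (0.5, 1) for the nonstationary model")
  inn <- innovationCovariance(K, H, sigmaU)
  theta <- transferMatrix(spec, K, nGenes)
  Cxk <- stateCovariance(theta, expandInnovationCovariance(inn$Cuk, nGenes))
  new("CovarianceSet",
    Ruk = inn$Ruk, Cuk = inn$Cuk, theta = theta, Cxk = Cxk,
    hurst = H, sigmaU = sigmaU, nGenes = as.integer(nGenes),
    K = as.integer(K)
  )
}

#' Simulate fractional Gaussian noise
#'
#' Draws exact fGn sample paths from the Toeplitz covariance via Cholesky
#' factorization.
#'
#' @param n series length.
#' @param H Hurst exponent in (0, 1).
#' @param sigmaU innovation sd.
#' @param nSeries number of independent series.
#' @param seed optional integer seed.
#' @return `nSeries x n` matrix of fGn draws.
#' @export
simulateFgn <- function(n, H, sigmaU = 1, nSeries = 1, seed = NULL) {
  if (sigmaU == 0) {
    return(matrix(0, nSeries, n))
  }
  R <- stats::toeplitz(fgnAutocorrelation(0:(n - 1), H))
  L <- cholJitter(sigmaU^2 * R)
  withSeed(seed, {
    z <- matrix(rnorm(nSeries * n), nSeries, n)
    z %*% L
  })
}

#' Fit the Hurst exponent by covariance matching
#'
#' Grid search for the Hurst exponent minimizing the Frobenius-norm error
#' between the model innovation covariance `sigma^2 R(H)` and an empirical
#' covariance estimate, with `sigma^2` profiled out by least squares at each
#' grid point. Ties break to the smaller `H`.
#'
#' The empirical covariance is obtained from `x` according to `input`:
#' \describe{
#'   \item{`series`}{`x` is a single time series; the lagged sample
#'     autocovariances up to `maxLag` are arranged as a Toeplitz matrix.}
#'   \item{`replicates`}{`x` is a matrix of replicate series in rows (e.g.,
#'     genes x stages); the cross-sectional K x K covariance is used.}
#'   \item{`covariance`}{`x` is already a covariance matrix.}
#'   \item{`auto`}{vector -> `series`; square symmetric matrix ->
#'     `covariance`; otherwise `replicates`.}
#' }
#'
#' @param x numeric vector or matrix (see `input`).
#' @param grid candidate Hurst values inside (0.5, 1); default
#'   `seq(0.55, 0.95, by = 0.05)`.
#' @param input how to interpret `x` (see Details).
#' @param maxLag maximum lag used for a single series (default
#'   `min(n - 1, 5)`: the autocorrelation curves of different Hurst
#'   exponents separate most at short lags, where sample autocovariances
#'   are also least noisy).
#' @return list with `H` (the selected value), `sigmaU` (profiled), and
#'   `errors` (Frobenius errors per grid point).
#' @export
fitHurst <- function(x, grid = seq(0.55, 0.95, by = 0.05),
                     input = c("auto", "series", "replicates", "covariance"),
                     maxLag = NULL) {
  input <- match.arg(input)
  stopIfNot(all(grid > 0.5 & grid < 1), "grid must lie inside (0.5, 1)")
  grid <- sort(grid)
  if (input == "auto") {
    input <- if (!is.matrix(x)) {
      "series"
    } else if (nrow(x) == ncol(x) && max(abs(x - t(x))) < 1e-8) {
      "covariance"
    } else {
      "replicates"
    }
  }
  emp <- switch(input,
    series = {
      x <- as.numeric(x)
      n <- length(x)
      stopIfNot(n >= 2, "need at least 2 observations (invalid-input)")
      if (is.null(maxLag)) maxLag <- min(n - 1, 5L)
      xc <- x - mean(x)
      g <- vapply(0:maxLag, function(tau) {
        sum(xc[seq_len(n - tau)] * xc[seq_len(n - tau) + tau]) / n
      }, numeric(1))
      stats::toeplitz(g)
    },
    replicates = {
      stopIfNot(is.matrix(x) && nrow(x) >= 2,
        "need at least 2 replicate series (invalid-input)")
      crossprod(x) / nrow(x)
    },
    covariance = {
      stopIfNot(is.matrix(x) && nrow(x) == ncol(x),
        "covariance input must be square")
      symmetrize(x)
    }
  )
  Kc <- nrow(emp)
  errors <- vapply(grid, function(H) {
    R <- stats::toeplitz(fgnAutocorrelation(0:(Kc - 1), H))
    s2 <- max(0, sum(R * emp) / sum(R * R)) # profiled sigma^2
    sqrt(sum((s2 * R - emp)^2))
  }, numeric(1))
  best <- which(errors <= min(errors) + 1e-12)[1] # tie -> smaller H
  H <- grid[best]
  R <- stats::toeplitz(fgnAutocorrelation(0:(Kc - 1), H))
  list(
    H = H,
    sigmaU = sqrt(max(0, sum(R * emp) / sum(R * R))),
    errors = stats::setNames(errors, grid)
  )
}
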