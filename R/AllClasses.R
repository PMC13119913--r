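#' ExpressionTensor: cluster-by-stage mean expression
#'
#' Holds the genes x stages x clusters array of cluster-level mean expression
#' values that the temporal model consumes, together with a presence mask for
#' (stage, cluster) combinations that contained no cells. Absent combinations
#' are masked, never imputed.
#'
#' @slot means numeric array, genes x stages x clusters.
#' @slot mask logical matrix, stages x clusters; `TRUE` where cells were
#'   present and the mean is defined.
#' @slot stages ordered character vector of stage labels.
#'
#' @exportClass ExpressionTensor
setClass("ExpressionTensor",
  representation(means = "array", mask = "matrix", stages = "character")
)

setValidity("ExpressionTensor", function(object) {
  d <- dim(object@means)
  if (length(d) != 3) {
    return("means must be a 3-d array (genes x stages x clusters)")
  }
  if (!identical(dim(object@mask), d[2:3])) {
    return("mask must be stages x clusters")
  }
  if (length(object@stages) != d[2]) {
    return("stages must match the second dimension of means")
  }
  if (any(!is.finite(object@means[rep(object@mask, each = d[1])]))) {
    return("unmasked means must be finite")
  }
  TRUE
})

#' CovarianceSet: state-space covariance structure
#'
#' The covariance building blocks of the time-varying ARMA state-space model:
#' the fractional-Gaussian-noise Toeplitz correlation matrix over stages, the
#' innovation covariance, the block transfer matrix mapping stacked
#' innovations to stacked latent states, and the induced state covariance.
#' Stacked vectors are ordered gene-major, time-minor.
#'
#' @slot Ruk K x K Toeplitz correlation matrix of the innovation process.
#' @slot Cuk K x K innovation covariance, `sigmaU^2 * Ruk`.
#' @slot theta (N*K) x (N*K) transfer matrix (block lower-triangular with
#'   unit-diagonal blocks).
#' @slot Cxk (N*K) x (N*K) state covariance, `theta Cuk_lifted theta^T`.
#' @slot hurst Hurst exponent in (0.5, 1).
#' @slot sigmaU innovation standard deviation.
#' @slot nGenes number of genes N.
#' @slot K number of stages.
#'
#' @exportClass CovarianceSet
setClass("CovarianceSet",
  representation(
    Ruk = "matrix", Cuk = "matrix", theta = "matrix", Cxk = "matrix",
    hurst = "numeric", sigmaU = "numeric", nGenes = "integer", K = "integer"
  )
)

setValidity("CovarianceSet", function(object) {
  K <- object@K
  N <- object@nGenes
  if (!identical(dim(object@Ruk), c(K, K))) {
    return("Ruk must be K x K")
  }
  if (max(abs(object@Ruk - t(object@Ruk))) > 1e-8) {
    return("Ruk must be symmetric")
  }
  if (max(abs(diag(object@Ruk) - 1)) > 1e-8) {
    return("Ruk must have unit diagonal")
  }
  d <- as.integer(N * K)
  if (!identical(dim(object@theta), c(d, d))) {
    return("theta must be (N*K) x (N*K)")
  }
  if (!identical(dim(object@Cxk), c(d, d))) {
    return("Cxk must be (N*K) x (N*K)")
  }
  if (max(abs(object@Cxk - t(object@Cxk))) > 1e-8) {
    return("Cxk must be symmetric")
  }
  TRUE
})

#' GaussianPosterior: variational posterior over stacked latent states
#'
#' @slot mean numeric vector of length N*K (gene-major, time-minor).
#' @slot cov (N*K) x (N*K) symmetric PSD covariance.
#' @slot nGenes number of genes.
#' @slot K number of stages.
#'
#' @exportClass GaussianPosterior
setClass("GaussianPosterior",
  representation(
    mean = "numeric", cov = "matrix", nGenes = "integer", K = "integer"
  )
)

setValidity("GaussianPosterior", function(object) {
  d <- as.integer(object@nGenes * object@K)
  if (length(object@mean) != d) {
    return("mean must have length N*K")
  }
  if (!identical(dim(object@cov), c(d, d))) {
    return("cov must be (N*K) x (N*K)")
  }
  if (max(abs(object@cov - t(object@cov))) > 1e-8) {
    return("cov must be symmetric")
  }
  TRUE
})

#' GammaPosterior: variational posterior over the interaction matrix
#'
#' Elementwise gamma posteriors q(phi_ij) with shape and rate matrices; the
#' posterior expectation is `shape / rate`.
#'
#' @slot shape N x N matrix of gamma shapes (> 0).
#' @slot rate N x N matrix of gamma rates (> 0).
#'
#' @exportClass GammaPosterior
setClass("GammaPosterior",
  representation(shape = "matrix", rate = "matrix")
)

setValidity("GammaPosterior", function(object) {
  if (!identical(dim(object@shape), dim(object@rate))) {
    return("shape and rate must share dimensions")
  }
  if (any(object@shape <= 0) || any(object@rate <= 0)) {
    return("shape and rate must be strictly positive")
  }
  TRUE
})

#' VbFit: result of variational inference
#'
#' @slot statePosterior [GaussianPosterior] over stacked latent states.
#' @slot interactionPosterior [GammaPosterior] over the interaction matrix.
#' @slot elbo numeric vector, evidence-lower-bound trace per sweep.
#' @slot converged logical flag.
#' @slot iterations number of coordinate-ascent sweeps run.
#' @slot sigmaV estimated observation noise sd (reporting only).
#' @slot settings list snapshot of the settings used.
#' @slot observations the N x K observation matrix the fit was run on.
#'
#' @exportClass VbFit
setClass("VbFit",
  representation(
    statePosterior = "GaussianPosterior",
    interactionPosterior = "GammaPosterior",
    elbo = "numeric", converged = "logical", iterations = "integer",
    sigmaV = "numeric", settings = "list", observations = "matrix"
  )
)

#' PosteriorSamples: MCMC draws from the state posterior
#'
#' @slot draws n_samples x (N*K) matrix of draws from q(x | <phi>).
#' @slot phiDraws optional array of interaction draws (0-length when x-only).
#' @slot method sampler name, "direct" or "metropolis".
#' @slot seed integer seed used.
#' @slot acceptanceRate Metropolis acceptance rate (NA for direct sampling).
#' @slot nGenes,K dimensions.
#'
#' @exportClass PosteriorSamples
setClass("PosteriorSamples",
  representation(
    draws = "matrix", phiDraws = "array", method = "character",
    seed = "integer", acceptanceRate = "numeric",
    nGenes = "integer", K = "integer"
  )
)

setValidity("PosteriorSamples", function(object) {
  if (nrow(object@draws) < 1) {
    return("at least one draw required")
  }
  if (ncol(object@draws) != object@nGenes * object@K) {
    return("draws must have N*K columns")
  }
  if (any(!is.finite(object@draws))) {
    return("draws must be finite")
  }
  TRUE
})

setMethod("show", "ExpressionTensor", function(object) {
  d <- dim(object@means)
  cat(
    "ExpressionTensor:", d[1], "genes x", d[2], "stages x", d[3],
    "clusters\n"
  )
  cat("  stages:", paste(object@stages, collapse = " < "), "\n")
  cat("  present (stage, cluster) groups:", sum(object@mask), "/",
    length(object@mask), "\n"
  )
})

setMethod("show", "CovarianceSet", function(object) {
  cat(
    "CovarianceSet: N =", object@nGenes, "genes, K =", object@K,
    "stages\n  H =", object@hurst, ", sigma_u =",
    signif(object@sigmaU, 4), "\n"
  )
  cat("  stacking: gene-major, time-minor\n")
})

setMethod("show", "VbFit", function(object) {
  cat(
    "VbFit:", object@statePosterior@nGenes, "genes x",
    object@statePosterior@K, "stages\n"
  )
  cat(
    "  ", object@iterations, "sweeps,",
    if (object@converged) "converged" else "NOT converged",
    "; final ELBO", signif(tail(object@elbo, 1), 8), "\n"
  )
})

setMethod("show", "PosteriorSamples", function(object) {
  cat(
    "PosteriorSamples:", nrow(object@draws), object@method, "draws over",
    object@nGenes, "genes x", object@K, "stages\n"
  )
  if (is.finite(object@acceptanceRate)) {
    cat("  acceptance rate:", signif(object@acceptanceRate, 3), "\n")
  }
})

# ---- accessors -------------------------------------------------------------

#' Accessors for driverDyn result objects
#'
#' `tensorMeans` returns the genes x stages x clusters array,
#' `tensorMask` the stage-by-cluster presence mask, `stageLabels` the ordered
#' stage labels. `stateMean`/`stateCov` return the variational Gaussian
#' posterior moments, `interactionMean` the expected interaction matrix
#' `shape / rate`, `elboTrace` the ELBO values per sweep, and
#' `posteriorDraws` the MCMC draw matrix.
#'
#' @param x a driverDyn S4 object.
#' @return the requested component.
#' @name accessors
#' @aliases tensorMeans tensorMask stageLabels stateMean stateCov
#'   interactionMean elboTrace posteriorDraws
NULL

#' @rdname accessors
#' @export
tensorMeans <- function(x) {
  stopIfNot(is(x, "ExpressionTensor"), "x must be an ExpressionTensor")
  x@means
}

#' @rdname accessors
#' @export
tensorMask <- function(x) {
  stopIfNot(is(x, "ExpressionTensor"), "x must be an ExpressionTensor")
  x@mask
}

#' @rdname accessors
#' @export
stageLabels <- function(x) {
  stopIfNot(is(x, "ExpressionTensor"), "x must be an ExpressionTensor")
  x@stages
}

#' @rdname accessors
#' @export
stateMean <- function(x) {
  if (is(x, "VbFit")) x <- x@statePosterior
  stopIfNot(is(x, "GaussianPosterior"), "x must be a VbFit/GaussianPosterior")
  x@mean
}

#' @rdname accessors
#' @export
stateCov <- function(x) {
  if (is(x, "VbFit")) x <- x@statePosterior
  stopIfNot(is(x, "GaussianPosterior"), "x must be a VbFit/GaussianPosterior")
  x@cov
}

#' @rdname accessors
#' @export
interactionMean <- function(x) {
  if (is(x, "VbFit")) x <- x@interactionPosterior
  stopIfNot(is(x, "GammaPosterior"), "x must be a VbFit/GammaPosterior")
  x@shape / x@rate
}

#' @rdname accessors
#' @export
elboTrace <- function(x) {
  stopIfNot(is(x, "VbFit"), "x must be a VbFit")
  x@elbo
}

#' @rdname accessors
#' @export
posteriorDraws <- function(x) {
  stopIfNot(is(x, "PosteriorSamples"), "x must be PosteriorSamples")
  x@draws
}

#' Posterior-mean expression matrix of a fit
#'
#' Reshapes the stacked posterior mean back into a genes x stages matrix of
#' predicted expression values.
#'
#' @param fit a [VbFit].
#' @return numeric matrix, genes x stages, with the dimnames of the
#'   observations.
#' @export
predictedExpression <- function(fit) {
  stopIfNot(is(fit, "VbFit"), "fit must be a VbFit")
  g <- fit@statePosterior
  out <- unstackVector(g@mean, g@nGenes, g@K)
  dimnames(out) <- dimnames(fit@observations)
  out
}
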