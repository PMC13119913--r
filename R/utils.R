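#' @import methods
#' @importFrom stats rnorm runif rgamma cor cor.test quantile sd var setNames
#'   dist toeplitz optimize pnorm
#' @importFrom utils head tail modifyList read.table write.table
NULL

# Symmetrize a square matrix; tolerance guards against silently "fixing" a
# genuinely non-symmetric input.
symmetrize <- function(x) (x + t(x)) / 2

#' Project a symmetric matrix onto the PSD cone
#'
#' Eigenvalues below `floor` are clipped to `floor`. Used wherever a matrix
#' must enter a quadratic form or a Cholesky factorization: the expected
#' interaction matrix before it tilts the Gaussian posterior, and covariance
#' matrices after accumulated floating-point asymmetry.
#'
#' @param x square numeric matrix (symmetrized internally).
#' @param floor smallest admissible eigenvalue (default 0).
#' @return symmetric matrix with eigenvalues >= `floor`.
#' @keywords internal
psdClip <- function(x, floor = 0) {
  x <- symmetrize(x)
  es <- eigen(x, symmetric = TRUE)
  if (min(es$values) >= floor) {
    return(x)
  }
  v <- pmax(es$values, floor)
  symmetrize(es$vectors %*% (v * t(es$vectors)))
}

# Cholesky with escalating jitter; covariance matrices here are PSD by
# construction but can lose definiteness at machine precision.
cholJitter <- function(x, maxTries = 8L) {
  x <- symmetrize(x)
  jitter <- 0
  for (i in seq_len(maxTries)) {
    out <- tryCatch(chol(x + diag(jitter, nrow(x))), error = function(e) NULL)
    if (!is.null(out)) {
      return(out)
    }
    jitter <- if (jitter == 0) 1e-10 * mean(diag(x) + 1) else jitter * 10
  }
  stop("matrix could not be factorized even after jitter (numerical-failure)")
}

# Inverse via Cholesky, symmetrized.
invPsd <- function(x) {
  R <- cholJitter(x)
  symmetrize(chol2inv(R))
}

# log-determinant of a PSD matrix via Cholesky
logDetPsd <- function(x) {
  2 * sum(log(diag(cholJitter(x))))
}

# Stacked-vector index helpers. The package's stacking convention is
# gene-major, time-minor: element (gene i, time k) sits at (i - 1) * K + k.
stackIndex <- function(gene, time, K) (gene - 1L) * K + time

stackVector <- function(x) {
  # x: genes x times matrix -> stacked vector in gene-major, time-minor order
  as.vector(t(x))
}

unstackVector <- function(v, nGenes, K) {
  matrix(v, nrow = nGenes, ncol = K, byrow = TRUE)
}

# Deterministic seeded evaluation that does not disturb the caller's RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(seed)
  }
  force(expr)
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
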