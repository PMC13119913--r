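test_that("fGn autocorrelation matches its closed form", {
  expect_equal(fgnAutocorrelation(0, 0.7), 1)
  expect_equal(fgnAutocorrelation(0, 0.55), 1)
  expect_equal(fgnAutocorrelation(3, 0.5), 0)
  expect_equal(fgnAutocorrelation(1, 0.6), 0.5 * (2^1.2 - 2))
  expect_error(fgnAutocorrelation(1, 1.2), "invalid-argument")
  expect_error(fgnAutocorrelation(-1, 0.6), "invalid-argument")

  # continuity at the white-noise boundary
  expect_lt(abs(fgnAutocorrelation(1, 0.5 + 1e-6)), 1e-4)
  expect_lt(abs(fgnAutocorrelation(4, 0.5 + 1e-6)), 1e-4)
})

test_that("innovation covariance is Toeplitz, symmetric and PSD", {
  # white-noise limit
  expect_equal(innovationCovariance(3, 0.5, 1)$Ruk, diag(3))

  inn <- innovationCovariance(4, 0.9, 2)
  expect_equal(inn$Ruk, t(inn$Ruk))
  expect_equal(unname(diag(inn$Ruk)), rep(1, 4))
  expect_equal(inn$Cuk, 4 * inn$Ruk)
  # gamma_u(tau) = sigma_u^2 rho_u(tau), entry by entry
  for (tau in 1:3) {
    expect_equal(inn$Cuk[1, 1 + tau], 4 * fgnAutocorrelation(tau, 0.9))
  }
  # off-diagonals positive and non-increasing in lag for H > 0.5
  offs <- inn$Ruk[1, 2:4]
  expect_true(all(offs > 0))
  expect_true(all(diff(offs) <= 0))
})

test_that("the transfer matrix reproduces the unrolled recursion", {
  # no dynamics: identity
  expect_equal(transferMatrix(armaSpec(0, 0), K = 3, nGenes = 2), diag(6))

  # AR(1) with a = 0.5, one gene, two stages, by hand
  th <- transferMatrix(armaSpec(1, 0, ar = 0.5), K = 2, nGenes = 1)
  expect_equal(th, rbind(c(1, 0), c(0.5, 1)))

  # oracle: unrolled recursion on random coefficients and innovations
  unroll <- function(ar, ma, u) {
    K <- length(u)
    x <- numeric(K)
    for (k in seq_len(K)) {
      x[k] <- u[k]
      for (i in seq_len(min(length(ar), k - 1))) {
        x[k] <- x[k] + ar[i] * x[k - i]
      }
      for (j in seq_len(min(length(ma), k - 1))) {
        x[k] <- x[k] + ma[j] * u[k - j]
      }
    }
    x
  }
  set.seed(17)
  for (case in 1:100) {
    K <- sample(2:5, 1)
    N <- sample(1:3, 1)
    m <- sample(0:2, 1)
    n <- sample(0:2, 1)
    ar <- if (m > 0) matrix(runif(N * m, -0.8, 0.8), N, m) else NULL
    ma <- if (n > 0) matrix(runif(N * n, -0.8, 0.8), N, n) else NULL
    spec <- armaSpec(m, n, ar = ar, ma = ma, perGene = TRUE)
    th <- transferMatrix(spec, K, N)
    u <- matrix(rnorm(N * K), N, K)
    viaTheta <- th %*% driverDyn:::stackVector(u)
    direct <- driverDyn:::stackVector(t(vapply(seq_len(N), function(g) {
      unroll(
        if (m > 0) ar[g, ] else numeric(0),
        if (n > 0) ma[g, ] else numeric(0), u[g, ]
      )
    }, numeric(K))))
    expect_lt(max(abs(viaTheta - direct)), 1e-10)
  }
})

test_that("state covariance follows Theta Cuk Theta^T", {
  # identity transfer: state covariance equals innovation covariance
  Cuk <- innovationCovariance(3, 0.7, 1.5)$Cuk
  lifted <- expandInnovationCovariance(Cuk, 2)
  expect_equal(stateCovariance(diag(6), lifted), lifted)

  # hand product for one gene, two stages
  th <- rbind(c(1, 0), c(0.5, 1))
  expect_equal(
    stateCovariance(th, diag(2)),
    rbind(c(1, 0.5), c(0.5, 1.25))
  )

  # symmetric and PSD on a random instance
  spec <- armaSpec(1, 1, ar = 0.6, ma = -0.3)
  cs <- buildCovarianceSet(spec, K = 4, nGenes = 3, H = 0.8, sigmaU = 1.2)
  expect_lt(max(abs(cs@Cxk - t(cs@Cxk))), 1e-12)
  expect_gt(min(eigen(cs@Cxk, symmetric = TRUE)$values), -1e-10)
  expect_error(stateCovariance(diag(2), diag(3)), "square")
})

test_that("state covariance matches simulated draws", {
  spec <- armaSpec(1, 1, ar = 0.5, ma = 0.2)
  K <- 3
  N <- 2
  cs <- buildCovarianceSet(spec, K, N, H = 0.7, sigmaU = 1)
  set.seed(99)
  n <- 20000
  L <- chol(expandInnovationCovariance(cs@Cuk, N))
  u <- matrix(rnorm(n * N * K), n) %*% L
  x <- u %*% t(cs@theta)
  emp <- crossprod(x) / n
  # elementwise within 3 Monte-Carlo standard errors
  se <- sqrt((diag(cs@Cxk) %o% diag(cs@Cxk) + cs@Cxk^2) / n)
  expect_true(all(abs(emp - cs@Cxk) < 3.5 * se))
})

test_that("Hurst fitting recovers self-consistent inputs on the grid", {
  inn <- innovationCovariance(5, 0.6, 1.3)
  fit <- fitHurst(inn$Cuk, input = "covariance")
  expect_equal(fit$H, 0.6)
  expect_equal(fit$sigmaU, 1.3, tolerance = 1e-10)

  # output always within the supplied grid
  set.seed(3)
  x <- as.numeric(simulateFgn(100, 0.7, seed = 3))
  fit2 <- fitHurst(x)
  expect_true(fit2$H %in% seq(0.55, 0.95, by = 0.05))
  expect_error(fitHurst(1), "invalid-input")
})

test_that("Hurst estimates concentrate near the generating value", {
  ests <- vapply(1:60, function(s) {
    fitHurst(as.numeric(simulateFgn(200, 0.7, seed = s)))$H
  }, numeric(1))
  # modal estimate at the truth, most mass within one grid step
  tab <- table(ests)
  expect_equal(as.numeric(names(tab)[which.max(tab)]), 0.7)
  expect_gt(mean(abs(ests - 0.7) <= 0.05), 0.5)
})
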