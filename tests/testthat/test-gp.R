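# dense naive reference implementation used as linear-algebra oracle
naiveGP <- function(theta, X, y, nugget = 1e-10) {
  l <- nrow(X); q <- ncol(X)
  R <- matrix(1, l, l)
  for (j in seq_len(q))
    R <- R * exp(-theta[j] * abs(outer(X[, j], X[, j], "-"))^2)
  R <- R + diag(nugget * mean(diag(R)), l)
  Ri <- solve(R)
  one <- rep(1, l)
  beta <- drop((t(one) %*% Ri %*% y) / (t(one) %*% Ri %*% one))
  s2 <- drop(t(y - beta) %*% Ri %*% (y - beta)) / l
  nll <- 0.5 * l * log(s2) +
    0.5 * as.numeric(determinant(R)$modulus)
  predict <- function(Xn) {
    r <- matrix(1, nrow(Xn), l)
    for (j in seq_len(q))
      r <- r * exp(-theta[j] * abs(outer(Xn[, j], X[, j], "-"))^2)
    m <- beta + r %*% Ri %*% (y - beta)
    v <- s2 * (1 - diag(r %*% Ri %*% t(r)) +
               (1 - drop(r %*% Ri %*% one))^2 /
               drop(t(one) %*% Ri %*% one))
    list(mean = drop(m), variance = v)
  }
  list(nll = nll, beta = beta, sigma2 = s2, predict = predict)
}

test_that("the product correlation rule holds", {
  x <- matrix(c(0.2, 0.5, 0.9), 3, 1)
  expect_equal(diag(gpCorrelation(x, x, theta = 3)), rep(1, 3))
  expect_true(all(gpCorrelation(x, x, theta = 0) == 1))
  expect_equal(gpCorrelation(matrix(0), matrix(1), theta = 1)[1, 1],
               exp(-1))
  # multiplicative across dimensions
  X2 <- cbind(x, 2 * x)
  r2 <- gpCorrelation(X2[1, , drop = FALSE], X2[3, , drop = FALSE],
                      theta = c(1, 2))
  expect_equal(r2[1, 1], exp(-1 * 0.7^2) * exp(-2 * 1.4^2))
  expect_error(gpCorrelation(x, x, theta = -1), "parameter error")
  expect_error(gpCorrelation(x, cbind(x, x), theta = 1), "shape error")
})

test_that("concentrated likelihood agrees with the dense oracle to 1e-8", {
  set.seed(42)
  for (rep in 1:3) {
    l <- 20; q <- 3
    X <- matrix(runif(l * q), l, q)
    y <- sin(3 * X[, 1]) + 2 * X[, 2]^2 + rnorm(l, sd = 0.05)
    theta <- runif(q, 0.3, 3)
    nv <- naiveGP(theta, X, y)
    mine <- concentratedNLL(theta, X, y)
    expect_equal(as.numeric(mine), nv$nll, tolerance = 1e-8)
    expect_equal(attr(mine, "beta"), nv$beta, tolerance = 1e-8)
    expect_equal(attr(mine, "sigma2"), nv$sigma2, tolerance = 1e-8)
  }
})

test_that("two-sample closed forms match the hand derivation", {
  X <- matrix(c(0, 1), 2, 1)
  y <- c(2, 5)
  theta <- 0.7
  r <- exp(-theta)
  val <- concentratedNLL(theta, X, y)
  expect_equal(attr(val, "beta"), mean(y), tolerance = 1e-6)
  e <- (y[1] - y[2]) / 2
  expect_equal(attr(val, "sigma2"), e^2 / (1 - r), tolerance = 1e-6)
})

test_that("constant outputs short-circuit to a degenerate model", {
  val <- concentratedNLL(1, matrix(1:5, 5, 1), rep(3, 5))
  expect_true(attr(val, "degenerate"))
  expect_lt(as.numeric(val), -1e300)
  fit <- gpFit(list(X = matrix(runif(10), 5, 2), y = rep(2, 5)),
               mode = "isotropic", budget = 50)
  expect_true(fit$model@degenerate)
  pr <- gpPredict(fit$model, matrix(runif(4), 2, 2))
  expect_equal(pr$mean, c(2, 2))
  expect_equal(pr$variance, c(0, 0))
})

test_that("the concentrated objective is invariant to output shifts", {
  set.seed(5)
  X <- matrix(runif(30), 15, 2)
  y <- rnorm(15)
  a <- concentratedNLL(c(1, 2), X, y)
  b <- concentratedNLL(c(1, 2), X, y + 100)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-7)
})

test_that("posterior mean and variance match the dense oracle and interpolate", {
  set.seed(11)
  l <- 20; q <- 3
  X <- matrix(runif(l * q), l, q)
  y <- cos(2 * X[, 1]) + X[, 3]
  # pin moderate correlation rates (a well-conditioned regime) so both
  # routes are algebraically and numerically comparable
  th <- c(1.5, 0.7, 2.5)
  fit <- gpFit(list(X = X, y = y), mode = "anisotropic", budget = 5,
               bounds = rbind(log10(th) - 1e-9, log10(th) + 1e-9))
  nv <- naiveGP(fit$model@theta, X, y, nugget = fit$model@nugget)
  Xn <- matrix(runif(18), 6, 3)
  a <- gpPredict(fit$model, Xn)
  b <- nv$predict(Xn)
  expect_equal(a$mean, b$mean, tolerance = 1e-8)
  expect_equal(a$variance, b$variance, tolerance = 1e-8)
  # Kriging interpolates its training data
  tr <- gpPredict(fit$model, X)
  expect_lt(max(abs(tr$mean - y)), 1e-6)
  expect_lt(max(tr$variance), 1e-6 * fit$model@sigma2)
  expect_error(gpPredict(fit$model, Xn[, 1:2]), "shape error")
})

test_that("a far point reverts to the trend with inflated variance", {
  set.seed(3)
  X <- matrix(runif(20), 10, 2)
  y <- rnorm(10)
  fit <- gpFit(list(X = X, y = y), mode = "isotropic", budget = 100)
  far <- matrix(50, 1, 2)
  pr <- gpPredict(fit$model, far)
  expect_equal(pr$mean, fit$model@beta, tolerance = 1e-8)
  U <- fit$model@chol
  oneRinv1 <- sum(backsolve(U, rep(1, 10), transpose = TRUE)^2)
  expect_equal(pr$variance, fit$model@sigma2 * (1 + 1 / oneRinv1),
               tolerance = 1e-8)
})

test_that("posterior mean is linear in the training outputs", {
  set.seed(6)
  X <- matrix(runif(24), 12, 2)
  y1 <- rnorm(12); y2 <- rnorm(12)
  # pin theta by a degenerate search box so all three fits share it
  b <- rbind(c(0, 0), c(0.01, 0.01))
  Xn <- matrix(runif(8), 4, 2)
  p <- function(y) gpPredict(gpFit(list(X = X, y = y), budget = 5,
                                   mode = "anisotropic",
                                   bounds = b)$model, Xn)$mean
  expect_equal(p(y1 + 2 * y2), p(y1) + 2 * p(y2) -
               2 * p(numeric(12)), tolerance = 1e-6)
})

test_that("adding a training point cannot increase posterior variance", {
  set.seed(8)
  X <- matrix(runif(20), 10, 2)
  y <- sin(3 * X[, 1]) + X[, 2]
  b <- rbind(c(0.9, 0.9), c(1, 1))           # shared hyperparameters
  fit10 <- gpFit(list(X = X, y = y), budget = 5, mode = "anisotropic",
                 bounds = b)
  Xtra <- matrix(runif(2), 1, 2)
  fit11 <- gpFit(list(X = rbind(X, Xtra),
                      y = c(y, sin(3 * Xtra[1]) + Xtra[2])),
                 budget = 5, mode = "anisotropic", bounds = b)
  Xn <- matrix(runif(20), 10, 2)
  v10 <- gpPredict(fit10$model, Xn)$variance / fit10$model@sigma2
  v11 <- gpPredict(fit11$model, Xn)$variance / fit11$model@sigma2
  expect_true(all(v11 <= v10 + 1e-8))
})

test_that("smooth kernel reproduces a quadratic between samples", {
  x <- matrix(seq(0, 1, length.out = 5), 5, 1)
  f <- function(z) 2 + 3 * z - 4 * z^2
  b <- rbind(-0.5, 0.5)                       # theta ~ 1: smooth regime
  fit <- gpFit(list(X = x, y = f(x[, 1])), budget = 30, bounds = b,
               mode = "isotropic", nuggetStart = 1e-12)
  xn <- matrix(seq(0.05, 0.95, length.out = 30), ncol = 1)
  pr <- gpPredict(fit$model, xn)
  expect_lt(max(abs(pr$mean - f(xn[, 1]))) / max(abs(f(xn[, 1]))), 0.01)
})

test_that("isotropic fits are nested within anisotropic fits", {
  set.seed(13)
  d <- sampleGP(syntheticGPSpec(q = 2, l = 40, thetaTrue = c(8, 0.2),
                                seed = 13))
  an <- gpFit(list(X = d$X, y = d$y), mode = "anisotropic", budget = 200)
  iso <- gpFit(list(X = d$X, y = d$y), mode = "isotropic", budget = 200)
  expect_length(iso$mle@thetaHat, 1L)
  expect_length(an$mle@thetaHat, 2L)
  expect_gte(iso$mle@nll, an$mle@nll - 1e-6)
})

test_that("independent outputs push the correlation rates to the box edge", {
  set.seed(21)
  X <- matrix(runif(120), 60, 2)
  y <- rnorm(60)
  fit <- gpFit(list(X = X, y = y), mode = "isotropic", budget = 150)
  expect_gt(fit$mle@thetaHat, 1e2)            # upper bound is 1e4
})

test_that("grouped mode ties the neighbourhood feature blocks", {
  h <- analyticHierarchy()
  J <- 5
  feat <- buildFeatureTable(h$fields[[1]], J = J, metric = "cityblock",
                            outputKind = "free")
  train <- buildTrainingSet(feat, h$fields[[2]])
  fit <- gpFit(train, mode = "grouped", budget = 60)
  expect_length(fit$mle@thetaHat, 3L)
  th <- fit$model@theta
  expect_length(th, 2 * J + 1)
  expect_equal(length(unique(th[1:J])), 1L)
  expect_equal(length(unique(th[(J + 1):(2 * J)])), 1L)
  # profiled estimates satisfy their closed forms at theta-hat
  val <- concentratedNLL(fit$mle@thetaHat, train@X, train@y,
                         groups = c(rep(1L, J), rep(2L, J), 3L))
  expect_equal(attr(val, "beta"), fit$mle@betaHat, tolerance = 1e-10)
  expect_equal(attr(val, "sigma2"), fit$mle@sigma2Hat, tolerance = 1e-10)
})

test_that("gpFit rejects invalid budgets and odd grouped dimensions", {
  expect_error(gpFit(list(X = matrix(1:4, 2), y = c(1, 2)), budget = 0),
               "parameter error")
  expect_error(gpFit(list(X = matrix(runif(8), 2), y = c(1, 2)),
                     mode = "grouped"), "grouped mode")
})

test_that("DIRECT finds global minima of standard test functions", {
  # convex quadratic
  o <- directOptimize(function(x) sum((x - c(0.3, -0.2))^2),
                      c(-1, -1), c(1, 1), 300)
  expect_lt(sqrt(sum((o$par - c(0.3, -0.2))^2)), 0.01)
  # multimodal 1D: global min of sin(5x) + 0.1 x^2 near x ~ -0.3
  f <- function(x) sin(5 * x) + 0.1 * x^2
  o2 <- directOptimize(f, -3, 3, 200)
  grid <- seq(-3, 3, length.out = 20001)
  expect_lt(o2$value, min(f(grid)) + 1e-3)
  # deterministic
  o3 <- directOptimize(f, -3, 3, 200)
  expect_identical(o2$par, o3$par)
  expect_error(directOptimize(f, -3, 3, 0), "parameter error")
})
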