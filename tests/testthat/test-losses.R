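test_that("L1 loss equals the mean absolute voxel difference", {
  a <- matrix(1, 8, 8)
  expect_identical(l1Loss(a, a), 0)
  expect_identical(l1Loss(a, a * 0), 1)
  set.seed(30)
  y <- matrix(runif(64, -1, 1), 8, 8); g <- matrix(runif(64, -1, 1), 8, 8)
  expect_equal(l1Loss(y, g), oracleMAE(y, g, rep(TRUE, 64)), tolerance = 1e-12)
  lg <- l1Loss(y, g, gradient = TRUE)
  expect_equal(lg$grad, array(sign(g - y) / 64, c(8, 8)))
  expect_error(l1Loss(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("normalized mutual information hits its analytic anchors", {
  set.seed(31)
  a <- matrix(runif(32 * 32, -1, 1), 32, 32)
  expect_equal(normalizedMutualInformation(a, a), 1)
  b <- matrix(runif(128 * 128, -1, 1), 128, 128)
  b2 <- matrix(runif(128 * 128, -1, 1), 128, 128)
  expect_lt(normalizedMutualInformation(b, b2), 0.05)   # independent noise
  # matches the explicit double-loop joint-histogram oracle
  y <- matrix(runif(20 * 20, -1, 1), 20, 20)
  g <- tanh(y + 0.3 * matrix(rnorm(400), 20, 20))
  expect_equal(normalizedMutualInformation(y, g, bins = 16),
               oracleNMI(y, g, bins = 16), tolerance = 1e-12)
  # degenerate constant planes
  cst <- matrix(0.5, 4, 4)
  expect_identical(normalizedMutualInformation(cst, cst), 1)
  expect_identical(normalizedMutualInformation(cst, cst + 0.1), 0)
  expect_error(normalizedMutualInformation(numeric(0), numeric(0)), "empty")
})

test_that("nMI is symmetric and bounded over seeded pairs", {
  set.seed(32)
  for (i in 1:25) {
    a <- matrix(runif(16 * 16, -1, 1), 16, 16)
    b <- tanh(a * runif(1, -2, 2) + matrix(rnorm(256, 0, runif(1, 0, 1)), 16))
    n1 <- normalizedMutualInformation(a, b)
    n2 <- normalizedMutualInformation(b, a)
    expect_equal(n1, n2, tolerance = 1e-12)
    expect_gte(n1, 0); expect_lte(n1, 1)
  }
})

test_that("MI loss is one minus nMI and averages over a batch", {
  set.seed(33)
  y <- matrix(runif(64, -1, 1), 8, 8)
  expect_equal(miLoss(y, y), 0)
  a <- matrix(runif(128 * 128, -1, 1), 128)
  b <- matrix(runif(128 * 128, -1, 1), 128)
  expect_gt(miLoss(a, b), 0.95)
  ys <- list(y, a); gs <- list(y, b)
  expect_equal(miLoss(ys, gs), mean(c(miLoss(y, y), miLoss(a, b))))
})

test_that("least-squares adversarial losses follow the label convention", {
  ones <- matrix(1, 4, 4); zeros <- matrix(0, 4, 4); half <- matrix(0.5, 4, 4)
  expect_identical(discriminatorLoss(ones, zeros), 0)
  expect_identical(discriminatorLoss(half, half), 0.5)
  expect_identical(generatorAdversarialLoss(ones), 0)
  expect_identical(generatorAdversarialLoss(zeros), 1)
  expect_identical(generatorAdversarialLoss(half), 0.25)
  set.seed(34)
  r <- matrix(rnorm(16), 4); f <- matrix(rnorm(16), 4)
  # brute-force patch loop
  s <- 0
  for (i in seq_along(r)) s <- s + (r[i] - 1)^2 / 16 + f[i]^2 / 16
  expect_equal(discriminatorLoss(r, f), s, tolerance = 1e-12)
  # minimized at the label values (grid search over constant score maps)
  grid <- seq(-0.5, 1.5, by = 0.05)
  dl <- vapply(grid, function(v)
    discriminatorLoss(matrix(v, 2, 2), zeros[1:2, 1:2]), 1.0)
  expect_equal(grid[which.min(dl)], 1)
  gl <- vapply(grid, function(v) generatorAdversarialLoss(matrix(v, 2, 2)), 1.0)
  expect_equal(grid[which.min(gl)], 1)
})

test_that("the composite objective is linear with the configured weights", {
  w <- lossWeights()
  expect_identical(w$lambda1, 100)
  expect_identical(w$lambda2, 5)
  expect_equal(totalGeneratorLoss(0.2, 0.01, 0.1, w), 1.7)
  expect_identical(totalGeneratorLoss(0, 0, 0, w), 0)
  # lambda2 = 0 degenerates to the pix2pix objective
  expect_equal(totalGeneratorLoss(0.3, 0.02, 0.9, lossWeights(lambda2 = 0)),
               0.3 + 100 * 0.02)
  # linear in each component
  for (i in 1:3) {
    x <- c(0.1, 0.02, 0.4)
    x2 <- x; x2[i] <- x2[i] * 2
    d1 <- totalGeneratorLoss(x[1], x[2], x[3], w)
    d2 <- totalGeneratorLoss(x2[1], x2[2], x2[3], w)
    coef <- c(1, w$lambda1, w$lambda2)[i]
    expect_equal(d2 - d1, coef * x[i], tolerance = 1e-12)
  }
  expect_error(lossWeights(lambda1 = -1), "lambda1")
})

test_that("the soft-histogram MI gradient matches finite differences", {
  set.seed(35)
  y <- matrix(runif(144, -1, 1), 12, 12)
  g <- matrix(runif(144, -1, 1), 12, 12)
  sm <- synthCT:::softMILossGrad(y, g, bins = 16)
  eps <- 1e-6
  for (i in c(1, 50, 144)) {
    gp <- g; gp[i] <- gp[i] + eps
    gm <- g; gm[i] <- gm[i] - eps
    num <- (synthCT:::softMILossGrad(y, gp, bins = 16)$loss -
              synthCT:::softMILossGrad(y, gm, bins = 16)$loss) / (2 * eps)
    expect_equal(sm$grad[i], num, tolerance = 1e-5)
  }
  # the soft value tracks the hard-histogram reference
  expect_equal(sm$loss, miLoss(y, g, bins = 16), tolerance = 0.2)
})
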