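test_that("exterior masking applies the modality background and is idempotent", {
  d <- c(6, 6, 6)
  body <- Volume(array(rep(c(0, 1), each = 108), d), modality = "MASK")
  ct <- Volume(array(100, d), modality = "CT")
  mr <- Volume(array(500, d), modality = "MR")
  mct <- maskExterior(ct, body)
  mmr <- maskExterior(mr, body)
  out <- voxelValues(body) == 0
  expect_true(all(voxelValues(mct)[out] == -1000))
  expect_true(all(voxelValues(mmr)[out] == 0))
  expect_true(all(voxelValues(mct)[!out] == 100))
  expect_identical(voxelValues(maskExterior(mct, body)), voxelValues(mct))
  ones <- Volume(array(1, d), modality = "MASK")
  expect_identical(voxelValues(maskExterior(ct, ones)), voxelValues(ct))
  expect_error(maskExterior(body, body), "MASK")
  expect_error(maskExterior(ct, Volume(array(1, c(4, 4, 4)), modality = "MASK")),
               "mismatch")
})

test_that("CT normalization is pinned at the Hounsfield endpoints", {
  expect_identical(normalizeCT(-1000), -1)
  expect_identical(normalizeCT(3095), 1)
  expect_identical(normalizeCT(1047.5), 0)
  expect_identical(denormalizeCT(-1), -1000)
  expect_identical(denormalizeCT(1), 3095)
  expect_identical(denormalizeCT(0), 1047.5)
  hu <- seq(-1000, 3095, by = 0.25)
  expect_true(all(diff(normalizeCT(hu)) > 0))  # strictly increasing
  expect_equal(denormalizeCT(normalizeCT(hu)), hu, tolerance = 1e-10)
  # clipping first, then the affine map
  expect_identical(normalizeCT(-2000), -1)
  expect_identical(normalizeCT(5000), 1)
  expect_error(normalizeCT(NA_real_), "finite")
  expect_error(denormalizeCT(1.5), "outside")
})

test_that("MR z-score normalization excludes sub-threshold voxels", {
  set.seed(20)
  vals <- c(rnorm(4000, 500, 100), rep(10, 500))   # tissue + air
  a <- array(vals, c(15, 15, 20))
  nm <- normalizeMR(a)
  inc <- vals >= 40
  expect_equal(nm$params$mean, mean(vals[inc]))
  expect_equal(nm$params$sd, sd(vals[inc]))
  # appending more air voxels leaves mu and sd unchanged
  a2 <- array(c(vals, rep(10, 500)), c(20, 25, 10))
  nm2 <- normalizeMR(a2)
  expect_equal(nm2$params$mean, nm$params$mean)
  expect_equal(nm2$params$sd, nm$params$sd)
  # a voxel at exactly mu maps to 0; far tails truncate to +/-1; air is -1
  mu <- nm$params$mean; sdv <- nm$params$sd
  probe <- array(c(mu, mu + 3 * sdv, mu + 10 * sdv, 0, rep(vals, length.out = 4092)),
                 c(16, 16, 16))
  np <- normalizeMR(probe)   # bare-array input: normalized array out
  pv <- np$volume[1:4]
  expect_equal(pv[1], (mu - np$params$mean) / np$params$sd / 3, tolerance = 1e-9)
  expect_lt(abs(pv[1]), 0.05)
  expect_equal(pv[3], 1)
  expect_equal(pv[4], -1)
  expect_true(all(np$volume >= -1 & np$volume <= 1))
  # included-region mean maps to 0 and one included SD to 1/3 (before clip)
  z1 <- ((nm$params$mean + nm$params$sd) - nm$params$mean) / nm$params$sd / 3
  expect_equal(z1, 1 / 3)
})

test_that("degenerate MR inputs are rejected", {
  expect_error(normalizeMR(array(10, c(4, 4, 4))), "fewer than 2")
  expect_error(normalizeMR(array(100, c(4, 4, 4))), "constant")
})

test_that("bias-field correction removes a known smooth field", {
  set.seed(5)
  d <- c(48, 48, 48)
  cx <- array(seq(-1, 1, length.out = 48), d)
  cy <- array(rep(seq(-1, 1, length.out = 48), each = 48), d)
  cz <- array(rep(seq(-1, 1, length.out = 48), each = 48 * 48), d)
  body <- (cx / 0.8)^2 + (cy / 0.7)^2 + (cz / 0.9)^2 <= 1
  bias <- exp(0.18 * (cx + 0.6 * cy * cz - 0.5 * cx^2))
  bias <- bias / mean(bias[body])
  vb <- Volume(array(as.numeric(body), d), spacing = 4, modality = "MASK")
  cv <- function(x) sd(x) / mean(x)

  # flat phantom, no bias: nothing to correct (within 1%)
  flat <- array(0, d); flat[body] <- 300
  cflat <- correctBiasField(Volume(flat, spacing = 4, modality = "MR"), vb)
  expect_lt(max(abs(cflat$volume@values[body] - 300) / 300), 0.01)

  # flat phantom with 20% bias: in-body CV reduced by at least half
  biased <- array(0, d); biased[body] <- 300 * bias[body]
  cb <- correctBiasField(Volume(biased, spacing = 4, modality = "MR"), vb)
  expect_lt(cv(voxelValues(cb$volume)[body]), 0.5 * cv(biased[body]))
  # exterior untouched, mean preserved
  expect_true(all(voxelValues(cb$volume)[!body] == 0))
  expect_equal(mean(voxelValues(cb$volume)[body]), mean(biased[body]),
               tolerance = 1e-9)
  expect_error(correctBiasField(Volume(biased, spacing = 4, modality = "MR"),
                                Volume(array(0, d), modality = "MASK")),
               "empty")
})

test_that("body mask derivation thresholds, keeps one component, fills holes", {
  cs <- generatePairedCase(phantomSpec(seed = 6, shape = c(32, 32, 32),
                                       spacing = c(12, 12, 8)))
  derived <- bodyMaskFromCT(cs@ct)
  truth <- voxelValues(cs@bodyMask)
  dv <- voxelValues(derived)
  dice <- 2 * sum(dv * truth) / (sum(dv) + sum(truth))
  expect_gt(dice, 0.95)
  # gas pockets (below -400 HU) must be filled, not holes
  gas <- cs@truthLabels == 1
  expect_true(all(dv[gas] == 1))
})

test_that("the full preprocessing chain lands in [-1, 1]", {
  cs <- generatePairedCase(phantomSpec(seed = 7, shape = c(32, 32, 32),
                                       spacing = c(12, 12, 8)))
  pp <- preprocessCase(cs)
  expect_true(all(abs(voxelValues(pp$mr)) <= 1))
  expect_true(all(abs(voxelValues(pp$ct)) <= 1))
  out <- voxelValues(cs@bodyMask) == 0
  expect_true(all(voxelValues(pp$mr)[out] == -1))
  expect_true(all(voxelValues(pp$ct)[out] == -1))
  # the recorded N4 reference configuration is complete
  n4 <- defaultN4Params()
  expect_identical(n4$shrinkFactor, 4L)
  expect_identical(n4$maxIterations, c(50L, 40L, 30L))
})
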