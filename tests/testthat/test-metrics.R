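mkVol <- function(a, modality = "CT") Volume(a, modality = modality)

test_that("tissue segmentation follows the -200/200 HU thresholds", {
  d <- c(4, 4, 4)
  hu <- array(0, d)
  hu[1] <- -500; hu[2] <- 0; hu[3] <- 500; hu[4] <- -200; hu[5] <- 200
  ct <- mkVol(hu)
  body <- mkVol(array(1, d), "MASK")
  seg <- segmentTissues(ct, body)
  expect_true(seg$air[1]); expect_true(seg$soft[2]); expect_true(seg$bone[3])
  expect_true(seg$soft[4])   # -200 is soft (inclusive residual class)
  expect_true(seg$soft[5])   # +200 is soft
  # partition of the body ROI
  expect_identical(sum(seg$air) + sum(seg$soft) + sum(seg$bone),
                   as.integer(sum(voxelValues(body))))
  expect_false(any(seg$air & seg$soft) || any(seg$soft & seg$bone) ||
                 any(seg$air & seg$bone))
  expect_error(segmentTissues(ct, mkVol(array(0, d), "MASK")), "empty")
})

test_that("MAE and ME agree with brute-force voxel loops", {
  set.seed(70)
  d <- c(10, 10, 10)
  ct <- mkVol(array(rnorm(1000, 0, 300), d))
  sct <- mkVol(array(voxelValues(ct) + rnorm(1000, 10, 40), d), "SCT")
  roi <- array(runif(1000) < 0.6, d)
  expect_equal(maeHU(sct, ct, roi),
               oracleMAE(voxelValues(sct), voxelValues(ct), roi),
               tolerance = 1e-12)
  expect_equal(meHU(sct, ct, roi),
               oracleME(voxelValues(sct), voxelValues(ct), roi),
               tolerance = 1e-12)
  # constant offsets and the sign convention (synthetic minus reference)
  up <- mkVol(voxelValues(ct) + 50, "SCT")
  expect_equal(maeHU(up, ct, roi), 50)
  expect_equal(meHU(up, ct, roi), 50)
  expect_equal(meHU(mkVol(voxelValues(ct) - 50, "SCT"), ct, roi), -50)
  expect_equal(meHU(sct, ct, roi), -meHU(ct, sct, roi))
  expect_lte(abs(meHU(sct, ct, roi)), maeHU(sct, ct, roi))
  expect_error(maeHU(sct, ct, array(FALSE, d)), "empty")
})

test_that("PSNR uses the global reference maximum and log base 10", {
  set.seed(71)
  d <- c(8, 8, 8)
  ct <- mkVol(array(runif(512, -500, 1500), d))
  roi <- array(TRUE, d)
  sct <- mkVol(voxelValues(ct) + rnorm(512, 0, 30), "SCT")
  expect_equal(psnrHU(sct, ct, roi),
               oraclePSNR(voxelValues(sct), voxelValues(ct), roi),
               tolerance = 1e-12)
  # MSE == MAX^2 gives exactly 0 dB
  maxCT <- max(voxelValues(ct))
  flat <- mkVol(voxelValues(ct) + maxCT, "SCT")
  expect_equal(psnrHU(flat, ct, roi), 0, tolerance = 1e-12)
  # halving the RMS error raises PSNR by 20*log10(2) dB
  e <- rnorm(512, 0, 40)
  p1 <- psnrHU(mkVol(voxelValues(ct) + e, "SCT"), ct, roi)
  p2 <- psnrHU(mkVol(voxelValues(ct) + e / 2, "SCT"), ct, roi)
  expect_equal(p2 - p1, 20 * log10(2), tolerance = 1e-9)
  # identical volumes: unbounded sentinel
  expect_identical(psnrHU(mkVol(voxelValues(ct), "SCT"), ct, roi), Inf)
  # strictly decreasing under a growing noise ladder
  set.seed(72)
  base <- rnorm(512)
  psnrs <- vapply(c(10, 20, 40, 80), function(s)
    psnrHU(mkVol(voxelValues(ct) + base * s, "SCT"), ct, roi), 1.0)
  expect_true(all(diff(psnrs) < 0))
})

test_that("global SSIM matches the closed form", {
  set.seed(73)
  d <- c(8, 8, 8)
  ct <- mkVol(array(runif(512, -1000, 2000), d))
  sct <- mkVol(voxelValues(ct) + rnorm(512, 0, 100), "SCT")
  expect_equal(ssimGlobal(sct, ct),
               oracleSSIM(voxelValues(sct), voxelValues(ct)),
               tolerance = 1e-12)
  expect_equal(ssimGlobal(ct, ct), 1)
  # identical constants are perfectly similar; a full-range offset is not
  a <- mkVol(array(100, d))
  expect_equal(ssimGlobal(a, a), 1)
  b <- mkVol(array(100 + 4095, d), "SCT")
  expect_lt(ssimGlobal(b, a), 0.1)
  expect_true(abs(ssimGlobal(sct, ct)) <= 1)
  # the windowed variant also sits in [-1, 1] and is 1 at identity
  expect_equal(ssimGlobal(ct, ct, windowed = TRUE), 1)
})

test_that("the quality report assembles consistent segment metrics", {
  spec <- phantomSpec(seed = 74, shape = c(32, 32, 32), spacing = c(12, 12, 8))
  cs <- generatePairedCase(spec)
  ct <- cs@ct
  # perfect synthetic copy
  perfect <- Volume(voxelValues(ct), spacing = voxelSpacing(ct),
                    modality = "SCT")
  rp <- evaluateQuality(perfect, ct, cs@bodyMask)
  expect_equal(rp$maeWhole, 0)
  expect_equal(rp$ssim, 1)
  expect_identical(rp$psnr, Inf)
  # +100 HU bias applied to bone only shows up in the bone ME alone
  seg <- segmentTissues(ct, cs@bodyMask)
  biased <- voxelValues(ct)
  biased[seg$bone] <- biased[seg$bone] + 100
  rb <- evaluateQuality(Volume(biased, modality = "SCT"), ct, cs@bodyMask)
  expect_equal(rb$meBone, 100)
  expect_equal(rb$meSoft, 0)
  expect_equal(rb$maeBone, 100)
  # segment counts partition the body
  expect_identical(rb$nVoxels[["air"]] + rb$nVoxels[["soft"]] +
                     rb$nVoxels[["bone"]], rb$nVoxels[["body"]])
  # whole-body MAE is the voxel-count-weighted mean of segment MAEs
  set.seed(74)
  noisy <- voxelValues(ct) + rnorm(length(biased), 0, 60)
  rn <- evaluateQuality(Volume(noisy, modality = "SCT"), ct, cs@bodyMask)
  w <- c(rn$nVoxels[["air"]], rn$nVoxels[["soft"]], rn$nVoxels[["bone"]])
  parts <- c(rn$maeAir, rn$maeSoft, rn$maeBone)
  expect_equal(rn$maeWhole, sum(w * parts) / sum(w), tolerance = 1e-12)
  expect_output(print(rn), "Image-quality report")
})
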