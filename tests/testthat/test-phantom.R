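test_that("phantom generation is deterministic for a fixed seed", {
  s <- phantomSpec(seed = 5, shape = c(32, 32, 32), spacing = c(12, 12, 8))
  a <- generatePairedCase(s)
  b <- generatePairedCase(s)
  expect_identical(voxelValues(a@mr), voxelValues(b@mr))
  expect_identical(voxelValues(a@ct), voxelValues(b@ct))
  expect_identical(a@truthLabels, b@truthLabels)
  c2 <- generatePairedCase(phantomSpec(seed = 6, shape = c(32, 32, 32),
                                       spacing = c(12, 12, 8)))
  expect_false(identical(voxelValues(a@mr), voxelValues(c2@mr)))
})

test_that("phantom volumes respect the modality conventions", {
  for (seed in c(1, 17)) {
    cs <- generatePairedCase(phantomSpec(seed = seed, shape = c(40, 40, 40),
                                         spacing = c(8, 8, 6)))
    ct <- voxelValues(cs@ct); mr <- voxelValues(cs@mr)
    body <- voxelValues(cs@bodyMask)
    expect_true(all(ct >= -1000 & ct <= 3095))
    expect_true(all(mr >= 0))
    expect_true(all(body %in% c(0, 1)))
    expect_true(all(ct[body == 0] == -1000))
    expect_true(all(mr[body == 0] == 0))
    for (st in cs@structures) {
      expect_true(all(voxelValues(st) %in% c(0, 1)))
      expect_true(all(voxelValues(st) <= body))
    }
  }
})

test_that("gas pockets and tissue-class contrast are constructed correctly", {
  cs <- generatePairedCase(phantomSpec(seed = 2, shape = c(40, 40, 40),
                                       spacing = c(8, 8, 6)))
  ct <- voxelValues(cs@ct); mr <- voxelValues(cs@mr)
  body <- voxelValues(cs@bodyMask); tl <- cs@truthLabels
  # gas pocket: in-body voxels below the air threshold
  expect_true(any(ct[body == 1] < -200))
  # truth bone: CT median above the bone threshold, MR darker than soft tissue
  expect_gt(median(ct[tl == 6]), 200)
  expect_lt(median(mr[tl == 6]), median(mr[tl == 3]))
  # no-gas spec removes sub -200 HU voxels except noise tails
  cs2 <- generatePairedCase(phantomSpec(seed = 2, shape = c(40, 40, 40),
                                        spacing = c(8, 8, 6),
                                        gasPocket = FALSE))
  expect_false(any(cs2@truthLabels == 1))
})

test_that("threshold segmentation recovers the truth bone class", {
  # class separability: >= 90% of truth bone voxels are recovered by the
  # -200/200 HU segmentation on a low-noise phantom
  cs <- generatePairedCase(phantomSpec(seed = 8, shape = c(40, 40, 40),
                                       spacing = c(8, 8, 6), noiseSdCT = 30))
  seg <- segmentTissues(cs@ct, cs@bodyMask)
  bone <- cs@truthLabels == 6
  expect_gte(sum(seg$bone & bone) / sum(bone), 0.90)
})

test_that("a class-mean lookup reproduces the CT up to noise and smoothing", {
  # guarantees a learnable MR -> CT mapping exists
  spec <- phantomSpec(seed = 4, shape = c(40, 40, 40), spacing = c(8, 8, 6))
  cs <- generatePairedCase(spec)
  lookup <- array(spec$classCTMeans[match(cs@truthLabels,
                                          synthCT:::PHANTOM_CLASSES)],
                  dim(cs@truthLabels))
  body <- voxelValues(cs@bodyMask) == 1
  mae <- mean(abs(lookup[body] - voxelValues(cs@ct)[body]))
  expect_lt(mae, 2 * spec$noiseSdCT)
})

test_that("the analytic dose is anchored at the PTV and falls off monotonically", {
  cs <- generatePairedCase(phantomSpec(seed = 3, shape = c(40, 40, 40),
                                       spacing = c(8, 8, 6)))
  dose <- generateDose(cs, prescription = 36.25)
  dv <- voxelValues(dose)
  expect_equal(max(dv), 36.25, tolerance = 1e-12)
  cIdx <- which(dv == max(dv), arr.ind = TRUE)[1, ]
  # non-increasing along the +x, -x, +y, +z rays from the centroid voxel
  expect_true(all(diff(dv[cIdx[1]:dim(dv)[1], cIdx[2], cIdx[3]]) <= 0))
  expect_true(all(diff(dv[cIdx[1]:1, cIdx[2], cIdx[3]]) <= 0))
  expect_true(all(diff(dv[cIdx[1], cIdx[2]:dim(dv)[2], cIdx[3]]) <= 0))
  expect_true(all(diff(dv[cIdx[1], cIdx[2], cIdx[3]:dim(dv)[3]]) <= 0))
  # D95% of the PTV equals the sorted-percentile oracle
  ptv <- voxelValues(cs@structures$PTV) == 1
  d95 <- dvhMetric(computeDVH(dose, ptv), 95)
  expect_equal(d95, oracleDx(dv[ptv], 95), tolerance = 1e-12)
  expect_error(generateDose(PairedCase(cs@mr, cs@ct, cs@bodyMask,
                                       structures = list())), "PTV")
})

test_that("dose perturbation scales and shifts exactly", {
  cs <- generatePairedCase(phantomSpec(seed = 3, shape = c(32, 32, 32),
                                       spacing = c(12, 12, 8)))
  dose <- generateDose(cs)
  dv <- voxelValues(dose)
  expect_identical(voxelValues(perturbDose(dose)), dv)
  expect_equal(voxelValues(perturbDose(dose, scale = 1.03)), dv * 1.03,
               tolerance = 1e-15)
  sh <- perturbDose(dose, shiftMM = c(12, 0, 0))
  expect_equal(voxelValues(sh)[2:32, , ], dv[1:31, , ], tolerance = 1e-15)
  expect_error(perturbDose(dose, shiftMM = c(5, 0, 0)), "multiple")
  expect_silent(perturbDose(dose, shiftMM = c(5, 0, 0), interpolate = TRUE))
})

test_that("too-small phantom shapes are rejected", {
  expect_error(phantomSpec(shape = c(16, 64, 64)), "too small")
})
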