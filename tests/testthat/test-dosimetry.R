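test_that("the cumulative DVH is the exact survival curve of voxel doses", {
  d <- c(6, 6, 6)
  m <- array(FALSE, d); m[2:5, 2:5, 2:5] <- TRUE
  # uniform dose: step function dropping from 1 to 0 at the dose level
  uni <- Volume(array(20, d), modality = "DOSE")
  cv <- computeDVH(uni, m)
  expect_equal(cv@cumulativeFraction[cv@doseAxis <= 20], rep(1, 2))
  expect_equal(cv@cumulativeFraction[cv@doseAxis > 20], 0)
  set.seed(80)
  dose <- Volume(array(rgamma(216, 3, 0.2), d), modality = "DOSE")
  curve <- computeDVH(dose, m)
  expect_true(all(diff(curve@cumulativeFraction) <= 1e-12))
  dv <- voxelValues(dose)[m]
  # counting oracle at arbitrary probe doses
  for (t in c(0, 5, 12.3, max(dv))) {
    i <- max(which(curve@doseAxis <= t))
    expect_equal(curve@cumulativeFraction[i] * curve@voxelCount,
                 sum(dv >= curve@doseAxis[i]))
  }
  expect_error(computeDVH(dose, array(FALSE, d)), "empty")
})

test_that("Dx% metrics interpolate order statistics correctly", {
  d <- c(10, 10, 10)
  m <- array(TRUE, d)
  uni <- Volume(array(15, d), modality = "DOSE")
  cu <- computeDVH(uni, m)
  expect_equal(dvhMetric(cu, 95), 15)
  expect_equal(dvhMetric(cu, 2), 15)
  ramp <- Volume(array(seq(0, 100, length.out = 1000), d), modality = "DOSE")
  cr <- computeDVH(ramp, m)
  expect_equal(dvhMetric(cr, 95), 5, tolerance = 1e-9)
  expect_equal(dvhMetric(cr, 2), 98, tolerance = 1e-9)
  expect_equal(dvhMetric(cr, "D95%"), dvhMetric(cr, 95))
  set.seed(81)
  rnd <- Volume(array(runif(1000, 0, 40), d), modality = "DOSE")
  crn <- computeDVH(rnd, m)
  expect_gte(dvhMetric(crn, 2), dvhMetric(crn, 95))
  expect_equal(dvhMetric(crn, 95), oracleDx(voxelValues(rnd)[m], 95),
               tolerance = 1e-12)
  # scaling the dose scales every Dx% linearly
  sc <- computeDVH(Volume(voxelValues(rnd) * 1.7, modality = "DOSE"), m)
  for (x in c(95, 50, 2))
    expect_equal(dvhMetric(sc, x), 1.7 * dvhMetric(crn, x), tolerance = 1e-9)
  expect_error(dvhMetric(crn, 0), "between")
  expect_error(dvhMetric(crn, 100), "between")
})

test_that("dose-difference tables report Gy and percent-of-prescription", {
  ref <- c("PTV D95%" = 36.11, "PTV D2%" = 40.83, "Rectum D2%" = 35.53)
  same <- doseDifferenceReport(ref, ref)
  expect_true(all(same$diffGy == 0) && all(same$diffPct == 0))
  ev <- ref + 0.2
  r <- doseDifferenceReport(ref, ev, prescription = 36.25)
  expect_equal(r$diffGy, rep(0.2, 3), tolerance = 1e-12)
  expect_equal(r$diffPct, rep(100 * 0.2 / 36.25, 3), tolerance = 1e-12)
  expect_equal(r$diffPct[1], 0.55, tolerance = 0.01)
  # antisymmetry under swapping the roles
  r2 <- doseDifferenceReport(ev, ref)
  expect_equal(r2$diffGy, -r$diffGy)
  expect_error(doseDifferenceReport(ref, c(a = 1)), "mismatch")
})

test_that("gamma analysis satisfies its analytic anchor cases", {
  d <- array(10, c(8, 8, 8))
  ref <- Volume(d, spacing = c(2, 2, 2), modality = "DOSE")
  expect_equal(as.numeric(gammaPassRate(ref, ref, gammaCriteria(1, 1))), 100)
  # uniform 5%-of-max offset with zero gradient cannot pass 2%/2mm anywhere
  ev <- Volume(d * 1.05, spacing = c(2, 2, 2), modality = "DOSE")
  expect_equal(as.numeric(gammaPassRate(ref, ev, gammaCriteria(2, 2))), 0)
  # a 1.5% offset passes the 2% dose criterion everywhere
  expect_equal(as.numeric(gammaPassRate(
    ref, Volume(d * 1.015, spacing = 2, modality = "DOSE"),
    gammaCriteria(2, 2))), 100)
  expect_error(gammaPassRate(Volume(d * 0, spacing = 2, modality = "DOSE"),
                             ref, gammaCriteria(1, 1)), "all-zero")
})

test_that("gamma pass rates match the exhaustive brute-force search", {
  set.seed(82)
  d <- c(8, 8, 8)
  base <- array(0, d)
  cx <- array(seq(-1, 1, length.out = 8), d)
  cy <- array(rep(seq(-1, 1, length.out = 8), each = 8), d)
  cz <- array(rep(seq(-1, 1, length.out = 8), each = 64), d)
  base <- 30 * exp(-(cx^2 + cy^2 + cz^2) / 0.5)
  ref <- Volume(base, spacing = c(1, 1, 1), modality = "DOSE")
  ev <- Volume(base * (1 + rnorm(512, 0, 0.015)), spacing = c(1, 1, 1),
               modality = "DOSE")
  for (crit in list(gammaCriteria(1, 1), gammaCriteria(2, 2))) {
    got <- as.numeric(gammaPassRate(ref, ev, crit))
    want <- oracleGammaPassRate(ref, ev, crit$dosePercent, crit$dtaMM)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("gamma pass rates are monotone in the dose/DTA criteria", {
  # looser criteria can never fail a voxel that tighter criteria pass
  set.seed(83)
  cs <- generatePairedCase(phantomSpec(seed = 83, shape = c(32, 32, 32),
                                       spacing = c(12, 12, 8)))
  dose <- generateDose(cs)
  for (i in 1:20) {
    pert <- perturbDose(dose, scale = 1 + rnorm(1, 0, 0.02),
                        shiftMM = round(rnorm(3)) * voxelSpacing(dose),
                        interpolate = FALSE)
    p11 <- as.numeric(gammaPassRate(dose, pert, gammaCriteria(1, 1)))
    p22 <- as.numeric(gammaPassRate(dose, pert, gammaCriteria(2, 2)))
    expect_gte(p22, p11)
  }
  # near-identity perturbation approaches a 100% pass rate
  tiny <- perturbDose(dose, scale = 1.001)
  expect_equal(as.numeric(gammaPassRate(dose, tiny, gammaCriteria(1, 1))), 100)
})
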