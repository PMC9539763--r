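# Independent brute-force oracles; deliberately written as plain loops /
# direct definitions, sharing no code with the package implementations.

oracleMAE <- function(a, b, roi) {
  s <- 0; n <- 0
  for (i in which(roi)) { s <- s + abs(a[i] - b[i]); n <- n + 1 }
  s / n
}

oracleME <- function(a, b, roi) {
  s <- 0; n <- 0
  for (i in which(roi)) { s <- s + (a[i] - b[i]); n <- n + 1 }
  s / n
}

oraclePSNR <- function(sct, ct, roi) {
  s <- 0; n <- 0
  for (i in which(roi)) { s <- s + (sct[i] - ct[i])^2; n <- n + 1 }
  mse <- s / n
  10 * log10(max(ct)^2 / mse)
}

oracleSSIM <- function(x, y, L = 4095) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

# greatest dose received by at least x% of the volume, linear interpolation
# between order statistics (hand-coded type-7 percentile)
oracleDx <- function(doses, x) {
  d <- sort(doses)
  n <- length(d)
  p <- 1 - x / 100
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(d[n])
  d[lo] + (h - lo) * (d[lo + 1] - d[lo])
}

# joint-histogram nMI computed with an explicit bin double-loop
oracleNMI <- function(a, b, bins = 64) {
  edges <- seq(-1, 1, length.out = bins + 1)
  n <- length(a)
  av <- pmin(pmax(as.vector(a), -1), 1)
  bv <- pmin(pmax(as.vector(b), -1), 1)
  J <- matrix(0, bins, bins)
  for (i in seq_len(bins)) {
    inA <- if (i < bins) av >= edges[i] & av < edges[i + 1] else
      av >= edges[i] & av <= edges[i + 1]
    for (j in seq_len(bins)) {
      inB <- if (j < bins) bv >= edges[j] & bv < edges[j + 1] else
        bv >= edges[j] & bv <= edges[j + 1]
      J[i, j] <- sum(inA & inB)
    }
  }
  J <- J / n
  pa <- rowSums(J); pb <- colSums(J)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  if (H(pa) == 0 || H(pb) == 0) return(if (all(av == bv)) 1 else 0)
  mi <- 0
  for (i in seq_len(bins)) for (j in seq_len(bins))
    if (J[i, j] > 0) mi <- mi + J[i, j] * log(J[i, j] / (pa[i] * pb[j]))
  mi / sqrt(H(pa) * H(pb))
}

# exhaustive gamma search: every ROI voxel, every lattice offset within the
# search sphere, trilinear interpolation, no early exit
oracleGammaPassRate <- function(refVol, evVol, dosePercent, dtaMM,
                                threshold = 0.1, radiusFactor = 2,
                                stepFrac = 0.1) {
  ref <- voxelValues(refVol); ev <- voxelValues(evVol)
  sp <- voxelSpacing(refVol)
  d <- dim(ref)
  maxRef <- max(ref)
  deltaD <- dosePercent / 100 * maxRef
  step <- stepFrac * dtaMM
  r <- radiusFactor * dtaMM
  n0 <- floor(r / step)
  offs <- expand.grid(dx = (-n0:n0) * step, dy = (-n0:n0) * step,
                      dz = (-n0:n0) * step)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= r^2 + 1e-12, ]
  r2 <- offs$dx^2 + offs$dy^2 + offs$dz^2
  interpMany <- function(ci, cj, ck) {
    ok <- ci >= 0 & cj >= 0 & ck >= 0 &
      ci <= d[1] - 1 & cj <= d[2] - 1 & ck <= d[3] - 1
    out <- rep(NA_real_, length(ci))
    if (!any(ok)) return(out)
    i0 <- pmin(floor(ci[ok]), d[1] - 2); i0 <- pmax(i0, 0)
    j0 <- pmin(floor(cj[ok]), d[2] - 2); j0 <- pmax(j0, 0)
    k0 <- pmin(floor(ck[ok]), d[3] - 2); k0 <- pmax(k0, 0)
    fx <- ci[ok] - i0; fy <- cj[ok] - j0; fz <- ck[ok] - k0
    at <- function(ii, jj, kk) ref0[cbind(ii + 1, jj + 1, kk + 1)]
    ref0 <- ev
    out[ok] <-
      at(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
      at(i0 + 1, j0, k0) * fx * (1 - fy) * (1 - fz) +
      at(i0, j0 + 1, k0) * (1 - fx) * fy * (1 - fz) +
      at(i0 + 1, j0 + 1, k0) * fx * fy * (1 - fz) +
      at(i0, j0, k0 + 1) * (1 - fx) * (1 - fy) * fz +
      at(i0 + 1, j0, k0 + 1) * fx * (1 - fy) * fz +
      at(i0, j0 + 1, k0 + 1) * (1 - fx) * fy * fz +
      at(i0 + 1, j0 + 1, k0 + 1) * fx * fy * fz
    out
  }
  passed <- 0L; evaluated <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    rv <- ref[i, j, k]
    if (rv <= threshold * maxRef) next
    evaluated <- evaluated + 1L
    vals <- interpMany(i - 1 + offs$dx / sp[1], j - 1 + offs$dy / sp[2],
                       k - 1 + offs$dz / sp[3])
    g2 <- ((vals - rv) / deltaD)^2 + r2 / dtaMM^2
    if (any(g2 <= 1, na.rm = TRUE)) passed <- passed + 1L
  }
  100 * passed / evaluated
}

# direct 1D linear interpolation of a ramp, for the resampling oracle
oracleLinear1D <- function(values, srcIdx) {
  n <- length(values)
  vapply(srcIdx, function(ci) {
    if (ci <= 0) return(values[1])
    if (ci >= n - 1) return(values[n])
    lo <- floor(ci)
    f <- ci - lo
    values[lo + 1] * (1 - f) + values[lo + 2] * f
  }, 1.0)
}

# small seeded paired phantom preprocessed for training tests
makeTrainingCases <- function(seeds, shape = c(32, 32, 32),
                              spacing = c(12, 12, 8)) {
  lapply(seeds, function(s)
    preprocessCase(generatePairedCase(phantomSpec(seed = s, shape = shape,
                                                  spacing = spacing))))
}

tinyGenSpec <- function() generatorSpec(depth = 3, baseChannels = 8)
tinyDiscSpec <- function() discriminatorSpec(downsampleFactor = 8,
                                             baseChannels = 8)
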