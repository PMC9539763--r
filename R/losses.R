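#' Loss weights of the composite generator objective
#'
#' The total generator objective is
#' `L_T = L_cGAN + lambda1 * L_L1 + lambda2 * L_MI`
#' with defaults lambda1 = 100 on the voxelwise L1 reconstruction term and
#' lambda2 = 5 on the normalized-mutual-information term.
#'
#' @param lambda1 weight on the L1 term (>= 0).
#' @param lambda2 weight on the nMI term (>= 0).
#' @return A list of class `"LossWeights"`.
#' @export
lossWeights <- function(lambda1 = 100, lambda2 = 5) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2), class = "LossWeights")
}

#' Mean-absolute-error reconstruction loss
#'
#' Mean over all voxels of `|y - g|` between a real CT plane and a generated
#' synthetic CT plane (both normalized to [-1, 1] during training).
#'
#' @param y real plane (any numeric array).
#' @param g generated plane of the same shape.
#' @param gradient also return `d loss / d g`.
#' @return The scalar loss, or a list `(loss, grad)` when `gradient = TRUE`.
#' @export
l1Loss <- function(y, g, gradient = FALSE) {
  if (!identical(dim(y), dim(g)) || length(y) != length(g))
    stop("shape mismatch")
  loss <- mean(abs(y - g))
  if (!gradient) return(loss)
  list(loss = loss, grad = array(sign(g - y) / length(g), dim(g)))
}

#' Normalized mutual information between two planes
#'
#' Builds a joint hard histogram over `bins x bins` equal-width bins on
#' [-1, 1] and returns `I(a, b) / sqrt(H(a) * H(b))`, which is 1 for
#' identical images and tends to 0 for independent ones (entropies in nats;
#' the ratio is base-invariant). If either marginal entropy is zero
#' (constant image) the value is 1 when the two planes are identical and 0
#' otherwise.
#'
#' @param a,b numeric planes in [-1, 1], same length.
#' @param bins number of histogram bins per axis (default 64).
#' @return nMI in [0, 1].
#' @export
normalizedMutualInformation <- function(a, b, bins = 64L) {
  if (length(a) == 0L) stop("empty input")
  if (length(a) != length(b)) stop("shape mismatch")
  ia <- binIndex(a, bins)
  ib <- binIndex(b, bins)
  joint <- matrix(0, bins, bins)
  tab <- table(factor(ia, levels = seq_len(bins)),
               factor(ib, levels = seq_len(bins)))
  joint <- matrix(as.numeric(tab), bins, bins) / length(a)
  pa <- rowSums(joint); pb <- colSums(joint)
  ha <- entropyNats(pa); hb <- entropyNats(pb)
  if (ha == 0 || hb == 0) return(if (isTRUE(all(a == b))) 1 else 0)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] /
                              (outer(pa, pb)[nz])))
  max(0, min(1, mi / sqrt(ha * hb)))
}

binIndex <- function(x, bins) {
  x <- pmin(pmax(x, -1), 1)
  pmin(floor((x + 1) / 2 * bins) + 1L, bins)
}

entropyNats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mutual-information loss
#'
#' `1 - nMI(y, g)`: zero when the generated plane is a deterministic
#' one-to-one match of the real plane, approaching 1 for statistically
#' independent planes. For a batch (list of plane pairs) the mean per-plane
#' loss is returned.
#'
#' @param y,g planes in [-1, 1], or lists of planes of equal length.
#' @param bins histogram bins.
#' @return Scalar loss in [0, 1].
#' @export
miLoss <- function(y, g, bins = 64L) {
  if (is.list(y)) {
    stopifnot(is.list(g), length(y) == length(g))
    return(mean(mapply(function(yi, gi) miLoss(yi, gi, bins), y, g)))
  }
  1 - normalizedMutualInformation(y, g, bins)
}

# Soft (triangular-kernel) joint histogram nMI with an analytic gradient in
# the second argument; used for gradient flow during training while the hard
# histogram above remains the reference value.
softMILossGrad <- function(y, g, bins = 64L, eps = 1e-12) {
  n <- length(g)
  h <- 2 / bins
  centers <- seq(-1 + h / 2, 1 - h / 2, length.out = bins)
  assign2 <- function(x) {
    x <- pmin(pmax(x, -1 + h / 2 + 1e-9), 1 - h / 2 - 1e-9)
    lo <- pmin(pmax(floor((x - centers[1]) / h) + 1L, 1L), bins - 1L)
    t <- (x - centers[lo]) / h
    list(lo = lo, w0 = 1 - t, w1 = t)
  }
  A <- assign2(as.vector(y))
  B <- assign2(as.vector(g))
  joint <- matrix(0, bins, bins)
  for (da in 0:1) for (db in 0:1) {
    wa <- if (da == 0) A$w0 else A$w1
    wb <- if (db == 0) B$w0 else B$w1
    idx <- cbind(A$lo + da, B$lo + db)
    contrib <- wa * wb
    agg <- rowsum(contrib, group = (idx[, 1] - 1L) * bins + idx[, 2])
    lin <- as.integer(rownames(agg))
    joint[cbind((lin - 1L) %/% bins + 1L, (lin - 1L) %% bins + 1L)] <-
      joint[cbind((lin - 1L) %/% bins + 1L, (lin - 1L) %% bins + 1L)] +
      agg[, 1]
  }
  joint <- joint / n
  pa <- rowSums(joint); pb <- colSums(joint)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha < 1e-9 || hb < 1e-9)
    return(list(loss = if (isTRUE(all(y == g))) 0 else 1,
                grad = array(0, dim(g))))
  lj <- log(pmax(joint, eps))
  lpa <- log(pmax(pa, eps)); lpb <- log(pmax(pb, eps))
  mi <- sum(joint * (lj - outer(lpa, rep(1, bins)) -
                       outer(rep(1, bins), lpb)))
  S <- sqrt(ha * hb)
  nmi <- mi / S
  # d nMI / d p_cd
  dI <- lj - outer(lpa, rep(1, bins)) - outer(rep(1, bins), lpb) - 1
  dHa <- -(lpa + 1)   # per row
  dHb <- -(lpb + 1)   # per col
  dS <- (outer(dHa, rep(1, bins)) * hb + outer(rep(1, bins), dHb) * ha) /
    (2 * S)
  M <- (dI * S - mi * dS) / S^2
  # chain to g_i: loss = 1 - nMI, dw/dg of the two touched bins is -1/h, +1/h
  rows0 <- A$lo; rows1 <- A$lo + 1L
  cols0 <- B$lo; cols1 <- B$lo + 1L
  dmi <- (A$w0 * (M[cbind(rows0, cols1)] - M[cbind(rows0, cols0)]) +
            A$w1 * (M[cbind(rows1, cols1)] - M[cbind(rows1, cols0)])) / (h * n)
  grad <- array(-dmi, dim(g))   # loss = 1 - nMI
  list(loss = 1 - nmi, grad = grad)
}

#' Least-squares discriminator loss
#'
#' Standard least-squares adversarial convention: real patches target 1,
#' fake (generated) patches target 0, averaged over the score map so the
#' value does not depend on the patch count:
#' `mean((realScores - 1)^2) + mean(fakeScores^2)`.
#'
#' @param realScores,fakeScores 2D patch score maps.
#' @param gradient also return gradients w.r.t. both maps.
#' @return Scalar loss, or list `(loss, gradReal, gradFake)`.
#' @export
discriminatorLoss <- function(realScores, fakeScores, gradient = FALSE) {
  loss <- mean((realScores - 1)^2) + mean(fakeScores^2)
  if (!gradient) return(loss)
  list(loss = loss,
       gradReal = 2 * (realScores - 1) / length(realScores),
       gradFake = 2 * fakeScores / length(fakeScores))
}

#' Generator adversarial loss
#'
#' The generator is rewarded when the discriminator scores its output as
#' real: `mean((fakeScores - 1)^2)`.
#'
#' @param fakeScores 2D patch score map of a generated pair.
#' @param gradient also return the gradient w.r.t. the map.
#' @return Scalar loss, or list `(loss, grad)`.
#' @export
generatorAdversarialLoss <- function(fakeScores, gradient = FALSE) {
  loss <- mean((fakeScores - 1)^2)
  if (!gradient) return(loss)
  list(loss = loss, grad = 2 * (fakeScores - 1) / length(fakeScores))
}

#' Total generator objective
#'
#' `adv + lambda1 * l1 + lambda2 * mi` with the configured [lossWeights()].
#'
#' @param adv adversarial component.
#' @param l1 L1 component.
#' @param mi mutual-information component.
#' @param w a [lossWeights()].
#' @return Scalar total loss.
#' @examples
#' totalGeneratorLoss(0.2, 0.01, 0.1, lossWeights())  # 1.7
#' @export
totalGeneratorLoss <- function(adv, l1, mi, w = lossWeights()) {
  stopifnot(inherits(w, "LossWeights"))
  adv + w$lambda1 * l1 + w$lambda2 * mi
}
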