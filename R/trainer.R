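#' Training configuration
#'
#' Houses the optimization schedule of the translation network: Adam with an
#' initial learning rate of 2e-4 for the generator and 5e-5 for the
#' discriminator, momentum parameters (0.5, 0.999), learning rates decayed
#' multiplicatively by 1% per epoch, 100 epochs at full scale, and a
#' history buffer feeding the discriminator with previously generated
#' planes.
#'
#' @param epochs number of epochs (default 100).
#' @param lrG,lrD initial learning rates.
#' @param momentumParams Adam (beta1, beta2).
#' @param decayPerEpoch fractional multiplicative decay per epoch in [0, 1).
#' @param bufferSize history-buffer capacity (default 50).
#' @param swapProbability probability of answering from the buffer once
#'   full (default 0.5).
#' @param seed RNG seed; the whole training run is a pure function of it.
#' @param weights a [lossWeights()].
#' @param miBins histogram bins of the mutual-information term.
#' @return A list of class `"TrainConfig"`.
#' @export
trainConfig <- function(epochs = 100L, lrG = 2e-4, lrD = 5e-5,
                        momentumParams = c(0.5, 0.999),
                        decayPerEpoch = 0.01, bufferSize = 50L,
                        swapProbability = 0.5, seed = 1L,
                        weights = lossWeights(), miBins = 64L) {
  stopifnot(lrG > 0, lrD > 0, decayPerEpoch >= 0, decayPerEpoch < 1,
            epochs >= 1, bufferSize >= 1,
            swapProbability >= 0, swapProbability <= 1)
  structure(list(epochs = as.integer(epochs), lrG = lrG, lrD = lrD,
                 momentumParams = momentumParams,
                 decayPerEpoch = decayPerEpoch,
                 bufferSize = as.integer(bufferSize),
                 swapProbability = swapProbability,
                 seed = as.integer(seed), weights = weights,
                 miBins = as.integer(miBins),
                 n4Reference = defaultN4Params()),
            class = "TrainConfig")
}

#' Learning rate at a given epoch
#'
#' Multiplicative 1%-per-epoch decay: `initial * (1 - decay)^epoch`. (A
#' linear reading of "decreased by 1% per epoch" would reach zero at epoch
#' 100 and go negative after; the multiplicative schedule never does.)
#'
#' @param initial initial learning rate (epoch 0).
#' @param epoch 0-based epoch index.
#' @param decay per-epoch fractional decay.
#' @return The decayed learning rate.
#' @examples
#' lrAtEpoch(2e-4, 1)  # 0.000198
#' @export
lrAtEpoch <- function(initial, epoch, decay = 0.01) {
  stopifnot(epoch >= 0)
  initial * (1 - decay)^epoch
}

#' Per-epoch slice bookkeeping
#'
#' One epoch visits each case `slicesPerVolume` times; a batch draws one
#' unused slice per orientation per case, so no slice index repeats within
#' an epoch for a given case and orientation. The iteration cap is
#' `slicesPerVolume * nCases`.
#'
#' @param cases list of preprocessed cases (for their grid dimensions).
#' @return An environment-backed plan with the unused-slice sets.
#' @export
epochPlan <- function(cases) {
  stopifnot(length(cases) >= 1)
  plan <- new.env(parent = emptyenv())
  plan$unused <- lapply(cases, function(cs) {
    d <- dim(cs$mr@values)
    list(sagittal = seq_len(d[1]), coronal = seq_len(d[2]),
         axial = seq_len(d[3]))
  })
  plan$slicesPerVolume <- dim(cases[[1]]$mr@values)[3]
  plan$maxIterations <- plan$slicesPerVolume * length(cases)
  plan
}

#' Draw one multi-planar batch
#'
#' Draws exactly one axial, one sagittal and one coronal MR/CT plane pair
#' from the case's unused slice indices (uniformly), marks them used, and
#' returns either the three pairs or a skip marker when any extracted plane
#' contains no anatomy (the drawn indices stay consumed either way).
#'
#' @param case preprocessed case: list with `mr`, `ct` volumes in [-1, 1].
#' @param caseIdx index of the case in the plan.
#' @param plan an [epochPlan()].
#' @return List of class `"PlaneBatch"` with `planes` (3 pairs) and
#'   `skip` (logical).
#' @export
sampleMultiplanarBatch <- function(case, caseIdx, plan) {
  unused <- plan$unused[[caseIdx]]
  if (any(vapply(unused, length, 1L) == 0L))
    stop("epoch plan exhausted for this case")
  planes <- list()
  skip <- FALSE
  for (ori in ORIENTATIONS) {
    pool <- unused[[ori]]
    i <- if (length(pool) == 1L) pool else pool[sample.int(length(pool), 1L)]
    unused[[ori]] <- setdiff(pool, i)
    mrP <- extractPlane(case$mr@values, ori, i)
    ctP <- extractPlane(case$ct@values, ori, i)
    if (isEmptyPlane(mrP, "MR") || isEmptyPlane(ctP, "CT")) skip <- TRUE
    planes[[ori]] <- list(mr = mrP, ct = ctP, orientation = ori, index = i)
  }
  plan$unused[[caseIdx]] <- unused
  structure(list(planes = planes, skip = skip), class = "PlaneBatch")
}

#' Does a normalized plane contain any anatomy?
#'
#' After preprocessing, the background value is -1 for both modalities
#' (exterior CT is -1000 HU -> -1; exterior MR is 0, far below the air
#' threshold -> -1). A plane is empty iff every voxel equals -1.
#'
#' @param p 2D plane in [-1, 1].
#' @param modality `"MR"` or `"CT"` (both share the -1 background).
#' @return TRUE iff the plane is pure background.
#' @export
isEmptyPlane <- function(p, modality = c("MR", "CT")) {
  modality <- match.arg(modality)
  all(p == -1)
}

#' History buffer for discriminator updates
#'
#' Stores up to `capacity` previously generated planes. While below
#' capacity a fresh plane is stored and returned as-is; once full, with
#' probability `swapProbability` a stored plane is returned and replaced by
#' the fresh one, otherwise the fresh plane passes through.
#'
#' @param capacity pool size.
#' @param swapProbability swap probability once full.
#' @return An environment-backed buffer for [bufferDraw()].
#' @export
historyBuffer <- function(capacity = 50L, swapProbability = 0.5) {
  b <- new.env(parent = emptyenv())
  b$capacity <- as.integer(capacity)
  b$swapProbability <- swapProbability
  b$pool <- list()
  b
}

#' @rdname historyBuffer
#' @param b the buffer.
#' @param fresh newly generated plane.
#' @export
bufferDraw <- function(b, fresh) {
  if (length(b$pool) < b$capacity) {
    b$pool[[length(b$pool) + 1L]] <- fresh
    return(fresh)
  }
  if (stats::runif(1) <= b$swapProbability) {
    i <- sample.int(length(b$pool), 1L)
    out <- b$pool[[i]]
    b$pool[[i]] <- fresh
    out
  } else {
    fresh
  }
}

#' Train the MR to CT translator
#'
#' The full adversarial training loop: per iteration one multi-planar batch
#' (axial + sagittal + coronal plane pairs of one case) is drawn from the
#' epoch plan; empty batches are disregarded (their slice indices stay
#' consumed and no optimizer step is taken). For kept batches the generator
#' is updated with the composite objective (least-squares adversarial + L1 +
#' nMI, soft-histogram gradient) and the discriminator with the
#' least-squares real/fake loss, its fake planes routed through the history
#' buffer. One generator and one discriminator Adam step per batch;
#' learning rates decay 1% per epoch. Deterministic for a fixed
#' `config$seed`.
#'
#' @param cases list of preprocessed cases ([preprocessCase()] outputs) with
#'   all values in [-1, 1].
#' @param config a [trainConfig()].
#' @param genSpec,discSpec architecture specs.
#' @param verbose print one line per epoch.
#' @return A list with `generator` (trained), `history` (data.frame per
#'   epoch: lrG, lrD, meanL1, meanAdv, meanMI, meanD, iterations, skipped).
#' @export
trainTranslator <- function(cases, config = trainConfig(),
                            genSpec = generatorSpec(),
                            discSpec = discriminatorSpec(),
                            verbose = FALSE) {
  stopifnot(length(cases) >= 1)
  for (cs in cases) {
    rng <- range(cs$mr@values, cs$ct@values)
    if (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9)
      stop("cases must be preprocessed to [-1, 1] before training")
  }
  withSeed(config$seed, trainLoop(cases, config, genSpec, discSpec, verbose))
}

trainLoop <- function(cases, config, genSpec, discSpec, verbose) {
  gen <- buildGenerator(genSpec)
  disc <- buildDiscriminator(discSpec)
  adamG <- adamInit(gen$params)
  adamD <- adamInit(disc$params)
  buffer <- historyBuffer(config$bufferSize, config$swapProbability)
  b1 <- config$momentumParams[1]; b2 <- config$momentumParams[2]
  w <- config$weights
  hist <- data.frame()

  for (epoch in seq_len(config$epochs) - 1L) {
    lrG <- lrAtEpoch(config$lrG, epoch, config$decayPerEpoch)
    lrD <- lrAtEpoch(config$lrD, epoch, config$decayPerEpoch)
    plan <- epochPlan(cases)
    caseOrder <- rep(seq_along(cases), each = plan$slicesPerVolume)
    caseOrder <- caseOrder[sample.int(length(caseOrder))]
    sums <- c(l1 = 0, adv = 0, mi = 0, d = 0)
    kept <- 0L; skipped <- 0L

    for (ci in caseOrder) {
      batch <- sampleMultiplanarBatch(cases[[ci]], ci, plan)
      if (batch$skip) { skipped <- skipped + 1L; next }
      gG <- NULL; gD <- NULL
      bl <- c(l1 = 0, adv = 0, mi = 0, d = 0)
      for (pl in batch$planes) {
        fw <- generatorForward(gen, pl$mr, keepCache = TRUE)
        fake <- fw$y
        # generator step gradients
        dfw <- discriminatorForward(disc, pl$mr, fake, keepCache = TRUE)
        adv <- generatorAdversarialLoss(dfw$y, gradient = TRUE)
        gAdvCT <- discriminatorBackward(disc, dfw$cache, adv$grad)$gct
        l1 <- l1Loss(pl$ct, fake, gradient = TRUE)
        mi <- softMILossGrad(pl$ct, fake, bins = config$miBins)
        gOut <- gAdvCT + w$lambda1 * l1$grad + w$lambda2 * mi$grad
        gG <- addGrads(gG, generatorBackward(gen, fw$cache, gOut))
        # discriminator step gradients (fake via history buffer, detached)
        histFake <- bufferDraw(buffer, list(mr = pl$mr, ct = fake))
        dReal <- discriminatorForward(disc, pl$mr, pl$ct, keepCache = TRUE)
        dFake <- discriminatorForward(disc, histFake$mr, histFake$ct,
                                      keepCache = TRUE)
        dl <- discriminatorLoss(dReal$y, dFake$y, gradient = TRUE)
        gD <- addGrads(gD, discriminatorBackward(disc, dReal$cache,
                                                 dl$gradReal)$grads)
        gD <- addGrads(gD, discriminatorBackward(disc, dFake$cache,
                                                 dl$gradFake)$grads)
        bl <- bl + c(l1 = l1$loss, adv = adv$loss,
                     mi = miLoss(pl$ct, fake, config$miBins), d = dl$loss)
      }
      nP <- length(batch$planes)
      stepG <- adamStep(gen$params, scaleGrads(gG, 1 / nP), adamG, lrG,
                        b1, b2)
      gen$params <- stepG$params; adamG <- stepG$state
      stepD <- adamStep(disc$params, scaleGrads(gD, 1 / nP), adamD, lrD,
                        b1, b2)
      disc$params <- stepD$params; adamD <- stepD$state
      sums <- sums + bl / nP
      kept <- kept + 1L
    }
    mean4 <- if (kept > 0) sums / kept else sums * NA
    hist <- rbind(hist, data.frame(
      epoch = epoch, lrG = lrG, lrD = lrD,
      meanL1 = mean4[["l1"]], meanAdv = mean4[["adv"]],
      meanMI = mean4[["mi"]], meanD = mean4[["d"]],
      iterations = kept + skipped, kept = kept, skipped = skipped))
    if (verbose)
      message(sprintf(
        "epoch %d lrG %.3g lrD %.3g L1 %.4f adv %.4f mi %.4f D %.4f (%d/%d kept)",
        epoch, lrG, lrD, mean4[["l1"]], mean4[["adv"]], mean4[["mi"]],
        mean4[["d"]], kept, kept + skipped))
  }
  list(generator = gen, history = hist)
}
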