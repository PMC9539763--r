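# Minimal deterministic conv-net machinery for the MR->CT translator:
# plain-R parameter lists over the compiled im2col conv kernels, with
# hand-derived backward passes and an Adam optimizer. All randomness goes
# through R's RNG so training is a pure function of the seed.

#' Generator architecture specification
#'
#' A U-Net encoder-decoder with skip connections: `depth` stride-2 encoder
#' convolutions (4x4 kernels), mirrored transposed-conv decoder, instance
#' normalization (except the first encoder block), LeakyReLU(0.2) in the
#' encoder, ReLU in the decoder and a final tanh so outputs stay in [-1, 1].
#' The input plane side must be divisible by `2^depth`. The compact default
#' (depth 3, 16 base channels) targets 64x64 planes on a single CPU; the
#' full-scale configuration for 256x256 planes is `depth >= 6` with more
#' base channels.
#'
#' @param depth number of encoder/decoder levels.
#' @param baseChannels channels of the first encoder block (doubling per
#'   level, capped at 8x).
#' @param inChannels,outChannels plane channel counts (both 1 here).
#' @return A list of class `"GeneratorSpec"`.
#' @export
generatorSpec <- function(depth = 3L, baseChannels = 16L, inChannels = 1L,
                          outChannels = 1L) {
  stopifnot(depth >= 1, baseChannels >= 1)
  structure(list(depth = as.integer(depth),
                 baseChannels = as.integer(baseChannels),
                 inChannels = as.integer(inChannels),
                 outChannels = as.integer(outChannels)),
            class = "GeneratorSpec")
}

#' Discriminator architecture specification
#'
#' A PatchGAN: stride-2 convolutions shrink the conditioned (MR, CT) pair by
#' `downsampleFactor`, ending in a linear 2D score map (one score per image
#' patch, never a scalar). With the full-scale factor 16, a 256x256 input
#' yields the 16x16 patch score map; a 64x64 desk-scale input yields 4x4.
#'
#' @param downsampleFactor power of two; output side = input side / factor.
#' @param baseChannels channels of the first block.
#' @return A list of class `"DiscriminatorSpec"`.
#' @export
discriminatorSpec <- function(downsampleFactor = 16L, baseChannels = 16L) {
  stopifnot(downsampleFactor >= 2,
            abs(log2(downsampleFactor) - round(log2(downsampleFactor))) < 1e-9)
  structure(list(downsampleFactor = as.integer(downsampleFactor),
                 baseChannels = as.integer(baseChannels)),
            class = "DiscriminatorSpec")
}

asCube <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

initConv <- function(k, cin, cout, sd = 0.02) {
  list(w = matrix(stats::rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout),
       b = numeric(cout), k = k)
}

initConvT <- function(k, cin, cout, sd = 0.02) {
  list(w = matrix(stats::rnorm(k * k * cout * cin, 0, sd), k * k * cout, cin),
       b = numeric(cout), k = k)
}

initINorm <- function(c) list(gamma = rep(1, c), beta = numeric(c))

# ---- primitive forward/backward (caches kept as lists) ----

lreluFwd <- function(x, alpha = 0.2) list(y = ifelse(x > 0, x, alpha * x),
                                          x = x, alpha = alpha)
lreluBwd <- function(cache, gy) gy * ifelse(cache$x > 0, 1, cache$alpha)

reluFwd <- function(x) list(y = pmax(x, 0), x = x)
reluBwd <- function(cache, gy) gy * (cache$x > 0)

tanhFwd <- function(x) { y <- tanh(x); list(y = y) }
tanhBwd <- function(cache, gy) gy * (1 - cache$y^2)

inormFwd <- function(p, x, eps = 1e-5) {
  d <- dim(x)
  y <- x
  mu <- numeric(d[3]); istd <- numeric(d[3]); xhat <- x
  for (c in seq_len(d[3])) {
    xc <- x[, , c]
    mu[c] <- mean(xc)
    v <- mean((xc - mu[c])^2)
    istd[c] <- 1 / sqrt(v + eps)
    xhat[, , c] <- (xc - mu[c]) * istd[c]
    y[, , c] <- p$gamma[c] * xhat[, , c] + p$beta[c]
  }
  list(y = y, xhat = xhat, istd = istd)
}

inormBwd <- function(p, cache, gy) {
  d <- dim(gy)
  gx <- gy
  ggamma <- numeric(d[3]); gbeta <- numeric(d[3])
  n <- d[1] * d[2]
  for (c in seq_len(d[3])) {
    gyc <- gy[, , c]; xh <- cache$xhat[, , c]
    ggamma[c] <- sum(gyc * xh)
    gbeta[c] <- sum(gyc)
    gxhat <- gyc * p$gamma[c]
    gx[, , c] <- cache$istd[c] *
      (gxhat - mean(gxhat) - xh * mean(gxhat * xh))
  }
  list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
}

convFwd <- function(p, x, stride, pad) {
  x <- asCube(x)
  list(y = cpp_conv_fwd(x, p$w, p$b, p$k, stride, pad), x = x,
       stride = stride, pad = pad)
}
convBwd <- function(p, cache, gy) {
  r <- cpp_conv_bwd(cache$x, p$w, gy, p$k, cache$stride, cache$pad)
  list(gx = r$gx, grads = list(w = r$gw, b = as.numeric(r$gb)))
}

convtFwd <- function(p, x, stride, pad) {
  x <- asCube(x)
  list(y = cpp_convt_fwd(x, p$w, p$b, p$k, stride, pad), x = x,
       stride = stride, pad = pad)
}
convtBwd <- function(p, cache, gy) {
  r <- cpp_convt_bwd(cache$x, p$w, gy, p$k, cache$stride, cache$pad)
  list(gx = r$gx, grads = list(w = r$gw, b = as.numeric(r$gb)))
}

# ---- generator ----

encChannels <- function(spec) {
  pmin(spec$baseChannels * 2^(seq_len(spec$depth) - 1), spec$baseChannels * 8)
}

#' Build an untrained generator
#'
#' Initializes all weights from N(0, 0.02) using R's RNG (seed it for
#' reproducibility). The returned object is a parameter container consumed
#' by [generatorForward()], [trainTranslator()] and [predictVolume()].
#'
#' @param spec a [generatorSpec()].
#' @return A list of class `"Generator"` with fields `spec` and `params`.
#' @export
buildGenerator <- function(spec = generatorSpec()) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  ch <- encChannels(spec)
  enc <- list(); dec <- list()
  cin <- spec$inChannels
  for (l in seq_len(spec$depth)) {
    enc[[l]] <- list(conv = initConv(4L, cin, ch[l]),
                     norm = if (l > 1) initINorm(ch[l]) else NULL)
    cin <- ch[l]
  }
  for (l in seq_len(spec$depth - 1)) {
    lev <- spec$depth - l           # decodes up to level `lev`
    cinDec <- if (l == 1) ch[spec$depth] else 2L * ch[lev + 1]
    dec[[l]] <- list(convt = initConvT(4L, cinDec, ch[lev]),
                     norm = initINorm(ch[lev]))
  }
  cinFinal <- if (spec$depth == 1) ch[1] else 2L * ch[1]
  final <- initConvT(4L, cinFinal, spec$outChannels)
  structure(list(spec = spec,
                 params = list(enc = enc, dec = dec, final = final)),
            class = "Generator")
}

#' Generator forward pass
#'
#' @param gen a [buildGenerator()] object.
#' @param x input plane (2D matrix or HxWx1 array) in [-1, 1].
#' @param keepCache keep intermediate activations for [generatorBackward()].
#' @return A list with `y` (output plane, values in [-1, 1]) and, when
#'   requested, `cache`.
#' @export
generatorForward <- function(gen, x, keepCache = FALSE) {
  spec <- gen$spec; p <- gen$params
  x <- asCube(x)
  side <- dim(x)[1:2]
  if (any(side %% 2^spec$depth != 0))
    stop("input side must be divisible by 2^depth")
  cache <- list(enc = vector("list", spec$depth),
                dec = vector("list", max(spec$depth - 1, 0)))
  skips <- vector("list", spec$depth)
  h <- x
  for (l in seq_len(spec$depth)) {
    cv <- convFwd(p$enc[[l]]$conv, h, 2L, 1L)
    blk <- list(conv = cv)
    h <- cv$y
    if (!is.null(p$enc[[l]]$norm)) {
      no <- inormFwd(p$enc[[l]]$norm, h)
      blk$norm <- no
      h <- no$y
    }
    ac <- lreluFwd(h)
    blk$act <- ac
    h <- ac$y
    skips[[l]] <- h
    cache$enc[[l]] <- blk
  }
  for (l in seq_along(p$dec)) {
    lev <- spec$depth - l
    ct <- convtFwd(p$dec[[l]]$convt, h, 2L, 1L)
    no <- inormFwd(p$dec[[l]]$norm, ct$y)
    ac <- reluFwd(no$y)
    skipC <- dim(skips[[lev]])[3]
    h <- abind3(ac$y, skips[[lev]])
    cache$dec[[l]] <- list(convt = ct, norm = no, act = ac, skipC = skipC)
  }
  fin <- convtFwd(p$final, h, 2L, 1L)
  tn <- tanhFwd(fin$y)
  cache$final <- fin
  cache$tanh <- tn
  out <- tn$y[, , 1]
  if (keepCache) list(y = out, cache = cache) else list(y = out)
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

#' Generator backward pass
#'
#' Backpropagates a gradient with respect to the output plane through the
#' cached forward pass, returning parameter gradients in the same structure
#' as `gen$params`.
#'
#' @param gen the generator.
#' @param cache forward cache from [generatorForward()] with
#'   `keepCache = TRUE`.
#' @param gout gradient w.r.t. the output plane (2D matrix).
#' @return A parameter-gradient list.
#' @export
generatorBackward <- function(gen, cache, gout) {
  spec <- gen$spec; p <- gen$params
  grads <- list(enc = vector("list", spec$depth),
                dec = vector("list", length(p$dec)), final = NULL)
  g <- asCube(tanhBwd(cache$tanh, asCube(gout)))
  fb <- convtBwd(p$final, cache$final, g)
  grads$final <- fb$grads
  g <- fb$gx
  gskips <- vector("list", spec$depth)   # gradient flowing into each skip
  for (l in rev(seq_along(p$dec))) {
    lev <- spec$depth - l
    blk <- cache$dec[[l]]
    nOwn <- dim(blk$act$y)[3]
    gOwn <- g[, , seq_len(nOwn), drop = FALSE]
    gSkip <- g[, , nOwn + seq_len(blk$skipC), drop = FALSE]
    gskips[[lev]] <- addOrInit(gskips[[lev]], gSkip)
    ga <- reluBwd(blk$act, gOwn)
    nb <- inormBwd(p$dec[[l]]$norm, blk$norm, ga)
    cb <- convtBwd(p$dec[[l]]$convt, blk$convt, nb$gx)
    grads$dec[[l]] <- list(convt = cb$grads, norm = nb$grads)
    g <- cb$gx
  }
  # g is now the gradient into the deepest encoder activation (used directly
  # by the first decoder); merge with any skip gradient at that level
  gskips[[spec$depth]] <- addOrInit(gskips[[spec$depth]], g)
  for (l in rev(seq_len(spec$depth))) {
    blk <- cache$enc[[l]]
    g <- gskips[[l]]
    g <- lreluBwd(blk$act, g)
    encG <- list()
    if (!is.null(p$enc[[l]]$norm)) {
      nb <- inormBwd(p$enc[[l]]$norm, blk$norm, g)
      encG$norm <- nb$grads
      g <- nb$gx
    }
    cb <- convBwd(p$enc[[l]]$conv, blk$conv, g)
    encG$conv <- cb$grads
    grads$enc[[l]] <- encG
    if (l > 1) gskips[[l - 1]] <- addOrInit(gskips[[l - 1]], cb$gx)
  }
  grads
}

addOrInit <- function(a, b) if (is.null(a)) b else a + b

#' Build an untrained PatchGAN discriminator
#'
#' @param spec a [discriminatorSpec()].
#' @return A list of class `"Discriminator"`.
#' @export
buildDiscriminator <- function(spec = discriminatorSpec()) {
  stopifnot(inherits(spec, "DiscriminatorSpec"))
  nDown <- as.integer(round(log2(spec$downsampleFactor)))
  ch <- pmin(spec$baseChannels * 2^(seq_len(nDown) - 1), spec$baseChannels * 8)
  blocks <- list()
  cin <- 2L   # conditioned pair: MR plane stacked with CT plane
  for (l in seq_len(nDown)) {
    blocks[[l]] <- list(conv = initConv(4L, cin, ch[l]),
                        norm = if (l > 1) initINorm(ch[l]) else NULL)
    cin <- ch[l]
  }
  final <- initConv(3L, cin, 1L)
  structure(list(spec = spec, params = list(blocks = blocks, final = final)),
            class = "Discriminator")
}

#' Discriminator forward pass
#'
#' @param disc a [buildDiscriminator()] object.
#' @param mr,ct conditioned input pair of equal-shape 2D planes in [-1, 1].
#' @param keepCache keep activations for [discriminatorBackward()].
#' @return List with `y`, the 2D patch score map (side = input side /
#'   `downsampleFactor`), and optionally `cache`.
#' @export
discriminatorForward <- function(disc, mr, ct, keepCache = FALSE) {
  if (!identical(dim(mr), dim(ct))) stop("MR/CT plane shape mismatch")
  p <- disc$params
  h <- abind3(asCube(mr), asCube(ct))
  cache <- list(blocks = vector("list", length(p$blocks)))
  for (l in seq_along(p$blocks)) {
    cv <- convFwd(p$blocks[[l]]$conv, h, 2L, 1L)
    blk <- list(conv = cv)
    h <- cv$y
    if (!is.null(p$blocks[[l]]$norm)) {
      no <- inormFwd(p$blocks[[l]]$norm, h)
      blk$norm <- no
      h <- no$y
    }
    ac <- lreluFwd(h)
    blk$act <- ac
    h <- ac$y
    cache$blocks[[l]] <- blk
  }
  fin <- convFwd(p$final, h, 1L, 1L)
  cache$final <- fin
  out <- fin$y[, , 1]
  if (keepCache) list(y = out, cache = cache) else list(y = out)
}

#' Discriminator backward pass
#'
#' @param disc the discriminator.
#' @param cache forward cache.
#' @param gout gradient w.r.t. the score map.
#' @return List with `grads` (parameter gradients) and `gct` (gradient
#'   w.r.t. the CT input plane, used to train the generator through the
#'   adversarial term).
#' @export
discriminatorBackward <- function(disc, cache, gout) {
  p <- disc$params
  grads <- list(blocks = vector("list", length(p$blocks)), final = NULL)
  fb <- convBwd(p$final, cache$final, asCube(gout))
  grads$final <- fb$grads
  g <- fb$gx
  for (l in rev(seq_along(p$blocks))) {
    blk <- cache$blocks[[l]]
    g <- lreluBwd(blk$act, g)
    blkG <- list()
    if (!is.null(p$blocks[[l]]$norm)) {
      nb <- inormBwd(p$blocks[[l]]$norm, blk$norm, g)
      blkG$norm <- nb$grads
      g <- nb$gx
    }
    cb <- convBwd(p$blocks[[l]]$conv, blk$conv, g)
    blkG$conv <- cb$grads
    grads$blocks[[l]] <- blkG
    g <- cb$gx
  }
  list(grads = grads, gct = g[, , 2])
}

# ---- parameter-tree utilities and Adam ----

isParamLeaf <- function(x) is.numeric(x)

mapParams <- function(a, b, f) {
  if (isParamLeaf(a)) return(f(a, b))
  out <- a
  for (nm in seq_along(a)) {
    if (is.null(a[[nm]])) next
    if (is.list(a[[nm]]) || isParamLeaf(a[[nm]]))
      out[[nm]] <- mapParams(a[[nm]], b[[nm]], f)
  }
  out
}

zeroLike <- function(a) {
  if (isParamLeaf(a)) return(a * 0)
  out <- a
  for (nm in seq_along(a))
    if (!is.null(a[[nm]]) && (is.list(a[[nm]]) || isParamLeaf(a[[nm]])))
      out[[nm]] <- zeroLike(a[[nm]])
  out
}

# strip non-parameter metadata (kernel sizes) from a params tree for Adam
paramNames <- c("w", "b", "gamma", "beta")

treeApply <- function(params, grads, state, update) {
  # walks the parameter tree; `update(p, g, m, v)` returns list(p, m, v)
  rec <- function(p, g, m, v) {
    if (is.numeric(p)) {
      r <- update(p, g, m, v)
      return(r)
    }
    for (nm in names(p)) {
      if (is.null(p[[nm]])) next
      if (nm %in% c("k")) next
      if (is.numeric(p[[nm]]) || is.list(p[[nm]])) {
        r <- rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
    }
    list(p = p, m = m, v = v)
  }
  # unnamed list levels (enc/dec/blocks are unnamed lists)
  recAny <- function(p, g, m, v) {
    if (is.numeric(p)) return(update(p, g, m, v))
    idx <- if (is.null(names(p))) seq_along(p) else names(p)
    for (nm in idx) {
      if (is.null(p[[nm]])) next
      if (identical(nm, "k")) next
      if (is.numeric(p[[nm]]) || is.list(p[[nm]])) {
        r <- recAny(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
    }
    list(p = p, m = m, v = v)
  }
  recAny(params, grads, state$m, state$v)
}

adamInit <- function(params) list(m = zeroLike(params), v = zeroLike(params),
                                  t = 0L)

adamStep <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- treeApply(params, grads, state, upd)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

scaleGrads <- function(g, s) {
  if (is.numeric(g)) return(g * s)
  idx <- if (is.null(names(g))) seq_along(g) else names(g)
  for (nm in idx) {
    if (is.null(g[[nm]]) || identical(nm, "k")) next
    if (is.numeric(g[[nm]]) || is.list(g[[nm]])) g[[nm]] <- scaleGrads(g[[nm]], s)
  }
  g
}

addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.numeric(a)) return(a + b)
  idx <- if (is.null(names(a))) seq_along(a) else names(a)
  for (nm in idx) {
    if (is.null(a[[nm]]) || identical(nm, "k")) next
    if (is.numeric(a[[nm]]) || is.list(a[[nm]])) a[[nm]] <- addGrads(a[[nm]], b[[nm]])
  }
  a
}

#' Save / load a generator checkpoint
#'
#' One file holding the architecture spec, all weights and the RNG state at
#' save time, so downstream synthesis and resumed experiments are exactly
#' reproducible.
#'
#' @param gen a Generator.
#' @param path checkpoint file path (`.rds`).
#' @return `readCheckpoint` returns the Generator.
#' @export
writeCheckpoint <- function(gen, path) {
  rng <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  obj <- list(spec = gen$spec, params = gen$params, rngState = rng,
              package = "synthCT", formatVersion = 1L)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  obj <- readRDS(path)
  structure(list(spec = obj$spec, params = obj$params), class = "Generator")
}
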