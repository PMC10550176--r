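## Two-step gradient visualization of the most facilitative center and
## the most suppressive / facilitative surround.
##
## Images are parameterized in the frequency domain with a 1/f amplitude
## rescale and squashed to [0, 1] through a sigmoid; optimization runs
## Adam on the spectral coefficients of the neuron's pre-activation
## response, with per-step random circular jitter of the rendered image
## before compositing. Only these two regularizers (1/f prior, jitter)
## are applied.

#' Visualization configuration
#'
#' @param iterations Adam steps per optimization (default 500).
#' @param learningRate default Adam learning rate (fixture networks use
#'   0.005; deep trained networks typically need smaller rates in early
#'   layers, supplied via `learningRateTable`).
#' @param learningRateTable optional named vector mapping layer names to
#'   learning rates, overriding `learningRate` for those layers.
#' @param jitterMax maximum circular shift in pixels on each axis.
#' @param seed integer seed; the whole two-step run is keyed on it.
#' @param initSd standard deviation of the Gaussian initialization of
#'   the spectral coefficients.
#' @param beta1,beta2,eps Adam moment parameters.
#' @return named list.
#' @export
visConfig <- function(iterations = 500L, learningRate = 0.005,
                      learningRateTable = NULL, jitterMax = 8L,
                      seed = 1L, initSd = 0.01, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  list(iterations = as.integer(iterations), learningRate = learningRate,
       learningRateTable = learningRateTable,
       jitterMax = as.integer(jitterMax), seed = as.integer(seed),
       initSd = initSd, beta1 = beta1, beta2 = beta2, eps = eps)
}

resolveLearningRate <- function(config, layer) {
  tab <- config$learningRateTable
  if (!is.null(tab) && layer %in% names(tab)) tab[[layer]]
  else config$learningRate
}

## 1/f amplitude profile over the discrete frequency grid, normalized to
## 1 at the lowest nonzero frequency bin.
freqScale <- function(size) {
  fr <- c(seq(0, floor(size / 2)), seq(-ceiling(size / 2) + 1, -1)) / size
  f <- sqrt(outer(fr^2, fr^2, "+"))
  sc <- 1 / pmax(f, 1 / size)
  sc / max(sc[f > 0])
}

#' Spectral image parameterization
#'
#' Real parameter set mapping differentiably to a 3-channel image:
#' per-channel complex Fourier coefficients (stored as real and
#' imaginary parts), multiplied by a 1/f amplitude profile, inverse
#' transformed (the real part enforces conjugate symmetry) and squashed
#' to `[0, 1]` by a sigmoid.
#'
#' @param size image side length.
#' @param seed seed for the Gaussian initialization.
#' @param initSd initialization standard deviation (0 gives the constant
#'   mid-gray render).
#' @return object of class `spectralParam`.
#' @export
spectralParam <- function(size, seed = 1L, initSd = 0.01) {
  p <- withSeed(seed, list(
    re = array(stats::rnorm(size * size * 3, sd = initSd), c(size, size, 3)),
    im = array(stats::rnorm(size * size * 3, sd = initSd), c(size, size, 3))))
  p$scale <- freqScale(size)
  p$size <- size
  class(p) <- "spectralParam"
  p
}

#' Render a spectral parameterization to an image
#'
#' @param param a `spectralParam`.
#' @return list with `image` (`size x size x 3` in `[0, 1]`) and `pre`
#'   (the pre-sigmoid field, needed for the backward pass).
#' @export
renderParam <- function(param) {
  n <- param$size
  pre <- array(0, c(n, n, 3))
  for (ch in 1:3) {
    Z <- param$scale * complex(real = param$re[, , ch],
                               imaginary = param$im[, , ch])
    dim(Z) <- c(n, n)
    pre[, , ch] <- Re(stats::fft(Z, inverse = TRUE))
  }
  list(image = 1 / (1 + exp(-pre)), pre = pre)
}

## Adjoint of renderParam: gradient w.r.t. the stored coefficients given
## the gradient w.r.t. the rendered image.
renderParamBackward <- function(param, pre, gImage) {
  n <- param$size
  gRe <- array(0, c(n, n, 3)); gIm <- gRe
  sig <- 1 / (1 + exp(-pre))
  gPre <- gImage * sig * (1 - sig)
  for (ch in 1:3) {
    G <- stats::fft(gPre[, , ch])
    gRe[, , ch] <- param$scale * Re(G)
    gIm[, , ch] <- param$scale * Im(G)
  }
  list(re = gRe, im = gIm)
}

circShift <- function(img, dx, dy) {
  ## dx shifts columns (x), dy shifts rows (y), circularly
  n <- dim(img)[1]
  if (dy != 0) img <- img[((seq_len(n) - 1 - dy) %% n) + 1, , , drop = FALSE]
  if (dx != 0) img <- img[, ((seq_len(n) - 1 - dx) %% n) + 1, , drop = FALSE]
  img
}

maskToRGB <- function(mask) array(rep(mask, 3L), c(dim(mask), 3L))

#' Center / gap / surround mask set from receptive-field geometry
#'
#' Center disc of GSF diameter at the unit's true center; a gray gap
#' ring of 4 px (GSF to GSF + 4); surround annulus from GSF + 4 px to
#' the theoretical receptive field. The gap stays gray during both
#' optimization steps.
#'
#' @param geometry the unit's [RFGeometry].
#' @param gsf grating summation field in pixels.
#' @param size canvas side length.
#' @return list of logical matrices `center`, `gap`, `surround`.
#' @export
buildMaskSet <- function(geometry, gsf, size) {
  regionMasks(size, geometry@stimulusCenter, gsf, gsf + 4,
              min(geometry@r, size))
}

composeRegions <- function(render, masks, region, fixedCenter = NULL) {
  mC <- maskToRGB(masks$center)
  if (region == "center") {
    render * mC + 0.5 * (1 - mC)
  } else {
    mS <- maskToRGB(masks$surround)
    fixedCenter * mC + render * mS + 0.5 * (1 - mC - mS)
  }
}

optimizeRegion <- function(net, neuron, masks, region, direction,
                           config, fixedCenter = NULL) {
  size <- net@spec@inputSize
  lr <- resolveLearningRate(config, neuron@layer)
  sgn <- if (direction == "max") 1 else -1
  mask3 <- maskToRGB(if (region == "center") masks$center else masks$surround)
  withSeed(config$seed, {
    drawParam <- function() {
      p <- list(re = array(stats::rnorm(size^2 * 3, sd = config$initSd),
                           c(size, size, 3)),
                im = array(stats::rnorm(size^2 * 3, sd = config$initSd),
                           c(size, size, 3)),
                scale = freqScale(size), size = size)
      class(p) <- "spectralParam"
      p
    }
    param <- drawParam()
    ## dead-start guard: rectifiers upstream of the probed unit can zero
    ## the gradient for an unlucky initialization; redraw from the
    ## seeded stream until some gradient reaches the optimized region
    if (config$iterations > 0L && config$initSd > 0) {
      for (try in seq_len(20L)) {
        comp0 <- composeRegions(renderParam(param)$image, masks, region,
                                fixedCenter)
        if (any(neuronGradient(net, neuron, comp0) * mask3 != 0)) break
        param <- drawParam()
      }
    }
    mRe <- array(0, dim(param$re)); vRe <- mRe
    mIm <- mRe; vIm <- mRe
    trace <- numeric(config$iterations)
    sawGradient <- FALSE
    for (it in seq_len(config$iterations)) {
      rp <- renderParam(param)
      dx <- if (config$jitterMax > 0)
        sample(-config$jitterMax:config$jitterMax, 1L) else 0L
      dy <- if (config$jitterMax > 0)
        sample(-config$jitterMax:config$jitterMax, 1L) else 0L
      shifted <- circShift(rp$image, dx, dy)
      comp <- composeRegions(shifted, masks, region, fixedCenter)
      resp <- probeResponse(net, neuron, comp, stage = "pre")
      if (!is.finite(resp)) stop("non-finite response during optimization")
      trace[it] <- resp
      g <- neuronGradient(net, neuron, comp) * mask3
      g <- circShift(g, -dx, -dy)
      if (any(g != 0)) sawGradient <- TRUE
      gp <- renderParamBackward(param, rp$pre, sgn * g)
      ## Adam ascent step
      mRe <- config$beta1 * mRe + (1 - config$beta1) * gp$re
      vRe <- config$beta2 * vRe + (1 - config$beta2) * gp$re^2
      mIm <- config$beta1 * mIm + (1 - config$beta1) * gp$im
      vIm <- config$beta2 * vIm + (1 - config$beta2) * gp$im^2
      bc1 <- 1 - config$beta1^it; bc2 <- 1 - config$beta2^it
      param$re <- param$re + lr * (mRe / bc1) / (sqrt(vRe / bc2) + config$eps)
      param$im <- param$im + lr * (mIm / bc1) / (sqrt(vIm / bc2) + config$eps)
    }
    render <- renderParam(param)$image
    list(render = render,
         composite = composeRegions(render, masks, region, fixedCenter),
         trace = trace,
         failed = config$iterations > 0L && !sawGradient)
  })
}

#' Optimize the most facilitative center image
#'
#' Runs Adam on the spectral parameters to maximize the unit's
#' pre-activation response to the composite in which everything outside
#' the center disc is gray; the rendered image is circularly jittered
#' before compositing at every step. The reported image is the
#' unjittered render.
#'
#' @param net a [Network].
#' @param neuron a [NeuronAddress].
#' @param masks mask set from [buildMaskSet()].
#' @param config a [visConfig()].
#' @return list with `render` (full render), `composite` (center on gray),
#'   `trace` (per-step pre-activation responses), `failed` (TRUE when no
#'   gradient ever reached the parameters).
#' @export
optimizeCenter <- function(net, neuron, masks, config = visConfig()) {
  optimizeRegion(net, neuron, masks, "center", "max", config)
}

#' Optimize the most suppressive or facilitative surround
#'
#' With the center region fixed to a given center image (any image, not
#' only the optimum) and the gap ring gray, optimizes only the surround
#' region content to minimize (`"suppressive"`) or maximize
#' (`"facilitative"`) the unit's pre-activation response. The
#' suppressive objective is the signed pre-activation, not clamped at
#' zero.
#'
#' @inheritParams optimizeCenter
#' @param centerImage image whose center-disc content is held fixed.
#' @param direction `"suppressive"` or `"facilitative"`.
#' @return as [optimizeCenter()]; `composite` is center + optimized
#'   surround.
#' @export
optimizeSurround <- function(net, neuron, centerImage,
                             direction = c("suppressive", "facilitative"),
                             masks, config = visConfig()) {
  direction <- match.arg(direction)
  optimizeRegion(net, neuron, masks, "surround",
                 if (direction == "suppressive") "min" else "max",
                 config, fixedCenter = centerImage)
}

#' Two-step surround visualization
#'
#' Step 1 finds the most facilitative center (surround gray); step 2
#' holds that center fixed and finds the most suppressive and the most
#' facilitative surround. Final responses are evaluated on the
#' unjittered composites at both stages. Identical (seed, config,
#' weights) produce bit-identical results.
#'
#' @inheritParams optimizeCenter
#' @param geometry the unit's [RFGeometry]; with `gsf`, used to build
#'   the masks unless `masks` is given.
#' @param gsf grating summation field in pixels.
#' @return a [VisResult].
#' @export
twoStepVisualize <- function(net, neuron, geometry = NULL, gsf = NULL,
                             masks = NULL, config = visConfig()) {
  size <- net@spec@inputSize
  if (is.null(masks)) {
    if (is.null(geometry) || is.null(gsf))
      stop("either masks or (geometry, gsf) must be supplied")
    masks <- buildMaskSet(geometry, gsf, size)
  }
  cfg1 <- config; cfg1$seed <- config$seed
  cfg2 <- config; cfg2$seed <- config$seed + 1L
  cfg3 <- config; cfg3$seed <- config$seed + 2L
  ctr <- optimizeCenter(net, neuron, masks, cfg1)
  sup <- optimizeSurround(net, neuron, ctr$composite, "suppressive",
                          masks, cfg2)
  fac <- optimizeSurround(net, neuron, ctr$composite, "facilitative",
                          masks, cfg3)
  respOf <- function(img) c(
    pre = probeResponse(net, neuron, img, stage = "pre"),
    post = probeResponse(net, neuron, img, stage = "post"))
  rc <- respOf(ctr$composite)
  rs <- respOf(sup$composite)
  rf <- respOf(fac$composite)
  new("VisResult",
      center = ctr$composite,
      suppressive = sup$composite,
      facilitative = fac$composite,
      responses = c(center_pre = rc[["pre"]], center_post = rc[["post"]],
                    suppressive_pre = rs[["pre"]],
                    suppressive_post = rs[["post"]],
                    facilitative_pre = rf[["pre"]],
                    facilitative_post = rf[["post"]]),
      trace = list(center = ctr$trace, suppressive = sup$trace,
                   facilitative = fac$trace),
      converged = config$iterations > 0L && !ctr$failed && !sup$failed &&
        !fac$failed,
      seed = as.integer(config$seed), config = config)
}

#' Permute the color channels of a center image
#'
#' @param image `h x w x 3` array.
#' @param perm permutation of 1:3.
#' @return channel-permuted image (used as the altered fixed center for
#'   surround re-optimization).
#' @export
permuteCenterColors <- function(image, perm) {
  stopifnot(length(perm) == 3L, setequal(perm, 1:3))
  image[, , perm, drop = FALSE]
}

## Bilinear resampling of a source center disc onto a target center disc.
resampleCenter <- function(srcImage, srcCenter, srcDiameter,
                           dstCenter, dstDiameter, size) {
  out <- array(0.5, c(size, size, 3))
  sc <- srcDiameter / dstDiameter
  n <- dim(srcImage)[1]
  g <- pixelGrid(size)
  sx <- (g$X - dstCenter[1]) * sc + srcCenter[1]
  sy <- (g$Y - dstCenter[2]) * sc + srcCenter[2]
  cx <- pmin(pmax(sx + 0.5, 1), n); cy <- pmin(pmax(sy + 0.5, 1), n)
  x0 <- pmin(floor(cx), n - 1); y0 <- pmin(floor(cy), n - 1)
  fx <- cx - x0; fy <- cy - y0
  for (ch in 1:3) {
    p <- srcImage[, , ch]
    v <- p[cbind(as.vector(y0), as.vector(x0))] * (1 - fx) * (1 - fy) +
      p[cbind(as.vector(y0), as.vector(x0 + 1))] * fx * (1 - fy) +
      p[cbind(as.vector(y0 + 1), as.vector(x0))] * (1 - fx) * fy +
      p[cbind(as.vector(y0 + 1), as.vector(x0 + 1))] * fx * fy
    out[, , ch] <- matrix(v, size, size)
  }
  out
}

#' Surround optimization against a foreign (exchanged) center
#'
#' Takes the most facilitative center of a source visualization, places
#' it in the target unit's center disc (bilinear resampling when the
#' grating summation fields differ), and optimizes the target's
#' suppressive (or facilitative) surround against it.
#'
#' @param source a [VisResult] (its center image is used) or an image
#'   array.
#' @param net target [Network].
#' @param neuron target [NeuronAddress].
#' @param masks target mask set.
#' @param sourceMasks mask set of the source (for resampling); `NULL`
#'   assumes matching geometry.
#' @param direction surround objective.
#' @param config a [visConfig()].
#' @param resample allow resampling when geometries differ.
#' @return as [optimizeSurround()], plus the placed `center` image.
#' @export
exchangeCenter <- function(source, net, neuron, masks,
                           sourceMasks = NULL,
                           direction = "suppressive",
                           config = visConfig(), resample = TRUE) {
  srcImg <- if (is(source, "VisResult")) source@center else source
  size <- net@spec@inputSize
  sameGeom <- is.null(sourceMasks) ||
    (identical(dim(srcImg)[1:2], c(size, size)) &&
     identical(sourceMasks$center, masks$center))
  if (!sameGeom && !resample)
    stop("source and target center geometries differ; enable resampling")
  placed <- if (sameGeom) srcImg else {
    sd_ <- 2 * sqrt(sum(sourceMasks$center) / pi)
    dd <- 2 * sqrt(sum(masks$center) / pi)
    sctr <- maskCentroid(sourceMasks$center)
    dctr <- maskCentroid(masks$center)
    resampleCenter(srcImg, sctr, sd_, dctr, dd, size)
  }
  res <- optimizeSurround(net, neuron, placed, direction, masks, config)
  res$center <- placed
  res
}

maskCentroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 2]) - 0.5, mean(idx[, 1]) - 0.5)
}
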