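## Self-contained fixture networks and synthetic inputs: the two-pathway
## conceptual model and its image-domain instantiation, the oriented
## toy convolutional model, analytic center-surround Gabor units, random
## linear conv stacks, and procedural texture sources. Every fixture is
## seeded-deterministic and constructed in well under a second.

#' Oriented Gabor kernel
#'
#' Even (cosine-phase) Gabor with zero DC response: a Gaussian envelope
#' times a cosine carrier modulating perpendicular to the bar
#' orientation, with the envelope-weighted mean subtracted.
#'
#' @param k kernel side length.
#' @param orientation bar orientation in degrees.
#' @param period carrier period in pixels.
#' @param sigma envelope standard deviation (default `k / 4`).
#' @param phase carrier phase in degrees.
#' @return `k x k` numeric matrix.
#' @export
gaborKernel <- function(k, orientation, period, sigma = k / 4, phase = 0) {
  xs <- seq_len(k) - (k + 1) / 2
  X <- matrix(xs, k, k, byrow = TRUE)
  Y <- matrix(xs, k, k)
  th <- (orientation + 90) * pi / 180
  u <- X * cos(th) + Y * sin(th)
  env <- exp(-(X^2 + Y^2) / (2 * sigma^2))
  g <- env * cos(2 * pi * u / period + phase * pi / 180)
  g - env * sum(g) / sum(env)
}

## Replicate a single-channel spatial weight over the 3 input channels so
## a grayscale pattern drives all channels equally (weights are split so
## the summed response equals the grayscale inner product).
rgbWeight <- function(mat, outChannels = 1L) {
  W <- array(0, c(nrow(mat), ncol(mat), 3L, outChannels))
  for (oc in seq_len(outChannels)) for (ch in 1:3) W[, , ch, oc] <- mat / 3
  W
}

#' Random linear convolution stack
#'
#' Conv-only network with dense Gaussian weights (no zeros almost
#' surely) and no nonlinearity: the input gradient is then independent of
#' the probe image and its support is exactly the theoretical receptive
#' field. Used as the empirical oracle for the receptive-field recursion.
#'
#' @param arch list of `c(kernel, stride)` pairs (one conv layer each).
#' @param inputSize input side length.
#' @param channels channels per conv layer.
#' @param seed RNG seed for the weights.
#' @return a [Network].
#' @export
buildRandomConvNet <- function(arch, inputSize = 64L, channels = 2L,
                               seed = 1L) {
  layers <- list()
  weights <- list()
  inC <- 3L
  withSeed(seed, {
    for (i in seq_along(arch)) {
      k <- arch[[i]][1]; s <- arch[[i]][2]
      nm <- sprintf("conv%d", i)
      layers[[i]] <- LayerSpec(nm, "conv", k, s, channels)
      weights[[i]] <- list(
        W = array(stats::rnorm(k * k * inC * channels), c(k, k, inC, channels)),
        b = rep(0, channels))
      inC <- channels
    }
  })
  Network(NetworkSpec(inputSize, layers), weights)
}

#' Closed-form two-pathway conceptual model
#'
#' Two center-surround pathways with orthogonal optimal patterns: the
#' optimal pattern in the center elicits a pathway pre-activation of
#' `centerGain` (+1), in the surround `surroundGain` (-0.8); cross-pathway
#' responses are 0. The output is the weighted sum of the rectified
#' pathway responses, with `w1 > w2 > 0`. The returned response function
#' takes center and surround mixes `(alpha1, alpha2)`, `(beta1, beta2)`
#' and supports exhaustive enumeration over discretized mixes.
#'
#' @param w1,w2 readout weights, `w1 > w2 > 0`.
#' @param centerGain,surroundGain pathway gains.
#' @return list with `respond(alpha, beta)`, the weights and gains.
#' @export
buildConceptualModel <- function(w1 = 1, w2 = 0.5, centerGain = 1,
                                 surroundGain = -0.8) {
  stopifnot(w1 > w2, w2 > 0)
  respond <- function(alpha, beta = c(0, 0)) {
    pre <- centerGain * alpha + surroundGain * beta
    w1 * max(0, pre[1]) + w2 * max(0, pre[2])
  }
  list(respond = respond, w1 = w1, w2 = w2, centerGain = centerGain,
       surroundGain = surroundGain)
}

#' Exhaustive enumeration of the conceptual model over surround mixes
#'
#' @param model from [buildConceptualModel()].
#' @param alpha fixed center mix `(alpha1, alpha2)`.
#' @param mixes grid of surround amplitudes per pattern.
#' @return data.frame of `beta1`, `beta2`, `response`, sorted as the
#'   grid; the suppressive optimum is the row with minimal response
#'   (first-row tie-break).
#' @export
enumerateConceptualModel <- function(model, alpha = c(1, 0),
                                     mixes = seq(0, 1, by = 0.25)) {
  grid <- expand.grid(beta1 = mixes, beta2 = mixes)
  grid$response <- apply(grid, 1, function(b)
    model$respond(alpha, c(b[["beta1"]], b[["beta2"]])))
  grid
}

#' Image-domain instantiation of the conceptual model
#'
#' A differentiable network realizing the two-pathway conceptual model on
#' real stimulus images: pathway filters are orthogonal oriented cosine
#' patterns weighted +`centerGain` inside the center disc and
#' `surroundGain` in the surround ring, calibrated so the canonical
#' full-contrast center grating of pathway c elicits a pre-activation of
#' exactly `centerGain` and the canonical surround grating
#' `surroundGain`. A rectifier and a 1x1 readout (`w1`, `w2`) complete
#' the model. Probing the readout's pre-activation reproduces the
#' closed-form model on pattern mixtures.
#'
#' @inheritParams buildConceptualModel
#' @param size input side length.
#' @param orientations the two orthogonal pattern orientations (degrees).
#' @param period pattern period in pixels.
#' @param centerDiameter center-disc diameter; the surround ring runs
#'   from `centerDiameter + 4` to `size`.
#' @return list: `net` ([Network]), `neuron` (readout unit), `masks`
#'   (center/gap/surround logical masks), `patterns` (the two pattern
#'   fields), `centerSpec`/`surroundSpec` factories for canonical
#'   stimuli, `model` (the closed form), `centerDiameter`, `size`.
#' @export
buildConceptualNetwork <- function(size = 64L, w1 = 1, w2 = 0.5,
                                   centerGain = 1, surroundGain = -0.8,
                                   orientations = c(0, 90), period = 8,
                                   centerDiameter = 24) {
  ctr <- c(size / 2, size / 2)
  inner <- centerDiameter + 4
  masks <- regionMasks(size, ctr, centerDiameter, inner, size)
  patterns <- lapply(orientations, function(ori)
    gratingField(GratingSpec(ori, period, contrast = 1, center = ctr),
                 size) * 2 - 1)           # cosine pattern in [-1, 1]
  W1 <- array(0, c(size, size, 3L, 2L))
  for (c_i in 1:2) {
    p <- patterns[[c_i]]
    wc <- matrix(0, size, size)
    ## canonical stimuli are gray +/- 0.5 * pattern -> centered input is
    ## 0.5 * pattern inside the region
    aC <- centerGain / sum((0.5 * p * masks$center) * (p * masks$center))
    aS <- surroundGain / sum((0.5 * p * masks$surround) * (p * masks$surround))
    wc[masks$center] <- aC * p[masks$center]
    wc[masks$surround] <- aS * p[masks$surround]
    W1[, , , c_i] <- rgbWeight(wc)[, , , 1]
  }
  spec <- NetworkSpec(size, list(
    LayerSpec("pathways", "conv", size, size, 2L),
    LayerSpec("rect", "relu"),
    LayerSpec("readout", "conv", 1L, 1L, 1L)))
  weights <- list(
    list(W = W1, b = c(0, 0)),
    NULL,
    list(W = array(c(w1, w2), c(1, 1, 2, 1)), b = 0))
  list(net = Network(spec, weights), neuron = NeuronAddress("readout"),
       masks = masks, patterns = patterns,
       model = buildConceptualModel(w1, w2, centerGain, surroundGain),
       centerDiameter = centerDiameter, innerDiameter = inner,
       size = size, orientations = orientations, period = period)
}

#' Canonical pattern-mixture stimulus for the conceptual network
#'
#' Gray canvas carrying `0.5 * sum(alpha_c P_c)` inside the center disc
#' and `0.5 * sum(beta_c P_c)` in the surround ring. With
#' `sum(abs(alpha)) <= 1` and `sum(abs(beta)) <= 1` the image stays in
#' `[0, 1]` and the network's response equals the closed-form model at
#' those mixes.
#'
#' @param cm from [buildConceptualNetwork()].
#' @param alpha,beta pattern mixes.
#' @return image array.
#' @export
conceptualStimulus <- function(cm, alpha = c(1, 0), beta = c(0, 0)) {
  lum <- matrix(0.5, cm$size, cm$size)
  fieldC <- 0.5 * (alpha[1] * cm$patterns[[1]] + alpha[2] * cm$patterns[[2]])
  fieldS <- 0.5 * (beta[1] * cm$patterns[[1]] + beta[2] * cm$patterns[[2]])
  lum[cm$masks$center] <- 0.5 + fieldC[cm$masks$center]
  lum[cm$masks$surround] <- 0.5 + fieldS[cm$masks$surround]
  toRGB(lum)
}

#' Toy convolutional model of center-surround pattern matching
#'
#' Two oriented filter maps (rectified quadrature pairs, so the maps are
#' non-negative and phase-robust) convolved with a kernel of center
#' weight +1 and surround weight `-surroundGain`, rectified, and read
#' out as a weighted sum at the map-center unit. The readout unit is
#' suppressed most by surround content matching the center content, and
#' the rectifier blocks suppression from the orthogonal pathway.
#'
#' @param size input side length.
#' @param orientations two distinct filter orientations (degrees).
#' @param period carrier period of the oriented filters.
#' @param k1 oriented filter size (odd).
#' @param k2 center-surround kernel size (odd).
#' @param centerRadius radius of the +1 kernel center (pixels of the
#'   filter map).
#' @param surroundGain magnitude of the negative surround kernel weight.
#' @param w1,w2 readout weights.
#' @return list: `net`, `neuron` (readout center unit), `layer` names.
#' @export
buildToyConvModel <- function(size = 64L, orientations = c(0, 90),
                              period = 6, k1 = 9L, k2 = 15L,
                              centerRadius = 3.5, surroundGain = 0.4,
                              w1 = 1, w2 = 0.5) {
  stopifnot(length(orientations) == 2L,
            orientations[1] != orientations[2])
  ## stage 1: rectified quadrature pairs per orientation, so the oriented
  ## maps are non-negative and phase-robust
  W1 <- array(0, c(k1, k1, 3L, 4L))
  for (oi in 1:2) for (ph in 0:1) {
    g <- gaborKernel(k1, orientations[oi], period, phase = 90 * ph)
    W1[, , , 2L * (oi - 1L) + ph + 1L] <- rgbWeight(g / sqrt(sum(g^2)))[, , , 1]
  }
  xs <- seq_len(k2) - (k2 + 1) / 2
  rad <- sqrt(outer(xs^2, xs^2, "+"))
  cs <- matrix(-surroundGain, k2, k2)
  cs[rad <= centerRadius] <- 1
  W2 <- array(0, c(k2, k2, 4L, 2L))
  W2[, , 1, 1] <- cs; W2[, , 2, 1] <- cs
  W2[, , 3, 2] <- cs; W2[, , 4, 2] <- cs
  spec <- NetworkSpec(size, list(
    LayerSpec("oriented", "conv", k1, 1L, 4L),
    LayerSpec("halfwave", "relu", channels = 4L),
    LayerSpec("cs", "conv", k2, 1L, 2L),
    LayerSpec("rect", "relu", channels = 2L),
    LayerSpec("readout", "conv", 1L, 1L, 1L)))
  weights <- list(
    list(W = W1, b = rep(0, 4)),
    NULL,
    list(W = W2, b = c(0, 0)),
    NULL,
    list(W = array(c(w1, w2), c(1, 1, 2, 1)), b = 0))
  net <- Network(spec, weights)
  list(net = net, neuron = centerNeuron(spec, "readout"),
       orientations = orientations, period = period)
}

#' Analytic center-surround Gabor unit
#'
#' Two-stage single-neuron network with a planted preferred orientation,
#' period and center extent. Stage 1 is a rectified quadrature pair of
#' oriented Gabor subunits (even and odd phase), so subunit outputs are
#' non-negative and phase-robust; stage 2 pools them with weight +1
#' inside the center disc and `-surroundStrength` in the surrounding
#' ring. A grating confined to the surround therefore drives the
#' (rectified) unit to zero at every phase, surround suppression is
#' strongest at the planted orientation, and the diameter tuning curve
#' peaks at the planted center extent. Stage-2 weights are calibrated so
#' the phase-averaged response to the planted center grating is 1.
#'
#' @param size input side length.
#' @param orientation planted preferred orientation (degrees).
#' @param period planted spatial period (pixels).
#' @param centerDiameter planted excitatory extent (pixels).
#' @param surroundStrength positive weight magnitude of the inhibitory
#'   ring.
#' @param k1 subunit Gabor kernel size (odd).
#' @return list: `net`, `neuron` (the pooling unit, probed pre/post
#'   rectification), planted parameters.
#' @export
buildCenterSurroundGabor <- function(size = 64L, orientation = 45,
                                     period = 8, centerDiameter = 32,
                                     surroundStrength = 0.2, k1 = 9L) {
  ctr <- c(size / 2, size / 2)
  ge <- gaborKernel(k1, orientation, period, phase = 0)
  go <- gaborKernel(k1, orientation, period, phase = 90)
  nrm <- sqrt(sum(ge^2))
  W1 <- array(0, c(k1, k1, 3L, 2L))
  W1[, , , 1] <- rgbWeight(ge / nrm)[, , , 1]
  W1[, , , 2] <- rgbWeight(go / nrm)[, , , 1]
  pool <- matrix(0, size, size)
  cmask <- discMask(size, ctr, centerDiameter)
  smask <- annulusMask(size, ctr, centerDiameter, 2 * size)
  pool[cmask] <- 1
  pool[smask] <- -surroundStrength
  W2 <- array(0, c(size, size, 2L, 1L))
  W2[, , 1, 1] <- pool
  W2[, , 2, 1] <- pool
  spec <- NetworkSpec(size, list(
    LayerSpec("subunits", "conv", k1, 1L, 2L),
    LayerSpec("halfwave", "relu", channels = 2L),
    LayerSpec("unit", "conv", size, size, 1L),
    LayerSpec("rect", "relu")))
  net <- Network(spec, list(list(W = W1, b = c(0, 0)), NULL,
                            list(W = W2, b = 0), NULL))
  neuron <- NeuronAddress("unit")
  ## calibrate: phase-averaged response to the planted center grating = 1
  resp <- mean(vapply(phaseSet(8L), function(ph)
    probeResponse(net, neuron, renderGrating(
      GratingSpec(orientation, period, phase = ph,
                  diameter = centerDiameter, center = ctr), size)),
    numeric(1)))
  ## rebuild with calibrated weights (Network caches are tied to weights)
  net <- Network(spec, list(list(W = W1, b = c(0, 0)), NULL,
                            list(W = W2 / resp, b = 0), NULL))
  list(net = net, neuron = neuron,
       orientation = orientation, period = period,
       centerDiameter = centerDiameter, size = size)
}

#' Procedural structured texture source
#'
#' Seeded grayscale image with genuine higher-order structure: sparse
#' heavy-tailed impulses convolved with one or two elongated oriented
#' Gabor kernels (circularly, via the FFT), plus faint Gaussian noise.
#' Band-pass coefficients of such sparse-edge images are heavy-tailed
#' (kurtosis well above the Gaussian value of 3); phase randomization
#' Gaussianizes them.
#'
#' @param seed RNG seed.
#' @param size image side length.
#' @param config list: `density` of impulses (default 0.004),
#'   `nOrientations` (default 2), `period` (default 9), `lengthRatio`
#'   elongation of the kernels (default 3).
#' @return grayscale matrix in `[0, 1]`.
#' @export
generateProceduralTexture <- function(seed = 1L, size = 128L,
                                      config = list()) {
  density <- config$density %||% 0.004
  nOri <- config$nOrientations %||% 2L
  period <- config$period %||% 9
  lengthRatio <- config$lengthRatio %||% 3
  withSeed(seed, {
    img <- matrix(0, size, size)
    oris <- stats::runif(1) * 180 + (seq_len(nOri) - 1) * 180 / nOri
    for (ori in oris) {
      imp <- matrix(0, size, size)
      n <- max(4L, round(density * size^2))
      pos <- sample.int(size^2, n)
      imp[pos] <- sample(c(-1, 1), n, replace = TRUE) * stats::rexp(n)
      k <- 2L * floor(period) + 1L
      ker <- elongatedGabor(k, ori, period, lengthRatio)
      kerPad <- matrix(0, size, size)
      kerPad[seq_len(k), seq_len(k)] <- ker
      img <- img + Re(stats::fft(stats::fft(imp) * stats::fft(kerPad),
                                 inverse = TRUE)) / size^2
    }
    img <- img + matrix(stats::rnorm(size^2, sd = 0.02 * stats::sd(img)),
                        size)
    img <- img / (5 * stats::sd(img)) + 0.5
    pmin(pmax(img, 0), 1)
  })
}

elongatedGabor <- function(k, orientation, period, lengthRatio) {
  xs <- seq_len(k) - (k + 1) / 2
  X <- matrix(xs, k, k, byrow = TRUE)
  Y <- matrix(xs, k, k)
  th <- (orientation + 90) * pi / 180
  u <- X * cos(th) + Y * sin(th)          # across bars
  v <- -X * sin(th) + Y * cos(th)         # along bars
  su <- period / 4
  env <- exp(-(u^2 / (2 * su^2) + v^2 / (2 * (su * lengthRatio)^2)))
  g <- env * cos(2 * pi * u / period)
  g - env * sum(g) / sum(env)
}

#' Kurtosis of band-pass coefficients
#'
#' Convolves a grayscale image with a zero-mean isotropic band-pass
#' (difference-of-Gaussians) kernel and returns the kurtosis of the
#' coefficients. Gaussian-phase images give values near 3; sparse-edge
#' images give heavy tails well above 3.
#'
#' @param image grayscale matrix.
#' @param scale center-surround scale of the DoG in pixels.
#' @return kurtosis value.
#' @export
bandPassKurtosis <- function(image, scale = 2) {
  n <- nrow(image)
  k <- 4L * ceiling(scale) * 2L + 1L
  xs <- seq_len(k) - (k + 1) / 2
  r2 <- outer(xs^2, xs^2, "+")
  g1 <- exp(-r2 / (2 * scale^2)); g1 <- g1 / sum(g1)
  g2 <- exp(-r2 / (2 * (2 * scale)^2)); g2 <- g2 / sum(g2)
  dog <- g1 - g2
  kerPad <- matrix(0, n, n)
  kerPad[seq_len(k), seq_len(k)] <- dog
  co <- Re(stats::fft(stats::fft(image) * stats::fft(kerPad),
                      inverse = TRUE)) / n^2
  x <- as.vector(co)
  mean((x - mean(x))^4) / stats::var(x)^2
}

#' Fixture network registry
#'
#' Constructs named, fully self-contained fixture networks:
#' `"toy_conv"`, `"conceptual"`, `"gabor_cs"`, and `"random_conv"`.
#'
#' @param name fixture name.
#' @param seed seed for random-weight fixtures.
#' @return a list with at least `net` and `neuron`.
#' @export
fixtureNetwork <- function(name = c("toy_conv", "conceptual", "gabor_cs",
                                    "random_conv"), seed = 1L) {
  switch(match.arg(name),
    toy_conv = buildToyConvModel(),
    conceptual = {
      cm <- buildConceptualNetwork()
      list(net = cm$net, neuron = cm$neuron, fixture = cm)
    },
    gabor_cs = buildCenterSurroundGabor(),
    random_conv = {
      net <- buildRandomConvNet(list(c(7, 1), c(5, 2)), seed = seed)
      list(net = net, neuron = centerNeuron(net@spec, "conv2"))
    })
}
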