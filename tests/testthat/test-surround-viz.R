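test_that("spectral rendering is bounded, deterministic, and 1/f-weighted", {
  ## zero parameters render the squashing midpoint exactly
  p0 <- spectralParam(16, seed = 1, initSd = 0)
  expect_true(all(renderParam(p0)$image == 0.5))
  ## deterministic given parameters
  p <- spectralParam(16, seed = 4, initSd = 0.05)
  expect_identical(renderParam(p)$image, renderParam(p)$image)
  expect_true(all(renderParam(p)$image >= 0 & renderParam(p)$image <= 1))
  ## a low-frequency coefficient moves the image more than an equal
  ## high-frequency one
  bump <- function(i, j) {
    p2 <- p0
    p2$re[i, j, 1] <- 1
    sqrt(sum((renderParam(p2)$image - 0.5)^2))
  }
  expect_gt(bump(2, 1), bump(8, 8))
})

test_that("the spectral adjoint matches finite differences", {
  set.seed(31)
  n <- 12
  p <- spectralParam(n, seed = 31, initSd = 0.05)
  rp <- renderParam(p)
  g <- array(rnorm(n * n * 3), c(n, n, 3))
  gb <- surroundscope:::renderParamBackward(p, rp$pre, g)
  L <- function(pp) sum(g * renderParam(pp)$image)
  for (t in 1:4) {
    i <- sample(n, 1); j <- sample(n, 1); ch <- sample(3, 1)
    p2 <- p; p2$re[i, j, ch] <- p2$re[i, j, ch] + 1e-6
    expect_equal(gb$re[i, j, ch], (L(p2) - L(p)) / 1e-6, tolerance = 1e-4)
    p3 <- p; p3$im[i, j, ch] <- p3$im[i, j, ch] + 1e-6
    expect_equal(gb$im[i, j, ch], (L(p3) - L(p)) / 1e-6, tolerance = 1e-4)
  }
})

test_that("optimization respects masks and the zero-iteration contract", {
  cm <- cachedConceptual()
  cfg0 <- visConfig(iterations = 0L, seed = 9L, jitterMax = 0L)
  out <- optimizeCenter(cm$net, cm$neuron, cm$masks, cfg0)
  ## 0 iterations: the composite is the seeded initial render
  init <- surroundscope:::withSeed(9L, {
    pr <- list(re = array(rnorm(64^2 * 3, sd = cfg0$initSd), c(64, 64, 3)),
               im = array(rnorm(64^2 * 3, sd = cfg0$initSd), c(64, 64, 3)),
               scale = surroundscope:::freqScale(64), size = 64)
    class(pr) <- "spectralParam"
    renderParam(pr)$image
  })
  expect_identical(out$render, init)
  ## everything outside the optimized region is exactly gray
  cfg <- visConfig(iterations = 15L, seed = 9L, jitterMax = 0L)
  ctr <- optimizeCenter(cm$net, cm$neuron, cm$masks, cfg)
  outside <- !cm$masks$center
  for (ch in 1:3) expect_true(all(ctr$composite[, , ch][outside] == 0.5))
  sup <- optimizeSurround(cm$net, cm$neuron, ctr$composite, "suppressive",
                          cm$masks, cfg)
  for (ch in 1:3) {
    ## fixed center is carried over bit-identically
    expect_identical(sup$composite[, , ch][cm$masks$center],
                     ctr$composite[, , ch][cm$masks$center])
    expect_true(all(sup$composite[, , ch][cm$masks$gap] == 0.5))
  }
})

test_that("two-step visualization is bit-reproducible and flags no-op runs", {
  cm <- cachedConceptual()
  cfg <- visConfig(iterations = 20L, seed = 77L, jitterMax = 2L)
  v1 <- twoStepVisualize(cm$net, cm$neuron, masks = cm$masks, config = cfg)
  v2 <- twoStepVisualize(cm$net, cm$neuron, masks = cm$masks, config = cfg)
  expect_identical(v1@center, v2@center)
  expect_identical(v1@suppressive, v2@suppressive)
  expect_identical(v1@responses, v2@responses)
  v0 <- twoStepVisualize(cm$net, cm$neuron, masks = cm$masks,
                         config = visConfig(iterations = 0L, seed = 1L))
  expect_false(v0@converged)
})

test_that("the conceptual model's printed gains give the enumeration optimum", {
  model <- buildConceptualModel(w1 = 1, w2 = 0.5)
  ## closed-form arithmetic from the printed gains
  expect_equal(model$respond(c(1, 0)), 1)
  expect_equal(model$respond(c(1, 0), c(1, 0)), 0.2)   # matched surround
  expect_equal(model$respond(c(1, 0), c(0, 1)), 1)     # blocked by ReLU
  expect_equal(model$respond(c(0, 1)), 0.5)
  en <- enumerateConceptualModel(model, alpha = c(1, 0))
  best <- en[which.min(en$response), ]
  expect_equal(c(best$beta1, best$beta2), c(1, 0))
  expect_equal(best$response, 0.2)
  ## the matched pattern is the unique suppressive dimension: every
  ## minimizer saturates beta1 (the orthogonal mix is blocked by the
  ## rectifier and cannot deepen the optimum)
  mins <- en[en$response == min(en$response), ]
  expect_true(all(mins$beta1 == 1))
  ## the image-domain instantiation reproduces the closed form
  cm <- cachedConceptual()
  for (b in list(c(0, 0), c(1, 0), c(0, 1), c(0.5, 0.5))) {
    expect_equal(probeResponse(cm$net, cm$neuron,
                               conceptualStimulus(cm, c(1, 0), b), "pre"),
                 model$respond(c(1, 0), b), tolerance = 0.05)
  }
})

test_that("gradient visualization agrees with the enumeration oracle", {
  cm <- cachedConceptual()
  cfg <- visConfig(iterations = 250L, seed = 5L, jitterMax = 0L)
  vr <- twoStepVisualize(cm$net, cm$neuron, masks = cm$masks, config = cfg)
  r <- vr@responses
  expect_lt(r[["suppressive_pre"]], r[["center_pre"]])
  expect_gt(r[["facilitative_pre"]], r[["center_pre"]])
  ## suppressive surround dominated by the center's own pattern
  dp <- dominantPattern(vr@suppressive, cm$patterns, cm$masks$surround)
  expect_equal(dp$index, 1L)
  expect_gt(dp$projections[1], 0)   # in phase, not anti-phase
  ## exchanged center (pathway 2): the surround follows the new center
  ex <- exchangeCenter(conceptualStimulus(cm, alpha = c(0, 1)), cm$net,
                       cm$neuron, cm$masks,
                       config = visConfig(iterations = 250L, seed = 6L,
                                          jitterMax = 0L))
  dpe <- dominantPattern(ex$render, cm$patterns, cm$masks$surround)
  expect_equal(dpe$index, 2L)
  expect_gt(dpe$projections[2], 0)
  expect_lt(tail(ex$trace, 1), 0.5)  # suppressed below the center response
})

test_that("surround-insensitive units yield flat, flagged optimizations", {
  ## dense unit with zero connectivity beyond the center disc
  size <- 64
  ctr <- c(32, 32)
  pat <- surroundscope:::gratingField(GratingSpec(0, 8, center = ctr),
                                      size) * 2 - 1
  w <- array(0, c(size, size, 3, 1))
  cmask <- surroundscope:::discMask(size, ctr, 24)
  for (ch in 1:3) w[, , ch, 1][cmask] <- pat[cmask] / 3
  net <- denseLinearNet(w, size)
  neuron <- NeuronAddress("unit")
  geo <- rfGeometry(net@spec, "unit")
  masks <- buildMaskSet(geo, 24, size)
  cfg <- visConfig(iterations = 10L, seed = 3L, jitterMax = 0L)
  ctrOpt <- optimizeCenter(net, neuron, masks, cfg)
  sup <- optimizeSurround(net, neuron, ctrOpt$composite, "suppressive",
                          masks, cfg)
  fac <- optimizeSurround(net, neuron, ctrOpt$composite, "facilitative",
                          masks, cfg)
  rc <- probeResponse(net, neuron, ctrOpt$composite, "pre")
  expect_equal(probeResponse(net, neuron, sup$composite, "pre"), rc)
  expect_equal(probeResponse(net, neuron, fac$composite, "pre"), rc)
  expect_true(sup$failed)   # no gradient ever reached the surround
})

test_that("color permutations behave as a group action", {
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_identical(permuteCenterColors(img, 1:3), img)
  perm <- c(2, 3, 1)
  inv <- order(perm)
  expect_identical(permuteCenterColors(permuteCenterColors(img, perm),
                                       inv), img)
  gray <- array(rep(runif(64), 3), c(8, 8, 3))
  for (p in list(c(1, 3, 2), c(3, 2, 1), c(2, 1, 3)))
    expect_identical(permuteCenterColors(gray, p), gray)
})

test_that("exchanging a neuron's own center reproduces the standard pipeline", {
  cm <- cachedConceptual()
  cfg <- visConfig(iterations = 15L, seed = 21L, jitterMax = 0L)
  ctr <- optimizeCenter(cm$net, cm$neuron, cm$masks, cfg)
  direct <- optimizeSurround(cm$net, cm$neuron, ctr$composite,
                             "suppressive", cm$masks, cfg)
  ex <- exchangeCenter(ctr$composite, cm$net, cm$neuron, cm$masks,
                       config = cfg)
  expect_identical(ex$composite, direct$composite)
  ## a gray center reduces to surround-alone minimization
  exg <- exchangeCenter(grayCanvas(64), cm$net, cm$neuron, cm$masks,
                        config = cfg)
  expect_true(all(exg$composite[, , 1][cm$masks$center] == 0.5))
})
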