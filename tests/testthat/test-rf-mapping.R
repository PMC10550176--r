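mkDiamCurve <- function(values, responses)
  TuningCurve("diameter", values, responses, unit = "px")

test_that("grating summation field reads the 95% crossing", {
  cv <- mkDiamCurve(seq(10, 60, by = 10), c(0.2, 0.5, 0.8, 0.96, 1.0, 0.9))
  expect_equal(gratingSummationField(cv), 40)
  ## strictly increasing curve: first diameter reaching 95% of the final
  cv2 <- mkDiamCurve(1:10, seq(0.1, 1, by = 0.1))
  expect_equal(gratingSummationField(cv2), 10)  # 0.95 first reached at 1.0
  cv3 <- mkDiamCurve(1:20, seq(0.05, 1, by = 0.05))
  expect_equal(gratingSummationField(cv3), 19)  # 0.95 at the 19th step
  ## scale invariance
  cv4 <- mkDiamCurve(seq(10, 60, by = 10),
                     7.3 * c(0.2, 0.5, 0.8, 0.96, 1.0, 0.9))
  expect_equal(gratingSummationField(cv4), 40)
  expect_error(gratingSummationField(mkDiamCurve(1:3, c(0, 0, 0))),
               "undefined")
})

test_that("GSF matches the closed-form crossing of a ratio-of-Gaussians curve", {
  ## difference-of-integrated-Gaussians size tuning: R(d) propto
  ## erf-like growth of excitation minus broader inhibition
  ds <- seq(0, 60, by = 2)
  R <- function(d) (1 - exp(-(d / 20)^2)) - 0.3 * (1 - exp(-(d / 45)^2))
  cv <- mkDiamCurve(ds, R(ds))
  ## independent oracle: root-finding on the continuous closed form
  rmax <- stats::optimize(R, c(0, 60), maximum = TRUE)$objective
  root <- stats::uniroot(function(d) R(d) - 0.95 * rmax, c(1, 40))$root
  expect_lte(abs(gratingSummationField(cv) - root), 2)
})

test_that("suppression indices follow both printed conventions", {
  cv <- mkDiamCurve(1:5, c(0.2, 1.0, 0.8, 0.6, 0.4))
  expect_equal(suppressionIndex(cv, "peak_vs_largest"), 0.6)
  ## monotone non-decreasing curve has zero suppression
  expect_equal(suppressionIndex(mkDiamCurve(1:4, c(0.1, 0.2, 0.3, 0.3))),
               0)
  ## max-vs-min with the minimum restricted to the post-peak limb
  cv2 <- mkDiamCurve(1:3, c(0.1, 1.0, 0.3))
  expect_equal(suppressionIndex(cv2, "max_vs_min"), 0.7)
  ## the rising limb cannot inflate the texture-convention index
  cv3 <- mkDiamCurve(1:4, c(0.01, 1.0, 0.9, 0.9))
  expect_equal(suppressionIndex(cv3, "max_vs_min"), 0.1, tolerance = 1e-9)
  ## bounded in [0, 1] and zero iff no post-peak decline
  set.seed(42)
  for (i in 1:50) {
    r <- runif(8)
    cv4 <- mkDiamCurve(1:8, r)
    for (conv in c("peak_vs_largest", "max_vs_min")) {
      si <- suppressionIndex(cv4, conv)
      expect_gte(si, 0); expect_lte(si, 1)
    }
    declines <- any(r[which.max(r):8] < max(r))
    expect_identical(suppressionIndex(cv4, "max_vs_min") > 0, declines)
  }
})

test_that("selection criteria implement the GSF and variation gates", {
  geo <- new("RFGeometry", layer = "l", r = 100, j = 1, mapSize = 10L,
             displacement = c(0, 0), stimulusCenter = c(32, 32))
  flat <- TuningCurve("orientation", seq(0, 165, 15), rep(0.5, 12),
                      cyclic = TRUE)
  varying <- TuningCurve("orientation", seq(0, 165, 15),
                         seq(0, 1.1, by = 0.1), cyclic = TRUE)
  ok <- selectNeuron(geo, gsf = 50, varying, varying)
  expect_true(ok$included)
  ## GSF bounds at 30% and 70% of r
  expect_false(selectNeuron(geo, 20, varying, varying)$included)
  expect_false(selectNeuron(geo, 80, varying, varying)$included)
  expect_true(selectNeuron(geo, 30, varying, varying)$gsfFractionOk)
  ## flat curves are silent
  expect_false(selectNeuron(geo, 50, flat, flat)$included)
  ## 'any' passes when one curve varies; 'all' requires both
  expect_true(selectNeuron(geo, 50, varying, flat)$included)
  expect_false(selectNeuron(geo, 50, varying, flat,
                            variationRule = "all")$included)
})

test_that("grid search recovers planted grating parameters", {
  gb <- cachedGabor()
  grid <- list(sizes = 0.5, periods = c(4, 6, 8, 10, 12, 16),
               orientations = seq(0, 165, by = 15), nPhases = 4L)
  opt <- gridSearchOptimal(gb$net, gb$neuron, gb$geometry, grid)
  expect_false(opt$silent)
  expect_lte(min(abs(opt$orientation - gb$orientation),
                 180 - abs(opt$orientation - gb$orientation)), 15)
  expect_lte(abs(opt$period - gb$period), 2)
})

test_that("a silent neuron is flagged with first-cell parameters", {
  spec <- NetworkSpec(32, list(LayerSpec("c", "conv", 32, 32, 1),
                               LayerSpec("r", "relu")))
  zero <- Network(spec, list(list(W = array(0, c(32, 32, 3, 1)), b = 0),
                             NULL))
  geo <- rfGeometry(spec, "c")
  grid <- list(sizes = c(0.5, 0.7), periods = c(6, 8),
               orientations = c(0, 90), nPhases = 2L)
  opt <- gridSearchOptimal(zero, NeuronAddress("c"), geo, grid)
  expect_true(opt$silent)
  expect_equal(opt$orientation, 0)
  expect_equal(opt$period, 6)
  expect_equal(opt$sizeFraction, 0.5)
})

test_that("with two subunits of unequal gain the stronger one wins the search", {
  size <- 32
  ctr <- c(16, 16)
  p1 <- surroundscope:::gratingField(GratingSpec(0, 8, center = ctr),
                                     size) * 2 - 1
  p2 <- surroundscope:::gratingField(GratingSpec(90, 8, center = ctr),
                                     size) * 2 - 1
  w <- array(0, c(size, size, 3, 1))
  for (ch in 1:3) w[, , ch, 1] <- (1.0 * p1 + 0.4 * p2) / 3
  net <- denseLinearNet(w, size)
  geo <- rfGeometry(net@spec, "unit")
  grid <- list(sizes = 0.9, periods = 8,
               orientations = seq(0, 165, by = 15), nPhases = 8L)
  opt <- gridSearchOptimal(net, NeuronAddress("unit"), geo, grid)
  expect_equal(opt$orientation, 0)
})

test_that("an independently coded evaluator agrees on the argmax", {
  ## direct inner-product evaluation of rectified dense linear units,
  ## sharing nothing with the engine's forward pass
  size <- 24
  grid <- list(sizes = 0.8, periods = c(6, 10),
               orientations = seq(0, 150, by = 30), nPhases = 4L)
  for (seed in 1:20) {
    set.seed(seed + 100)
    w <- array(rnorm(size * size * 3), c(size, size, 3, 1))
    net <- denseLinearNet(w, size)
    geo <- rfGeometry(net@spec, "unit")
    opt <- gridSearchOptimal(net, NeuronAddress("unit"), geo, grid)
    best <- NULL; bestR <- -Inf
    for (pd in grid$periods) for (ori in grid$orientations) {
      resp <- mean(vapply(phaseSet(grid$nPhases), function(ph) {
        img <- renderGrating(GratingSpec(ori, pd, phase = ph,
                                         diameter = 0.8 * geo@r,
                                         center = geo@stimulusCenter),
                             size)
        max(0, sum((img - 0.5) * w[, , , 1]))
      }, numeric(1)))
      if (resp > bestR + 1e-12) {
        bestR <- resp; best <- c(pd, ori)
      }
    }
    expect_equal(c(opt$period, opt$orientation), best)
  }
})

test_that("diameter tuning reflects the unit's spatial pooling", {
  ## gray input at diameter 0 for balanced units
  gb <- cachedGabor()
  expect_equal(gb$diameterCurve@responses[1], 0)
  ## all-positive pooling gives a non-decreasing curve
  size <- 32
  w <- array(1 / (3 * size^2), c(size, size, 3, 1))
  spec <- NetworkSpec(size, list(LayerSpec("u", "conv", size, size, 1)))
  net <- Network(spec, list(list(W = w, b = 0)), "identity")
  geo <- rfGeometry(spec, "u")
  opt <- list(orientation = 0, period = 64)  # near-DC bright disc
  cv <- diameterTuning(net, NeuronAddress("u"), opt, geo,
                       diameters = seq(0, 32, by = 4), nPhases = 1L)
  expect_true(all(diff(cv@responses) >= -1e-12))
  ## center-surround pooling rises then falls
  r <- gb$diameterCurve@responses
  pk <- which.max(r)
  expect_gt(pk, 1)
  expect_lt(pk, length(r))
  expect_true(all(diff(r[1:pk]) >= -1e-9))
  expect_lt(r[length(r)], r[pk])
})

test_that("mapReceptiveField assembles a coherent record", {
  gb <- cachedGabor()
  grid <- list(sizes = 0.5, periods = c(6, 8, 10),
               orientations = seq(0, 165, by = 45), nPhases = 2L)
  rec <- mapReceptiveField(gb$net, "unit", grid = grid)
  expect_false(rec$silent)
  expect_equal(rec$optimal$orientation, 45)
  expect_true(rec$gsf >= 0.3 * rec$geometry@r &
                rec$gsf <= 0.7 * rec$geometry@r)
  expect_gte(rec$si, 0)
})
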