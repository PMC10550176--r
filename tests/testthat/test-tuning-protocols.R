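oriCurve <- function(responses, values = seq(0, 165, by = 15))
  TuningCurve("orientation", values, responses, unit = "deg",
              cyclic = TRUE)

test_that("tuning-curve correlation is plain Pearson with NA degeneracy", {
  a <- oriCurve(c(1, 2, 3), values = c(0, 60, 120))
  b <- oriCurve(c(3, 1, 2), values = c(0, 60, 120))
  ## independent oracle: direct Pearson formula
  x <- c(1, 2, 3); y <- c(3, 1, 2)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(tuningCurveCorrelation(a, b), hand)
  expect_equal(hand, -0.5)
  ## affine anti-relation and identity
  supp <- oriCurve(1 - 0.4 * seq(0, 1.1, by = 0.1))
  cen <- oriCurve(seq(0, 1.1, by = 0.1))
  expect_equal(tuningCurveCorrelation(cen, supp), -1)
  expect_equal(tuningCurveCorrelation(cen, cen), 1)
  expect_true(is.na(tuningCurveCorrelation(cen, oriCurve(rep(1, 12)))))
})

test_that("circular variance hits its analytic calibration points", {
  imp <- oriCurve(c(1, rep(0, 11)))
  expect_equal(circularVariance(imp), 0)
  expect_equal(circularVariance(oriCurve(rep(0.7, 12))), 1)
  ## two equal peaks 90 degrees apart cancel on the doubled circle
  two <- oriCurve(c(1, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0))
  expect_equal(circularVariance(two), 1)
  expect_true(is.na(circularVariance(oriCurve(rep(0, 12)))))
  ## negative responses are clipped before the vector sum
  neg <- oriCurve(c(1, rep(-5, 11)))
  expect_equal(circularVariance(neg), 0)
})

test_that("orientation deviation wraps into (-90, 90]", {
  dip <- function(at) oriCurve(1 - 0.5 * (seq(0, 165, 15) == at))
  expect_equal(orientationDeviation(dip(45), 45), 0)
  ## minimum 100 degrees above the center wraps to -80
  expect_equal(orientationDeviation(dip(150), 50), -80)
  expect_equal(orientationDeviation(dip(120), 30), 90)
  expect_true(is.na(orientationDeviation(oriCurve(rep(1, 12)), 0)))
})

test_that("repeated-measures ANOVA matches textbook sums of squares", {
  ## 3 subjects x 4 conditions with a planted condition effect
  y <- c(1.0, 1.2, 0.9, 2.0, 2.1, 1.8, 1.5, 1.4, 1.6, 1.1, 1.0, 1.2)
  subject <- rep(1:3, times = 4)
  cond <- rep(1:4, each = 3)
  out <- rmAnova(y, subject, cond)
  ## hand computation of the univariate decomposition
  gm <- mean(y)
  ssCond <- 3 * sum((tapply(y, cond, mean) - gm)^2)
  ssSubj <- 4 * sum((tapply(y, subject, mean) - gm)^2)
  ssTot <- sum((y - gm)^2)
  ssErr <- ssTot - ssCond - ssSubj
  Fhand <- (ssCond / 3) / (ssErr / 6)
  expect_equal(out$F, Fhand, tolerance = 1e-10)
  expect_equal(out$df, c(3, 6))
  expect_equal(out$p, stats::pf(Fhand, 3, 6, lower.tail = FALSE),
               tolerance = 1e-10)
  ## fully degenerate table
  out0 <- rmAnova(rep(1, 12), subject, cond)
  expect_equal(out0$F, 0)
  expect_equal(out0$p, 1)
})

test_that("contrast-model fits recover planted parameters", {
  Rc <- seq(0.05, 1, length.out = 12)
  ## subtractive ground truth
  fitS <- fitContrastModels(Rc, pmax(0, Rc - 0.3))
  expect_lt(abs(fitS$a - 0.3), 1e-3)
  expect_lt(fitS$mseSubtractive, 1e-8)
  expect_gt(fitS$mseDivisive, fitS$mseSubtractive)
  ## divisive ground truth
  fitD <- fitContrastModels(Rc, Rc / 2)
  expect_lt(abs(fitD$b - 2), 1e-3)
  expect_lt(fitD$mseDivisive, 1e-10)
  expect_gt(fitD$mseSubtractive, fitD$mseDivisive)
  ## identity: a = 0, b = 1, both exact
  fitI <- fitContrastModels(Rc, Rc)
  expect_lt(abs(fitI$a), 1e-6)
  expect_equal(fitI$b, 1, tolerance = 1e-9)
  expect_lt(fitI$mseSubtractive, 1e-12)
  expect_lt(fitI$mseDivisive, 1e-12)
  ## fully suppressed: a = max(Rc), divisive flagged
  fit0 <- fitContrastModels(Rc, rep(0, 12))
  expect_equal(fit0$a, max(Rc))
  expect_true(fit0$illPosedDivisive)
})

test_that("the generating contrast model wins under noise", {
  set.seed(99)
  Rc <- seq(0.05, 1, length.out = 12)
  wins <- 0; n <- 60
  for (i in seq_len(n)) {
    truthSub <- i %% 2 == 0
    Rs <- if (truthSub) pmax(0, Rc - 0.25) else Rc / 1.8
    Rs <- pmax(0, Rs + rnorm(12, sd = 0.05 * max(Rc)))
    fit <- fitContrastModels(Rc, Rs)
    won <- if (truthSub) fit$mseSubtractive < fit$mseDivisive
           else fit$mseDivisive < fit$mseSubtractive
    wins <- wins + won
  }
  expect_gte(wins / n, 0.95)
})

test_that("zero-contrast surrounds leave the suppression curve at one", {
  gb <- cachedGabor()
  base <- surroundscope:::csResponse(gb$net, gb$neuron, gb$optimal,
                                     gb$geometry, gb$gsf,
                                     thC = gb$orientation, nPhases = 4L)
  for (thS in c(0, 45, 120)) {
    withS <- surroundscope:::csResponse(gb$net, gb$neuron, gb$optimal,
                                        gb$geometry, gb$gsf,
                                        thC = gb$orientation, thS = thS,
                                        nPhases = 4L,
                                        surroundContrast = 0)
    expect_equal(withS / base, 1, tolerance = 1e-12)
  }
})

test_that("the orientation triplet shows the surround-suppression signature", {
  gb <- cachedGabor()
  tri <- orientationTriplet(gb$net, gb$neuron, gb$optimal, gb$geometry,
                            gb$gsf, nPhases = 4L)
  ## suppression deepest at the planted orientation
  expect_equal(orientationDeviation(tri$suppression, gb$orientation), 0)
  ## surround alone is quiet
  expect_lt(max(tri$surround@responses), 0.01)
  ## anti-correlation between center tuning and suppression tuning
  expect_lt(tuningCurveCorrelation(tri$center, tri$suppression), 0)
  ## normalization: center curve is 1 at the planted orientation
  expect_equal(tri$center@responses[tri$center@values == gb$orientation],
               1, tolerance = 1e-9)
})

test_that("normalized protocol outputs ignore readout gain", {
  gb <- cachedGabor()
  w <- gb$net@weights
  w$unit$W <- w$unit$W * 3.7
  scaled <- Network(gb$net@spec, w)
  tri1 <- orientationTriplet(gb$net, gb$neuron, gb$optimal, gb$geometry,
                             gb$gsf, nPhases = 2L)
  tri2 <- orientationTriplet(scaled, gb$neuron, gb$optimal, gb$geometry,
                             gb$gsf, nPhases = 2L)
  expect_equal(tri1$center@responses, tri2$center@responses,
               tolerance = 1e-10)
  expect_equal(tri1$suppression@responses, tri2$suppression@responses,
               tolerance = 1e-10)
})

test_that("heatmap diagonal carries the row minima on the toy model", {
  toy <- cachedToy()
  oris <- c(0, 45, 90, 135)
  hm <- centerSurroundHeatmap(toy$net, toy$neuron, toy$optimal,
                              toy$geometry, toy$gsf,
                              centerOrientations = oris,
                              surroundOrientations = oris, nPhases = 2L)
  for (i in seq_along(oris))
    expect_equal(hm[i, i], min(hm[i, ]), tolerance = 1e-9)
})

test_that("offset-center suppression follows the center orientation", {
  toy <- cachedToy()
  off <- offsetCenterProtocol(toy$net, toy$neuron, toy$optimal,
                              toy$geometry, toy$gsf,
                              offsets = c(0, 45, 90), nPhases = 4L)
  ## the oblique center drives neither pathway: flagged and skipped
  expect_identical(off$skipped, c(FALSE, TRUE, FALSE))
  expect_null(off$curves[[2]])
  for (i in c(1L, 3L)) {
    cv <- off$curves[[i]]
    matched <- (toy$optimal$orientation + c(0, 45, 90)[i]) %% 180
    atMatched <- cv@responses[cv@values == matched]
    expect_equal(atMatched, min(cv@responses), tolerance = 1e-9)
  }
  ## offset 0 equals the triplet's suppression curve (same stimuli)
  tri <- orientationTriplet(toy$net, toy$neuron, toy$optimal,
                            toy$geometry, toy$gsf, nPhases = 4L)
  expect_equal(off$curves[["0"]]@responses, tri$suppression@responses,
               tolerance = 1e-10)
})

test_that("geometry protocol runs the patch ANOVA end to end", {
  gb <- cachedGabor()
  recs <- list(list(neuron = gb$neuron, optimal = gb$optimal,
                    geometry = gb$geometry, gsf = gb$gsf),
               list(neuron = gb$neuron, optimal = gb$optimal,
                    geometry = gb$geometry, gsf = gb$gsf))
  out <- geometryProtocol(gb$net, recs, patchAngles = c(0, 90),
                          surroundOrientations = "preferred",
                          nPhases = 2L)
  expect_equal(nrow(out$responses), 4L)
  ## identical neurons: no residual variance; the protocol degenerates
  ## to F = 0 only if the angle effect is also zero, otherwise p is tiny
  expect_true(is.finite(out$anova$preferred$F) ||
                is.na(out$anova$preferred$F))
  expect_error(geometryProtocol(gb$net, recs, patchAngles = 0),
               "at least 2")
})

test_that("contrast peak shift is zero for contrast-scaling units", {
  ## rectified dense unit with non-negative weights: response scales
  ## linearly with contrast, so the argmax diameter cannot move
  size <- 32
  w <- array(0, c(size, size, 3, 1))
  cmask <- surroundscope:::discMask(size, c(16, 16), 20)
  for (ch in 1:3) w[, , ch, 1][cmask] <- 1 / (3 * sum(cmask))
  net <- Network(NetworkSpec(size, list(
    LayerSpec("u", "conv", size, size, 1), LayerSpec("r", "relu"))),
    list(list(W = w, b = 0), NULL))
  geo <- rfGeometry(net@spec, "u")
  opt <- list(orientation = 0, period = 64)
  out <- contrastPeakShift(net, NeuronAddress("u"), opt, geo,
                           diameters = seq(0, 30, by = 2), nPhases = 2L)
  expect_equal(out$shift, 0)
  expect_equal(out$low@responses / 0.17, out$high@responses,
               tolerance = 1e-9)
})

test_that("matched surrounds matter less at low center contrast", {
  gb <- cachedGabor()
  cmp <- surroundContrastComparison(gb$net, gb$neuron, gb$optimal,
                                    gb$geometry, gb$gsf, nPhases = 4L)
  expect_equal(cmp$contrast, c(1, 0.17))
  ## orthogonal-minus-preferred difference shrinks at 17% contrast
  expect_gt(cmp$difference[1], cmp$difference[2])
  expect_gt(cmp$difference[1], 0)
})
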