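## Shared fixtures, built once per test run (construction is cheap; the
## cache mainly avoids re-running grid searches).

.fx <- new.env(parent = emptyenv())

cachedGabor <- function() {
  if (is.null(.fx$gabor)) {
    gb <- buildCenterSurroundGabor()
    gb$geometry <- rfGeometry(gb$net@spec, "unit")
    gb$optimal <- list(orientation = gb$orientation, period = gb$period)
    curve <- diameterTuning(gb$net, gb$neuron, gb$optimal, gb$geometry,
                            nPhases = 4L)
    gb$diameterCurve <- curve
    gb$gsf <- gratingSummationField(curve)
    .fx$gabor <- gb
  }
  .fx$gabor
}

cachedToy <- function() {
  if (is.null(.fx$toy)) {
    toy <- buildToyConvModel()
    toy$geometry <- rfGeometry(toy$net@spec, "readout")
    toy$optimal <- list(orientation = toy$orientations[1],
                        period = toy$period)
    toy$gsf <- 12
    .fx$toy <- toy
  }
  .fx$toy
}

cachedConceptual <- function() {
  if (is.null(.fx$conceptual)) .fx$conceptual <- buildConceptualNetwork()
  .fx$conceptual
}

## single dense linear unit + rectifier with an arbitrary weight field
denseLinearNet <- function(w, size = dim(w)[1]) {
  spec <- NetworkSpec(size, list(
    LayerSpec("unit", "conv", size, size, 1L),
    LayerSpec("rect", "relu")))
  Network(spec, list(list(W = w, b = 0), NULL))
}
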