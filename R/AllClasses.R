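#' @import methods
NULL

## Central S4 containers. Images are plain numeric arrays dim c(h, w, 3)
## with values in [0, 1] and mid-gray at 0.5; pixel i spans the continuous
## interval [i-1, i] so an image of side n has its center at n/2.

#' Single layer of a feedforward network
#'
#' Describes one layer of a feedforward convolutional network by its kind
#' and spatial geometry. `kernel` and `stride` are expressed in units of
#' the previous layer's feature map. Elementwise kinds (`"relu"`, `"norm"`)
#' always have kernel = stride = 1; `"dense"` layers carry no spatial
#' geometry and are rejected by the receptive-field operations.
#'
#' @slot name unique layer identifier.
#' @slot kind one of `"conv"`, `"pool"`, `"relu"`, `"norm"`, `"dense"`.
#' @slot kernel kernel size (pixels of the previous layer).
#' @slot stride stride (pixels of the previous layer).
#' @slot channels number of output channels.
#' @export
setClass("LayerSpec",
  representation(name = "character", kind = "character",
                 kernel = "integer", stride = "integer",
                 channels = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "layer must have a non-empty name")
    if (!object@kind %in% c("conv", "pool", "relu", "norm", "dense"))
      msg <- c(msg, sprintf("unknown layer kind '%s'", object@kind))
    if (object@kind %in% c("conv", "pool")) {
      if (object@kernel < 1L) msg <- c(msg, "kernel size must be >= 1")
      if (object@stride < 1L) msg <- c(msg, "stride must be >= 1")
    }
    if (object@kind %in% c("relu", "norm") &&
        (object@kernel != 1L || object@stride != 1L))
      msg <- c(msg, "elementwise layers must have kernel = stride = 1")
    if (length(msg)) msg else TRUE
  })

#' @describeIn LayerSpec constructor.
#' @param name,kind,kernel,stride,channels see slots.
#' @export
LayerSpec <- function(name, kind, kernel = 1L, stride = 1L, channels = 1L) {
  new("LayerSpec", name = as.character(name), kind = match.arg(kind,
        c("conv", "pool", "relu", "norm", "dense")),
      kernel = as.integer(kernel), stride = as.integer(stride),
      channels = as.integer(channels))
}

#' Network architecture description
#'
#' Ordered layer list plus the input raster geometry, mirroring the usual
#' tabular notation (kind, kernel, stride, channels per row). Square inputs
#' only; spatial dimensions must stay positive through all spatial layers.
#'
#' @slot inputSize input height = width in pixels.
#' @slot inputChannels number of input channels (3 for RGB stimuli).
#' @slot layers list of [LayerSpec] objects with unique names.
#' @export
setClass("NetworkSpec",
  representation(inputSize = "integer", inputChannels = "integer",
                 layers = "list"),
  validity = function(object) {
    msg <- character()
    if (object@inputSize < 1L) msg <- c(msg, "input size must be positive")
    nms <- vapply(object@layers, function(l) l@name, character(1))
    if (anyDuplicated(nms)) msg <- c(msg, "layer names must be unique")
    sz <- object@inputSize
    for (l in object@layers) {
      if (!is(l, "LayerSpec")) { msg <- c(msg, "layers must be LayerSpec"); break }
      if (l@kind %in% c("conv", "pool")) {
        sz <- convOutSize(sz, l@kernel, l@stride)
        if (sz < 1L) {
          msg <- c(msg, sprintf("feature map vanishes at layer '%s'", l@name))
          break
        }
      }
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn NetworkSpec constructor.
#' @param inputSize,inputChannels,layers see slots.
#' @export
NetworkSpec <- function(inputSize, layers, inputChannels = 3L) {
  new("NetworkSpec", inputSize = as.integer(inputSize),
      inputChannels = as.integer(inputChannels), layers = layers)
}

#' Weighted network instance
#'
#' A [NetworkSpec] together with layer weights and a per-network input
#' transform. Conv layers carry `list(W = array(k, k, inC, outC),
#' b = numeric(outC))`; pool layers `list(op = "avg" | "max")`; norm layers
#' an inference-mode channelwise affine `list(scale, shift)`; relu layers
#' need no weights. The adapter contract is: forward pass to any layer and
#' gradients of any unit with respect to the input.
#'
#' @slot spec the [NetworkSpec].
#' @slot weights named list parallel to `spec@layers`.
#' @slot inputTransform `"identity"` or `"center"` (subtract 0.5), applied
#'   before the first layer so stimuli can stay on the canonical
#'   `[0, 1]` / gray = 0.5 scale.
#' @slot cache internal environment memoizing im2col index maps.
#' @export
setClass("Network",
  representation(spec = "NetworkSpec", weights = "list",
                 inputTransform = "character", cache = "environment"))

#' @describeIn Network constructor.
#' @param spec,weights,inputTransform see slots.
#' @export
Network <- function(spec, weights, inputTransform = "center") {
  stopifnot(length(weights) == length(spec@layers))
  names(weights) <- layerNames(spec)
  new("Network", spec = spec, weights = weights,
      inputTransform = match.arg(inputTransform, c("center", "identity")),
      cache = new.env(parent = emptyenv()))
}

#' Address of a single unit on a feature map
#'
#' @slot layer layer name.
#' @slot channel channel index (1-based).
#' @slot row,col spatial position on that layer's feature map (1-based).
#' @export
setClass("NeuronAddress",
  representation(layer = "character", channel = "integer",
                 row = "integer", col = "integer"))

#' @describeIn NeuronAddress constructor.
#' @param layer,channel,row,col see slots.
#' @export
NeuronAddress <- function(layer, channel = 1L, row = 1L, col = 1L) {
  new("NeuronAddress", layer = as.character(layer),
      channel = as.integer(channel), row = as.integer(row),
      col = as.integer(col))
}

#' Theoretical receptive-field geometry of a unit
#'
#' Derived quantities of the kernel/stride recursion: receptive-field side
#' `r`, jump `j` (input-pixel distance between adjacent units of the map),
#' the per-axis displacement of the map-center unit's true center from the
#' image center, and the resulting continuous stimulus center coordinate.
#'
#' @slot layer layer the geometry refers to.
#' @slot r theoretical receptive-field size in pixels.
#' @slot j jump size in pixels.
#' @slot mapSize feature-map side length at that layer.
#' @slot displacement per-axis offset (pixels, real-valued, kept fractional).
#' @slot stimulusCenter continuous (x, y) pixel coordinate for stimulus
#'   placement.
#' @export
setClass("RFGeometry",
  representation(layer = "character", r = "numeric", j = "numeric",
                 mapSize = "integer", displacement = "numeric",
                 stimulusCenter = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@r < 1) msg <- c(msg, "r must be >= 1")
    if (object@j < 1) msg <- c(msg, "j must be >= 1")
    if (length(object@stimulusCenter) != 2L)
      msg <- c(msg, "stimulusCenter must have length 2")
    if (length(msg)) msg else TRUE
  })

#' Parametric grating description
#'
#' A sinusoidal luminance grating confined to a disc:
#' `L(x, y) = 0.5 + 0.5 c sin(2 pi ((x - x0) cos t + (y - y0) sin t) / lambda + phi)`
#' with gray (0.5) outside the disc.
#'
#' @slot orientation degrees in `[0, 180)`.
#' @slot period spatial period lambda in pixels (reciprocal of spatial
#'   frequency).
#' @slot phase degrees.
#' @slot contrast fraction of the full pixel range, in `[0, 1]`.
#' @slot diameter disc diameter in pixels (0 renders nothing).
#' @slot center continuous (x, y) pixel coordinates of the disc center.
#' @export
setClass("GratingSpec",
  representation(orientation = "numeric", period = "numeric",
                 phase = "numeric", contrast = "numeric",
                 diameter = "numeric", center = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@period <= 0) msg <- c(msg, "spatial period must be positive")
    if (object@diameter < 0) msg <- c(msg, "diameter must be >= 0")
    if (object@contrast < 0 || object@contrast > 1)
      msg <- c(msg, "contrast must lie in [0, 1]")
    if (length(object@center) != 2L) msg <- c(msg, "center must be (x, y)")
    if (length(msg)) msg else TRUE
  })

#' @describeIn GratingSpec constructor.
#' @param orientation,period,phase,contrast,diameter,center see slots.
#' @export
GratingSpec <- function(orientation, period, phase = 0, contrast = 1,
                        diameter = Inf, center = c(0, 0)) {
  o <- orientation %% 360
  if (o >= 180) {            # theta + 180 with negated phase is identical
    o <- o - 180
    phase <- -phase
  }
  new("GratingSpec", orientation = o, period = period,
      phase = phase, contrast = contrast, diameter = diameter,
      center = as.numeric(center))
}

#' Parametric surround description
#'
#' Either a full annulus or a diametrically opposite two-patch arrangement.
#' For `two_patch`, patch centers sit on the circle of radius
#' `(inner + outer) / 4` (the middle of the surround ring) at absolute angle
#' `patchAngle` measured relative to the center grating orientation.
#'
#' @slot form `"annulus"` or `"two_patch"`.
#' @slot innerDiameter,outerDiameter pixels, inner <= outer.
#' @slot grating the [GratingSpec] carried into the surround region.
#' @slot patchAngle degrees (two_patch only).
#' @slot patchDiameter pixels (two_patch only; defaults to the ring width).
#' @export
setClass("SurroundSpec",
  representation(form = "character", innerDiameter = "numeric",
                 outerDiameter = "numeric", grating = "GratingSpec",
                 patchAngle = "numeric", patchDiameter = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@form %in% c("annulus", "two_patch"))
      msg <- c(msg, "form must be 'annulus' or 'two_patch'")
    if (object@innerDiameter > object@outerDiameter)
      msg <- c(msg, "inner diameter must not exceed outer diameter")
    if (length(msg)) msg else TRUE
  })

#' @describeIn SurroundSpec constructor.
#' @param form,innerDiameter,outerDiameter,grating,patchAngle,patchDiameter
#'   see slots.
#' @export
SurroundSpec <- function(grating, innerDiameter, outerDiameter,
                         form = "annulus", patchAngle = 0,
                         patchDiameter = NULL) {
  if (is.null(patchDiameter))
    patchDiameter <- (outerDiameter - innerDiameter) / 2
  new("SurroundSpec", form = match.arg(form, c("annulus", "two_patch")),
      innerDiameter = innerDiameter, outerDiameter = outerDiameter,
      grating = grating, patchAngle = patchAngle,
      patchDiameter = patchDiameter)
}

#' Ordered (parameter, response) samples of a tuning protocol
#'
#' @slot parameter name of the swept stimulus parameter.
#' @slot unit unit of the parameter (`"px"`, `"deg"`, ...).
#' @slot values parameter values (strictly increasing for diameter curves,
#'   cyclic with period 180 for orientation curves).
#' @slot responses response per value.
#' @slot normalization `"none"`, `"by_optimal_center"` or `"by_max"`.
#' @slot cyclic whether the parameter is an orientation (period 180 deg).
#' @export
setClass("TuningCurve",
  representation(parameter = "character", unit = "character",
                 values = "numeric", responses = "numeric",
                 normalization = "character", cyclic = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@values) != length(object@responses))
      msg <- c(msg, "values and responses must have equal length")
    if (!object@cyclic && is.unsorted(object@values, strictly = TRUE))
      msg <- c(msg, "non-cyclic parameter values must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' @describeIn TuningCurve constructor.
#' @param parameter,values,responses,unit,normalization,cyclic see slots.
#' @export
TuningCurve <- function(parameter, values, responses, unit = "",
                        normalization = "none", cyclic = FALSE) {
  new("TuningCurve", parameter = parameter, unit = unit,
      values = as.numeric(values), responses = as.numeric(responses),
      normalization = match.arg(normalization,
        c("none", "by_optimal_center", "by_max")), cyclic = cyclic)
}

#' Two-step visualization result bundle
#'
#' @slot center most facilitative center image (h x w x 3 array).
#' @slot suppressive most suppressive surround image.
#' @slot facilitative most facilitative surround image.
#' @slot responses named numeric vector: `center_pre`, `center_post`,
#'   `suppressive_pre`, `suppressive_post`, `facilitative_pre`,
#'   `facilitative_post` (composite responses at both stages).
#' @slot trace list of per-step objective traces for the three
#'   optimizations.
#' @slot converged logical flag (FALSE when run with 0 iterations or when
#'   the optimizer saw no gradient).
#' @slot seed integer seed the run was keyed on.
#' @slot config the resolved visualization configuration.
#' @export
setClass("VisResult",
  representation(center = "array", suppressive = "array",
                 facilitative = "array", responses = "numeric",
                 trace = "list", converged = "logical", seed = "integer",
                 config = "list"))

## ---- accessors -------------------------------------------------------

#' Accessors for the central containers
#'
#' @param x object.
#' @return `layerNames` the layer identifiers; `rfSize`/`jumpSize`/
#'   `stimulusCenter` the receptive-field quantities; `responses` and
#'   `parameterValues` the tuning-curve samples.
#' @name accessors
NULL

#' @rdname accessors
#' @export
layerNames <- function(x) {
  spec <- if (is(x, "Network")) x@spec else x
  vapply(spec@layers, function(l) l@name, character(1))
}

#' @rdname accessors
#' @export
rfSize <- function(x) x@r

#' @rdname accessors
#' @export
jumpSize <- function(x) x@j

#' @rdname accessors
#' @export
stimulusCenter <- function(x) x@stimulusCenter

#' @rdname accessors
#' @export
responses <- function(x) x@responses

#' @rdname accessors
#' @export
parameterValues <- function(x) x@values

## ---- show methods ----------------------------------------------------

setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf("NetworkSpec: %dx%dx%d input, %d layers\n",
              object@inputSize, object@inputSize, object@inputChannels,
              length(object@layers)))
  for (l in object@layers)
    cat(sprintf("  %-12s %-5s k=%d s=%d ch=%d\n", l@name, l@kind,
                l@kernel, l@stride, l@channels))
})

setMethod("show", "Network", function(object) {
  cat("Weighted ")
  show(object@spec)
})

setMethod("show", "RFGeometry", function(object) {
  cat(sprintf(
    "RFGeometry '%s': r=%g px, j=%g px, map=%d, displacement=(%g, %g), center=(%g, %g)\n",
    object@layer, object@r, object@j, object@mapSize,
    object@displacement[1], object@displacement[2],
    object@stimulusCenter[1], object@stimulusCenter[2]))
})

setMethod("show", "TuningCurve", function(object) {
  cat(sprintf("TuningCurve over %s [%s], %d samples, normalization=%s\n",
              object@parameter, object@unit, length(object@values),
              object@normalization))
})

setMethod("show", "VisResult", function(object) {
  cat("Two-step visualization result\n")
  cat(sprintf("  converged: %s, seed: %d\n", object@converged, object@seed))
  r <- object@responses
  cat(sprintf("  pre-activation responses: center %.4g | +suppressive %.4g | +facilitative %.4g\n",
              r[["center_pre"]], r[["suppressive_pre"]],
              r[["facilitative_pre"]]))
})
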