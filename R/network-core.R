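## Theoretical receptive-field geometry from the kernel/stride recursion.

#' Theoretical receptive-field geometry at a layer
#'
#' Computes the receptive-field size `r` and jump size `j` of units at a
#' layer by the standard recursion over the preceding spatial layers:
#' starting from `r = 1`, `j = 1` at the input, each layer with kernel `k`
#' and stride `s` updates `r <- r + (k - 1) * j` and `j <- j * s`. The
#' closed form `r = sum_l (k_l - 1) prod_{i<l} s_i + 1` is evaluated as
#' well and must agree exactly. The displacement of the map-center unit
#' from the image center is `inputSize / (2 * mapSize)` per axis for
#' even-sized maps (the center unit of an odd map sits exactly at the
#' image center, displacement 0); it is kept fractional and used to place
#' stimuli at the unit's true center.
#'
#' @param spec a [NetworkSpec] (or [Network], whose spec is used).
#' @param layer layer name; must not be (or lie beyond) a dense layer.
#' @return an [RFGeometry].
#' @examples
#' spec <- NetworkSpec(64, list(LayerSpec("c1", "conv", 11, 4, 8)))
#' rfGeometry(spec, "c1")
#' @export
rfGeometry <- function(spec, layer) {
  if (is(spec, "Network")) spec <- spec@spec
  nms <- layerNames(spec)
  li <- match(layer, nms)
  if (is.na(li)) stop(sprintf("unknown layer '%s'", layer))
  r <- 1; j <- 1; sz <- spec@inputSize
  ks <- numeric(0); ss <- numeric(0)
  for (i in seq_len(li)) {
    l <- spec@layers[[i]]
    if (l@kind == "dense")
      stop("receptive-field geometry is undefined for dense layers")
    k <- if (l@kind %in% c("conv", "pool")) l@kernel else 1L
    s <- if (l@kind %in% c("conv", "pool")) l@stride else 1L
    r <- r + (k - 1) * j
    j <- j * s
    if (l@kind %in% c("conv", "pool")) sz <- convOutSize(sz, k, s)
    ks <- c(ks, k); ss <- c(ss, s)
  }
  closed <- sum((ks - 1) * cumprod(c(1, ss))[seq_along(ks)]) + 1
  stopifnot(identical(as.numeric(closed), as.numeric(r)))
  d <- if (sz %% 2L == 0L) centerDisplacement(sz, spec@inputSize) else 0
  new("RFGeometry", layer = layer, r = r, j = j, mapSize = as.integer(sz),
      displacement = c(d, d),
      stimulusCenter = c(spec@inputSize / 2 + d, spec@inputSize / 2 + d))
}

#' Center displacement of an even feature map
#'
#' The center unit of an even-sized feature map is half a unit away from
#' the image center; traced back to the input this is
#' `inputSize / (2 * featureMapHeight)` pixels. The value is real-valued
#' and never rounded: stimuli are rendered on a continuous coordinate
#' grid.
#'
#' @param featureMapHeight feature-map side length (> 0).
#' @param inputSize input image side length in pixels.
#' @return displacement in pixels.
#' @examples
#' centerDisplacement(112, 224)  # 1 px
#' centerDisplacement(56, 224)   # 2 px
#' @export
centerDisplacement <- function(featureMapHeight, inputSize) {
  if (featureMapHeight <= 0) stop("feature map height must be positive")
  inputSize / (2 * featureMapHeight)
}

#' Map-center unit of a layer
#'
#' Selects the center unit of a feature map: position
#' `floor(h / 2)` (0-based) on each axis, i.e. the unit whose input block
#' center is the image center plus the displacement of [rfGeometry()].
#'
#' @param spec a [NetworkSpec] or [Network].
#' @param layer layer name.
#' @param channel channel index.
#' @return a [NeuronAddress].
#' @export
centerNeuron <- function(spec, layer, channel = 1L) {
  geom <- rfGeometry(spec, layer)
  pos <- geom@mapSize %/% 2L + 1L
  NeuronAddress(layer, channel = channel, row = pos, col = pos)
}

## ---- plain structured config I/O ------------------------------------

#' Read/write a network architecture as a structured config
#'
#' The on-disk format mirrors the tabular architecture notation: a list
#' with `input_size`, `input_channels` and a `layers` sequence of
#' `{name, kind, kernel, stride, channels}` entries, serialized as YAML
#' (`.yml`/`.yaml`) or JSON.
#'
#' @param path file path.
#' @param spec a [NetworkSpec].
#' @return `readNetworkSpec` returns a [NetworkSpec];
#'   `writeNetworkSpec` returns `path` invisibly.
#' @export
readNetworkSpec <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  layers <- lapply(obj$layers, function(l)
    LayerSpec(l$name, l$kind, l$kernel %||% 1L, l$stride %||% 1L,
              l$channels %||% 1L))
  NetworkSpec(obj$input_size, layers, obj$input_channels %||% 3L)
}

#' @rdname readNetworkSpec
#' @export
writeNetworkSpec <- function(spec, path) {
  obj <- list(input_size = spec@inputSize,
              input_channels = spec@inputChannels,
              layers = lapply(spec@layers, function(l)
                list(name = l@name, kind = l@kind, kernel = l@kernel,
                     stride = l@stride, channels = l@channels)))
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path)
  else writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE),
                  path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
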