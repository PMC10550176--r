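## Forward/backward engine for small feedforward conv networks.
##
## Pure R: convolution is im2col + matrix multiply; gradients of a single
## unit with respect to the input are obtained by running the transposed
## operations backward. Only what the in-silico protocols need is
## implemented: conv, avg/max pool, ReLU, inference-mode channelwise
## affine normalization. Dense layers are accepted in architecture specs
## (so real architectures can be described) but cannot be probed.
##
## Padding convention: a conv/pool layer with kernel k and stride s is
## zero-padded by (k - s) / 2 on each side when k - s is even (floor left /
## ceil right otherwise, and no padding when k < s). Under this convention
## every feature-map unit is centered on its j-pixel input block, so the
## map-center unit of an even map sits exactly input/(2*height) pixels off
## the image center -- the displacement formula used for stimulus placement.

padSides <- function(k, s) {
  tot <- max(k - s, 0L)
  c(left = tot %/% 2L, right = tot - tot %/% 2L)
}

convOutSize <- function(inSize, k, s) {
  p <- padSides(k, s)
  as.integer((inSize + p[[1]] + p[[2]] - k) %/% s + 1L)
}

## im2col index map into the zero-padded input, memoized per network.
## Returns npos x (k*k*nc) matrix of linear indices; rows ordered like the
## column-major (oh, ow) output map, columns ordered (di, dj, channel).
im2colIndex <- function(cache, key, inSize, nc, k, s, pad = NULL) {
  if (!is.null(cache[[key]])) return(cache[[key]])
  p <- if (is.null(pad)) padSides(k, s) else pad
  hp <- inSize + p[[1]] + p[[2]]
  oh <- as.integer((hp - k) %/% s + 1L)
  rowIdx <- rep((seq_len(oh) - 1L) * s, times = oh)        # 0-based row starts
  colIdx <- rep((seq_len(oh) - 1L) * s, each = oh)
  base <- rowIdx + colIdx * hp
  off <- as.vector(outer(outer(seq_len(k), (seq_len(k) - 1L) * hp, "+"),
                         (seq_len(nc) - 1L) * hp * hp, "+"))
  idx <- outer(base, off, "+")
  cache[[key]] <- list(idx = idx, hp = hp, oh = oh, pad = p)
  cache[[key]]
}

padArray <- function(x, p) {
  if (p[[1]] == 0L && p[[2]] == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + sum(p), d[2] + sum(p), d[3]))
  out[p[[1]] + seq_len(d[1]), p[[1]] + seq_len(d[2]), ] <- x
  out
}

cropArray <- function(x, p, h) {
  if (p[[1]] == 0L && p[[2]] == 0L) return(x)
  x[p[[1]] + seq_len(h), p[[1]] + seq_len(h), , drop = FALSE]
}

layerForward <- function(net, l, x) {
  w <- net@weights[[l@name]]
  d <- dim(x)
  switch(l@kind,
    conv = {
      im <- im2colIndex(net@cache, paste0(l@name, ":", d[1]),
                        d[1], d[3], l@kernel, l@stride)
      xp <- padArray(x, im$pad)
      X <- matrix(xp[as.vector(im$idx)], nrow = nrow(im$idx))
      Wm <- matrix(w$W, ncol = dim(w$W)[4])
      out <- X %*% Wm
      out <- sweep(out, 2L, w$b, "+")
      list(out = array(out, c(im$oh, im$oh, dim(w$W)[4])), stash = NULL)
    },
    pool = {
      im <- im2colIndex(net@cache, paste0(l@name, ":", d[1]),
                        d[1], 1L, l@kernel, l@stride)
      oh <- im$oh
      out <- array(0, c(oh, oh, d[3]))
      argm <- if (identical(w$op, "max"))
        matrix(0L, nrow(im$idx), d[3]) else NULL
      plane <- im$hp * im$hp
      for (ch in seq_len(d[3])) {
        xp <- padArray(x[, , ch, drop = FALSE], im$pad)
        X <- matrix(xp[as.vector(im$idx)], nrow = nrow(im$idx))
        if (identical(w$op, "max")) {
          mc <- max.col(X, ties.method = "first")
          argm[, ch] <- im$idx[cbind(seq_len(nrow(X)), mc)] + (ch - 1L) * plane
          out[, , ch] <- X[cbind(seq_len(nrow(X)), mc)]
        } else {
          out[, , ch] <- rowMeans(X)
        }
      }
      list(out = out, stash = list(argm = argm))
    },
    relu = list(out = pmax(x, 0), stash = NULL),
    norm = {
      y <- x
      for (ch in seq_len(d[3])) y[, , ch] <- x[, , ch] * w$scale[ch] + w$shift[ch]
      list(out = y, stash = NULL)
    },
    dense = stop("dense layers cannot be probed by the spatial engine"))
}

layerBackward <- function(net, l, x, g, stash) {
  w <- net@weights[[l@name]]
  d <- dim(x)
  switch(l@kind,
    conv = {
      ## transposed convolution: dilate the output gradient to the
      ## stride-1 grid, pad by k-1, correlate with the flipped kernel
      k <- l@kernel; s <- l@stride
      im <- im2colIndex(net@cache, paste0(l@name, ":", d[1]),
                        d[1], d[3], k, s)
      oh <- im$oh
      outC <- dim(w$W)[4]
      if (oh == 1L) {
        ## single-window (dense-like) conv: gradient is a weighted sum
        ## of the kernels
        dpad <- array(0, c(im$hp, im$hp, d[3]))
        dpad[seq_len(k), seq_len(k), ] <-
          array(matrix(w$W, ncol = outC) %*% as.vector(g), c(k, k, d[3]))
        return(cropArray(dpad, im$pad, d[1]))
      }
      du <- (oh - 1L) * s + 1L
      Gd <- array(0, c(du, du, outC))
      Gd[seq(1L, du, by = s), seq(1L, du, by = s), ] <- g
      bw <- paste0(l@name, ":bw:", d[1])
      imb <- im2colIndex(net@cache, bw, du, outC, k, 1L,
                         pad = c(k - 1L, k - 1L))
      wbKey <- paste0(l@name, ":Wb")
      if (is.null(net@cache[[wbKey]]))
        net@cache[[wbKey]] <- matrix(aperm(
          w$W[k:1, k:1, , , drop = FALSE], c(1, 2, 4, 3)), ncol = d[3])
      gp <- padArray(Gd, imb$pad)
      X <- matrix(gp[as.vector(imb$idx)], nrow = nrow(imb$idx))
      dpad <- array(X %*% net@cache[[wbKey]], c(imb$oh, imb$oh, d[3]))
      cropArray(dpad, im$pad, d[1])
    },
    pool = {
      im <- im2colIndex(net@cache, paste0(l@name, ":", d[1]),
                        d[1], 1L, l@kernel, l@stride)
      gp <- numeric(im$hp * im$hp * d[3])
      if (identical(w$op, "max")) {
        acc <- rowsum(as.vector(g), as.vector(stash$argm))
        gp[as.integer(rownames(acc))] <- acc
      } else {
        kk <- l@kernel^2
        plane <- im$hp * im$hp
        for (ch in seq_len(d[3])) {
          gch <- as.vector(g[, , ch]) / kk
          acc <- rowsum(rep(gch, times = kk), as.vector(im$idx))
          sel <- as.integer(rownames(acc)) + (ch - 1L) * plane
          gp[sel] <- gp[sel] + acc
        }
      }
      cropArray(array(gp, c(im$hp, im$hp, d[3])), im$pad, d[1])
    },
    relu = g * (x > 0),
    norm = {
      y <- g
      for (ch in seq_len(d[3])) y[, , ch] <- g[, , ch] * w$scale[ch]
      y
    },
    dense = stop("dense layers cannot be probed by the spatial engine"))
}

applyInputTransform <- function(net, image) {
  if (net@inputTransform == "center") image - 0.5 else image
}

#' Forward pass through a weighted network
#'
#' Runs the network on a stimulus image up to (and including) a layer and
#' returns all intermediate activations. Batch-norm style layers are
#' always evaluated in inference mode (channelwise affine).
#'
#' @param net a [Network].
#' @param image numeric array `h x w x channels` on the `[0, 1]` stimulus
#'   scale (the network's input transform is applied internally).
#' @param upto layer name to stop after; default runs every probe-able
#'   layer.
#' @return list with `input` (transformed input) and `acts`, a named list
#'   of activation arrays per layer.
#' @export
networkForward <- function(net, image, upto = NULL) {
  spec <- net@spec
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[1] != spec@inputSize ||
      d[2] != spec@inputSize || d[3] != spec@inputChannels)
    stop(sprintf("image must be a %d x %d x %d array",
                 spec@inputSize, spec@inputSize, spec@inputChannels))
  x <- applyInputTransform(net, image)
  input <- x
  acts <- list()
  stash <- list()
  for (l in spec@layers) {
    if (l@kind == "dense") break
    fw <- layerForward(net, l, x)
    acts[[l@name]] <- fw$out
    stash[[l@name]] <- fw$stash
    x <- fw$out
    if (!is.null(upto) && identical(l@name, upto)) break
  }
  if (!is.null(upto) && is.null(acts[[upto]]))
    stop(sprintf("unknown or unreachable layer '%s'", upto))
  list(input = input, acts = acts, stash = stash)
}

#' Scalar response of an addressed unit
#'
#' The pre-activation response is the addressed layer's output at the
#' unit's (row, col, channel); the post-activation response is its
#' rectification `max(0, pre)`. Tuning and texture protocols read
#' post-activation responses; the visualization objective reads
#' pre-activation responses.
#'
#' @param net a [Network].
#' @param neuron a [NeuronAddress].
#' @param image stimulus array (see [networkForward()]).
#' @param stage `"post"` (`"post_activation"`) or `"pre"`
#'   (`"pre_activation"`).
#' @return scalar response.
#' @export
probeResponse <- function(net, neuron, image, stage = c("post", "pre")) {
  stage <- normalizeStage(stage)
  fw <- networkForward(net, image, upto = neuron@layer)
  pre <- unitValue(fw$acts[[neuron@layer]], neuron)
  if (stage == "post") max(0, pre) else pre
}

normalizeStage <- function(stage) {
  stage <- stage[1]
  if (stage %in% c("post", "post_activation")) return("post")
  if (stage %in% c("pre", "pre_activation")) return("pre")
  stop("stage must be 'pre' or 'post'")
}

unitValue <- function(act, neuron) {
  d <- dim(act)
  if (neuron@row > d[1] || neuron@col > d[2] || neuron@channel > d[3] ||
      neuron@row < 1L || neuron@col < 1L || neuron@channel < 1L)
    stop("neuron address outside the feature map")
  act[neuron@row, neuron@col, neuron@channel]
}

#' Gradient of a unit's pre-activation response with respect to the input
#'
#' @inheritParams probeResponse
#' @return array with the input's dimensions.
#' @export
neuronGradient <- function(net, neuron, image) {
  fw <- networkForward(net, image, upto = neuron@layer)
  layers <- net@spec@layers
  li <- match(neuron@layer, layerNames(net))
  g <- array(0, dim(fw$acts[[neuron@layer]]))
  g[neuron@row, neuron@col, neuron@channel] <- 1
  for (i in rev(seq_len(li))) {
    l <- layers[[i]]
    xin <- if (i == 1L) fw$input else fw$acts[[layers[[i - 1L]]@name]]
    g <- layerBackward(net, l, xin, g, fw$stash[[l@name]])
  }
  g
}

#' Empirical receptive-field support of a unit
#'
#' Bounding box of input pixels whose perturbation affects the unit's
#' pre-activation response, measured from input-gradient magnitude. For
#' linear stacks the gradient is input-independent; for rectified networks
#' additional random probe images can be maxed over.
#'
#' @inheritParams probeResponse
#' @param nProbes number of additional random probe images (0 evaluates at
#'   the gray canvas only).
#' @param seed seed for the probe images.
#' @param tol support threshold relative to the maximum gradient magnitude.
#' @return list with `empty` flag, `box` (rowMin, rowMax, colMin, colMax in
#'   1-based pixels), `side` (max box extent), and `centroid`, the box
#'   center in continuous pixel coordinates.
#' @export
empiricalRFSupport <- function(net, neuron, nProbes = 0L, seed = 1L,
                               tol = 1e-10) {
  sz <- net@spec@inputSize
  nc <- net@spec@inputChannels
  gmax <- abs(neuronGradient(net, neuron, array(0.5, c(sz, sz, nc))))
  if (nProbes > 0L) {
    imgs <- withSeed(seed, replicate(nProbes,
      array(stats::runif(sz * sz * nc), c(sz, sz, nc)), simplify = FALSE))
    for (img in imgs)
      gmax <- pmax(gmax, abs(neuronGradient(net, neuron, img)))
  }
  mag <- apply(gmax, c(1, 2), max)
  thr <- max(mag) * tol
  if (max(mag) == 0)
    return(list(empty = TRUE, box = rep(NA_integer_, 4), side = 0L,
                centroid = c(NA_real_, NA_real_)))
  rows <- which(apply(mag, 1, max) > thr)
  cols <- which(apply(mag, 2, max) > thr)
  box <- c(min(rows), max(rows), min(cols), max(cols))
  list(empty = FALSE, box = box,
       side = max(box[2] - box[1], box[4] - box[3]) + 1L,
       centroid = c((box[3] - 1 + box[4]) / 2, (box[1] - 1 + box[2]) / 2))
}

## Evaluate an expression with a temporary RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
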