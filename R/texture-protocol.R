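## Texture selectivity and texture-versus-noise surround suppression.

#' Modulation index
#'
#' Texture selectivity of a neuron: the difference of the responses to
#' the naturalistic and the spectrally matched noise images divided by
#' their sum. Lies in `[-1, 1]` and is antisymmetric under swapping its
#' arguments; both responses zero is undefined (`NA`).
#'
#' @param rNat response to the naturalistic image(s), >= 0.
#' @param rNoise response to the noise image(s), >= 0.
#' @return modulation index.
#' @examples modulationIndex(0.3, 0.1)  # 0.5
#' @export
modulationIndex <- function(rNat, rNoise) {
  stopifnot(rNat >= 0, rNoise >= 0)
  if (rNat + rNoise == 0) return(NA_real_)
  (rNat - rNoise) / (rNat + rNoise)
}

#' Build paired texture families
#'
#' For each source image, synthesizes `nSeeds` naturalistic images and
#' pairs each with a spectrally matched noise image (the phase of the
#' naturalistic image replaced by Gaussian white-noise phase). Each
#' (naturalistic, noise) pair is mapped into `[0, 1]` by one shared
#' affine transform, so the pair's Fourier magnitude spectra stay
#' identical to machine precision.
#'
#' @param sources list of grayscale source matrices (15 sources of 15
#'   seeds each mirrors the standard design; counts are free).
#' @param nSeeds naturalistic images per source.
#' @param seed root seed; every image derives its own stream from it.
#' @param synthConfig configuration for [synthesizeTexture()].
#' @return list of families; each family is a list with `id`,
#'   `naturalistic` and `noise` (parallel lists of matrices).
#' @export
buildTextureFamilies <- function(sources, nSeeds = 3L, seed = 1L,
                                 synthConfig = list()) {
  lapply(seq_along(sources), function(fi) {
    nat <- list(); noi <- list()
    for (si in seq_len(nSeeds)) {
      s1 <- seed + 1000L * fi + 2L * si
      t <- synthesizeTexture(sources[[fi]], seed = s1,
                             config = synthConfig)
      attr(t, "spectralError") <- NULL
      attr(t, "converged") <- NULL
      n <- spectrallyMatchedNoise(t, seed = s1 + 1L, rescale = FALSE)
      lo <- min(t, n); hi <- max(t, n)
      if (hi > lo) { t <- (t - lo) / (hi - lo); n <- (n - lo) / (hi - lo) }
      nat[[si]] <- t; noi[[si]] <- n
    }
    list(id = fi, naturalistic = nat, noise = noi)
  })
}

textureDiscStimulus <- function(image, size, center, diameter) {
  canvas <- matrix(0.5, size, size)
  mask <- discMask(size, center, diameter)
  src <- image
  n <- nrow(src)
  ## place the texture so its center sits at the stimulus center
  g <- pixelGrid(size)
  sx <- round(g$X - center[1] + n / 2 + 0.5)
  sy <- round(g$Y - center[2] + n / 2 + 0.5)
  ok <- mask & sx >= 1 & sx <= n & sy >= 1 & sy <= n
  canvas[ok] <- src[cbind(sy[ok], sx[ok])]
  toRGB(canvas)
}

familyResponse <- function(net, neuron, images, size, center, diameter) {
  mean(vapply(images, function(img)
    probeResponse(net, neuron,
                  textureDiscStimulus(img, size, center, diameter)),
    numeric(1)))
}

#' Select a neuron's top texture families by modulation index
#'
#' Ranks families by modulation index at full-RF-size stimuli,
#' restricted to families that elicit a nonzero response (naturalistic
#' or noise); returns at most `top` ids, fewer if fewer qualify, and an
#' empty selection with `dropped = TRUE` when no family responds.
#'
#' @param natResponses,noiseResponses per-family mean responses.
#' @param top maximum number of families (default 5).
#' @return list with `ids`, `modulation` (per ranked id), `dropped`.
#' @export
selectTopTextures <- function(natResponses, noiseResponses, top = 5L) {
  stopifnot(length(natResponses) == length(noiseResponses))
  responsive <- which(natResponses + noiseResponses > 0)
  if (length(responsive) == 0L)
    return(list(ids = integer(0), modulation = numeric(0), dropped = TRUE))
  mi <- vapply(responsive, function(i)
    modulationIndex(natResponses[i], noiseResponses[i]), numeric(1))
  ord <- order(mi, decreasing = TRUE)
  keep <- ord[seq_len(min(top, length(ord)))]
  list(ids = responsive[keep], modulation = mi[keep], dropped = FALSE)
}

#' Texture versus noise diameter tuning of one neuron
#'
#' Computes per-diameter responses to the selected families'
#' naturalistic and noise images (averaged over images within family,
#' then over families), divides both curves by the single maximum across
#' both, and reads a suppression index per curve with the max-vs-min
#' convention (minimum restricted to diameters at or beyond the peak).
#'
#' @param net a [Network].
#' @param neuron a [NeuronAddress].
#' @param geometry the unit's [RFGeometry].
#' @param families texture families from [buildTextureFamilies()].
#' @param selected family ids to use (from [selectTopTextures()]).
#' @param diameters diameter grid; default 8 px steps up to `r`.
#' @return list with `textureCurve`, `noiseCurve` ([TuningCurve]s,
#'   jointly normalized to maximum 1), `siTexture`, `siNoise`,
#'   `dropped`.
#' @export
textureNoiseTuning <- function(net, neuron, geometry, families, selected,
                               diameters = NULL) {
  if (length(selected) == 0L)
    return(list(textureCurve = NULL, noiseCurve = NULL,
                siTexture = NA_real_, siNoise = NA_real_, dropped = TRUE))
  size <- net@spec@inputSize
  ctr <- geometry@stimulusCenter
  if (is.null(diameters)) diameters <- seq(8, geometry@r, by = 8)
  fams <- families[selected]
  perDiam <- function(key) vapply(diameters, function(d)
    mean(vapply(fams, function(f)
      familyResponse(net, neuron, f[[key]], size, ctr, d), numeric(1))),
    numeric(1))
  natR <- perDiam("naturalistic")
  noiR <- perDiam("noise")
  normF <- max(natR, noiR)
  if (normF <= 0)
    return(list(textureCurve = NULL, noiseCurve = NULL,
                siTexture = NA_real_, siNoise = NA_real_, dropped = TRUE))
  tc <- TuningCurve("diameter", diameters, natR / normF, unit = "px",
                    normalization = "by_max")
  nc <- TuningCurve("diameter", diameters, noiR / normF, unit = "px",
                    normalization = "by_max")
  si <- function(curve) if (max(curve@responses) > 0)
    suppressionIndex(curve, "max_vs_min") else NA_real_
  list(textureCurve = tc, noiseCurve = nc,
       siTexture = si(tc), siNoise = si(nc), dropped = FALSE)
}

#' Population comparison of texture and noise suppression indices
#'
#' Classical paired t-test on (SI_noise - SI_texture) over neurons; a
#' positive t indicates stronger surround suppression for spectrally
#' matched noise than for naturalistic texture.
#'
#' @param siTexture,siNoise per-neuron suppression indices (paired).
#' @return list with `t`, `df`, `p`, `meanDifference`, `degenerate`
#'   (TRUE when the differences have zero variance; then t is 0 for
#'   all-zero differences and infinite otherwise, with p NA).
#' @export
siComparison <- function(siTexture, siNoise) {
  stopifnot(length(siTexture) == length(siNoise), length(siTexture) >= 2L)
  d <- siNoise - siTexture
  if (stats::var(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = length(d) - 1L, p = NA_real_,
                meanDifference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(siNoise, siTexture, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanDifference = mean(d), degenerate = FALSE)
}

#' Full texture protocol for one neuron
#'
#' Ranks families at full-RF stimuli, selects the top families, and
#' returns the texture/noise tuning result together with the ranking.
#'
#' @inheritParams textureNoiseTuning
#' @param top maximum families to keep.
#' @return list combining [selectTopTextures()] and
#'   [textureNoiseTuning()] outputs.
#' @export
textureProtocol <- function(net, neuron, geometry, families, top = 5L,
                            diameters = NULL) {
  size <- net@spec@inputSize
  ctr <- geometry@stimulusCenter
  natR <- vapply(families, function(f)
    familyResponse(net, neuron, f$naturalistic, size, ctr, geometry@r),
    numeric(1))
  noiR <- vapply(families, function(f)
    familyResponse(net, neuron, f$noise, size, ctr, geometry@r),
    numeric(1))
  sel <- selectTopTextures(natR, noiR, top = top)
  tuning <- textureNoiseTuning(net, neuron, geometry, families, sel$ids,
                               diameters = diameters)
  c(list(selection = sel, natResponses = natR, noiseResponses = noiR),
    tuning)
}
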