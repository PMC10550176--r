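## Center-surround similarity metrics of visualization outputs.

#' Color correlation between center and surround
#'
#' Averages each color channel inside the center mask and inside the
#' surround mask and returns the Pearson correlation between the two
#' 3-vectors of channel means. 1 means the center and surround have the
#' same color; achromatic regions (zero variance across the three
#' channel means) give an undefined result (`NA`), which propagates as
#' missing, never as zero.
#'
#' @param centerImage,surroundImage `h x w x 3` arrays (they may be the
#'   same composite).
#' @param centerMask,surroundMask non-empty logical matrices.
#' @return Pearson correlation in `[-1, 1]` or `NA`.
#' @export
colorCorrelation <- function(centerImage, centerMask, surroundImage,
                             surroundMask) {
  stopifnot(any(centerMask), any(surroundMask))
  cm <- vapply(1:3, function(ch) mean(centerImage[, , ch][centerMask]),
               numeric(1))
  sm <- vapply(1:3, function(ch) mean(surroundImage[, , ch][surroundMask]),
               numeric(1))
  if (stats::var(cm) == 0 || stats::var(sm) == 0) return(NA_real_)
  stats::cor(cm, sm)
}

#' Feature correlation between center and surround in a reference network
#'
#' Passes the composite image through a reference network, takes the
#' feature vector at the reference-layer unit nearest the stimulus
#' center, and the four feature vectors at the cardinal units (top,
#' bottom, left, right) nearest the radius midway between the GSF radius
#' and the theoretical-RF radius, i.e. `(gsf + r) / 4` pixels from the
#' center. Returns the Pearson correlation between the center vector and
#' the mean of the four surround vectors. Feature vectors are
#' post-activation (rectified). The reference layer should not be so
#' deep that its own receptive field spans the surround ring; a warning
#' is issued when the reference RF exceeds the gap distance.
#'
#' @param image composite `h x w x 3` array.
#' @param refNet reference [Network].
#' @param refLayer reference layer name.
#' @param geometry the probed unit's [RFGeometry] (in the probed
#'   network).
#' @param gsf grating summation field of the probed unit (pixels).
#' @return list with `correlation` (`NA` for zero-variance vectors) and
#'   `positions` (the sampled reference-map units, recorded for
#'   reproducibility).
#' @export
featureCorrelation <- function(image, refNet, refLayer, geometry, gsf) {
  refGeom <- rfGeometry(refNet@spec, refLayer)
  radius <- (gsf + geometry@r) / 4
  if (refGeom@r > (geometry@r - gsf) / 2)
    warning("reference layer receptive field is large relative to the surround ring")
  fw <- networkForward(refNet, image, upto = refLayer)
  act <- pmax(fw$acts[[refLayer]], 0)
  j <- refGeom@j
  nearest <- function(p) {
    i <- round(p / j + 0.5)
    pmin(pmax(i, 1L), dim(act)[1])
  }
  ctr <- geometry@stimulusCenter
  centerUnit <- c(nearest(ctr[2]), nearest(ctr[1]))   # (row, col)
  offs <- list(top = c(0, -radius), bottom = c(0, radius),
               left = c(-radius, 0), right = c(radius, 0))
  positions <- lapply(offs, function(o)
    c(row = nearest(ctr[2] + o[2]), col = nearest(ctr[1] + o[1])))
  cv <- act[centerUnit[1], centerUnit[2], ]
  sv <- rowMeans(vapply(positions, function(p) act[p[1], p[2], ],
                        numeric(dim(act)[3])))
  corr <- if (stats::var(cv) == 0 || stats::var(sv) == 0) NA_real_
          else stats::cor(cv, sv)
  list(correlation = corr,
       positions = c(list(center = c(row = centerUnit[1],
                                     col = centerUnit[2])), positions))
}

#' Oriented energy of an image region
#'
#' Quadrature-pair Gabor filter energy per orientation, summed over a
#' region: the image (averaged over channels) is convolved with even and
#' odd Gabors at each bank orientation and the squared responses are
#' summed. Used as instrumentation to read the dominant orientation of
#' visualization outputs.
#'
#' @param image `h x w x 3` array or grayscale matrix.
#' @param orientations filter-bank orientations covering `[0, 180)`.
#' @param period carrier period in pixels.
#' @param mask optional logical matrix restricting the summation region.
#' @return named numeric vector of energies per orientation.
#' @export
orientedEnergy <- function(image, orientations = seq(0, 165, by = 15),
                           period = 8, mask = NULL) {
  gray <- if (length(dim(image)) == 3L)
    (image[, , 1] + image[, , 2] + image[, , 3]) / 3 else image
  n <- nrow(gray)
  G <- stats::fft(gray - mean(gray))
  k <- 2L * floor(period) + 1L
  conv <- function(ker) {
    kp <- matrix(0, n, n)
    kp[seq_len(k), seq_len(k)] <- ker
    Re(stats::fft(G * stats::fft(kp), inverse = TRUE)) / n^2
  }
  en <- vapply(orientations, function(ori) {
    ev <- conv(gaborKernel(k, ori, period, sigma = period / 2, phase = 0))
    od <- conv(gaborKernel(k, ori, period, sigma = period / 2, phase = 90))
    e <- ev^2 + od^2
    if (!is.null(mask)) sum(e[mask]) else sum(e)
  }, numeric(1))
  stats::setNames(en, orientations)
}

#' Dominant pattern of a region by projection
#'
#' Projects a region of an image onto candidate zero-mean patterns and
#' returns the index of the largest absolute projection. Used to compare
#' optimized surrounds against the enumeration optimum of the
#' conceptual model.
#'
#' @param image `h x w x 3` array or matrix.
#' @param patterns list of pattern matrices.
#' @param mask logical matrix selecting the region.
#' @return list with `index` and the `projections`.
#' @export
dominantPattern <- function(image, patterns, mask) {
  gray <- if (length(dim(image)) == 3L)
    (image[, , 1] + image[, , 2] + image[, , 3]) / 3 else image
  pr <- vapply(patterns, function(p)
    sum((gray[mask] - 0.5) * p[mask]) / sqrt(sum(p[mask]^2)), numeric(1))
  list(index = which.max(abs(pr)), projections = pr)
}
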