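## Orientation, offset-center, heatmap, geometry and contrast protocols,
## with their derived statistics.

surroundAnnulus <- function(orientation, period, geometry, gsf, phase = 0,
                            contrast = 1) {
  SurroundSpec(GratingSpec(orientation, period, phase = phase,
                           contrast = contrast,
                           center = geometry@stimulusCenter),
               innerDiameter = gsf + 4, outerDiameter = geometry@r)
}

centerGrating <- function(orientation, period, geometry, gsf, phase = 0,
                          contrast = 1) {
  GratingSpec(orientation, period, phase = phase, contrast = contrast,
              diameter = gsf, center = geometry@stimulusCenter)
}

## Phase-averaged response to center grating (orientation thC) plus an
## optional annular surround (orientation thS); the same drifting phase
## is applied to center and surround.
csResponse <- function(net, neuron, optimal, geometry, gsf,
                       thC = NULL, thS = NULL, nPhases = 8L,
                       centerContrast = 1, surroundContrast = 1,
                       surroundForm = "annulus", patchAngle = 0) {
  size <- net@spec@inputSize
  mean(vapply(phaseSet(nPhases), function(ph) {
    ctr <- if (!is.null(thC))
      centerGrating(thC, optimal$period, geometry, gsf, phase = ph,
                    contrast = centerContrast)
    else centerGrating(0, optimal$period, geometry, gsf, phase = ph,
                       contrast = 0)
    sur <- if (!is.null(thS)) {
      s <- surroundAnnulus(thS, optimal$period, geometry, gsf, phase = ph,
                           contrast = surroundContrast)
      if (surroundForm == "two_patch")
        initialize(s, form = "two_patch", patchAngle = patchAngle,
                   patchDiameter = (geometry@r - (gsf + 4)) / 2)
      else s
    } else NULL
    probeResponse(net, neuron, composeCenterSurround(ctr, sur, size))
  }, numeric(1)))
}

#' Orientation tuning triplet
#'
#' The three standard orientation protocols on a shared grid, all
#' phase-averaged and normalized by the optimal-center response:
#' the center orientation tuning curve (rotating center disc of GSF
#' diameter), the surround orientation tuning curve (rotating surround
#' annulus alone, from GSF + 4 px to the theoretical receptive field),
#' and the surround suppression tuning curve (center fixed at the
#' optimal orientation, surround rotating).
#'
#' @param net a [Network].
#' @param neuron a [NeuronAddress].
#' @param optimal result of [gridSearchOptimal()].
#' @param geometry the unit's [RFGeometry].
#' @param gsf grating summation field in pixels.
#' @param orientations orientation grid in degrees (default 15-degree
#'   steps).
#' @param nPhases phases to average over.
#' @return list of [TuningCurve]s: `center`, `surround`, `suppression`,
#'   plus `normalization` (the optimal-center response).
#' @export
orientationTriplet <- function(net, neuron, optimal, geometry, gsf,
                               orientations = seq(0, 165, by = 15),
                               nPhases = 8L) {
  norm <- csResponse(net, neuron, optimal, geometry, gsf,
                     thC = optimal$orientation, nPhases = nPhases)
  if (norm <= 0)
    stop("silent neuron: optimal-center response is not positive")
  cc <- vapply(orientations, function(th)
    csResponse(net, neuron, optimal, geometry, gsf, thC = th,
               nPhases = nPhases), numeric(1)) / norm
  sc <- vapply(orientations, function(th)
    csResponse(net, neuron, optimal, geometry, gsf, thS = th,
               nPhases = nPhases), numeric(1)) / norm
  pc <- vapply(orientations, function(th)
    csResponse(net, neuron, optimal, geometry, gsf,
               thC = optimal$orientation, thS = th,
               nPhases = nPhases), numeric(1)) / norm
  mk <- function(r) TuningCurve("orientation", orientations, r,
                                unit = "deg",
                                normalization = "by_optimal_center",
                                cyclic = TRUE)
  list(center = mk(cc), surround = mk(sc), suppression = mk(pc),
       normalization = norm)
}

#' Surround suppression curves for offset centers
#'
#' One surround-orientation suppression curve per center offset (0, 15,
#' 30, 45 degrees off the optimal by default). Each curve is normalized
#' by that offset's own center-alone response so curves are comparable
#' across offsets; an offset whose center-alone response is not positive
#' is flagged and skipped (NULL entry).
#'
#' @inheritParams orientationTriplet
#' @param offsets center-orientation offsets in degrees.
#' @return list with `curves` (named by offset), `centerResponses`, and
#'   `skipped` (logical per offset).
#' @export
offsetCenterProtocol <- function(net, neuron, optimal, geometry, gsf,
                                 offsets = c(0, 15, 30, 45),
                                 orientations = seq(0, 165, by = 15),
                                 nPhases = 8L) {
  curves <- stats::setNames(vector("list", length(offsets)),
                            as.character(offsets))
  centerResp <- numeric(length(offsets))
  skipped <- logical(length(offsets))
  for (i in seq_along(offsets)) {
    thC <- (optimal$orientation + offsets[i]) %% 180
    norm <- csResponse(net, neuron, optimal, geometry, gsf, thC = thC,
                       nPhases = nPhases)
    centerResp[i] <- norm
    if (norm <= 0) { skipped[i] <- TRUE; next }
    r <- vapply(orientations, function(th)
      csResponse(net, neuron, optimal, geometry, gsf, thC = thC,
                 thS = th, nPhases = nPhases), numeric(1)) / norm
    curves[[i]] <- TuningCurve("orientation", orientations, r,
                               unit = "deg", cyclic = TRUE)
  }
  list(curves = curves, centerResponses = centerResp, skipped = skipped)
}

#' Center x surround orientation response heatmap
#'
#' Matrix of phase-averaged responses for every combination of center
#' and surround orientation; low values along the diagonal indicate that
#' the most suppressive surround orientation follows the center.
#'
#' @inheritParams orientationTriplet
#' @param centerOrientations,surroundOrientations grids in degrees.
#' @return numeric matrix `[center theta, surround theta]` with
#'   dimnames.
#' @export
centerSurroundHeatmap <- function(net, neuron, optimal, geometry, gsf,
                                  centerOrientations = seq(0, 165, by = 15),
                                  surroundOrientations = seq(0, 165, by = 15),
                                  nPhases = 8L) {
  m <- outer(centerOrientations, surroundOrientations,
             Vectorize(function(thC, thS)
               csResponse(net, neuron, optimal, geometry, gsf, thC = thC,
                          thS = thS, nPhases = nPhases)))
  dimnames(m) <- list(center = centerOrientations,
                      surround = surroundOrientations)
  m
}

#' Correlation between center tuning and surround suppression tuning
#'
#' Pearson correlation coefficient between the center orientation tuning
#' curve and the surround suppression tuning curve on the same grid;
#' negative values indicate that the most suppressive surround
#' orientation matches the optimal center orientation.
#'
#' @param centerCurve,suppressionCurve [TuningCurve]s on equal grids.
#' @return correlation in `[-1, 1]`, or `NA` when either curve has zero
#'   variance.
#' @export
tuningCurveCorrelation <- function(centerCurve, suppressionCurve) {
  stopifnot(isTRUE(all.equal(centerCurve@values, suppressionCurve@values)))
  x <- centerCurve@responses; y <- suppressionCurve@responses
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Circular variance of an orientation tuning curve
#'
#' Orientation selectivity on the doubled-angle circle:
#' `CV = 1 - |sum R(theta) exp(2 i theta)| / sum R(theta)` with responses
#' clipped at 0. 0 means perfectly selective (a single responsive
#' orientation), 1 means flat (or two equal peaks 90 degrees apart,
#' whose doubled-angle vectors cancel).
#'
#' @param curve orientation [TuningCurve].
#' @return value in `[0, 1]`, or `NA` for an all-zero curve.
#' @export
circularVariance <- function(curve) {
  r <- pmax(curve@responses, 0)
  if (sum(r) == 0) return(NA_real_)
  th <- curve@values * pi / 180
  1 - Mod(sum(r * exp(2i * th))) / sum(r)
}

#' Deviation of the most suppressive surround orientation from the center
#'
#' Signed cyclic difference (period 180 degrees) between the orientation
#' of the suppression-curve minimum (first-minimum tie-break) and the
#' center orientation, mapped into `(-90, 90]`.
#'
#' @param suppressionCurve surround suppression [TuningCurve].
#' @param centerOrientation degrees.
#' @param variationThreshold curves with response variance below this are
#'   flat and return `NA` (no meaningful minimum).
#' @return degrees in `(-90, 90]` or `NA`.
#' @export
orientationDeviation <- function(suppressionCurve, centerOrientation,
                                 variationThreshold = 0.001) {
  if (stats::var(suppressionCurve@responses) < variationThreshold)
    return(NA_real_)
  thMin <- suppressionCurve@values[which.min(suppressionCurve@responses)]
  d <- (thMin - centerOrientation) %% 180
  if (d > 90) d <- d - 180
  d
}

#' Surround geometry protocol with repeated-measures ANOVA
#'
#' For each neuron, presents the optimal center with a two-patch
#' surround at each patch angle (angle measured relative to the center
#' orientation; 0 is collinear with the bars), with the surround grating
#' either at the preferred or the orthogonal orientation, and normalizes
#' by the center-alone response. Patch-angle modulation per surround
#' orientation is assessed with a classical one-way repeated-measures
#' ANOVA (subjects = neurons, factor = patch angle, univariate
#' decomposition without sphericity correction).
#'
#' @param net a [Network].
#' @param neurons list of neuron records, each a list with `neuron`,
#'   `optimal`, `geometry`, `gsf` (as from [mapReceptiveField()]).
#' @param patchAngles angles of the patch pair in degrees.
#' @param surroundOrientations `"preferred"`, `"orthogonal"` or both.
#' @param nPhases phases to average over.
#' @return list with `responses` (data.frame: neuron, surround, angle,
#'   response) and `anova` (per surround orientation: F, df, p).
#' @export
geometryProtocol <- function(net, neurons, patchAngles = c(0, 45, 90, 135),
                             surroundOrientations = c("preferred",
                                                      "orthogonal"),
                             nPhases = 8L) {
  if (length(patchAngles) < 2L) stop("need at least 2 patch angles")
  rows <- list()
  for (ni in seq_along(neurons)) {
    rec <- neurons[[ni]]
    norm <- csResponse(net, rec$neuron, rec$optimal, rec$geometry,
                       rec$gsf, thC = rec$optimal$orientation,
                       nPhases = nPhases)
    for (so in surroundOrientations) {
      thS <- if (so == "preferred") rec$optimal$orientation
             else (rec$optimal$orientation + 90) %% 180
      for (ang in patchAngles) {
        resp <- csResponse(net, rec$neuron, rec$optimal, rec$geometry,
                           rec$gsf, thC = rec$optimal$orientation,
                           thS = thS, nPhases = nPhases,
                           surroundForm = "two_patch", patchAngle = ang)
        rows[[length(rows) + 1L]] <- data.frame(
          neuron = ni, surround = so, angle = ang,
          response = if (norm > 0) resp / norm else NA_real_)
      }
    }
  }
  df <- do.call(rbind, rows)
  anova <- lapply(stats::setNames(surroundOrientations,
                                  surroundOrientations), function(so) {
    sub <- df[df$surround == so & !is.na(df$response), ]
    if (length(unique(sub$neuron)) < 2L) return(list(F = NA, p = NA))
    rmAnova(sub$response, sub$neuron, sub$angle)
  })
  list(responses = df, anova = anova)
}

#' One-way repeated-measures ANOVA
#'
#' Classical univariate decomposition via `aov` with a subject error
#' stratum. A fully degenerate table (no condition variance at all)
#' returns F = 0, p = 1.
#'
#' @param y response vector.
#' @param subject subject identifier per observation.
#' @param condition within-subject condition per observation.
#' @return list with `F`, `df` (numerator, denominator), `p`.
#' @export
rmAnova <- function(y, subject, condition) {
  d <- data.frame(y = y, s = factor(subject), c = factor(condition))
  fit <- stats::aov(y ~ c + Error(s), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fv <- tab["c", "F value"]
  pv <- tab["c", "Pr(>F)"]
  if (isTRUE(tab["c", "Sum Sq"] < 1e-12)) {  # no condition effect at all
    Fv <- 0
    pv <- 1
  }
  list(F = Fv, df = c(tab["c", "Df"], tab["Residuals", "Df"]), p = pv)
}

#' Peak shift of the diameter tuning curve at low contrast
#'
#' Difference between the peak diameters of the low-contrast and
#' high-contrast diameter tuning curves (low minus high; positive means
#' the low-contrast curve peaks at a larger size). First-maximum
#' tie-break.
#'
#' @inheritParams orientationTriplet
#' @param lowFactor low-contrast factor (0.17 for the standard
#'   low-contrast condition).
#' @param diameters diameter grid; `NULL` for the default.
#' @return list with `shift` (pixels, `NA` if silent at low contrast),
#'   `high` and `low` [TuningCurve]s.
#' @export
contrastPeakShift <- function(net, neuron, optimal, geometry,
                              lowFactor = 0.17, diameters = NULL,
                              nPhases = 8L) {
  high <- diameterTuning(net, neuron, optimal, geometry,
                         diameters = diameters, contrast = 1,
                         nPhases = nPhases)
  low <- diameterTuning(net, neuron, optimal, geometry,
                        diameters = diameters, contrast = lowFactor,
                        nPhases = nPhases)
  if (max(low@responses) <= 0 || max(high@responses) <= 0)
    return(list(shift = NA_real_, high = high, low = low))
  list(shift = low@values[which.max(low@responses)] -
         high@values[which.max(high@responses)],
       high = high, low = low)
}

#' Center contrast response functions with and without surround
#'
#' Sweeps the center contrast at the optimal grating (GSF diameter) with
#' no surround (`Rc`) and with the preferred full-contrast surround
#' annulus (`Rs`).
#'
#' @inheritParams orientationTriplet
#' @param contrasts center contrast levels.
#' @return list with `contrasts`, `Rc`, `Rs`.
#' @export
contrastResponseProtocol <- function(net, neuron, optimal, geometry, gsf,
                                     contrasts = seq(0.1, 1, by = 0.1),
                                     nPhases = 8L) {
  Rc <- vapply(contrasts, function(cc)
    csResponse(net, neuron, optimal, geometry, gsf,
               thC = optimal$orientation, nPhases = nPhases,
               centerContrast = cc), numeric(1))
  Rs <- vapply(contrasts, function(cc)
    csResponse(net, neuron, optimal, geometry, gsf,
               thC = optimal$orientation, thS = optimal$orientation,
               nPhases = nPhases, centerContrast = cc), numeric(1))
  list(contrasts = contrasts, Rc = Rc, Rs = Rs)
}

#' Fit subtractive and divisive surround models to contrast responses
#'
#' The subtractive model is `Rs = max(0, Rc - a)`; the divisive model is
#' `Rs = Rc / b`. Each parameter is fitted by one-parameter least
#' squares on linear responses (`a` by bounded search over
#' `[0, max(Rc)]`, `b` over `[1e-3, 1e3]`); both mean squared errors are
#' reported along with their log10.
#'
#' @param Rc center-alone responses per contrast (non-negative).
#' @param Rs center-plus-surround responses per contrast.
#' @return list with `a`, `b`, `mseSubtractive`, `mseDivisive`,
#'   `logMseSubtractive`, `logMseDivisive`, `illPosedDivisive`.
#' @export
fitContrastModels <- function(Rc, Rs) {
  stopifnot(length(Rc) == length(Rs), length(Rc) >= 3L, all(Rc >= 0))
  sseSub <- function(a) mean((Rs - pmax(0, Rc - a))^2)
  if (all(Rs == 0)) {
    a <- max(Rc)
    bFit <- list(b = 1e3, illPosed = TRUE)
  } else {
    grid <- sort(unique(c(Rc, seq(0, max(Rc), length.out = 201))))
    g <- vapply(grid, sseSub, numeric(1))
    i <- which.min(g)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    a <- if (hi > lo) stats::optimize(sseSub, c(lo, hi))$minimum
         else grid[i]
    if (sseSub(grid[i]) < sseSub(a)) a <- grid[i]
    gam <- sum(Rs * Rc) / sum(Rc^2)
    b <- if (gam > 0) min(max(1 / gam, 1e-3), 1e3) else 1e3
    bFit <- list(b = b, illPosed = gam <= 0)
  }
  mseS <- sseSub(a)
  mseD <- mean((Rs - Rc / bFit$b)^2)
  list(a = a, b = bFit$b, mseSubtractive = mseS, mseDivisive = mseD,
       logMseSubtractive = log10(mseS), logMseDivisive = log10(mseD),
       illPosedDivisive = isTRUE(bFit$illPosed))
}

#' Preferred versus orthogonal surround at high and low center contrast
#'
#' Measures the response with the preferred-orientation surround and the
#' orthogonal surround at each center contrast (normalized by the
#' center-alone response at that contrast). The orthogonal-minus-
#' preferred difference quantifies how much more suppressive the matched
#' surround is; it shrinks at low center contrast.
#'
#' @inheritParams orientationTriplet
#' @param centerContrasts contrast levels (default high = 1 and the
#'   standard 17% low-contrast condition).
#' @return data.frame: contrast, preferred, orthogonal, difference.
#' @export
surroundContrastComparison <- function(net, neuron, optimal, geometry, gsf,
                                       centerContrasts = c(1, 0.17),
                                       nPhases = 8L) {
  rows <- lapply(centerContrasts, function(cc) {
    norm <- csResponse(net, neuron, optimal, geometry, gsf,
                       thC = optimal$orientation, nPhases = nPhases,
                       centerContrast = cc)
    pref <- csResponse(net, neuron, optimal, geometry, gsf,
                       thC = optimal$orientation,
                       thS = optimal$orientation,
                       nPhases = nPhases, centerContrast = cc)
    orth <- csResponse(net, neuron, optimal, geometry, gsf,
                       thC = optimal$orientation,
                       thS = (optimal$orientation + 90) %% 180,
                       nPhases = nPhases, centerContrast = cc)
    if (norm > 0) { pref <- pref / norm; orth <- orth / norm }
    data.frame(contrast = cc, preferred = pref, orthogonal = orth,
               difference = orth - pref)
  })
  do.call(rbind, rows)
}
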