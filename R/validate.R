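## Validation analyses: FWHM point-spread radii, detection scoring,
## ROC/AUC, and the grid perturbation battery.

#' Full-width-half-maximum radius of the PLV-vs-distance profile
#'
#' Orders the PLVs from a seed vertex to every other vertex by Cartesian
#' distance, smooths the profile by distance-binned means, and returns
#' the smallest distance at which the profile falls to half its maximum.
#' This radius quantifies the spatial point spread of the reconstruction
#' around a source.
#'
#' @param plv a [PLVMatrix-class].
#' @param geom a [SurfaceGeometry-class] with matching vertex count.
#' @param seedVertex index of the seed vertex.
#' @param nBins number of distance bins (default 25).
#' @return list with `radius` (the half-max distance, linearly
#'   interpolated between bin centers), `binWidth`, and `profile`
#'   (data.frame of bin centers and mean PLV).  A profile that never
#'   falls to half its maximum is an error (undefined FWHM).
#' @export
computeFwhm <- function(plv, geom, seedVertex, nBins = 25L) {
  stopifnot(is(plv, "PLVMatrix"), is(geom, "SurfaceGeometry"))
  V <- geom@vertices
  if (nrow(V) != nrow(plv@values)) stop("geometry/PLV dimension mismatch")
  seedVertex <- as.integer(seedVertex)
  d <- sqrt(rowSums(sweep(V, 2L, V[seedVertex, ])^2))
  vals <- plv@values[seedVertex, ]
  d <- d[-seedVertex]; vals <- vals[-seedVertex]
  breaks <- seq(0, max(d) * (1 + 1e-9), length.out = nBins + 1L)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  prof <- vapply(seq_len(nBins), function(b)
    if (any(bin == b)) mean(vals[bin == b]) else NA_real_, numeric(1))
  centers <- (breaks[-1L] + breaks[-(nBins + 1L)]) / 2
  ok <- !is.na(prof)
  prof <- prof[ok]; centers <- centers[ok]
  half <- max(prof) / 2
  below <- which(prof <= half)
  if (!length(below))
    stop("flat profile: PLV never falls to half its maximum")
  i <- below[1L]
  radius <- if (i == 1L) centers[1L] else {
    ## linear interpolation between the straddling bin centers
    f <- (prof[i - 1L] - half) / (prof[i - 1L] - prof[i])
    centers[i - 1L] + f * (centers[i] - centers[i - 1L])
  }
  list(radius = radius, binWidth = diff(breaks[1:2]),
       profile = data.frame(distance = centers, plv = prof))
}

## Unordered-pair key for edge lookup.
pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))

#' Score a region network against simulation ground truth
#'
#' Two definitions of a true positive are evaluated.  Dipole criterion:
#' the clusters containing the two generator vertices are significantly
#' connected.  FWHM criterion (when radii are supplied): at least one
#' cluster intersecting each generator's FWHM ball is significantly
#' connected to a cluster intersecting the other's.  False positives are
#' significant pairs wholly outside both criteria; the FPR denominator
#' is the number of pairs outside the truth-eligible set.
#'
#' @param network a [RegionNetwork-class].
#' @param parc the [Parcellation-class] the network was built on.
#' @param truth integer vector of the two generator vertex indices.
#' @param geom geometry (required for the FWHM criterion and centroid
#'   offsets).
#' @param fwhmRadii optional numeric vector of two FWHM radii.
#' @return list with `tpDipole`, `pDipole`, `tpFwhm`, `nFP`,
#'   `nNegatives`, `fpr`, and `centroidOffsets` (distance between each
#'   generator and the mass center of its significantly connected
#'   FWHM-cluster centroids; NA when undefined).
#' @export
scoreDetection <- function(network, parc, truth, geom = NULL,
                           fwhmRadii = NULL) {
  stopifnot(is(network, "RegionNetwork"), is(parc, "Parcellation"),
            length(truth) == 2L)
  labels <- parcelLabels(parc)
  edges <- networkEdges(network)
  keys <- pairKey(edges$regionA, edges$regionB)
  sigKeys <- keys[edges$significant]
  ca <- labels[truth[1L]]; cb <- labels[truth[2L]]

  eligible <- character()
  tpDipole <- FALSE; pDipole <- NA_real_
  if (ca != cb) {
    kd <- pairKey(ca, cb)
    eligible <- kd
    tpDipole <- kd %in% sigKeys
    pDipole <- edges$p[keys == kd]
  }

  tpFwhm <- NA
  centroidOffsets <- c(NA_real_, NA_real_)
  if (!is.null(fwhmRadii)) {
    if (is.null(geom)) stop("geom required for the FWHM criterion")
    V <- geom@vertices
    ball <- function(v, r) {
      d <- sqrt(rowSums(sweep(V, 2L, V[v, ])^2))
      unique(labels[d <= r])
    }
    setA <- ball(truth[1L], fwhmRadii[1L])
    setB <- ball(truth[2L], fwhmRadii[2L])
    fPairs <- unique(unlist(lapply(setA, function(a)
      vapply(setB[setB != a], pairKey, character(1), a = a))))
    eligible <- unique(c(eligible, fPairs))
    tpFwhm <- any(fPairs %in% sigKeys)
    ## centroid offsets: mass center of significantly connected
    ## FWHM-cluster centroids on each side
    clCentroid <- function(cl)
      colMeans(V[labels == cl, , drop = FALSE])
    conn <- function(mySet, otherSet) {
      hits <- mySet[vapply(mySet, function(a)
        any(pairKey(a, otherSet[otherSet != a]) %in% sigKeys),
        logical(1))]
      if (!length(hits)) return(NULL)
      colMeans(do.call(rbind, lapply(hits, clCentroid)))
    }
    mA <- conn(setA, setB); mB <- conn(setB, setA)
    if (!is.null(mA))
      centroidOffsets[1L] <- sqrt(sum((mA - V[truth[1L], ])^2))
    if (!is.null(mB))
      centroidOffsets[2L] <- sqrt(sum((mB - V[truth[2L], ])^2))
  }

  nNeg <- length(keys) - length(eligible)
  nFP <- sum(!sigKeys %in% eligible)
  list(tpDipole = tpDipole, pDipole = pDipole, tpFwhm = tpFwhm,
       nFP = nFP, nNegatives = nNeg,
       fpr = if (nNeg > 0) nFP / nNeg else NA_real_,
       centroidOffsets = centroidOffsets)
}

#' ROC curve and AUC from an alpha sweep
#'
#' Sorts (FPR, TPR) operating points, anchors the curve at (0, 0) and
#' (1, 1), and integrates the area under the curve by the trapezoid
#' rule.
#'
#' @param results data.frame with columns `fpr` and `tpr` (one row per
#'   alpha or threshold).
#' @return list with `points` (ordered data.frame) and `auc`.
#' @export
rocAnalysis <- function(results) {
  stopifnot(all(c("fpr", "tpr") %in% names(results)))
  if (nrow(results) < 2L) stop("need at least two operating points")
  pts <- rbind(data.frame(fpr = 0, tpr = 0),
               results[, c("fpr", "tpr")],
               data.frame(fpr = 1, tpr = 1))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  pts <- unique(pts)
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  list(points = pts, auc = auc)
}

#' ROC from detection scores and binary labels
#'
#' Sweeps a decision threshold across all observed score values
#' (`score >= threshold` predicts positive) and feeds the operating
#' points to [rocAnalysis()].  Perfectly separated scores give AUC 1;
#' scores independent of the labels give AUC near 0.5.
#'
#' @param scores numeric detection scores (higher = more positive).
#' @param labels logical (or 0/1) ground-truth labels.
#' @return as [rocAnalysis()].
#' @export
rocFromScores <- function(scores, labels) {
  labels <- as.logical(labels)
  if (all(labels) || !any(labels))
    stop("degenerate single-class truth")
  thr <- sort(unique(scores))
  ops <- do.call(rbind, lapply(thr, function(th) {
    pred <- scores >= th
    data.frame(tpr = sum(pred & labels) / sum(labels),
               fpr = sum(pred & !labels) / sum(!labels))
  }))
  rocAnalysis(ops)
}

#' Grid perturbation battery
#'
#' Runs the full pipeline on grid simulations under the four
#' perturbation conditions -- SNR multipliers (2.0, 1.0, 0.5, 0.1),
#' low-frequency modulators (0.1, 0.5, 1, 5 Hz), phase-jitter bounds
#' (pi/10, pi/4, pi/2, pi) and frequency offsets (w2 = 20, 15, 10, 1 Hz
#' against w1 = 25 Hz) -- with `reps` repetitions per setting (4 x 4 x
#' reps runs in total; the study design uses 50 repetitions).  Each run
#' simulates an active grid and an independent signal-free null grid,
#' computes the PLV matrix at the carrier frequency, parcellates, tests
#' all region pairs, and scores detection of the generator-block
#' connection.  Repetition seeds are shared across settings so
#' settings are compared on paired noise realizations.
#'
#' Defaults are desk-scale: a 30 x 30 grid, 8 s records and a base SNR
#' of -17 dB, which places the generators at the same signal-to-noise-
#' floor operating point that the full-scale study (-26 dB, 300 s)
#' occupies; see the package vignette for the derivation.
#'
#' @param reps repetitions per setting.
#' @param seed master seed.
#' @param gridDims,blockSize,duration,fs grid scenario geometry.
#' @param carrier generator/analysis frequency w1 (Hz).
#' @param cRatio wavelet spectral ratio.
#' @param k number of regions.
#' @param alpha significance level.
#' @param snrDb base SNR in dB at multiplier 1.
#' @param minPerms,maxPerms,maxEdges,stopTol permutation-test controls.
#' @param decimate phase decimation for [pairwisePLV()].
#' @param nstart k-means restarts.
#' @param conditions named list of the four setting vectors.
#' @return data.frame with one row per run: `condition`, `setting`,
#'   `rep`, `tp`, `p`, `fpr`, `nFP`.
#' @seealso [batteryTPR()] to aggregate true-positive rates.
#' @export
perturbationBattery <- function(reps = 50L, seed = 1L,
                                gridDims = c(30L, 30L), blockSize = 5L,
                                duration = 8, fs = 250, carrier = 25,
                                cRatio = 7, k = 40L, alpha = 0.05,
                                snrDb = -17, minPerms = 5000L,
                                maxPerms = 6000L, maxEdges = 100L,
                                stopTol = 1e-4, decimate = 6L,
                                nstart = 3L,
                                conditions = list(
                                  snr = c(2, 1, 0.5, 0.1),
                                  modulation = c(0.1, 0.5, 1, 5),
                                  jitter = c(pi / 10, pi / 4, pi / 2, pi),
                                  frequency = c(20, 15, 10, 1))) {
  set.seed(as.integer(seed))
  repSeeds <- sample.int(.Machine$integer.max - 1L, reps)
  nullSeeds <- sample.int(.Machine$integer.max - 1L, reps)
  spec <- makeWaveletSpec(carrier, cRatio)
  rows <- list()
  for (cond in names(conditions)) {
    for (setting in conditions[[cond]]) {
      for (r in seq_len(reps)) {
        scn <- switch(cond,
          snr = gridScenario(gridDims, blockSize, w1 = carrier,
                             amplitudeMultiplier = setting,
                             snrDb = snrDb, duration = duration,
                             fs = fs, seed = repSeeds[r]),
          modulation = gridScenario(gridDims, blockSize, w1 = carrier,
                                    modFreq = setting, snrDb = snrDb,
                                    duration = duration, fs = fs,
                                    seed = repSeeds[r]),
          jitter = gridScenario(gridDims, blockSize, w1 = carrier,
                                jitterM = setting, snrDb = snrDb,
                                duration = duration, fs = fs,
                                seed = repSeeds[r]),
          frequency = gridScenario(gridDims, blockSize, w1 = carrier,
                                   w2 = setting, snrDb = snrDb,
                                   duration = duration, fs = fs,
                                   seed = repSeeds[r]))
        rest <- simulateGrid(scn)
        null <- simulateGrid(nullGridScenario(gridDims, duration, fs,
                                              seed = nullSeeds[r]))
        sc <- gridDetectionRun(rest, null, spec, k, alpha,
                               seed = repSeeds[r], minPerms = minPerms,
                               maxPerms = maxPerms, maxEdges = maxEdges,
                               stopTol = stopTol, decimate = decimate,
                               nstart = nstart)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, setting = setting, rep = r,
          tp = sc$tpDipole, p = sc$pDipole, fpr = sc$fpr, nFP = sc$nFP)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## One pipeline run on a simulated grid pair, scored against truth.
gridDetectionRun <- function(rest, null, spec, k, alpha, seed,
                             minPerms, maxPerms, maxEdges, stopTol,
                             decimate, nstart) {
  plvR <- pairwisePLV(rest$series, spec, decimate = decimate)
  plvN <- pairwisePLV(null$series, spec, decimate = decimate)
  evc <- eigenvectorCentrality(plvR)
  feats <- buildFeatures(rest$geometry, evc, dropConstant = TRUE)
  parc <- kmeansCosine(feats, k, seed = seed, nstart = nstart)
  net <- buildRegionNetwork(plvR, plvN, parc, alpha = alpha, seed = seed,
                            minPerms = minPerms, maxPerms = maxPerms,
                            maxEdges = maxEdges, stopTol = stopTol)
  scoreDetection(net, parc, rest$truth$centers, geom = rest$geometry)
}

#' Aggregate battery true-positive rates
#'
#' @param battery output of [perturbationBattery()].
#' @return data.frame of mean TPR and FPR per condition and setting.
#' @export
batteryTPR <- function(battery) {
  agg <- aggregate(cbind(tp, fpr) ~ condition + setting, data = battery,
                   FUN = mean, na.action = stats::na.omit)
  names(agg)[names(agg) == "tp"] <- "tpr"
  agg[order(agg$condition, agg$setting), ]
}
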