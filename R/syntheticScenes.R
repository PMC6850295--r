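# rasterise an ellipse: centre (cr, cc) in rows/cols, semi-axes a >= b,
# orientation theta; returns logical matrix of the given dimensions
.ellipseMask <- function(nr, nc, cr, cc, a, b, theta) {
    rr <- matrix(seq_len(nr), nr, nc) - cr
    ccM <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
    u <- ccM * cos(theta) + rr * sin(theta)
    v <- -ccM * sin(theta) + rr * cos(theta)
    (u / a)^2 + (v / b)^2 <= 1
}

.composeScene <- function(nr, nc, labels, fgLevels, bgLevel, rampAmplitude,
                          blurSigma, noiseSd, bitDepth) {
    img <- matrix(bgLevel + 0, nr, nc)
    if (max(labels) > 0L)
        img[labels > 0L] <- fgLevels[labels[labels > 0L]]
    if (rampAmplitude != 0) {
        ramp <- rampAmplitude * (2 * (seq_len(nc) - 1) / (nc - 1) - 1)
        img <- img + matrix(ramp, nr, nc, byrow = TRUE)
    }
    if (blurSigma > 0) img <- .gaussSmooth(img, blurSigma)
    if (noiseSd > 0)
        img <- img + stats::rnorm(length(img), 0, noiseSd)
    top <- 2^bitDepth - 1
    greyImage(pmin(pmax(round(img), 0), top), bitDepth)
}

#' Generate a synthetic nuclei-like scene with ground truth
#'
#' Places non-overlapping, randomly oriented ellipses (dark objects) on a
#' brighter background, each with its own mean intensity, optionally adds a
#' linear illumination ramp across the field (from -amplitude at the left
#' edge to +amplitude at the right), blurs edges with a Gaussian, and adds
#' seeded Gaussian noise. The gold standard is the ideal pre-blur label
#' mask, so edge blur alone already makes a Jaccard of exactly 1
#' unattainable by design.
#'
#' @param nObjects number of ellipses (default 20).
#' @param width,height image size in pixels (default 256 x 256).
#' @param radiusRange semi-major axis range in pixels (default 8--16).
#' @param fgRange object mean-intensity range (default 50--120).
#' @param bgLevel background level (default 200).
#' @param rampAmplitude illumination ramp amplitude in grey levels
#'   (default 0; e.g. 40 gives a -40..+40 left-to-right ramp).
#' @param blurSigma edge blur sigma in pixels (default 1).
#' @param noiseSd additive Gaussian noise sd in grey levels (default 0).
#' @param seed integer seed; scenes are fully determined by it.
#' @param bitDepth 8 (default) or 16.
#' @param axisRatioRange minor/major semi-axis ratio range (default
#'   0.7--1, keeping objects plausibly nucleus-like and circular).
#' @param minGap minimum gap between object envelopes in pixels (default 4).
#' @param centres optional n x 2 matrix of (row, col) centres overriding
#'   random placement.
#' @param fgLevels optional vector of per-object intensities overriding the
#'   random draw.
#' @param maxTries placement attempts before an infeasible-packing error.
#' @return a [SyntheticScene-class] with gold class \code{objects}.
#' @examples
#' sc <- generateScene(nObjects = 5, width = 96, height = 96, seed = 7)
#' sc
#' @export
generateScene <- function(nObjects = 20, width = 256, height = 256,
                          radiusRange = c(8, 16), fgRange = c(50, 120),
                          bgLevel = 200, rampAmplitude = 0, blurSigma = 1,
                          noiseSd = 0, seed = 1, bitDepth = 8L,
                          axisRatioRange = c(0.7, 1), minGap = 4,
                          centres = NULL, fgLevels = NULL,
                          maxTries = 200 * max(nObjects, 1)) {
    stopifnot(radiusRange[1L] >= 2, nObjects >= 0)
    params <- list(preset = "nuclei", nObjects = nObjects, width = width,
                   height = height, radiusRange = radiusRange,
                   fgRange = fgRange, bgLevel = bgLevel,
                   rampAmplitude = rampAmplitude, blurSigma = blurSigma,
                   noiseSd = noiseSd, seed = seed, bitDepth = bitDepth,
                   axisRatioRange = axisRatioRange, minGap = minGap)
    scene <- .withSeed(seed, {
        labels <- matrix(0L, height, width)
        ctr <- matrix(NA_real_, nObjects, 2L)
        rad <- numeric(nObjects)
        placed <- 0L
        tries <- 0L
        while (placed < nObjects && tries < maxTries) {
            tries <- tries + 1L
            a <- stats::runif(1, radiusRange[1L], radiusRange[2L])
            b <- max(2, a * stats::runif(1, axisRatioRange[1L],
                                         axisRatioRange[2L]))
            theta <- stats::runif(1, 0, pi)
            if (is.null(centres)) {
                m <- a + 2
                cr <- stats::runif(1, 1 + m, height - m)
                cc <- stats::runif(1, 1 + m, width - m)
            } else {
                cr <- centres[placed + 1L, 1L]
                cc <- centres[placed + 1L, 2L]
            }
            if (placed > 0L) {
                dd <- sqrt((ctr[seq_len(placed), 1L] - cr)^2 +
                           (ctr[seq_len(placed), 2L] - cc)^2)
                if (any(dd < rad[seq_len(placed)] + a + minGap)) {
                    if (!is.null(centres))
                        stop("supplied centres produce overlapping objects")
                    next
                }
            }
            placed <- placed + 1L
            ctr[placed, ] <- c(cr, cc)
            rad[placed] <- a
            labels[.ellipseMask(height, width, cr, cc, a, b, theta)] <-
                placed
        }
        if (placed < nObjects)
            stop(sprintf(
                "infeasible packing: placed %d of %d objects in %d tries",
                placed, nObjects, maxTries))
        fg <- if (is.null(fgLevels))
            round(stats::runif(max(nObjects, 1L), fgRange[1L], fgRange[2L]))
        else rep_len(fgLevels, max(nObjects, 1L))
        img <- .composeScene(height, width, labels, fg, bgLevel,
                             rampAmplitude, blurSigma, noiseSd, bitDepth)
        list(img = img, labels = labels, fg = fg)
    })
    params$fgLevels <- scene$fg
    new("SyntheticScene", image = scene$img,
        gold = list(objects = scene$labels), params = params)
}

#' Generate a three-tone scene (nuclei inside cells)
#'
#' Concentric ellipse pairs mimic cells with darker nuclei: nucleus tone <
#' cytoplasm tone < background tone. The boundary-gradient curve of such a
#' scene shows one local maximum between nucleus and cytoplasm tones
#' (thresholding there segments nuclei) and one between cytoplasm and
#' background (segmenting whole cells). Gold carries the two label classes
#' \code{nuclei} and \code{cells}.
#'
#' @param nCells number of cells (default 5).
#' @param width,height image size (default 192 x 192).
#' @param tones numeric vector \code{c(nucleus, cytoplasm, background)},
#'   strictly increasing (default 60, 140, 220).
#' @param cellRadiusRange cell semi-major axis range (default 14--20).
#' @param nucleusFraction nucleus semi-axis as a fraction of the cell's
#'   (default 0.5).
#' @param blurSigma,noiseSd,seed,bitDepth,axisRatioRange,minGap,maxTries as
#'   in [generateScene()].
#' @return a [SyntheticScene-class] with gold classes \code{nuclei} and
#'   \code{cells}.
#' @export
threeToneScene <- function(nCells = 5, width = 192, height = 192,
                           tones = c(60, 140, 220),
                           cellRadiusRange = c(14, 20),
                           nucleusFraction = 0.5, blurSigma = 1,
                           noiseSd = 0, seed = 1, bitDepth = 8L,
                           axisRatioRange = c(0.8, 1), minGap = 6,
                           maxTries = 200 * max(nCells, 1)) {
    if (!(tones[1L] < tones[2L] && tones[2L] < tones[3L]))
        stop("tones must satisfy nucleus < cytoplasm < background")
    params <- list(preset = "threetone", nCells = nCells, width = width,
                   height = height, tones = tones,
                   cellRadiusRange = cellRadiusRange,
                   nucleusFraction = nucleusFraction, blurSigma = blurSigma,
                   noiseSd = noiseSd, seed = seed, bitDepth = bitDepth)
    scene <- .withSeed(seed, {
        cells <- matrix(0L, height, width)
        nuclei <- matrix(0L, height, width)
        ctr <- matrix(NA_real_, nCells, 2L)
        rad <- numeric(nCells)
        placed <- 0L
        tries <- 0L
        while (placed < nCells && tries < maxTries) {
            tries <- tries + 1L
            a <- stats::runif(1, cellRadiusRange[1L], cellRadiusRange[2L])
            b <- max(2, a * stats::runif(1, axisRatioRange[1L],
                                         axisRatioRange[2L]))
            theta <- stats::runif(1, 0, pi)
            m <- a + 2
            cr <- stats::runif(1, 1 + m, height - m)
            cc <- stats::runif(1, 1 + m, width - m)
            if (placed > 0L) {
                dd <- sqrt((ctr[seq_len(placed), 1L] - cr)^2 +
                           (ctr[seq_len(placed), 2L] - cc)^2)
                if (any(dd < rad[seq_len(placed)] + a + minGap)) next
            }
            placed <- placed + 1L
            ctr[placed, ] <- c(cr, cc)
            rad[placed] <- a
            cells[.ellipseMask(height, width, cr, cc, a, b, theta)] <-
                placed
            nuclei[.ellipseMask(height, width, cr, cc,
                                max(2, a * nucleusFraction),
                                max(2, b * nucleusFraction), theta)] <-
                placed
        }
        if (placed < nCells)
            stop(sprintf(
                "infeasible packing: placed %d of %d cells in %d tries",
                placed, nCells, maxTries))
        img <- matrix(tones[3L] + 0, height, width)
        img[cells > 0L] <- tones[2L]
        img[nuclei > 0L] <- tones[1L]
        if (blurSigma > 0) img <- .gaussSmooth(img, blurSigma)
        if (noiseSd > 0)
            img <- img + stats::rnorm(length(img), 0, noiseSd)
        top <- 2^bitDepth - 1
        list(img = greyImage(pmin(pmax(round(img), 0), top), bitDepth),
             cells = cells, nuclei = nuclei)
    })
    new("SyntheticScene", image = scene$img,
        gold = list(nuclei = scene$nuclei, cells = scene$cells),
        params = params)
}
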