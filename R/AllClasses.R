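#' @import methods
NULL

#' GreyImage: a single-channel greyscale raster
#'
#' Container for an intensity image with an explicit bit depth. Pixel values
#' are stored as an integer matrix indexed \code{[row, column]} (origin
#' top-left); coordinates reported by the package are 0-based \code{(x, y)} =
#' \code{(column - 1, row - 1)}.
#'
#' @slot pixels integer matrix of grey levels.
#' @slot bitDepth integer, 8 or 16; all pixels must lie in
#'   \code{[0, 2^bitDepth - 1]}.
#'
#' @seealso [greyImage()], [pixels()], [bitDepth()]
#' @exportClass GreyImage
setClass("GreyImage",
         representation(pixels = "matrix", bitDepth = "integer"))

setValidity("GreyImage", function(object) {
    px <- object@pixels
    if (!is.numeric(px)) return("'pixels' must be a numeric matrix")
    if (length(object@bitDepth) != 1L || !object@bitDepth %in% c(8L, 16L))
        return("'bitDepth' must be 8 or 16")
    if (anyNA(px)) return("'pixels' must not contain NA")
    top <- 2^object@bitDepth - 1
    if (min(px) < 0 || max(px) > top)
        return(sprintf("pixel values must lie in [0, %d]", top))
    if (any(px != round(px))) return("pixel values must be integers")
    TRUE
})

#' GradientCurve: per-level boundary-gradient statistics
#'
#' For every candidate threshold level L the curve records the size of the
#' phase boundary N(L), the total gradient over the boundary and the average
#' gradient per boundary pixel. The optimal global threshold is the level
#' maximising one of the two statistics.
#'
#' @slot levels integer vector of grey levels (image minimum to maximum).
#' @slot nBoundary integer vector, boundary pixel counts N(L).
#' @slot gTotal numeric vector, summed gradient over the boundary at each L.
#' @slot gAverage numeric vector, mean gradient per boundary pixel
#'   (0 where N(L) = 0).
#' @slot polarity character, \code{"dark"} or \code{"bright"}.
#'
#' @seealso [gradientCurves()], [findOptimalThreshold()],
#'   [findThresholdMaxima()]
#' @exportClass GradientCurve
setClass("GradientCurve",
         representation(levels = "integer", nBoundary = "integer",
                        gTotal = "numeric", gAverage = "numeric",
                        polarity = "character"))

setValidity("GradientCurve", function(object) {
    n <- length(object@levels)
    if (length(object@nBoundary) != n || length(object@gTotal) != n ||
        length(object@gAverage) != n)
        return("all per-level vectors must have equal length")
    if (any(object@nBoundary < 0) || any(object@gTotal < 0) ||
        any(object@gAverage < 0))
        return("curve entries must be non-negative")
    pos <- object@nBoundary > 0
    if (any(abs(object@gTotal[pos] -
                object@gAverage[pos] * object@nBoundary[pos]) >
            1e-6 * pmax(1, object@gTotal[pos])))
        return("gTotal must equal gAverage * nBoundary where nBoundary > 0")
    if (any(object@gAverage[!pos] != 0))
        return("gAverage must be 0 where nBoundary = 0")
    TRUE
})

#' ObjectSpec: shape and size admission constraints
#'
#' Object specification applied to candidate regions while the labelled
#' boundary stack is built: a region is admitted iff its circularity
#' (4 pi Area / Perimeter^2) is at least \code{minCircularity} and its area
#' lies in \code{[minArea, maxArea]} (all bounds inclusive).
#'
#' @slot minCircularity numeric in [0, 1].
#' @slot minArea,maxArea numeric areas in squared pixels, 0 < minArea <= maxArea.
#'
#' @seealso [objectSpec()], [passesSpec()]
#' @exportClass ObjectSpec
setClass("ObjectSpec",
         representation(minCircularity = "numeric", minArea = "numeric",
                        maxArea = "numeric"))

setValidity("ObjectSpec", function(object) {
    if (length(object@minCircularity) != 1L ||
        object@minCircularity < 0 || object@minCircularity > 1)
        return("'minCircularity' must be a single value in [0, 1]")
    if (length(object@minArea) != 1L || length(object@maxArea) != 1L ||
        object@minArea <= 0 || object@minArea > object@maxArea)
        return("area bounds must satisfy 0 < minArea <= maxArea")
    TRUE
})

#' LabelledBoundarySlice: scored boundary components at one level
#'
#' One slice of the labelled boundary stack S: the 8-connected components of
#' the phase boundary E(L), each labelled with the average gradient over its
#' pixels, together with the area and circularity of the corresponding filled
#' region (used by the object specification filter).
#'
#' @slot level integer grey level L.
#' @slot labels integer matrix; 0 = not boundary, k = pixel of component k.
#' @slot scores numeric vector; \code{scores[k]} is the mean gradient of
#'   component k.
#' @slot regionArea numeric vector, filled-region areas (NA when no spec was
#'   applied and the region was not measured).
#' @slot regionCircularity numeric vector, filled-region circularities (NA as
#'   above).
#'
#' @seealso [labelBoundaries()], [buildProjection()]
#' @exportClass LabelledBoundarySlice
setClass("LabelledBoundarySlice",
         representation(level = "integer", labels = "matrix",
                        scores = "numeric", regionArea = "numeric",
                        regionCircularity = "numeric"))

setValidity("LabelledBoundarySlice", function(object) {
    k <- length(object@scores)
    if (max(0L, object@labels) > k)
        return("label ids exceed the number of scores")
    if (length(object@regionArea) != k || length(object@regionCircularity) != k)
        return("per-component vectors must have equal length")
    if (any(object@scores < 0)) return("scores must be non-negative")
    TRUE
})

#' ProjectionImage: maximum projection of the labelled boundary stack
#'
#' Per-pixel maximum of the boundary-component scores over all threshold
#' levels (the simplified gradient P), plus provenance: the level whose
#' boundary won at each pixel (lower level wins exact ties; NA where no
#' boundary ever occurred).
#'
#' @slot scores numeric matrix of projected scores (>= 0).
#' @slot levels integer matrix of winning levels (NA where scores == 0 and no
#'   boundary was seen).
#' @slot polarity character, search polarity used.
#'
#' @seealso [buildProjection()], [regionalMaxima()]
#' @exportClass ProjectionImage
setClass("ProjectionImage",
         representation(scores = "matrix", levels = "matrix",
                        polarity = "character"))

setValidity("ProjectionImage", function(object) {
    if (!all(dim(object@scores) == dim(object@levels)))
        return("'scores' and 'levels' must have identical dimensions")
    if (min(object@scores) < 0) return("projected scores must be >= 0")
    TRUE
})

#' SegmentationResult: final mask with per-region provenance
#'
#' The binary mask produced by the region-based method (filled regional
#' maxima of the projection) together with a region table carrying, for each
#' detected region, the grey level and score of the winning boundary, its
#' area, circularity, centroid (0-based x = column, y = row) and whether it
#' touches the image frame.
#'
#' @slot mask logical matrix, final foreground.
#' @slot labels integer matrix labelling the 8-connected regions of the mask.
#' @slot regions data.frame with columns \code{region_id}, \code{source_level},
#'   \code{score}, \code{area}, \code{circularity}, \code{touches_border},
#'   \code{centroid_x}, \code{centroid_y}.
#'
#' @seealso [segmentRegions()], [excludeBorderRegions()], [matchObjects()]
#' @exportClass SegmentationResult
setClass("SegmentationResult",
         representation(mask = "matrix", labels = "matrix",
                        regions = "data.frame"))

setValidity("SegmentationResult", function(object) {
    if (!is.logical(object@mask)) return("'mask' must be a logical matrix")
    if (!all(dim(object@mask) == dim(object@labels)))
        return("'mask' and 'labels' must have identical dimensions")
    if (!identical(unname(object@mask), unname(object@labels > 0L)))
        return("'mask' must be the union of the labelled regions")
    TRUE
})

#' SyntheticScene: generated test image with ground truth
#'
#' A synthetic nuclei-like scene: roughly elliptical dark objects of varying
#' mean intensity on a brighter background, optionally with a linear
#' illumination ramp, Gaussian edge blur and additive Gaussian noise. The
#' gold standard holds the ideal (pre-blur) object masks.
#'
#' @slot image a [GreyImage-class].
#' @slot gold named list of integer label matrices (one entry per object
#'   class; nuclei scenes have \code{$objects}, three-tone scenes
#'   \code{$nuclei} and \code{$cells}).
#' @slot params named list recording every generation parameter, including
#'   the seed.
#'
#' @seealso [generateScene()], [threeToneScene()]
#' @exportClass SyntheticScene
setClass("SyntheticScene",
         representation(image = "GreyImage", gold = "list", params = "list"))

setValidity("SyntheticScene", function(object) {
    d <- dim(object@image@pixels)
    for (g in object@gold) {
        if (!all(dim(g) == d))
            return("gold label matrices must match the image dimensions")
        if (min(g) < 0) return("gold labels must be non-negative")
    }
    TRUE
})

#' EvaluationReport: object-matched Jaccard evaluation
#'
#' Pairing of gold-standard objects with detected regions by greatest
#' overlap, with the per-pair Jaccard index and its mean over all gold
#' objects (unmatched gold objects count 0).
#'
#' @slot matches data.frame with columns \code{gold_id}, \code{test_id}
#'   (NA when unmatched) and \code{jaccard}.
#' @slot meanJaccard numeric scalar.
#' @slot nGold,nTest integer object counts.
#'
#' @seealso [matchObjects()], [meanJaccard()]
#' @exportClass EvaluationReport
setClass("EvaluationReport",
         representation(matches = "data.frame", meanJaccard = "numeric",
                        nGold = "integer", nTest = "integer"))

setValidity("EvaluationReport", function(object) {
    j <- object@matches$jaccard
    if (any(j < 0 | j > 1)) return("Jaccard values must lie in [0, 1]")
    if (object@meanJaccard < 0 || object@meanJaccard > 1)
        return("'meanJaccard' must lie in [0, 1]")
    TRUE
})
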