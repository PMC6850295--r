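#' Construct a GreyImage
#'
#' @param pixels numeric matrix of integer grey levels, indexed
#'   \code{[row, column]}.
#' @param bitDepth 8 or 16.
#' @return a [GreyImage-class] object.
#' @examples
#' img <- greyImage(matrix(0:63, 8, 8))
#' dim(img)
#' bitDepth(img)
#' @export
greyImage <- function(pixels, bitDepth = 8L) {
    pixels <- as.matrix(pixels)
    # plain integer matrix: drop any reader metadata attributes
    pixels <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
    new("GreyImage", pixels = pixels, bitDepth = as.integer(bitDepth))
}

#' Pixel raster of an image-like object
#' @param x a [GreyImage-class].
#' @return integer matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "GreyImage", function(x) x@pixels)

#' Bit depth of an image
#' @param x a [GreyImage-class].
#' @return 8 or 16.
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @rdname bitDepth
#' @export
setMethod("bitDepth", "GreyImage", function(x) x@bitDepth)

#' @describeIn greyImage image dimensions (rows, columns)
#' @param x a GreyImage
#' @export
setMethod("dim", "GreyImage", function(x) dim(x@pixels))

#' Grey-level range of an image
#'
#' The minimum and maximum grey level actually present, defining the
#' exhaustive threshold search range.
#' @param x a [GreyImage-class].
#' @return integer vector \code{c(min, max)}.
#' @export
setGeneric("greyRange", function(x) standardGeneric("greyRange"))

#' @rdname greyRange
#' @export
setMethod("greyRange", "GreyImage", function(x) range(x@pixels))

setMethod("show", "GreyImage", function(object) {
    d <- dim(object@pixels)
    r <- range(object@pixels)
    cat(sprintf("GreyImage %d x %d, %d-bit, grey levels [%d, %d]\n",
                d[1L], d[2L], object@bitDepth, r[1L], r[2L]))
})

setMethod("show", "GradientCurve", function(object) {
    cat(sprintf("GradientCurve over %d levels [%d, %d], polarity '%s'\n",
                length(object@levels), min(object@levels),
                max(object@levels), object@polarity))
    pos <- object@nBoundary > 0
    if (any(pos))
        cat(sprintf("  argmax gTotal: L = %d; argmax gAverage: L = %d\n",
                    object@levels[pos][which.max(object@gTotal[pos])],
                    object@levels[pos][which.max(object@gAverage[pos])]))
})

#' @describeIn gradientCurves coerce a curve to a data.frame with columns
#'   \code{level}, \code{n_boundary}, \code{g_total}, \code{g_average}
#' @export
setMethod("as.data.frame", "GradientCurve", function(x, ...) {
    data.frame(level = x@levels, n_boundary = x@nBoundary,
               g_total = x@gTotal, g_average = x@gAverage)
})

setMethod("show", "ProjectionImage", function(object) {
    d <- dim(object@scores)
    cat(sprintf(
        "ProjectionImage %d x %d, polarity '%s', max score %.4g, %d scored px\n",
        d[1L], d[2L], object@polarity, max(object@scores),
        sum(object@scores > 0)))
})

setMethod("show", "SegmentationResult", function(object) {
    cat(sprintf("SegmentationResult: %d region(s), %d foreground px\n",
                nrow(object@regions), sum(object@mask)))
    if (nrow(object@regions))
        print(utils::head(object@regions, 10L))
})

setMethod("show", "SyntheticScene", function(object) {
    cat(sprintf("SyntheticScene (%s): ", object@params$preset))
    show(object@image)
    cat(sprintf("  gold classes: %s\n",
                paste(names(object@gold), collapse = ", ")))
})

setMethod("show", "EvaluationReport", function(object) {
    cat(sprintf(
        "EvaluationReport: %d gold vs %d test object(s), mean Jaccard %.4f\n",
        object@nGold, object@nTest, object@meanJaccard))
})

setMethod("show", "ObjectSpec", function(object) {
    cat(sprintf(
        "ObjectSpec: circularity >= %.2f, area in [%g, %g] px^2\n",
        object@minCircularity, object@minArea, object@maxArea))
})

setMethod("show", "LabelledBoundarySlice", function(object) {
    cat(sprintf("LabelledBoundarySlice at L = %d: %d component(s)\n",
                object@level, length(object@scores)))
})

#' Mask and labels of a segmentation result
#' @param x a [SegmentationResult-class].
#' @return \code{segMask}: logical matrix; \code{segLabels}: integer label
#'   matrix; \code{regionTable}: the per-region data.frame.
#' @export
setGeneric("segMask", function(x) standardGeneric("segMask"))

#' @rdname segMask
#' @export
setMethod("segMask", "SegmentationResult", function(x) x@mask)

#' @rdname segMask
#' @export
setGeneric("segLabels", function(x) standardGeneric("segLabels"))

#' @rdname segMask
#' @export
setMethod("segLabels", "SegmentationResult", function(x) x@labels)

#' @rdname segMask
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @rdname segMask
#' @export
setMethod("regionTable", "SegmentationResult", function(x) x@regions)

#' Mean Jaccard index of an evaluation report
#' @param x an [EvaluationReport-class].
#' @return numeric scalar in [0, 1].
#' @export
setGeneric("meanJaccard", function(x) standardGeneric("meanJaccard"))

#' @rdname meanJaccard
#' @export
setMethod("meanJaccard", "EvaluationReport", function(x) x@meanJaccard)

#' @rdname meanJaccard
#' @export
setGeneric("matchTable", function(x) standardGeneric("matchTable"))

#' @rdname meanJaccard
#' @export
setMethod("matchTable", "EvaluationReport", function(x) x@matches)

#' Accessors for synthetic scenes
#' @param x a [SyntheticScene-class].
#' @return \code{sceneImage}: the [GreyImage-class]; \code{sceneGold}: named
#'   list of integer label matrices; \code{sceneParams}: parameter list.
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))

#' @rdname sceneImage
#' @export
setMethod("sceneImage", "SyntheticScene", function(x) x@image)

#' @rdname sceneImage
#' @export
setGeneric("sceneGold", function(x) standardGeneric("sceneGold"))

#' @rdname sceneImage
#' @export
setMethod("sceneGold", "SyntheticScene", function(x) x@gold)

#' @rdname sceneImage
#' @export
setGeneric("sceneParams", function(x) standardGeneric("sceneParams"))

#' @rdname sceneImage
#' @export
setMethod("sceneParams", "SyntheticScene", function(x) x@params)

#' Projection accessors
#' @param x a [ProjectionImage-class].
#' @return \code{projScores}: numeric score matrix; \code{projLevels}:
#'   integer matrix of winning levels (NA where never covered).
#' @export
setGeneric("projScores", function(x) standardGeneric("projScores"))

#' @rdname projScores
#' @export
setMethod("projScores", "ProjectionImage", function(x) x@scores)

#' @rdname projScores
#' @export
setGeneric("projLevels", function(x) standardGeneric("projLevels"))

#' @rdname projScores
#' @export
setMethod("projLevels", "ProjectionImage", function(x) x@levels)
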