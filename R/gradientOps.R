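#' Gaussian preprocessing of a greyscale image
#'
#' Smooths the image with a separable Gaussian kernel (sigma = \code{radius},
#' truncated at 3 sigma, replicate border padding), then rounds and clips
#' back to the image's bit-depth range. \code{radius = 0} returns the input
#' unchanged.
#'
#' @param image a [GreyImage-class].
#' @param radius non-negative Gaussian sigma in pixels.
#' @return a smoothed [GreyImage-class] of identical dimensions and depth.
#' @examples
#' img <- greyImage(matrix(c(rep(0L, 32), rep(200L, 32)), 8, 8))
#' gaussianPreprocess(img, 1)
#' @export
gaussianPreprocess <- function(image, radius) {
    stopifnot(is(image, "GreyImage"))
    if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
        stop("'radius' must be a single non-negative number")
    if (radius == 0) return(image)
    sm <- .gaussSmooth(image@pixels + 0, radius)
    top <- 2^image@bitDepth - 1
    greyImage(pmin(pmax(round(sm), 0), top), image@bitDepth)
}

#' Greyscale gradient magnitude of an image
#'
#' Computes the gradient image G used to score candidate phase boundaries.
#' \code{"beucher"} is the morphological gradient: greyscale dilation minus
#' erosion with the 3 x 3 square structuring element. \code{"sobel"} is the
#' Euclidean magnitude of the two 3 x 3 Sobel directional responses, kept in
#' full floating precision. Borders use replicate padding for both.
#'
#' @param image a [GreyImage-class] (or bare numeric matrix).
#' @param method \code{"beucher"} (default) or \code{"sobel"}.
#' @return numeric matrix of non-negative gradient magnitudes, same
#'   dimensions as the input.
#' @examples
#' img <- greyImage(matrix(c(rep(0L, 32), rep(10L, 32)), 8, 8))
#' range(computeGradient(img, "beucher"))
#' @export
computeGradient <- function(image, method = c("beucher", "sobel")) {
    method <- match.arg(method)
    px <- if (is(image, "GreyImage")) image@pixels + 0 else {
        stopifnot(is.matrix(image), is.numeric(image))
        image + 0
    }
    if (method == "beucher") {
        .localMax3(px) - .localMin3(px)
    } else {
        kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
        ky <- t(kx)
        sqrt(.conv3(px, kx)^2 + .conv3(px, ky)^2)
    }
}

#' Boundary of a thresholded phase
#'
#' Extracts the one-pixel inner boundary E(L) of a binary phase mask B(L).
#' \code{"internal_gradient"} (default) is the mask minus its erosion by the
#' 3 x 3 square, with outside-image treated as background so that regions
#' touching the frame contribute frame-edge boundary pixels and every
#' boundary stays a closed curve for filling. \code{"laplacian"} marks
#' foreground pixels with a nonzero response of the 4- or 8-neighbourhood
#' Laplacian kernel applied to the 0/1 mask.
#'
#' @param mask logical matrix (the phase).
#' @param method \code{"internal_gradient"} or \code{"laplacian"}.
#' @param laplacianNeighbourhood 4 or 8; kernel used when
#'   \code{method = "laplacian"}.
#' @return logical matrix, a subset of \code{mask}.
#' @examples
#' m <- matrix(FALSE, 7, 7); m[3:5, 3:5] <- TRUE
#' which(phaseBoundary(m))
#' @export
phaseBoundary <- function(mask, method = c("internal_gradient", "laplacian"),
                          laplacianNeighbourhood = 8) {
    method <- match.arg(method)
    stopifnot(is.matrix(mask))
    if (!is.logical(mask)) mask <- mask > 0
    if (method == "internal_gradient") {
        mask & !.binErode3(mask)
    } else {
        if (!laplacianNeighbourhood %in% c(4, 8))
            stop("'laplacianNeighbourhood' must be 4 or 8")
        kern <- if (laplacianNeighbourhood == 4)
            matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3, 3)
        else
            matrix(c(-1, -1, -1, -1, 8, -1, -1, -1, -1), 3, 3)
        # outside-image treated as background (0) to keep frame boundaries
        m01 <- matrix(0, nrow(mask), ncol(mask)); m01[mask] <- 1
        resp <- matrix(0, nrow(mask), ncol(mask))
        for (i in 1:3) for (j in 1:3)
            if (kern[i, j] != 0)
                resp <- resp + kern[i, j] * .shiftPad(m01, i - 2L, j - 2L, 0)
        mask & resp != 0
    }
}
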