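.checkPolarity <- function(polarity)
    match.arg(polarity, c("dark", "bright"))

#' Threshold an image into a binary phase
#'
#' For dark objects on a bright background the phase is every pixel with
#' value at most \code{level} (inclusive); for bright objects, every pixel
#' with value at least \code{level}.
#'
#' @param image a [GreyImage-class].
#' @param level integer grey level within the image's grey range.
#' @param polarity \code{"dark"} (default) or \code{"bright"}.
#' @return logical matrix (TRUE = phase).
#' @examples
#' img <- greyImage(matrix(0:24, 5, 5))
#' sum(thresholdPhase(img, 10L))
#' @export
thresholdPhase <- function(image, level, polarity = c("dark", "bright")) {
    polarity <- .checkPolarity(polarity)
    stopifnot(is(image, "GreyImage"))
    r <- range(image@pixels)
    if (!is.numeric(level) || length(level) != 1L ||
        level < r[1L] || level > r[2L])
        stop(sprintf("'level' must lie within the image grey range [%d, %d]",
                     r[1L], r[2L]))
    if (polarity == "dark") image@pixels <= level else image@pixels >= level
}

#' Boundary-gradient curves over all threshold levels
#'
#' Exhaustive sweep of the grey range: for every level L the phase B(L) and
#' its boundary E(L) are computed; the curve records the boundary pixel count
#' N(L), the total gradient over E(L) and the average gradient per boundary
#' pixel (0 where the boundary is empty).
#'
#' @param image a [GreyImage-class].
#' @param gradient either a gradient matrix of matching dimensions or the
#'   name of a gradient method ([computeGradient()]), default
#'   \code{"beucher"}.
#' @param polarity \code{"dark"} or \code{"bright"}.
#' @param boundaryMethod passed to [phaseBoundary()].
#' @return a [GradientCurve-class].
#' @examples
#' sc <- generateScene(nObjects = 3, width = 64, height = 64, seed = 1)
#' crv <- gradientCurves(sceneImage(sc))
#' findOptimalThreshold(crv, "average")
#' @export
gradientCurves <- function(image, gradient = "beucher",
                           polarity = c("dark", "bright"),
                           boundaryMethod = c("internal_gradient",
                                              "laplacian")) {
    polarity <- .checkPolarity(polarity)
    boundaryMethod <- match.arg(boundaryMethod)
    stopifnot(is(image, "GreyImage"))
    G <- if (is.character(gradient)) computeGradient(image, gradient)
         else gradient
    if (!all(dim(G) == dim(image@pixels)))
        stop("'gradient' dimensions must match the image")
    px <- image@pixels
    r <- range(px)
    lev <- r[1L]:r[2L]
    nB <- integer(length(lev))
    gT <- numeric(length(lev))
    for (i in seq_along(lev)) {
        B <- if (polarity == "dark") px <= lev[i] else px >= lev[i]
        E <- phaseBoundary(B, boundaryMethod)
        nB[i] <- sum(E)
        if (nB[i] > 0L) gT[i] <- sum(G[E])
    }
    gA <- ifelse(nB > 0L, gT / pmax(nB, 1L), 0)
    new("GradientCurve", levels = lev, nBoundary = nB,
        gTotal = gT, gAverage = gA, polarity = polarity)
}

.curveStat <- function(curve, statistic)
    switch(statistic, total = curve@gTotal, average = curve@gAverage)

#' Optimal global threshold from a gradient curve
#'
#' Returns the level maximising the chosen statistic over levels with a
#' non-empty boundary; ties break toward the smallest level.
#'
#' @param curve a [GradientCurve-class].
#' @param statistic \code{"average"} (default) or \code{"total"}.
#' @return integer grey level.
#' @export
findOptimalThreshold <- function(curve, statistic = c("average", "total")) {
    statistic <- match.arg(statistic)
    stopifnot(is(curve, "GradientCurve"))
    ok <- curve@nBoundary > 0L
    if (!any(ok))
        stop("no phase found: every level has an empty boundary")
    s <- .curveStat(curve, statistic)[ok]
    curve@levels[ok][which.max(s)]
}

#' Local maxima of a gradient curve (candidate multiple thresholds)
#'
#' Interior local maxima of the chosen statistic, ranked by value
#' (descending; ties toward the smaller level). Plateaus are reported at
#' their smallest level; sequence end points are not maxima. Peaks whose
#' prominence (height above the higher of the two flanking valleys, walking
#' outward until strictly higher terrain or the sequence end) is below
#' \code{minProminence} are suppressed, as are levels with an empty boundary.
#'
#' @param curve a [GradientCurve-class].
#' @param statistic \code{"average"} (default) or \code{"total"}.
#' @param maxCount maximum number of thresholds to return (>= 1).
#' @param minProminence non-negative prominence cut-off (gradient units).
#' @return integer vector of levels, possibly shorter than \code{maxCount}.
#' @export
findThresholdMaxima <- function(curve, statistic = c("average", "total"),
                                maxCount = 2L, minProminence = 0) {
    statistic <- match.arg(statistic)
    stopifnot(is(curve, "GradientCurve"))
    if (maxCount < 1L) stop("'maxCount' must be >= 1")
    if (minProminence < 0) stop("'minProminence' must be >= 0")
    s <- .curveStat(curve, statistic)
    n <- length(s)
    if (n < 3L) return(integer(0))
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- length(r$values)
    peaks <- integer(0)
    proms <- numeric(0)
    if (k >= 3L) for (j in 2:(k - 1L)) {
        v <- r$values[j]
        if (v > r$values[j - 1L] && v > r$values[j + 1L]) {
            pos <- starts[j]
            if (curve@nBoundary[pos] == 0L) next
            # prominence: lowest point toward strictly higher terrain, per side
            left <- v; for (jj in (j - 1L):1L) {
                if (r$values[jj] > v) break
                left <- min(left, r$values[jj])
            }
            right <- v; for (jj in (j + 1L):k) {
                if (r$values[jj] > v) break
                right <- min(right, r$values[jj])
            }
            prom <- v - max(left, right)
            if (prom >= minProminence) {
                peaks <- c(peaks, pos)
                proms <- c(proms, v)
            }
        }
    }
    if (!length(peaks)) return(integer(0))
    ord <- order(-proms, curve@levels[peaks])
    curve@levels[peaks][utils::head(ord, maxCount)]
}
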