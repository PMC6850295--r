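# fill + measure one boundary component given as a padded (1-px background
# margin) bounding-box mask; cheap pre-checks reject huge or tiny components
# without a full fill (the filled region is sandwiched between the boundary
# pixels and the bounding box)
.measureComponent <- function(pad, spec = NULL) {
    if (!is.null(spec)) {
        if ((nrow(pad) - 2L) * (ncol(pad) - 2L) < spec@minArea)
            return(list(area = NA_real_, circ = NA_real_, pass = FALSE))
        if (sum(pad) > spec@maxArea)
            return(list(area = NA_real_, circ = NA_real_, pass = FALSE))
    }
    filled <- fillRegions(pad)
    a <- sum(filled)
    circ <- min(1, 4 * pi * a / regionPerimeter(filled)^2)
    pass <- if (is.null(spec)) TRUE else
        (a >= spec@minArea && a <= spec@maxArea &&
         circ >= spec@minCircularity)
    list(area = a, circ = circ, pass = pass)
}

#' Label and score the boundary components at one level
#'
#' Extracts the 8-connected components of a phase-boundary mask and labels
#' each with the average gradient over its pixels. When an object
#' specification is supplied, components whose filled region fails the
#' circularity/size test are dropped before storage, so that only boundaries
#' of plausible objects enter the stack.
#'
#' @param boundary logical matrix, the phase boundary E(L).
#' @param gradient numeric gradient matrix of matching dimensions.
#' @param level integer grey level the boundary belongs to.
#' @param spec an [ObjectSpec-class] or NULL (no filtering).
#' @return a [LabelledBoundarySlice-class]; retained components are
#'   relabelled 1..k.
#' @export
labelBoundaries <- function(boundary, gradient, level, spec = NULL) {
    stopifnot(is.matrix(boundary), all(dim(boundary) == dim(gradient)))
    if (!is.logical(boundary)) boundary <- boundary > 0
    if (!is.null(spec)) stopifnot(is(spec, "ObjectSpec"))
    lab <- .label8(boundary)
    k <- max(lab)
    if (k == 0L)
        return(new("LabelledBoundarySlice", level = as.integer(level),
                   labels = lab, scores = numeric(0),
                   regionArea = numeric(0), regionCircularity = numeric(0)))
    idx <- which(boundary)
    comp <- lab[idx]
    scores <- as.vector(rowsum(gradient[idx], comp)) /
        tabulate(comp, nbins = k)
    area <- rep(NA_real_, k)
    circ <- rep(NA_real_, k)
    keep <- rep(TRUE, k)
    if (!is.null(spec)) {
        nr <- nrow(boundary)
        rows <- (idx - 1L) %% nr + 1L
        cols <- (idx - 1L) %/% nr + 1L
        for (c0 in seq_len(k)) {
            sel <- comp == c0
            rs <- rows[sel]; cs <- cols[sel]
            r1 <- min(rs); c1 <- min(cs)
            pad <- matrix(FALSE, max(rs) - r1 + 3L, max(cs) - c1 + 3L)
            pad[cbind(rs - r1 + 2L, cs - c1 + 2L)] <- TRUE
            m <- .measureComponent(pad, spec)
            area[c0] <- m$area
            circ[c0] <- m$circ
            keep[c0] <- m$pass
        }
    }
    newId <- integer(k)
    newId[keep] <- seq_len(sum(keep))
    lab2 <- matrix(0L, nrow(boundary), ncol(boundary))
    kept <- keep[comp]
    lab2[idx[kept]] <- newId[comp[kept]]
    new("LabelledBoundarySlice", level = as.integer(level), labels = lab2,
        scores = scores[keep], regionArea = area[keep],
        regionCircularity = circ[keep])
}

.sliceScoreImage <- function(slice) {
    v <- c(0, slice@scores)[slice@labels + 1L]
    matrix(v, nrow(slice@labels), ncol(slice@labels))
}

#' Maximum projection of the labelled boundary stack
#'
#' Runs the exhaustive threshold sweep: at every level L the phase boundary
#' is extracted, its components scored (and optionally filtered by the
#' object specification), and the scored slice enters the stack S. The
#' projection P is the per-pixel maximum over all slices. \code{"stack"}
#' materialises every slice and reduces at the end; \code{"cumulative"}
#' keeps a single running maximum (the memory-efficient variant). Both
#' produce bit-identical projections. Provenance (the level whose boundary
#' won at each pixel; the lower level on exact ties) is recorded alongside.
#'
#' @param image a [GreyImage-class].
#' @param gradient gradient matrix or method name (default \code{"beucher"}).
#' @param polarity \code{"dark"} or \code{"bright"}.
#' @param spec an [ObjectSpec-class] or NULL.
#' @param mode \code{"cumulative"} (default) or \code{"stack"}.
#' @param boundaryMethod passed to [phaseBoundary()].
#' @return a [ProjectionImage-class].
#' @export
buildProjection <- function(image, gradient = "beucher",
                            polarity = c("dark", "bright"), spec = NULL,
                            mode = c("cumulative", "stack"),
                            boundaryMethod = c("internal_gradient",
                                               "laplacian")) {
    polarity <- .checkPolarity(polarity)
    mode <- match.arg(mode)
    boundaryMethod <- match.arg(boundaryMethod)
    stopifnot(is(image, "GreyImage"))
    G <- if (is.character(gradient)) computeGradient(image, gradient)
         else gradient
    if (!all(dim(G) == dim(image@pixels)))
        stop("'gradient' dimensions must match the image")
    px <- image@pixels
    r <- range(px)
    lev <- r[1L]:r[2L]
    d <- dim(px)
    slices <- if (mode == "stack") vector("list", length(lev))
    proj <- matrix(0, d[1L], d[2L])
    won <- matrix(NA_integer_, d[1L], d[2L])
    for (i in seq_along(lev)) {
        B <- if (polarity == "dark") px <= lev[i] else px >= lev[i]
        E <- phaseBoundary(B, boundaryMethod)
        if (!any(E)) next
        slice <- labelBoundaries(E, G, lev[i], spec)
        if (!length(slice@scores)) next
        simg <- .sliceScoreImage(slice)
        if (mode == "stack") {
            slices[[i]] <- simg
        } else {
            upd <- simg > proj
            proj[upd] <- simg[upd]
            won[upd] <- lev[i]
        }
    }
    if (mode == "stack") {
        for (i in seq_along(lev)) {
            if (is.null(slices[[i]])) next
            upd <- slices[[i]] > proj
            proj[upd] <- slices[[i]][upd]
            won[upd] <- lev[i]
        }
    }
    new("ProjectionImage", scores = proj, levels = won, polarity = polarity)
}

#' Regional maxima of a projection
#'
#' Connected plateaus of constant value (8-connectivity, exact floating
#' equality) all of whose exterior 8-neighbours have strictly lower values.
#' A constant image is a single plateau with no exterior neighbours and is
#' returned whole.
#'
#' @param projection a [ProjectionImage-class] or bare numeric matrix.
#' @return logical matrix of regional-maximum pixels.
#' @export
regionalMaxima <- function(projection) {
    p <- if (is(projection, "ProjectionImage")) projection@scores
         else projection
    stopifnot(is.matrix(p), is.numeric(p), all(is.finite(p)))
    nr <- nrow(p); nc <- ncol(p)
    # seed: any pixel with a strictly greater 8-neighbour
    sup <- matrix(FALSE, nr, nc)
    for (k in seq_len(nrow(.OFF8)))
        sup <- sup | .shiftPad(p, .OFF8[k, 1L], .OFF8[k, 2L], -Inf) > p
    supv <- as.vector(sup)
    pv <- as.vector(p)
    frontier <- which(supv)
    # propagate suppression across equal-valued plateau neighbours
    while (length(frontier)) {
        nb <- .neigh8(frontier, nr, nc)
        keep <- !supv[nb$to] & pv[nb$to] == pv[nb$from]
        nxt <- unique(nb$to[keep])
        supv[nxt] <- TRUE
        frontier <- nxt
    }
    matrix(!supv, nr, nc)
}

#' Fill closed regions in a binary mask
#'
#' Background 4-connected to the image frame is identified by flood fill;
#' everything else becomes foreground. Closed boundary curves become solid
#' regions; open arcs stay thin.
#'
#' @param maxima logical matrix (e.g. regional maxima of the projection).
#' @return logical matrix with enclosed holes filled.
#' @export
fillRegions <- function(maxima) {
    stopifnot(is.matrix(maxima))
    if (!is.logical(maxima)) maxima <- maxima > 0
    !.floodFromFrame4(!maxima)
}

#' Region-based adaptive threshold segmentation
#'
#' End-to-end region-based method: build the maximum projection of the
#' scored boundary stack, take its regional maxima, fill the closed
#' boundaries, and report each resulting region with its provenance (the
#' grey level and score of the winning boundary), area, circularity,
#' centroid and a flag marking regions that touch the image frame.
#'
#' @param image a [GreyImage-class].
#' @param polarity \code{"dark"} or \code{"bright"}.
#' @param spec an [ObjectSpec-class] or NULL (no object specification).
#' @param gradientMethod \code{"beucher"} or \code{"sobel"}.
#' @param mode \code{"cumulative"} or \code{"stack"}.
#' @param gaussRadius optional Gaussian preprocessing radius (0 = none).
#' @param boundaryMethod passed to [phaseBoundary()].
#' @return a [SegmentationResult-class]; the region list may be empty.
#' @examples
#' sc <- generateScene(nObjects = 3, width = 64, height = 64, seed = 1)
#' seg <- segmentRegions(sceneImage(sc), spec = objectSpec(0.4, 50, 2000))
#' regionTable(seg)
#' @export
segmentRegions <- function(image, polarity = c("dark", "bright"),
                           spec = NULL,
                           gradientMethod = c("beucher", "sobel"),
                           mode = c("cumulative", "stack"),
                           gaussRadius = 0,
                           boundaryMethod = c("internal_gradient",
                                              "laplacian")) {
    polarity <- .checkPolarity(polarity)
    gradientMethod <- match.arg(gradientMethod)
    mode <- match.arg(mode)
    boundaryMethod <- match.arg(boundaryMethod)
    stopifnot(is(image, "GreyImage"))
    if (gaussRadius > 0) image <- gaussianPreprocess(image, gaussRadius)
    proj <- buildProjection(image, gradientMethod, polarity, spec, mode,
                            boundaryMethod)
    d <- dim(proj@scores)
    emptyRegions <- data.frame(region_id = integer(0),
                               source_level = integer(0),
                               score = numeric(0), area = numeric(0),
                               circularity = numeric(0),
                               touches_border = logical(0),
                               centroid_x = numeric(0),
                               centroid_y = numeric(0))
    if (max(proj@scores) == 0)      # no boundary scored at any level
        return(new("SegmentationResult",
                   mask = matrix(FALSE, d[1L], d[2L]),
                   labels = matrix(0L, d[1L], d[2L]),
                   regions = emptyRegions))
    R <- regionalMaxima(proj)
    filled <- fillRegions(R)
    labs <- .label8(filled)
    k <- max(labs)
    if (k == 0L)
        return(new("SegmentationResult", mask = filled, labels = labs,
                   regions = emptyRegions))
    idx <- which(filled)
    comp <- labs[idx]
    rows <- (idx - 1L) %% d[1L] + 1L
    cols <- (idx - 1L) %/% d[1L] + 1L
    onFrame <- rows == 1L | rows == d[1L] | cols == 1L | cols == d[2L]
    Rv <- R[idx]
    srcLevel <- integer(k); srcScore <- numeric(k)
    area <- numeric(k); circ <- numeric(k); touch <- logical(k)
    cx <- numeric(k); cy <- numeric(k)
    for (c0 in seq_len(k)) {
        sel <- comp == c0
        area[c0] <- sum(sel)
        touch[c0] <- any(onFrame[sel])
        cx[c0] <- mean(cols[sel]) - 1
        cy[c0] <- mean(rows[sel]) - 1
        cm <- matrix(FALSE, d[1L], d[2L])
        cm[idx[sel]] <- TRUE
        circ[c0] <- min(1, 4 * pi * area[c0] / regionPerimeter(cm)^2)
        ring <- sel & Rv                 # the winning-boundary pixels
        if (any(ring)) {
            sc <- proj@scores[idx[ring]]
            best <- max(sc)
            srcScore[c0] <- best
            srcLevel[c0] <- min(proj@levels[idx[ring]][sc == best],
                                na.rm = TRUE)
        } else {
            srcScore[c0] <- NA_real_
            srcLevel[c0] <- NA_integer_
        }
    }
    regions <- data.frame(region_id = seq_len(k), source_level = srcLevel,
                          score = srcScore, area = area, circularity = circ,
                          touches_border = touch, centroid_x = cx,
                          centroid_y = cy)
    new("SegmentationResult", mask = filled, labels = labs, regions = regions)
}
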