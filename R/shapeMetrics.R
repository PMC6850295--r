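#' Object specification constructor
#'
#' @param minCircularity minimum circularity in [0, 1] (default 0.5).
#' @param minArea,maxArea inclusive area bounds in squared pixels
#'   (defaults 250 and 3000, the nuclei operating range).
#' @return an [ObjectSpec-class].
#' @examples
#' objectSpec(0.5, 250, 3000)
#' @export
objectSpec <- function(minCircularity = 0.5, minArea = 250, maxArea = 3000) {
    new("ObjectSpec", minCircularity = as.numeric(minCircularity),
        minArea = as.numeric(minArea), maxArea = as.numeric(maxArea))
}

.asRegionMask <- function(region) {
    stopifnot(is.matrix(region))
    if (!is.logical(region)) region <- region > 0
    if (!any(region)) stop("region is empty")
    region
}

#' Region area
#'
#' @param region logical matrix (TRUE = member pixel).
#' @return pixel count.
#' @export
regionArea <- function(region) sum(.asRegionMask(region))

# clockwise Moore neighbourhood (row grows downward):
# W, NW, N, NE, E, SE, S, SW
.MOORE <- cbind(dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
                dc = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L))
.MOORE_LEN <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

#' Region perimeter (outer contour walk)
#'
#' Length of the outer 8-connected contour traced by Moore-neighbour
#' following: axial steps count 1, diagonal steps sqrt(2). A single pixel is
#' assigned perimeter 4 (its unit-square contour). The region must be one
#' 8-connected component; for regions with holes only the outer contour is
#' measured.
#'
#' @param region logical matrix (TRUE = member pixel).
#' @return perimeter in pixel lengths.
#' @examples
#' sq <- matrix(FALSE, 12, 12); sq[2:11, 2:11] <- TRUE
#' regionPerimeter(sq)  # 36
#' @export
regionPerimeter <- function(region) {
    region <- .asRegionMask(region)
    nr <- nrow(region); nc <- ncol(region)
    start <- which(region)[1L]
    r0 <- (start - 1L) %% nr + 1L
    c0 <- (start - 1L) %/% nr + 1L
    inReg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc &&
        region[r, c]
    # start pixel is first in column-major order: W and N neighbours are
    # outside the region
    p <- c(r0, c0)
    dirToB <- 1L                     # backtrack lies W of the start
    startP <- p
    firstQ <- NULL
    perim <- 0
    maxSteps <- 8L * sum(region) + 8L
    for (step in seq_len(maxSteps)) {
        found <- FALSE
        for (s in 1:8) {
            d <- (dirToB + s - 1L) %% 8L + 1L   # scan clockwise after b
            q <- p + .MOORE[d, ]
            if (inReg(q[1L], q[2L])) {
                # stop when the initial move start -> firstQ repeats
                if (!is.null(firstQ) && all(p == startP) &&
                    all(q == firstQ))
                    return(perim)
                if (is.null(firstQ)) firstQ <- q
                perim <- perim + .MOORE_LEN[d]
                # new backtrack: last background position checked, i.e. the
                # previous clockwise direction, expressed relative to q
                prev <- (dirToB + s - 2L) %% 8L + 1L
                bpos <- p + .MOORE[prev, ]
                off <- bpos - q
                dirToB <- which(.MOORE[, 1L] == off[1L] &
                                .MOORE[, 2L] == off[2L])
                p <- q
                found <- TRUE
                break
            }
        }
        if (!found) return(4)        # isolated pixel
    }
    perim
}

#' Circularity of a region
#'
#' 4 pi Area / Perimeter^2, capped at 1 (small digital shapes can exceed 1
#' under any discrete perimeter estimator). 1 for an ideal circle, tending
#' to 0 for elongated shapes.
#'
#' @param region logical matrix (TRUE = member pixel).
#' @return value in (0, 1].
#' @export
circularity <- function(region) {
    region <- .asRegionMask(region)
    min(1, 4 * pi * sum(region) / regionPerimeter(region)^2)
}

#' Does a region satisfy an object specification?
#'
#' TRUE iff circularity >= \code{minCircularity} and the area lies within
#' \code{[minArea, maxArea]}; all bounds inclusive.
#'
#' @param region logical matrix (TRUE = member pixel).
#' @param spec an [ObjectSpec-class].
#' @return logical scalar.
#' @export
passesSpec <- function(region, spec) {
    stopifnot(is(spec, "ObjectSpec"))
    region <- .asRegionMask(region)
    a <- sum(region)
    if (a < spec@minArea || a > spec@maxArea) return(FALSE)
    circularity(region) >= spec@minCircularity
}
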