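#' Jaccard index of two pixel sets
#'
#' |A intersect B| / |A union B|. Two empty sets are defined to agree
#' perfectly (index 1).
#'
#' @param a,b logical matrices of identical dimensions (or anything
#'   coercible by \code{> 0}).
#' @return value in [0, 1].
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1:2, 1:2] <- TRUE
#' jaccardIndex(m, m)  # 1
#' @export
jaccardIndex <- function(a, b) {
    if (!is.logical(a)) a <- a > 0
    if (!is.logical(b)) b <- b > 0
    stopifnot(all(dim(a) == dim(b)))
    u <- sum(a | b)
    if (u == 0L) return(1)
    sum(a & b) / u
}

.asLabels <- function(x) {
    if (is(x, "SegmentationResult")) return(x@labels)
    if (is(x, "GreyImage")) return(x@pixels)
    stopifnot(is.matrix(x))
    if (is.logical(x)) .label8(x) else {
        storage.mode(x) <- "integer"
        x
    }
}

#' Object-matched Jaccard evaluation against a gold standard
#'
#' Pairs every gold object with the detected region of greatest pixel
#' overlap (ties broken by larger Jaccard, then smaller region id); each
#' detected region is used at most once. The report's mean is taken over all
#' gold objects, with unmatched gold objects contributing 0, so missed
#' objects are penalised.
#'
#' @param test a [SegmentationResult-class], an integer label matrix, or a
#'   logical mask (labelled by 8-connectivity).
#' @param gold integer label matrix of gold-standard objects (0 =
#'   background); must contain at least one object.
#' @return an [EvaluationReport-class].
#' @examples
#' g <- matrix(0L, 8, 8); g[2:4, 2:4] <- 1L; g[6:7, 6:7] <- 2L
#' meanJaccard(matchObjects(g, g))  # 1
#' @export
matchObjects <- function(test, gold) {
    testL <- .asLabels(test)
    goldL <- .asLabels(gold)
    stopifnot(all(dim(testL) == dim(goldL)))
    goldIds <- sort(unique(goldL[goldL > 0L]))
    if (!length(goldIds)) stop("gold mask contains no objects")
    testIds <- sort(unique(testL[testL > 0L]))
    goldArea <- tabulate(goldL[goldL > 0L], nbins = max(goldIds))
    testArea <- if (length(testIds))
        tabulate(testL[testL > 0L], nbins = max(testIds)) else integer(0)
    both <- goldL > 0L & testL > 0L
    ov <- if (any(both)) {
        tb <- table(gold = goldL[both], test = testL[both])
        as.data.frame(tb, stringsAsFactors = FALSE)
    } else data.frame(gold = character(0), test = character(0),
                      Freq = integer(0))
    ov$gold <- as.integer(as.character(ov$gold))
    ov$test <- as.integer(as.character(ov$test))
    used <- integer(0)
    matches <- data.frame(gold_id = goldIds, test_id = NA_integer_,
                          jaccard = 0)
    for (i in seq_along(goldIds)) {
        gid <- goldIds[i]
        cand <- ov[ov$gold == gid & !(ov$test %in% used) & ov$Freq > 0L, ]
        if (!nrow(cand)) next
        jac <- cand$Freq /
            (goldArea[gid] + testArea[cand$test] - cand$Freq)
        ord <- order(-cand$Freq, -jac, cand$test)
        pick <- ord[1L]
        matches$test_id[i] <- cand$test[pick]
        matches$jaccard[i] <- jac[pick]
        used <- c(used, cand$test[pick])
    }
    new("EvaluationReport", matches = matches,
        meanJaccard = mean(matches$jaccard),
        nGold = length(goldIds), nTest = length(testIds))
}

#' Remove regions that intersect the image frame
#'
#' The "no borders" analysis: regions flagged as touching the frame are
#' dropped from both the mask and the region table. Remaining regions are
#' relabelled consecutively.
#'
#' @param result a [SegmentationResult-class].
#' @return a [SegmentationResult-class] without frame-touching regions.
#' @export
excludeBorderRegions <- function(result) {
    stopifnot(is(result, "SegmentationResult"))
    reg <- result@regions
    if (!nrow(reg) || !any(reg$touches_border)) return(result)
    keepIds <- reg$region_id[!reg$touches_border]
    labs <- result@labels
    labs[!(labs %in% keepIds)] <- 0L
    newId <- integer(max(1L, max(labs)))
    newId[keepIds] <- seq_along(keepIds)
    labs[labs > 0L] <- newId[labs[labs > 0L]]
    reg <- reg[!reg$touches_border, , drop = FALSE]
    reg$region_id <- seq_len(nrow(reg))
    rownames(reg) <- NULL
    new("SegmentationResult", mask = labs > 0L, labels = labs, regions = reg)
}

#' Add seeded Gaussian noise to an image
#'
#' Adds i.i.d. zero-mean Gaussian noise of the given standard deviation to
#' every pixel, then rounds and clips to the bit-depth range. The caller's
#' RNG state is left untouched.
#'
#' @param image a [GreyImage-class].
#' @param sd noise standard deviation in grey levels (>= 0).
#' @param seed integer seed; the same seed reproduces the same noise.
#' @return a [GreyImage-class].
#' @export
addGaussianNoise <- function(image, sd, seed = 1L) {
    stopifnot(is(image, "GreyImage"))
    if (!is.numeric(sd) || length(sd) != 1L || sd < 0)
        stop("'sd' must be a single non-negative number")
    if (sd == 0) return(image)
    px <- image@pixels
    noise <- .withSeed(seed, stats::rnorm(length(px), mean = 0, sd = sd))
    top <- 2^image@bitDepth - 1
    greyImage(matrix(pmin(pmax(round(px + noise), 0), top),
                     nrow(px), ncol(px)), image@bitDepth)
}

# evaluate an expression under a temporary seed, restoring the RNG state
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Noise-degradation sweep of segmentation performance
#'
#' For each noise standard deviation, Gaussian noise is added to the scene
#' image (one realisation per seed), the region-based segmentation is run,
#' and the object-matched mean Jaccard against the scene's gold standard is
#' averaged over seeds. Noise is applied to the raw image first; the
#' method's own Gaussian preprocessing (if any) then runs on the noisy
#' image, mirroring a noisy acquisition.
#'
#' @param scene a [SyntheticScene-class].
#' @param sds numeric vector of noise standard deviations (grey levels).
#' @param seeds integer vector of noise seeds.
#' @param spec an [ObjectSpec-class] or NULL.
#' @param polarity,gradientMethod,mode,gaussRadius passed to
#'   [segmentRegions()].
#' @param excludeBorder drop frame-touching regions before evaluation.
#' @param goldClass name of the gold class to evaluate against (default:
#'   first).
#' @return data.frame with columns \code{sd} and \code{mean_jaccard}.
#' @export
noiseSweep <- function(scene, sds, seeds = 1:5, spec = NULL,
                       polarity = "dark", gradientMethod = "beucher",
                       mode = "cumulative", gaussRadius = 0,
                       excludeBorder = FALSE, goldClass = NULL) {
    stopifnot(is(scene, "SyntheticScene"), length(sds) >= 1L)
    gold <- if (is.null(goldClass)) scene@gold[[1L]]
            else scene@gold[[goldClass]]
    res <- vapply(sds, function(s) {
        js <- vapply(seeds, function(sd0) {
            noisy <- addGaussianNoise(scene@image, s, sd0)
            seg <- segmentRegions(noisy, polarity = polarity, spec = spec,
                                  gradientMethod = gradientMethod,
                                  mode = mode, gaussRadius = gaussRadius)
            if (excludeBorder) seg <- excludeBorderRegions(seg)
            meanJaccard(matchObjects(seg, gold))
        }, numeric(1))
        mean(js)
    }, numeric(1))
    data.frame(sd = sds, mean_jaccard = res)
}
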