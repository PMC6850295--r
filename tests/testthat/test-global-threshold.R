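test_that("thresholding is inclusive and polarity-symmetric", {
    img <- greyImage(matrix(0:24, 5, 5))
    expect_true(all(thresholdPhase(img, 24L, "dark")))
    m <- thresholdPhase(img, 10L, "dark")
    expect_true(m[pixels(img) == 10L])          # inclusive at the level
    expect_equal(sum(m), 11)
    inv <- greyImage(255L - pixels(img))
    expect_identical(thresholdPhase(img, 10L, "dark"),
                     thresholdPhase(inv, 245L, "bright"))
    expect_error(thresholdPhase(img, 99L), "grey range")
})

test_that("phase masks nest with increasing level (threshold decomposition)", {
    for (seed in 1:3) {
        img <- randomGrey(15, 15, seed)
        px <- pixels(img)
        r <- greyRange(img)
        prev <- NULL
        for (L in r[1]:r[2]) {
            B <- thresholdPhase(img, L, "dark")
            if (!is.null(prev)) expect_true(all(B[prev]))
            prev <- B
        }
    }
})

test_that("gradient curves match the per-pixel brute-force oracle", {
    for (seed in 1:3) {
        img <- randomGrey(24, 24, seed)
        G <- computeGradient(img, "beucher")
        crv <- gradientCurves(img, G)
        ora <- bruteCurve(pixels(img), G)
        expect_identical(crv@levels, as.integer(ora$levels))
        expect_identical(crv@nBoundary, as.integer(ora$nBoundary))
        expect_equal(crv@gTotal, ora$gTotal, tolerance = 1e-12)
    }
})

test_that("curve identities hold: gTotal = gAverage * N, constant gradient", {
    img <- randomGrey(20, 20, seed = 8)
    crv <- gradientCurves(img)
    pos <- crv@nBoundary > 0
    expect_equal(crv@gTotal[pos], crv@gAverage[pos] * crv@nBoundary[pos])
    expect_true(all(crv@gAverage[!pos] == 0))
    # constant gradient raster: average equals the constant everywhere
    constG <- matrix(7, 20, 20)
    crv2 <- gradientCurves(img, constG)
    expect_true(all(crv2@gAverage[crv2@nBoundary > 0] == 7))
})

test_that("optimal threshold picks the maximum with smallest-level ties", {
    v <- c(0, 1, 5, 2, 1)
    expect_equal(findOptimalThreshold(curveFromStat(v), "average"), 2L)
    tie <- c(0, 7, 1, 7, 0)
    expect_equal(findOptimalThreshold(curveFromStat(tie), "average"), 1L)
    # levels with empty boundary are excluded from the search
    v2 <- curveFromStat(c(9, 1, 5), nBoundary = c(0L, 1L, 1L))
    expect_equal(findOptimalThreshold(v2, "average"), 2L)
    empty <- curveFromStat(c(0, 0), nBoundary = c(0L, 0L))
    expect_error(findOptimalThreshold(empty), "no phase")
})

test_that("threshold maxima: unimodal, monotone, plateau and prominence cases", {
    uni <- curveFromStat(c(0, 2, 6, 3, 1))
    expect_equal(findThresholdMaxima(uni, "average", maxCount = 2),
                 findOptimalThreshold(uni, "average"))
    mono <- curveFromStat(c(1, 2, 3, 4, 5))
    expect_length(findThresholdMaxima(mono, "average", maxCount = 3), 0)
    plateau <- curveFromStat(c(0, 5, 5, 5, 2, 8, 0))
    mx <- findThresholdMaxima(plateau, "average", maxCount = 2)
    expect_equal(mx, c(5L, 1L))    # ranked by value; plateau at smallest level
    # small bump suppressed by prominence
    bump <- curveFromStat(c(0, 9, 4, 4.6, 4, 0))
    expect_equal(findThresholdMaxima(bump, "average", maxCount = 3,
                                     minProminence = 1), 1L)
    expect_equal(findThresholdMaxima(bump, "average", maxCount = 3),
                 c(1L, 3L))
})

test_that("full global method is symmetric under image inversion", {
    sc <- generateScene(nObjects = 3, width = 64, height = 64, seed = 4)
    img <- sceneImage(sc)
    inv <- greyImage(255L - pixels(img))
    cD <- gradientCurves(img, polarity = "dark")
    cB <- gradientCurves(inv, polarity = "bright")
    tD <- findOptimalThreshold(cD, "average")
    tB <- findOptimalThreshold(cB, "average")
    expect_equal(tD, 255L - tB)
    expect_identical(thresholdPhase(img, tD, "dark"),
                     thresholdPhase(inv, tB, "bright"))
    # level axis reverses under inversion
    expect_equal(cD@gTotal, rev(cB@gTotal))
    expect_equal(cD@nBoundary, rev(cB@nBoundary))
})

test_that("both statistics separate the tones of a noise-free two-tone scene", {
    sc <- generateScene(nObjects = 4, width = 96, height = 96,
                        fgRange = c(80, 80), bgLevel = 190, seed = 6)
    crv <- gradientCurves(sceneImage(sc))
    for (st in c("total", "average")) {
        lv <- findOptimalThreshold(crv, st)
        expect_gt(lv, 80); expect_lt(lv, 190)
    }
})
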