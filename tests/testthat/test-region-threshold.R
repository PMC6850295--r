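test_that("boundary components are 8-connected and scored with mean gradient", {
    b <- matrix(FALSE, 9, 9)
    b[2, 2:4] <- TRUE                       # one 3-pixel component
    b[7, 7] <- TRUE; b[8, 8] <- TRUE        # diagonal pair: one component
    G <- matrix(0, 9, 9)
    G[2, 2:4] <- c(10, 20, 30)
    G[7, 7] <- 5; G[8, 8] <- 7
    sl <- labelBoundaries(b, G, 50L)
    expect_length(sl@scores, 2)
    expect_setequal(sl@scores, c(20, 6))
    # the diagonal pair must not fragment under 8-connectivity
    expect_equal(max(sl@labels), 2)
})

test_that("object specification drops small filled regions during labelling", {
    ring <- makeRing(40, 10, 20, 10, 20)    # filled region 11x11 = 121 px
    G <- matrix(1, 40, 40)
    keep <- labelBoundaries(ring, G, 5L, objectSpec(0, 100, 3000))
    drop <- labelBoundaries(ring, G, 5L, objectSpec(0, 250, 3000))
    expect_length(keep@scores, 1)
    expect_equal(keep@regionArea, 121)
    expect_length(drop@scores, 0)
})

test_that("regional maxima are plateaus with strictly lower exteriors", {
    p <- matrix(0, 7, 7); p[4, 4] <- 5
    rm1 <- regionalMaxima(p)
    expect_identical(which(rm1), which(p == 5))
    # two touching plateaus: only the higher survives
    p2 <- matrix(0, 5, 8)
    p2[2:4, 2:3] <- 5; p2[2:4, 4:5] <- 3
    rm2 <- regionalMaxima(p2)
    expect_true(all(rm2[p2 == 5]))
    expect_false(any(rm2[p2 == 3]))
    expect_false(any(rm2[p2 == 0]))
    # constant image: single plateau, vacuously maximal
    expect_true(all(regionalMaxima(matrix(2, 4, 4))))
})

test_that("region filling closes rings and leaves open arcs thin", {
    ring <- makeRing(9, 3, 7, 3, 7)
    filled <- fillRegions(ring)
    expect_true(all(filled[3:7, 3:7]))
    expect_equal(sum(filled), 25)
    arc <- matrix(FALSE, 6, 6); arc[2, 2:5] <- TRUE; arc[3, 5] <- TRUE
    expect_identical(fillRegions(arc), arc)
    # nested rings collapse to one solid region (no child-hole preservation)
    nest <- makeRing(13, 2, 12, 2, 12) | makeRing(13, 5, 9, 5, 9)
    fn <- fillRegions(nest)
    expect_true(all(fn[2:12, 2:12]))
})

test_that("region filling agrees with EBImage::fillHull on random blob masks", {
    suppressPackageStartupMessages(requireNamespace("EBImage"))
    set.seed(21)
    for (i in 1:5) {
        m <- matrix(runif(900) < 0.35, 30, 30)
        ours <- fillRegions(m)
        theirs <- EBImage::fillHull(matrix(as.integer(m), 30, 30)) > 0
        expect_identical(unname(ours), unname(theirs))
    }
})

test_that("stack and cumulative projections are bit-identical", {
    img <- randomGrey(32, 32, seed = 13)
    for (spec in list(NULL, objectSpec(0.3, 20, 500))) {
        a <- buildProjection(img, mode = "stack", spec = spec)
        b <- buildProjection(img, mode = "cumulative", spec = spec)
        expect_identical(projScores(a), projScores(b))
        expect_identical(projLevels(a), projLevels(b))
    }
    sc <- generateScene(nObjects = 3, width = 64, height = 64, seed = 2)
    a <- buildProjection(sceneImage(sc), mode = "stack")
    b <- buildProjection(sceneImage(sc), mode = "cumulative")
    expect_identical(projScores(a), projScores(b))
})

test_that("spec filtering can only lower the projection", {
    sc <- generateScene(nObjects = 4, width = 80, height = 80, seed = 7)
    free <- projScores(buildProjection(sceneImage(sc)))
    for (spec in list(objectSpec(0.4, 100, 3000),
                      objectSpec(0.8, 250, 500))) {
        constrained <- projScores(buildProjection(sceneImage(sc),
                                                  spec = spec))
        expect_true(all(constrained <= free))
    }
})

test_that("a single dark disk projects a closed top-scoring edge ring", {
    one <- generateScene(nObjects = 1, width = 48, height = 48,
                         fgRange = c(60, 60), centres = rbind(c(24, 24)),
                         radiusRange = c(9, 9), seed = 1)
    proj <- buildProjection(sceneImage(one))
    R <- regionalMaxima(proj)
    # the winning plateau fills to a solid region covering the gold disk
    filled <- fillRegions(R)
    gold <- sceneGold(one)$objects > 0
    expect_gt(jaccardIndex(filled, gold), 0.85)
    # maxima are locally maximal in the projection (sanity vs definition)
    s <- projScores(proj)
    idx <- which(R & s > 0, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
        r <- idx[k, 1]; c <- idx[k, 2]
        nb <- s[max(1, r - 1):min(nrow(s), r + 1),
                max(1, c - 1):min(ncol(s), c + 1)]
        expect_true(all(nb <= s[r, c]))
    }
})

test_that("segmentRegions returns provenance consistent with its regions", {
    sc <- generateScene(nObjects = 5, width = 112, height = 112, seed = 3)
    seg <- segmentRegions(sceneImage(sc), spec = objectSpec(0.4, 100, 3000))
    reg <- regionTable(seg)
    expect_gt(nrow(reg), 0)
    labs <- segLabels(seg)
    px <- pixels(sceneImage(sc))
    for (i in reg$region_id) {
        w <- which(labs == i, arr.ind = TRUE)
        rr <- range(w[, 1]); cc <- range(w[, 2])
        direct <- px[rr[1]:rr[2], cc[1]:cc[2]] <= reg$source_level[i]
        regm <- labs[rr[1]:rr[2], cc[1]:cc[2]] == i
        expect_gte(jaccardIndex(direct, regm), 0.99)
    }
    expect_true(all(reg$score > 0))
    expect_true(all(reg$area == tabulate(labs[labs > 0])))
})

test_that("segmentRegions handles blank images and harsh specs", {
    blank <- greyImage(matrix(120L, 32, 32))
    seg <- segmentRegions(blank)
    expect_equal(nrow(regionTable(seg)), 0)
    expect_false(any(segMask(seg)))
    # elongated blobs rejected by a strict circularity spec
    sc <- generateScene(nObjects = 2, width = 96, height = 96,
                        radiusRange = c(14, 15), axisRatioRange = c(0.3, 0.35),
                        fgRange = c(60, 60), seed = 5)
    segStrict <- segmentRegions(sceneImage(sc),
                                spec = objectSpec(0.9, 50, 3000))
    expect_equal(nrow(regionTable(segStrict)), 0)
})

test_that("noise-free single blob: regional mask equals the global-threshold mask", {
    one <- generateScene(nObjects = 1, width = 80, height = 80,
                         fgRange = c(60, 60), centres = rbind(c(40, 40)),
                         radiusRange = c(12, 12), seed = 9)
    img <- sceneImage(one)
    seg <- segmentRegions(img)
    glob <- thresholdPhase(img, findOptimalThreshold(gradientCurves(img),
                                                     "average"))
    expect_identical(unname(segMask(seg)), unname(glob))
})

test_that("frame-touching regions are flagged", {
    px <- matrix(200L, 60, 60)
    px[1:14, 1:14] <- 60L          # corner blob touching the frame
    px[30:44, 30:44] <- 60L        # interior blob
    img <- gaussianPreprocess(greyImage(px), 1)
    seg <- segmentRegions(img)
    reg <- regionTable(seg)
    expect_equal(sort(reg$touches_border), c(FALSE, TRUE))
})
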