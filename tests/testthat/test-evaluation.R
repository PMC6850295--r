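test_that("Jaccard index anchors and arithmetic", {
    a <- matrix(FALSE, 10, 10); a[2:5, 2:5] <- TRUE
    b <- matrix(FALSE, 10, 10); b[7:9, 7:9] <- TRUE
    expect_equal(jaccardIndex(a, a), 1)
    expect_equal(jaccardIndex(a, b), 0)
    # |intersection| 50, |union| 150
    x <- matrix(FALSE, 20, 20); x[1:10, 1:10] <- TRUE
    y <- matrix(FALSE, 20, 20); y[1:10, 6:15] <- TRUE
    expect_equal(sum(x & y), 50)
    expect_equal(sum(x | y), 150)
    expect_equal(jaccardIndex(x, y), 1 / 3)
    # both empty: defined as 1
    e <- matrix(FALSE, 4, 4)
    expect_equal(jaccardIndex(e, e), 1)
})

test_that("Jaccard is symmetric and monotone in the intersection", {
    set.seed(31)
    for (i in 1:5) {
        a <- matrix(runif(144) < 0.4, 12, 12)
        b <- matrix(runif(144) < 0.4, 12, 12)
        expect_equal(jaccardIndex(a, b), jaccardIndex(b, a))
    }
    expect_gte(jaccardIndex(x <- matrix(TRUE, 5, 5), x), jaccardIndex(x, !x))
})

test_that("object matching pairs by greatest overlap, one test region per gold", {
    g <- matrix(0L, 12, 12); g[2:5, 2:5] <- 1L; g[8:10, 8:10] <- 2L
    expect_equal(meanJaccard(matchObjects(g, g)), 1)
    # empty test segmentation
    expect_equal(meanJaccard(matchObjects(matrix(0L, 12, 12), g)), 0)
    # one gold object recovered exactly, the other missed -> mean 0.5
    t1 <- matrix(0L, 12, 12); t1[2:5, 2:5] <- 1L
    rep1 <- matchObjects(t1, g)
    expect_equal(meanJaccard(rep1), 0.5)
    expect_equal(rep1@matches$jaccard, c(1, 0))
    expect_true(is.na(rep1@matches$test_id[2]))
    # a single test region cannot serve two gold objects
    t2 <- matrix(0L, 12, 12); t2[2:10, 2:10] <- 1L
    rep2 <- matchObjects(t2, g)
    expect_equal(sum(!is.na(rep2@matches$test_id)), 1)
    expect_error(matchObjects(t1, matrix(0L, 12, 12)), "no objects")
})

test_that("border-region exclusion removes exactly the frame-touching regions", {
    # frame-hugging ring plus an interior disk
    px <- matrix(200L, 50, 50)
    px[1:10, 20:32] <- 60L           # touches row 1
    px[25:37, 20:32] <- 60L          # interior
    img <- gaussianPreprocess(greyImage(px), 1)
    seg <- segmentRegions(img)
    expect_equal(nrow(regionTable(seg)), 2)
    kept <- excludeBorderRegions(seg)
    expect_equal(nrow(regionTable(kept)), 1)
    expect_false(any(regionTable(kept)$touches_border))
    expect_false(any(segMask(kept)[1, ]))
    # idempotent on interior-only results
    expect_identical(regionTable(excludeBorderRegions(kept)),
                     regionTable(kept))
})

test_that("Gaussian noise is seeded, reproducible and correctly scaled", {
    img <- greyImage(matrix(128L, 150, 150))
    expect_identical(addGaussianNoise(img, 0, 1), img)
    n1 <- addGaussianNoise(img, 8, seed = 42)
    n2 <- addGaussianNoise(img, 8, seed = 42)
    expect_identical(pixels(n1), pixels(n2))
    n3 <- addGaussianNoise(img, 8, seed = 43)
    expect_false(identical(pixels(n1), pixels(n3)))
    # moment check at n >> 10^4, far from clipping
    resid <- as.numeric(pixels(n1)) - 128
    expect_lt(abs(sd(resid) - 8), 0.4)
    expect_error(addGaussianNoise(img, -1), "non-negative")
    # caller's RNG stream is not consumed
    set.seed(7); before <- runif(1)
    set.seed(7); invisible(addGaussianNoise(img, 3, 1)); after <- runif(1)
    expect_identical(before, after)
})

test_that("a zero-sd sweep equals the noise-free evaluation", {
    sc <- generateScene(nObjects = 4, width = 96, height = 96, seed = 11)
    spec <- objectSpec(0.4, 100, 3000)
    tab <- noiseSweep(sc, sds = 0, seeds = 1:2, spec = spec)
    seg <- segmentRegions(sceneImage(sc), spec = spec)
    direct <- meanJaccard(matchObjects(seg, sceneGold(sc)$objects))
    expect_equal(tab$mean_jaccard, direct)
    expect_equal(nrow(tab), 1)
})
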