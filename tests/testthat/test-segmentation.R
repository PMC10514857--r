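test_that("noiseless rectangular scratches are recovered exactly", {
    for (wd in c(20, 60, 100)) {
        sc <- generateScene(smallSpec(widthPx = wd, roughness = 0,
                                      noise = 0, seed = wd))
        wm <- segmentWound(sc, smallParams())
        expect_identical(woundArea(wm), truthArea(sc))
        expect_identical(truthArea(sc), as.integer(wd * 192))
        validObject(wm)   # conservation: areaPx == sum(mask), areaUm2 exact
        expect_equal(woundArea(wm, "um2"), woundArea(wm) * 1.6^2)
        expect_false(isClosed(wm))
    }
})

test_that("rough, noisy scratches are recovered within 5%", {
    for (s in 1:4) {
        sc <- generateScene(smallSpec(seed = s))
        wm <- segmentWound(sc, smallParams())
        expect_lt(abs(woundArea(wm) - truthArea(sc)) / truthArea(sc), 0.05)
    }
})

test_that("a fully confluent frame is reported closed, not an error", {
    sc <- generateScene(smallSpec(widthPx = 0, seed = 2))
    wm <- segmentWound(sc, smallParams())
    expect_true(isClosed(wm))
    expect_identical(woundArea(wm), 0L)
    expect_equal(measureCenterWidth(wm), 0)
})

test_that("segmentation is symmetric under image flips", {
    # noiseless: exact equality; noisy: within 1%
    sc0 <- generateScene(smallSpec(widthPx = 60, roughness = 0, noise = 0,
                                   seed = 5))
    a0 <- woundArea(segmentWound(sc0, smallParams()))
    pxf <- imagePixels(sceneImage(sc0))[, 256:1]
    expect_identical(woundArea(segmentWound(calibratedImage(pxf, 1.6),
                                            smallParams())), a0)
    scn <- generateScene(smallSpec(seed = 6))
    an <- woundArea(segmentWound(scn, smallParams()))
    pxn <- imagePixels(sceneImage(scn))[192:1, ]
    af <- woundArea(segmentWound(calibratedImage(pxn, 1.6), smallParams()))
    expect_lt(abs(af - an) / an, 0.01)
})

test_that("a rotated frame with scratchAxis = horizontal gives the same area", {
    sc <- generateScene(smallSpec(widthPx = 60, roughness = 0, noise = 0,
                                  seed = 5))
    pxT <- t(imagePixels(sceneImage(sc)))
    wh <- segmentWound(calibratedImage(pxT, 1.6),
                       smallParams(scratchAxis = "horizontal"))
    expect_identical(woundArea(wh), truthArea(sc))
    expect_identical(dim(woundMask(wh)), dim(pxT))
})

test_that("widening the scratch never decreases the measured area", {
    aNarrowExact <- woundArea(segmentWound(generateScene(
        smallSpec(widthPx = 50, roughness = 0, noise = 0, seed = 9)),
        smallParams()))
    aWideExact <- woundArea(segmentWound(generateScene(
        smallSpec(widthPx = 90, roughness = 0, noise = 0, seed = 9)),
        smallParams()))
    expect_identical(aWideExact - aNarrowExact, 40L * 192L)
    aNarrow <- woundArea(segmentWound(generateScene(
        smallSpec(widthPx = 60, seed = 9)), smallParams()))
    aWide <- woundArea(segmentWound(generateScene(
        smallSpec(widthPx = 90, seed = 9)), smallParams()))
    expect_gt(aWide, aNarrow * (1 - 0.02))
})

test_that("adding a migrated-cell island never increases the final area", {
    isl <- data.frame(row = 96, col = 128, radius = 10)
    for (s in c(3, 8)) {
        plain <- woundArea(segmentWound(generateScene(smallSpec(seed = s)),
                                        smallParams()))
        withIsl <- woundArea(segmentWound(
            generateScene(smallSpec(islands = isl, seed = s)), smallParams()))
        expect_lte(withIsl, plain)
    }
})

test_that("islands are subtracted, counted and sized against ground truth", {
    isl <- data.frame(row = 96, col = 128, radius = 10)
    sc <- generateScene(smallSpec(islands = isl, seed = 3))
    wm <- segmentWound(sc, smallParams())
    expect_identical(nIslands(wm), 1L)
    truthIsl <- sum(sc@truthIslandMask)
    expect_lt(abs(wm@islandAreaPx - truthIsl) / truthIsl, 0.15)
    expect_lt(abs(woundArea(wm) - truthArea(sc)) / truthArea(sc), 0.05)
})

test_that("standalone island subtraction removes islands and is a no-op without them", {
    isl <- data.frame(row = 96, col = 128, radius = 10)
    sc <- generateScene(smallSpec(islands = isl, seed = 3))
    # a huge island threshold makes segmentWound keep the island filled
    pBig <- smallParams(minIslandAreaPx = 10000L)
    wmFilled <- segmentWound(sc, pBig)
    expect_identical(nIslands(wmFilled), 0L)
    wmSub <- subtractMigratedCells(wmFilled, sceneImage(sc), smallParams())
    expect_identical(nIslands(wmSub), 1L)
    expect_lt(woundArea(wmSub), woundArea(wmFilled))
    # no-op on an island-free wound
    sc0 <- generateScene(smallSpec(seed = 4))
    wm0 <- segmentWound(sc0, smallParams())
    wmSame <- subtractMigratedCells(wm0, sceneImage(sc0))
    expect_identical(woundMask(wmSame), woundMask(wm0))
    expect_identical(nIslands(wmSame), 0L)
    # shape mismatch is a validation error
    other <- calibratedImage(matrix(1, 64, 64), 1)
    expect_error(subtractMigratedCells(wm0, other), "shape")
})

test_that("manual overrides edit the mask with exact area bookkeeping", {
    sc <- generateScene(smallSpec(widthPx = 60, roughness = 0, noise = 0,
                                  seed = 5))
    wm <- segmentWound(sc, smallParams())
    a <- woundArea(wm)
    edit <- matrix(FALSE, 192, 256)
    edit[50:54, 110:119] <- TRUE   # 50 px fully inside the wound
    wmRm <- applyManualOverride(wm, edit, "remove")
    expect_identical(woundArea(wmRm), a - 50L)
    expect_match(tail(wmRm@provenance, 1), "manual override")
    wmAdd <- applyManualOverride(wm, edit, "add")   # subset of the wound
    expect_identical(woundArea(wmAdd), a)
    wmId <- applyManualOverride(wm, matrix(FALSE, 192, 256), "remove")
    expect_identical(woundMask(wmId), woundMask(wm))
    expect_error(applyManualOverride(wm, matrix(FALSE, 10, 10)), "shape")
})

test_that("wound outlines have the expected topology", {
    sc <- generateScene(smallSpec(widthPx = 0, seed = 2))
    empty <- segmentWound(sc, smallParams())
    expect_identical(outlineWound(empty), list())
    square <- matrix(FALSE, 192, 256); square[30:39, 40:49] <- TRUE
    wmSq <- applyManualOverride(empty, square, "add")
    oc <- outlineWound(wmSq)
    expect_length(oc$outer, 1L)
    expect_length(oc$inner, 0L)
    expect_identical(attr(oc, "areaPx"), 100L)
    hole <- matrix(FALSE, 192, 256); hole[33:35, 43:45] <- TRUE
    ocH <- outlineWound(applyManualOverride(wmSq, hole, "remove"))
    expect_length(ocH$outer, 1L)
    expect_length(ocH$inner, 1L)
})

test_that("parameter validation rejects inconsistent settings", {
    expect_error(segmentationParams(textureRadiusPx = 0), "textureRadiusPx")
    expect_error(segmentationParams(thresholdMethod = "fixed"),
                 "fixedThreshold")
    expect_error(segmentationParams(thresholdMethod = "otsu",
                                    fixedThreshold = 3), "fixedThreshold")
    expect_error(segmentationParams(minWoundFraction = 1.5),
                 "minWoundFraction")
    p <- segmentationParams(thresholdMethod = "fixed", fixedThreshold = 12)
    expect_s4_class(p, "SegmentationParams")
})
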