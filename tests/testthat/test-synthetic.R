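test_that("noiseless rectangular geometry has exact truth area", {
    sc <- generateScene(smallSpec(widthPx = 80, roughness = 0, noise = 0,
                                  seed = 1))
    expect_identical(truthArea(sc), 80L * 192L)
    expect_identical(dim(truthMask(sc)), c(192L, 256L))
})

test_that("scene generation is bit-reproducible given the seed", {
    spec <- smallSpec(seed = 31)
    s1 <- generateScene(spec); s2 <- generateScene(spec)
    expect_identical(imagePixels(sceneImage(s1)), imagePixels(sceneImage(s2)))
    expect_identical(truthMask(s1), truthMask(s2))
    s3 <- generateScene(smallSpec(seed = 32))
    expect_false(identical(imagePixels(sceneImage(s1)),
                           imagePixels(sceneImage(s3))))
})

test_that("island discs are rasterized exactly and subtracted from truth", {
    isl <- data.frame(row = 96, col = 128, radius = 9)
    spec0 <- smallSpec(widthPx = 80, roughness = 0, seed = 5)
    specI <- smallSpec(widthPx = 80, roughness = 0, islands = isl, seed = 5)
    s0 <- generateScene(spec0); sI <- generateScene(specI)
    # independent oracle: direct pixel enumeration of the disc
    discPx <- sum(outer(1:192, 1:256, function(R, C)
        (R - 96)^2 + (C - 128)^2 <= 81))
    expect_identical(sum(sI@truthIslandMask), discPx)
    expect_identical(truthArea(s0) - truthArea(sI), discPx)
    expect_false(any(truthMask(sI) & sI@truthIslandMask))
})

test_that("ground truth does not depend on the noise level", {
    sNoisy <- generateScene(smallSpec(noise = 7.5, seed = 9))
    sClean <- generateScene(smallSpec(noise = 0, seed = 9))
    expect_identical(truthMask(sNoisy), truthMask(sClean))
    expect_identical(truthArea(sNoisy), truthArea(sClean))
})

test_that("invalid scene specifications are rejected", {
    expect_error(syntheticSceneSpec(scratchCenterColPx = 30,
                                    scratchWidthPx = 100), "fit inside")
    expect_error(syntheticSceneSpec(islands = data.frame(
        row = 100, col = 100, radius = 80)), "inside the scratch band")
    expect_error(syntheticSceneSpec(noiseSigma = -1), ">= 0")
})

test_that("a generated time course writes frames, truth and a valid manifest", {
    dir <- file.path(withr::local_tempdir(), "tc")
    out <- generateTimeCourse(smallSpec(seed = 1), c("0" = 1, "12" = 0.5),
                              nFovs = 2L, nReplicates = 2L, dir = dir,
                              seed = 5)
    expect_equal(out$nFrames, 8L)
    expect_length(list.files(dir, pattern = "\\.tif$"), 8L)
    m <- loadManifest(out$manifest)
    expect_equal(nrow(manifestTable(m)), 8L)
    truth <- read.csv(out$truth)
    expect_true(all(truth$truth_area_px[truth$timepoint_h == 0] > 0))
})

test_that("time-course generation is deterministic and honours closed frames", {
    base <- withr::local_tempdir()
    sched <- c("0" = 1, "24" = 0)
    o1 <- generateTimeCourse(smallSpec(seed = 1), sched, nFovs = 2L,
                             nReplicates = 1L,
                             dir = file.path(base, "a"), seed = 3)
    o2 <- generateTimeCourse(smallSpec(seed = 1), sched, nFovs = 2L,
                             nReplicates = 1L,
                             dir = file.path(base, "b"), seed = 3)
    expect_identical(readLines(o1$manifest), readLines(o2$manifest))
    f <- list.files(file.path(base, "a"), pattern = "\\.tif$")[1]
    expect_identical(unname(tools::md5sum(file.path(base, "a", f))),
                     unname(tools::md5sum(file.path(base, "b", f))))
    truth <- read.csv(o1$truth)
    expect_true(all(truth$truth_area_px[truth$timepoint_h == 24] == 0))
})

test_that("schedules must anchor at 0 h with scale 1", {
    dir <- withr::local_tempdir()
    expect_error(generateTimeCourse(smallSpec(), c("12" = 0.5), dir = dir),
                 "0 h")
    expect_error(generateTimeCourse(smallSpec(), c("0" = 0.9, "12" = 0.5),
                                    dir = dir), "0 h")
    expect_error(generateTimeCourse(smallSpec(), c("0" = 1, "12" = 1.4),
                                    dir = dir), "\\[0, 1\\]")
})
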