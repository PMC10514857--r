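writeManifestCsv <- function(tab, dir = NULL) {
    if (is.null(dir)) {
        dir <- tempfile("manifest")
        dir.create(dir)
    }
    path <- file.path(dir, "manifest.csv")
    write.csv(tab, path, row.names = FALSE)
    path
}

baseTab <- function() {
    expand.grid(fov_index = 1:3, timepoint_h = c(0, 12),
                KEEP.OUT.ATTRS = FALSE) |>
        transform(file_path = sprintf("f%d_t%d.tif", fov_index, timepoint_h),
                  well_id = "W1", replicate_id = "R1", pixel_size_um = 1.6)
}

test_that("a well-formed manifest loads, sorted and validated", {
    m <- loadManifest(writeManifestCsv(baseTab()))
    tab <- manifestTable(m)
    expect_equal(nrow(tab), 6L)
    expect_equal(tab$timepoint_h, c(0, 0, 0, 12, 12, 12))
    expect_equal(tab$fov_index, rep(1:3, 2))
})

test_that("manifest validation is order-independent and idempotent", {
    tab <- baseTab()
    m1 <- loadManifest(writeManifestCsv(tab))
    m2 <- loadManifest(writeManifestCsv(tab[sample(nrow(tab)), ]))
    expect_equal(manifestTable(m1), manifestTable(m2))
})

test_that("a replicate missing 0 h frames is rejected by name", {
    tab <- baseTab()
    expect_error(loadManifest(writeManifestCsv(
        tab[!(tab$timepoint_h == 0 & tab$fov_index == 2), ])),
        "W1/R1")
    expect_error(loadManifest(writeManifestCsv(
        tab[tab$timepoint_h != 0, ])), "no 0 h frames")
})

test_that("duplicate identity tuples are rejected and listed", {
    tab <- rbind(baseTab(), baseTab()[1, ])
    expect_error(loadManifest(writeManifestCsv(tab)),
                 "duplicate.*W1, R1, 1, 0")
})

test_that("missing required columns are named in the schema error", {
    tab <- baseTab(); tab$fov_index <- NULL
    expect_error(loadManifest(writeManifestCsv(tab)), "fov_index")
    expect_error(loadManifest(writeManifestCsv(baseTab()[0, ])), "no rows")
})

test_that("pixel size falls back to the configured default", {
    tab <- baseTab(); tab$pixel_size_um <- NA
    expect_error(loadManifest(writeManifestCsv(tab)), "pixel_size_um")
    m <- loadManifest(writeManifestCsv(tab), defaultPixelSizeUm = 0.8)
    expect_true(all(manifestTable(m)$pixel_size_um == 0.8))
})

test_that("16-bit TIFF intensities round-trip exactly through write/load", {
    dir <- withr::local_tempdir()
    px <- matrix(sample(0:65535, 64 * 70, replace = TRUE), 64, 70)
    img <- calibratedImage(px, 1.6, fovIndex = 2L, timepointH = 12)
    writeCalibratedImage(img, file.path(dir, "frame.tif"))
    tab <- data.frame(file_path = "frame.tif", well_id = "W1",
                      replicate_id = "R1", fov_index = 2, timepoint_h = 0,
                      pixel_size_um = 1.6)
    back <- loadImage(loadManifest(writeManifestCsv(tab, dir)))
    expect_identical(dim(imagePixels(back)), dim(px))
    expect_true(all(imagePixels(back) == px))
    expect_equal(pixelSize(back), 1.6)
})

test_that("8-bit PNG loads with integer intensities preserved", {
    dir <- withr::local_tempdir()
    px <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
    png::writePNG(px / 255, file.path(dir, "g.png"))
    tab <- data.frame(file_path = "g.png", well_id = "W1",
                      replicate_id = "R1", fov_index = 1, timepoint_h = 0,
                      pixel_size_um = 1)
    back <- loadImage(loadManifest(writeManifestCsv(tab, dir)))
    expect_true(all(imagePixels(back) == px))
})

test_that("multi-channel input becomes luminance with a warning", {
    dir <- withr::local_tempdir()
    arr <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
    png::writePNG(arr, file.path(dir, "rgb.png"))
    tab <- data.frame(file_path = "rgb.png", well_id = "W1",
                      replicate_id = "R1", fov_index = 1, timepoint_h = 0,
                      pixel_size_um = 1)
    expect_warning(img <- loadImage(loadManifest(writeManifestCsv(tab, dir))),
                   "luminance")
    expect_identical(dim(imagePixels(img)), c(64L, 64L))
})

test_that("unreadable files raise an I/O error naming the path", {
    dir <- withr::local_tempdir()
    writeBin(as.raw(1:100), file.path(dir, "broken.tif"))
    tab <- data.frame(file_path = "broken.tif", well_id = "W1",
                      replicate_id = "R1", fov_index = 1, timepoint_h = 0,
                      pixel_size_um = 1)
    expect_error(loadImage(loadManifest(writeManifestCsv(tab, dir))),
                 "broken.tif")
    tab$file_path <- "absent.tif"
    expect_error(loadImage(loadManifest(writeManifestCsv(tab, dir))),
                 "not found")
})
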