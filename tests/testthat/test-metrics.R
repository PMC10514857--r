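test_that("center-line width is the wall-to-wall span in micrometres", {
    sc <- generateScene(smallSpec(widthPx = 80, roughness = 0, noise = 0,
                                  seed = 1))
    wm <- segmentWound(sc, smallParams())
    expect_equal(measureCenterWidth(wm), 80 * 1.6)
    expect_equal(measureCenterWidth(wm, pixelSizeUm = 2), 160)
})

test_that("subtracted islands do not shorten the wall-to-wall span", {
    sc <- generateScene(smallSpec(widthPx = 80, roughness = 0, noise = 0,
                                  seed = 1))
    wm <- segmentWound(sc, smallParams())
    # carve an island-like gap out of the center row region
    gap <- matrix(FALSE, 192, 256)
    gap[90:102, 110:130] <- TRUE
    wmGap <- applyManualOverride(wm, gap, "remove")
    expect_equal(measureCenterWidth(wmGap), 80 * 1.6)
})

test_that("replicate totals are exact integer sums, permutation-invariant", {
    fov <- data.frame(well_id = "W1", replicate_id = "R1", fov_index = 1:5,
                      timepoint_h = 12,
                      area_px = c(12000, 9000, 11000, 8000, 10000),
                      area_um2 = c(12000, 9000, 11000, 8000, 10000) * 2.56)
    tot <- totalReplicateArea(fov)
    expect_equal(tot$total_area_px, 50000)
    expect_equal(tot$total_area_um2, 50000 * 2.56)
    expect_equal(tot$n_fovs, 5L)
    shuffled <- totalReplicateArea(fov[c(3, 5, 1, 4, 2), ])
    expect_equal(shuffled, tot)
    same <- fov; same$area_px <- 10000
    expect_equal(totalReplicateArea(same)$total_area_px, 50000)
})

test_that("replicate totals validate identity and the 0 h fov set", {
    fov <- data.frame(well_id = "W1", replicate_id = "R1", fov_index = 1:5,
                      timepoint_h = 12, area_px = 1000, area_um2 = 2560)
    mixed <- fov; mixed$replicate_id[3] <- "R2"
    expect_error(totalReplicateArea(mixed), "distinct identities")
    dup <- fov; dup$fov_index[2] <- 1
    expect_error(totalReplicateArea(dup), "duplicate fov_index")
    expect_error(totalReplicateArea(fov[-2, ], baselineFovs = 1:5),
                 "differs from its 0 h set")
    expect_silent(totalReplicateArea(fov, baselineFovs = 5:1))
})

test_that("percent open is an exact ratio with flagged widening", {
    for (A in c(1, 37, 50000, 230400.5))
        expect_identical(percentOpen(A, A), 100)
    expect_equal(percentOpen(0, 12345), 0)
    expect_equal(percentOpen(30000, 50000), 60)
    expect_warning(p <- percentOpen(60000, 50000), "widened")
    expect_equal(p, 120)
    expect_error(percentOpen(10, 0), "baseline")
    expect_error(percentOpen(-1, 10), "non-negative")
})

test_that("percent open is invariant under common area rescaling", {
    set.seed(11)
    for (i in 1:20) {
        a0 <- runif(1, 1e3, 1e6); at <- runif(1, 0, a0 * 1.2)
        k <- runif(1, 0.01, 100)
        expect_equal(suppressWarnings(percentOpen(at * k, a0 * k)),
                     suppressWarnings(percentOpen(at, a0)))
    }
})

test_that("replicate summaries use mean and sample SD", {
    s <- summarizeReplicates(c(60, 60, 60))
    expect_equal(s$mean, 60); expect_equal(s$sd, 0); expect_equal(s$n, 3L)
    s2 <- summarizeReplicates(c(50, 60, 70))
    expect_equal(s2$mean, 60); expect_equal(s2$sd, 10)
    expect_warning(s1 <- summarizeReplicates(42), "one replicate")
    expect_equal(s1$mean, 42); expect_equal(s1$sd, 0); expect_equal(s1$n, 1L)
    expect_error(summarizeReplicates(numeric(0)), "no replicate")
})

test_that("the coverage planner reproduces the standard well geometry", {
    plan <- planCoverage(15600, 2400, dropEnds = TRUE)
    expect_identical(plan@nTiled, 7L)
    expect_identical(plan@nIncluded, 5L)
    expect_equal(plan@coverageFraction, 5 * 2400 / 15600)
    expect_true(plan@meetsTarget)
    # smaller fields: more frames, still above target
    plan2 <- planCoverage(15600, 1000, dropEnds = TRUE)
    expect_gte(plan2@nIncluded, 13L)
    expect_true(plan2@meetsTarget)
    # keep-ends coverage is clipped at 1
    plan3 <- planCoverage(10000, 5000, dropEnds = FALSE)
    expect_identical(plan3@nTiled, 2L)
    expect_equal(plan3@coverageFraction, 1)
    expect_error(planCoverage(100, 100), "smaller")
    expect_error(planCoverage(0, 100), "positive")
    expect_error(planCoverage(2400, 1200, dropEnds = TRUE), "no frame")
})

test_that("seeding densities match the protocol's recommended values", {
    expect_identical(seedingDensity(10000, 1.9), 5263L)
    expect_identical(seedingDensity(60000, 1.9), 31578L)
    expect_identical(seedingDensity(100, 1), 100L)
    expect_error(seedingDensity(0, 1), "positive")
    expect_error(seedingDensity(100, -1), "positive")
})

test_that("total-area aggregation reduces percent-open variance vs single fields", {
    sims <- simulateClosureAreas(nExperiments = 120, seed = 7)
    expect_lte(mean(sims$sd_total), mean(sims$sd_single))
    # and not trivially: the reduction is substantial
    expect_lt(mean(sims$sd_total), 0.8 * mean(sims$sd_single))
})
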