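#' Generate a synthetic scratch scene
#'
#' Renders a phase-contrast-like scratch-assay frame with exact ground
#' truth: a textured cell monolayer (zero-mean random texture, blurred at
#' cell scale and standardized to SD \code{cellTextureContrast}) crossed
#' by a smooth band at \code{backgroundLevel} whose two edges are
#' perturbed per row by a smooth periodic roughness, optional
#' migrated-cell discs rendered with monolayer texture inside the band,
#' and additive Gaussian noise everywhere. Ground-truth masks are derived
#' from the analytic geometry before noise, so they are independent of
#' \code{noiseSigma}. Generation is bit-reproducible given
#' \code{spec@seed}.
#'
#' @param spec a [SyntheticSceneSpec-class].
#' @param wellId,replicateId,fovIndex,timepointH identity attached to the
#'   rendered frame.
#' @return A [SyntheticScene-class].
#' @examples
#' scene <- generateScene(syntheticSceneSpec(heightPx = 128, widthPx = 128,
#'     scratchCenterColPx = 64, scratchWidthPx = 40, edgeRoughnessAmpPx = 0,
#'     noiseSigma = 0, seed = 1))
#' truthArea(scene)   # 40 * 128
#' @seealso [generateTimeCourse()], [segmentWound()]
#' @name generateScene
NULL

#' @rdname generateScene
#' @export
setMethod("generateScene", "SyntheticSceneSpec",
    function(spec, wellId = "W1", replicateId = "R1", fovIndex = 1L,
             timepointH = 0) {
        validObject(spec)
        h <- spec@heightPx; w <- spec@widthPx
        .withSeed(spec@seed, {
            geom <- .sceneGeometry(spec)
            z <- matrix(stats::rnorm(h * w), h, w)
            if (spec@cellTextureContrast > 0) {
                z <- EBImage::gblur(z, sigma = 2)
                z <- matrix(as.numeric(z), h, w)
                z <- (z - mean(z)) / stats::sd(z)
            }
            cells <- spec@backgroundLevel + spec@cellTextureContrast * z
            img <- cells
            img[geom$wound] <- spec@backgroundLevel
            if (spec@noiseSigma > 0)
                img <- img + spec@noiseSigma * matrix(stats::rnorm(h * w), h, w)
            img <- pmax(img, 0)
            frame <- calibratedImage(img, spec@pixelSizeUm, wellId,
                                     replicateId, fovIndex, timepointH,
                                     magnificationLabel = "synthetic")
            new("SyntheticScene", image = frame,
                truthWoundMask = geom$wound, truthIslandMask = geom$island,
                truthAreaPx = as.integer(sum(geom$wound)), spec = spec)
        })
    })

# analytic scene geometry; consumes only the roughness-phase RNG draws so
# ground truth never depends on texture or noise draws
.sceneGeometry <- function(spec) {
    h <- spec@heightPx; w <- spec@widthPx
    ph <- stats::runif(2L, 0, 2 * pi)
    if (spec@scratchWidthPx > 0) {
        rows <- seq_len(h)
        amp <- spec@edgeRoughnessAmpPx
        lam <- spec@edgeRoughnessWavelengthPx
        left <- spec@scratchCenterColPx - spec@scratchWidthPx / 2 +
            amp * sin(2 * pi * rows / lam + ph[1L])
        right <- spec@scratchCenterColPx + spec@scratchWidthPx / 2 +
            amp * sin(2 * pi * rows / lam + ph[2L])
        cols <- seq_len(w)
        band <- outer(left, cols, function(L, C) C > L) &
                outer(right, cols, function(R, C) C <= R)
    } else {
        band <- matrix(FALSE, h, w)
    }
    island <- matrix(FALSE, h, w)
    isl <- spec@islands
    if (nrow(isl)) {
        R <- row(band); C <- col(band)
        for (k in seq_len(nrow(isl)))
            island <- island |
                ((R - isl$row[k])^2 + (C - isl$col[k])^2 <= isl$radius[k]^2)
        island <- island & band
    }
    list(wound = band & !island, island = island)
}

# drop islands that no longer fit a rescaled band (narrowing time course)
.fitIslands <- function(spec) {
    isl <- spec@islands
    if (!nrow(isl)) return(spec)
    lo <- spec@scratchCenterColPx - spec@scratchWidthPx / 2 +
        spec@edgeRoughnessAmpPx
    hi <- spec@scratchCenterColPx + spec@scratchWidthPx / 2 -
        spec@edgeRoughnessAmpPx
    ok <- isl$col - isl$radius >= lo & isl$col + isl$radius <= hi
    spec@islands <- isl[ok, , drop = FALSE]
    spec
}

#' Generate a synthetic scratch-assay time course on disk
#'
#' Emulates the standardized acquisition design — several technical
#' replicates, several sequential fields of view per replicate, imaged at
#' each timepoint — with a shared closure schedule and independent
#' per-field heterogeneity: each (replicate, fov) draws a fixed relative
#' width jitter, and each later timepoint an additional closure jitter,
#' mimicking the field-to-field variability seen in real scratches.
#' Writes 16-bit TIFF frames, a manifest CSV consumable by
#' [loadManifest()], and a ground-truth CSV. Sub-seeds are derived by
#' stable hashing of identity tuples, so adding a replicate never perturbs
#' existing frames.
#'
#' @param spec0 baseline [SyntheticSceneSpec-class] (0 h geometry).
#' @param schedule named numeric vector mapping timepoint (hours, names)
#'   to width scale in \code{[0, 1]}; must contain \code{"0" = 1}.
#' @param nFovs fields of view per replicate (default 5).
#' @param nReplicates technical replicates (default 3).
#' @param dir output directory (created if needed).
#' @param seed integer master seed.
#' @param widthJitterSd relative SD of the per-field initial width jitter
#'   (default 0.05).
#' @param closureJitterSd relative SD of the per-field, per-timepoint
#'   closure jitter (default 0.05).
#' @param wellId well label for the generated frames.
#' @return Invisibly, a list with \code{manifest} and \code{truth} CSV
#'   paths, the output \code{dir} and \code{nFrames}.
#' @examples
#' \donttest{
#' out <- generateTimeCourse(syntheticSceneSpec(), c("0" = 1, "12" = 0.5),
#'     dir = file.path(tempdir(), "tc"), seed = 1)
#' manifestTable(loadManifest(out$manifest))
#' }
#' @export
generateTimeCourse <- function(spec0, schedule, nFovs = 5L,
                               nReplicates = 3L, dir, seed = 1L,
                               widthJitterSd = 0.05,
                               closureJitterSd = 0.05,
                               wellId = "W1") {
    validObject(spec0)
    tps <- suppressWarnings(as.numeric(names(schedule)))
    if (any(is.na(tps)))
        stop("'schedule' must be a named numeric vector (names = hours)")
    if (!any(tps == 0 & schedule == 1))
        stop("'schedule' must contain timepoint 0 h with width scale 1.0")
    if (any(schedule < 0 | schedule > 1))
        stop("'schedule' width scales must lie in [0, 1]")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ord <- order(tps)
    tps <- tps[ord]; sched <- as.numeric(schedule)[ord]

    rowsM <- list(); rowsT <- list(); nFrames <- 0L
    for (rep in seq_len(nReplicates)) {
        repId <- sprintf("R%d", rep)
        for (fov in seq_len(nFovs)) {
            jw <- .withSeed(.stableSeed(seed, "jitter", wellId, repId, fov),
                            1 + stats::rnorm(1L, 0, widthJitterSd))
            jw <- max(jw, 0.2)
            for (k in seq_along(tps)) {
                t <- tps[k]
                eff <- sched[k]
                if (t > 0 && closureJitterSd > 0 && eff > 0)
                    eff <- eff * (1 + .withSeed(
                        .stableSeed(seed, "closure", wellId, repId, fov, t),
                        stats::rnorm(1L, 0, closureJitterSd)))
                eff <- max(eff, 0)
                sp <- spec0
                sp@scratchWidthPx <- spec0@scratchWidthPx * jw * eff
                sp@seed <- .stableSeed(seed, "scene", wellId, repId, fov, t)
                sp <- .fitIslands(sp)
                scene <- generateScene(sp, wellId, repId, fov, t)
                fn <- sprintf("%s_%s_F%d_t%04.1fh.tif", wellId, repId, fov, t)
                writeCalibratedImage(scene@image, file.path(dir, fn))
                nFrames <- nFrames + 1L
                rowsM[[nFrames]] <- data.frame(
                    file_path = fn, well_id = wellId, replicate_id = repId,
                    fov_index = fov, timepoint_h = t,
                    pixel_size_um = spec0@pixelSizeUm,
                    stringsAsFactors = FALSE)
                rowsT[[nFrames]] <- data.frame(
                    well_id = wellId, replicate_id = repId, fov_index = fov,
                    timepoint_h = t, truth_area_px = truthArea(scene),
                    truth_width_px = sp@scratchWidthPx,
                    stringsAsFactors = FALSE)
            }
        }
    }
    manifest <- do.call(rbind, rowsM)
    truth <- do.call(rbind, rowsT)
    mpath <- file.path(dir, "manifest.csv")
    tpath <- file.path(dir, "truth.csv")
    utils::write.csv(manifest, mpath, row.names = FALSE)
    utils::write.csv(truth, tpath, row.names = FALSE)
    invisible(list(manifest = mpath, truth = tpath, dir = dir,
                   nFrames = nFrames))
}

#' Area-level closure simulation: total-area vs single-field percent open
#'
#' Monte-Carlo model of the aggregation step alone, used to study why
#' combining all fields of view of a replicate into a total scratch area
#' yields more robust closure rates than tracking a single representative
#' field. Each replicate consists of \code{nFovs} fields whose baseline
#' areas scatter with relative SD \code{fovAreaCv} (field-to-field
#' heterogeneity along the scratch) and whose closure at later timepoints
#' scatters with relative SD \code{closureCv}. For every simulated
#' experiment the across-replicate SD of percent-open is computed twice:
#' from per-replicate total areas, and from one randomly chosen field per
#' replicate.
#'
#' @param nExperiments number of simulated experiments (default 100).
#' @param nReplicates technical replicates per experiment (default 3).
#' @param nFovs fields of view per replicate (default 5).
#' @param schedule named numeric vector of width scales, as in
#'   [generateTimeCourse()].
#' @param baselineAreaPx nominal per-field scratch area at 0 h.
#' @param fovAreaCv relative SD of per-field baseline area (default 0.15).
#' @param closureCv relative SD of per-field closure jitter (default 0.05).
#' @param seed integer seed.
#' @return data.frame with one row per experiment and later timepoint:
#'   \code{experiment}, \code{timepoint_h}, \code{sd_total},
#'   \code{sd_single}, \code{mean_total}, \code{mean_single}.
#' @examples
#' sims <- simulateClosureAreas(nExperiments = 10, seed = 1)
#' mean(sims$sd_total) <= mean(sims$sd_single)
#' @export
simulateClosureAreas <- function(nExperiments = 100L, nReplicates = 3L,
                                 nFovs = 5L,
                                 schedule = c("0" = 1, "12" = 0.5),
                                 baselineAreaPx = 230400,
                                 fovAreaCv = 0.15, closureCv = 0.05,
                                 seed = 1L) {
    tps <- as.numeric(names(schedule))
    if (!any(tps == 0 & schedule == 1))
        stop("'schedule' must contain timepoint 0 h with width scale 1.0")
    later <- which(tps > 0)
    if (!length(later)) stop("'schedule' needs at least one later timepoint")
    .withSeed(seed, {
        out <- vector("list", nExperiments * length(later))
        q <- 0L
        for (e in seq_len(nExperiments)) {
            a0 <- matrix(baselineAreaPx *
                pmax(1 + stats::rnorm(nReplicates * nFovs, 0, fovAreaCv), 0.05),
                nReplicates, nFovs)
            pick <- sample.int(nFovs, nReplicates, replace = TRUE)
            for (k in later) {
                at <- a0 * schedule[k] *
                    pmax(1 + matrix(stats::rnorm(nReplicates * nFovs, 0,
                                                 closureCv),
                                    nReplicates, nFovs), 0)
                pTotal <- 100 * rowSums(at) / rowSums(a0)
                pSingle <- 100 * at[cbind(seq_len(nReplicates), pick)] /
                    a0[cbind(seq_len(nReplicates), pick)]
                q <- q + 1L
                out[[q]] <- data.frame(
                    experiment = e, timepoint_h = tps[k],
                    sd_total = stats::sd(pTotal),
                    sd_single = stats::sd(pSingle),
                    mean_total = mean(pTotal),
                    mean_single = mean(pSingle))
            }
        }
        do.call(rbind, out)
    })
}
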