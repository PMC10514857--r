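#' @import methods
NULL

#' Calibrated microscopy frame
#'
#' One grayscale frame of a scratch-assay time course together with its
#' pixel calibration and its position in the experiment layout
#' (well, technical replicate, field-of-view index along the scratch,
#' timepoint).
#'
#' @slot pixels numeric matrix of non-negative intensities (rows x columns).
#' @slot pixelSizeUm physical size of one pixel in micrometres (> 0).
#' @slot wellId,replicateId character labels for the well and the technical
#'   replicate.
#' @slot fovIndex integer >= 1; position of the field of view along the
#'   scratch, 1 = topmost acquired frame.
#' @slot timepointH acquisition time in hours (>= 0).
#' @slot magnificationLabel free-text magnification label, e.g. \code{"4x"}.
#'
#' @seealso [calibratedImage()], [loadImage()], [segmentWound()]
#' @exportClass CalibratedImage
setClass("CalibratedImage",
    representation(
        pixels = "matrix",
        pixelSizeUm = "numeric",
        wellId = "character",
        replicateId = "character",
        fovIndex = "integer",
        timepointH = "numeric",
        magnificationLabel = "character"
    )
)

setValidity("CalibratedImage", function(object) {
    msg <- character()
    px <- object@pixels
    if (!is.numeric(px))
        msg <- c(msg, "'pixels' must be a numeric matrix")
    if (nrow(px) < 64L || ncol(px) < 64L)
        msg <- c(msg, sprintf(
            "'pixels' must have at least 64 rows and 64 columns (got %d x %d)",
            nrow(px), ncol(px)))
    if (any(!is.finite(px)) || any(px < 0))
        msg <- c(msg, "'pixels' must be finite and non-negative")
    if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
        object@pixelSizeUm <= 0)
        msg <- c(msg, "'pixelSizeUm' must be a single positive number")
    if (length(object@fovIndex) != 1L || object@fovIndex < 1L)
        msg <- c(msg, "'fovIndex' must be a single integer >= 1")
    if (length(object@timepointH) != 1L || !is.finite(object@timepointH) ||
        object@timepointH < 0)
        msg <- c(msg, "'timepointH' must be a single number >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a CalibratedImage
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixelSizeUm micrometres per pixel (> 0).
#' @param wellId,replicateId well / technical-replicate labels.
#' @param fovIndex field-of-view index along the scratch (1 = topmost).
#' @param timepointH timepoint in hours.
#' @param magnificationLabel free-text magnification label.
#' @return A [CalibratedImage-class] object.
#' @examples
#' img <- calibratedImage(matrix(100, 64, 64), pixelSizeUm = 1.6)
#' pixelSize(img)
#' @export
calibratedImage <- function(pixels, pixelSizeUm, wellId = "W1",
                            replicateId = "R1", fovIndex = 1L,
                            timepointH = 0, magnificationLabel = "4x") {
    new("CalibratedImage", pixels = pixels, pixelSizeUm = pixelSizeUm,
        wellId = as.character(wellId), replicateId = as.character(replicateId),
        fovIndex = as.integer(fovIndex), timepointH = as.numeric(timepointH),
        magnificationLabel = as.character(magnificationLabel))
}

#' Experiment manifest
#'
#' Tabular description of a scratch-assay imaging experiment: one row per
#' acquired frame with its file path, identity (well, replicate, fov,
#' timepoint) and pixel calibration. Constructed and validated by
#' [loadManifest()].
#'
#' @slot table data.frame with columns \code{file_path}, \code{well_id},
#'   \code{replicate_id}, \code{fov_index}, \code{timepoint_h},
#'   \code{pixel_size_um}, sorted by (well, replicate, timepoint, fov).
#' @slot dir directory against which relative file paths are resolved
#'   (the manifest's own directory).
#'
#' @exportClass ExperimentManifest
setClass("ExperimentManifest",
    representation(table = "data.frame", dir = "character"))

setValidity("ExperimentManifest", function(object) {
    req <- c("file_path", "well_id", "replicate_id", "fov_index",
             "timepoint_h", "pixel_size_um")
    miss <- setdiff(req, names(object@table))
    if (length(miss))
        return(sprintf("manifest table lacks column(s): %s",
                       paste(miss, collapse = ", ")))
    TRUE
})

#' Wound segmentation parameters
#'
#' Tunable parameters of the texture-based wound segmentation pipeline.
#' Construct with [segmentationParams()]; all defaults were calibrated on
#' the package's synthetic scene suite.
#'
#' @slot textureRadiusPx radius of the square local-texture window; the
#'   window has side 2*radius+1 pixels.
#' @slot thresholdMethod \code{"otsu"} (threshold chosen by Otsu's method on
#'   the texture map) or \code{"fixed"}.
#' @slot fixedThreshold texture-score cutoff, required iff
#'   \code{thresholdMethod == "fixed"} (otherwise \code{NA}).
#' @slot closingRadiusPx radius of the morphological closing that bridges
#'   small gaps in the low-texture mask (0 disables).
#' @slot minWoundFraction fraction of the frame area below which no wound is
#'   declared and the frame is flagged closed.
#' @slot minIslandAreaPx smallest high-texture region inside the wound that
#'   is treated as a migrated-cell island and subtracted; smaller regions
#'   are treated as debris and filled.
#' @slot scratchAxis \code{"vertical"} (scratch band runs along image rows)
#'   or \code{"horizontal"}.
#' @slot bandMarginPx margin in pixels added around the dominant scratch
#'   band when collecting wound components.
#'
#' @exportClass SegmentationParams
setClass("SegmentationParams",
    representation(
        textureRadiusPx = "integer",
        thresholdMethod = "character",
        fixedThreshold = "numeric",
        closingRadiusPx = "integer",
        minWoundFraction = "numeric",
        minIslandAreaPx = "integer",
        scratchAxis = "character",
        bandMarginPx = "integer"
    )
)

setValidity("SegmentationParams", function(object) {
    msg <- character()
    if (object@textureRadiusPx < 1L)
        msg <- c(msg, "'textureRadiusPx' must be >= 1")
    if (!object@thresholdMethod %in% c("otsu", "fixed"))
        msg <- c(msg, "'thresholdMethod' must be \"otsu\" or \"fixed\"")
    if (object@thresholdMethod == "fixed" && !is.finite(object@fixedThreshold))
        msg <- c(msg, "'fixedThreshold' is required when thresholdMethod = \"fixed\"")
    if (object@thresholdMethod == "otsu" && is.finite(object@fixedThreshold))
        msg <- c(msg, "'fixedThreshold' must be NA when thresholdMethod = \"otsu\"")
    if (object@closingRadiusPx < 0L)
        msg <- c(msg, "'closingRadiusPx' must be >= 0")
    if (!is.finite(object@minWoundFraction) || object@minWoundFraction < 0 ||
        object@minWoundFraction >= 1)
        msg <- c(msg, "'minWoundFraction' must be in [0, 1)")
    if (object@minIslandAreaPx < 1L)
        msg <- c(msg, "'minIslandAreaPx' must be >= 1")
    if (!object@scratchAxis %in% c("vertical", "horizontal"))
        msg <- c(msg, "'scratchAxis' must be \"vertical\" or \"horizontal\"")
    if (object@bandMarginPx < 0L)
        msg <- c(msg, "'bandMarginPx' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct segmentation parameters
#'
#' @param textureRadiusPx local-texture window radius in pixels (default 5).
#' @param thresholdMethod \code{"otsu"} or \code{"fixed"}.
#' @param fixedThreshold texture-score cutoff when \code{thresholdMethod =
#'   "fixed"}.
#' @param closingRadiusPx morphological closing radius in pixels (default 5).
#' @param minWoundFraction minimum wound area as a fraction of the frame
#'   (default 0.005) below which the frame is reported closed.
#' @param minIslandAreaPx minimum migrated-cell island area in pixels
#'   (default 200); smaller intra-wound structures count as debris.
#' @param scratchAxis orientation of the scratch band (default
#'   \code{"vertical"}).
#' @param bandMarginPx search margin around the dominant band (default 50).
#' @return A [SegmentationParams-class] object.
#' @examples
#' segmentationParams(textureRadiusPx = 4)
#' @export
segmentationParams <- function(textureRadiusPx = 5L,
                               thresholdMethod = c("otsu", "fixed"),
                               fixedThreshold = NA_real_,
                               closingRadiusPx = 5L,
                               minWoundFraction = 0.005,
                               minIslandAreaPx = 200L,
                               scratchAxis = c("vertical", "horizontal"),
                               bandMarginPx = 50L) {
    new("SegmentationParams",
        textureRadiusPx = as.integer(textureRadiusPx),
        thresholdMethod = match.arg(thresholdMethod),
        fixedThreshold = as.numeric(fixedThreshold),
        closingRadiusPx = as.integer(closingRadiusPx),
        minWoundFraction = as.numeric(minWoundFraction),
        minIslandAreaPx = as.integer(minIslandAreaPx),
        scratchAxis = match.arg(scratchAxis),
        bandMarginPx = as.integer(bandMarginPx))
}

#' Binary wound mask with area bookkeeping
#'
#' Result of segmenting one frame: the binary wound (cell-free) region,
#' its area in pixels and in square micrometres, the migrated-cell islands
#' subtracted from it, the parameters that produced it and the frame
#' identity. \code{areaUm2} always equals \code{areaPx * pixelSizeUm^2}.
#'
#' @slot mask logical matrix, \code{TRUE} = wound (cell-free).
#' @slot areaPx integer, count of \code{TRUE} pixels in \code{mask}.
#' @slot areaUm2 physical wound area.
#' @slot nIslandsSubtracted number of migrated-cell islands removed.
#' @slot islandAreaPx total pixel area removed as islands.
#' @slot closed TRUE when no wound was detected (terminal assay state).
#' @slot params the [SegmentationParams-class] used.
#' @slot pixelSizeUm,wellId,replicateId,fovIndex,timepointH frame calibration
#'   and identity, copied from the source image.
#' @slot provenance character vector logging the operations applied.
#'
#' @seealso [segmentWound()], [woundArea()], [measureCenterWidth()]
#' @exportClass WoundMask
setClass("WoundMask",
    representation(
        mask = "matrix",
        areaPx = "integer",
        areaUm2 = "numeric",
        nIslandsSubtracted = "integer",
        islandAreaPx = "integer",
        closed = "logical",
        params = "SegmentationParams",
        pixelSizeUm = "numeric",
        wellId = "character",
        replicateId = "character",
        fovIndex = "integer",
        timepointH = "numeric",
        provenance = "character"
    )
)

setValidity("WoundMask", function(object) {
    msg <- character()
    if (!is.logical(object@mask))
        msg <- c(msg, "'mask' must be a logical matrix")
    if (object@areaPx != sum(object@mask))
        msg <- c(msg, "'areaPx' must equal the number of TRUE pixels in 'mask'")
    if (object@areaUm2 != object@areaPx * object@pixelSizeUm^2)
        msg <- c(msg, "'areaUm2' must equal areaPx * pixelSizeUm^2")
    if (object@nIslandsSubtracted < 0L || object@islandAreaPx < 0L)
        msg <- c(msg, "island counters must be >= 0")
    if (length(msg)) msg else TRUE
})

# internal constructor keeping area bookkeeping consistent
.woundMask <- function(mask, image, params, nIslands = 0L, islandArea = 0L,
                       closed = FALSE, provenance = character()) {
    new("WoundMask", mask = mask, areaPx = as.integer(sum(mask)),
        areaUm2 = as.integer(sum(mask)) * image@pixelSizeUm^2,
        nIslandsSubtracted = as.integer(nIslands),
        islandAreaPx = as.integer(islandArea),
        closed = closed, params = params,
        pixelSizeUm = image@pixelSizeUm, wellId = image@wellId,
        replicateId = image@replicateId, fovIndex = image@fovIndex,
        timepointH = image@timepointH, provenance = provenance)
}

#' Field-of-view coverage plan
#'
#' How many fields of view are needed to tile a scratch of a given length,
#' how many remain after dropping the two blunt-end frames, and what
#' fraction of the scratched length the kept frames cover. The assay
#' guideline is that at least 76 percent of the scratched length must be
#' imaged for robust closure rates.
#'
#' @slot scratchLengthUm,fovExtentUm geometry in micrometres.
#' @slot nTiled total frames tiling the scratch.
#' @slot nIncluded frames kept for analysis.
#' @slot dropEnds whether the two end frames were dropped.
#' @slot coverageFraction fraction of the scratch covered by kept frames
#'   (clipped to 1).
#' @slot meetsTarget TRUE when coverageFraction >= 0.76.
#'
#' @seealso [planCoverage()]
#' @exportClass CoveragePlan
setClass("CoveragePlan",
    representation(
        scratchLengthUm = "numeric",
        fovExtentUm = "numeric",
        nTiled = "integer",
        nIncluded = "integer",
        dropEnds = "logical",
        coverageFraction = "numeric",
        meetsTarget = "logical"
    )
)

#' Synthetic scratch-scene specification
#'
#' Full parameterization of a generated scratch-assay frame: a textured
#' cell monolayer crossed by a roughly vertical smooth (cell-free) band of
#' known width, optional migrated-cell islands inside the band, and
#' additive Gaussian noise. Construct with [syntheticSceneSpec()].
#'
#' @slot heightPx,widthPx frame dimensions in pixels.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot scratchCenterColPx,scratchWidthPx nominal band geometry (columns).
#' @slot edgeRoughnessAmpPx,edgeRoughnessWavelengthPx amplitude and
#'   wavelength of the smooth periodic perturbation of each wound edge.
#' @slot cellTextureContrast intensity SD of the monolayer texture.
#' @slot backgroundLevel mean intensity.
#' @slot islands data.frame with columns \code{row}, \code{col},
#'   \code{radius}: migrated-cell discs inside the band.
#' @slot noiseSigma additive Gaussian noise SD.
#' @slot seed RNG seed; scenes are bit-reproducible given the seed.
#'
#' @exportClass SyntheticSceneSpec
setClass("SyntheticSceneSpec",
    representation(
        heightPx = "integer",
        widthPx = "integer",
        pixelSizeUm = "numeric",
        scratchCenterColPx = "numeric",
        scratchWidthPx = "numeric",
        edgeRoughnessAmpPx = "numeric",
        edgeRoughnessWavelengthPx = "numeric",
        cellTextureContrast = "numeric",
        backgroundLevel = "numeric",
        islands = "data.frame",
        noiseSigma = "numeric",
        seed = "integer"
    )
)

setValidity("SyntheticSceneSpec", function(object) {
    msg <- character()
    if (object@heightPx < 64L || object@widthPx < 64L)
        msg <- c(msg, "frame must be at least 64 x 64 pixels")
    if (object@pixelSizeUm <= 0)
        msg <- c(msg, "'pixelSizeUm' must be > 0")
    if (object@scratchWidthPx < 0)
        msg <- c(msg, "'scratchWidthPx' must be >= 0")
    if (object@edgeRoughnessAmpPx < 0 || object@noiseSigma < 0 ||
        object@cellTextureContrast < 0)
        msg <- c(msg, "amplitudes must be >= 0")
    if (object@edgeRoughnessWavelengthPx <= 0)
        msg <- c(msg, "'edgeRoughnessWavelengthPx' must be > 0")
    if (object@scratchWidthPx > 0) {
        lo <- object@scratchCenterColPx - object@scratchWidthPx / 2
        hi <- object@scratchCenterColPx + object@scratchWidthPx / 2
        if (lo - object@edgeRoughnessAmpPx < 1 ||
            hi + object@edgeRoughnessAmpPx > object@widthPx)
            msg <- c(msg, "scratch band (+ roughness margin) must fit inside the frame")
    }
    isl <- object@islands
    if (nrow(isl)) {
        if (!all(c("row", "col", "radius") %in% names(isl))) {
            msg <- c(msg, "'islands' needs columns row, col, radius")
        } else {
            lo <- object@scratchCenterColPx - object@scratchWidthPx / 2
            hi <- object@scratchCenterColPx + object@scratchWidthPx / 2
            bad <- isl$col - isl$radius < lo + object@edgeRoughnessAmpPx |
                   isl$col + isl$radius > hi - object@edgeRoughnessAmpPx |
                   isl$row - isl$radius < 1 |
                   isl$row + isl$radius > object@heightPx
            if (any(bad))
                msg <- c(msg, "island discs must lie inside the scratch band")
            if (any(isl$radius <= 0))
                msg <- c(msg, "island radii must be > 0")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a synthetic-scene specification
#'
#' Defaults describe the package's reference validation scene: a 768 x 1024
#' frame with a 300 px wide vertical scratch, edge roughness of amplitude
#' 10 px, monolayer texture contrast 30 intensity units and additive noise
#' SD 7.5 (contrast-to-noise ratio 4).
#'
#' @param heightPx,widthPx frame dimensions.
#' @param pixelSizeUm micrometres per pixel.
#' @param scratchCenterColPx,scratchWidthPx band center column and width.
#' @param edgeRoughnessAmpPx,edgeRoughnessWavelengthPx edge roughness.
#' @param cellTextureContrast monolayer texture intensity SD.
#' @param backgroundLevel mean intensity level.
#' @param islands data.frame(row, col, radius) of migrated-cell discs.
#' @param noiseSigma additive Gaussian noise SD.
#' @param seed integer RNG seed.
#' @return A [SyntheticSceneSpec-class].
#' @examples
#' spec <- syntheticSceneSpec(seed = 7)
#' scene <- generateScene(spec)
#' truthArea(scene)
#' @export
syntheticSceneSpec <- function(heightPx = 768L, widthPx = 1024L,
                               pixelSizeUm = 1.6,
                               scratchCenterColPx = 512,
                               scratchWidthPx = 300,
                               edgeRoughnessAmpPx = 10,
                               edgeRoughnessWavelengthPx = 96,
                               cellTextureContrast = 30,
                               backgroundLevel = 200,
                               islands = data.frame(row = numeric(0),
                                                    col = numeric(0),
                                                    radius = numeric(0)),
                               noiseSigma = 7.5,
                               seed = 1L) {
    new("SyntheticSceneSpec", heightPx = as.integer(heightPx),
        widthPx = as.integer(widthPx), pixelSizeUm = as.numeric(pixelSizeUm),
        scratchCenterColPx = as.numeric(scratchCenterColPx),
        scratchWidthPx = as.numeric(scratchWidthPx),
        edgeRoughnessAmpPx = as.numeric(edgeRoughnessAmpPx),
        edgeRoughnessWavelengthPx = as.numeric(edgeRoughnessWavelengthPx),
        cellTextureContrast = as.numeric(cellTextureContrast),
        backgroundLevel = as.numeric(backgroundLevel),
        islands = as.data.frame(islands), noiseSigma = as.numeric(noiseSigma),
        seed = as.integer(seed))
}

#' Synthetic scratch scene with ground truth
#'
#' A generated frame plus the exact wound and island masks implied by its
#' geometry. Ground truth is derived from the analytic scene geometry
#' before noise is added, so it does not depend on \code{noiseSigma}.
#'
#' @slot image the rendered [CalibratedImage-class].
#' @slot truthWoundMask logical matrix: cell-free region excluding islands.
#' @slot truthIslandMask logical matrix: migrated-cell discs.
#' @slot truthAreaPx integer, TRUE-pixel count of \code{truthWoundMask}.
#' @slot spec the generating [SyntheticSceneSpec-class].
#'
#' @exportClass SyntheticScene
setClass("SyntheticScene",
    representation(
        image = "CalibratedImage",
        truthWoundMask = "matrix",
        truthIslandMask = "matrix",
        truthAreaPx = "integer",
        spec = "SyntheticSceneSpec"
    )
)

setValidity("SyntheticScene", function(object) {
    msg <- character()
    if (object@truthAreaPx != sum(object@truthWoundMask))
        msg <- c(msg, "'truthAreaPx' must equal the TRUE count of truthWoundMask")
    if (any(object@truthWoundMask & object@truthIslandMask))
        msg <- c(msg, "wound and island truth masks must be disjoint")
    if (length(msg)) msg else TRUE
})
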