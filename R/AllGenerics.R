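#' Accessors for scratchquant classes
#'
#' Small accessor generics: \code{imagePixels} returns the intensity
#' matrix, \code{pixelSize} the micrometre-per-pixel calibration,
#' \code{frameId} the (well, replicate, fov, timepoint) identity as a
#' one-row data.frame, \code{woundArea} the wound area (pixels or um^2),
#' \code{isClosed} the closed flag, \code{nIslands} the number of
#' migrated-cell islands subtracted, \code{woundMask} the logical mask,
#' \code{manifestTable} the manifest data.frame, \code{truthArea} and
#' \code{truthMask} the ground-truth area / mask of a synthetic scene,
#' and \code{sceneImage} its rendered image.
#'
#' @param x an object of the documented classes.
#' @param units \code{"px"} or \code{"um2"} for \code{woundArea}.
#' @return See each accessor's description.
#' @name accessors
#' @examples
#' scene <- generateScene(syntheticSceneSpec(heightPx = 128, widthPx = 128,
#'     scratchCenterColPx = 64, scratchWidthPx = 40,
#'     edgeRoughnessAmpPx = 0, noiseSigma = 0, seed = 1))
#' truthArea(scene)
NULL

#' @rdname accessors
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("frameId", function(x) standardGeneric("frameId"))

#' @rdname accessors
#' @export
setGeneric("woundArea", function(x, units = c("px", "um2"))
    standardGeneric("woundArea"))

#' @rdname accessors
#' @export
setGeneric("isClosed", function(x) standardGeneric("isClosed"))

#' @rdname accessors
#' @export
setGeneric("nIslands", function(x) standardGeneric("nIslands"))

#' @rdname accessors
#' @export
setGeneric("woundMask", function(x) standardGeneric("woundMask"))

#' @rdname accessors
#' @export
setGeneric("manifestTable", function(x) standardGeneric("manifestTable"))

#' @rdname accessors
#' @export
setGeneric("truthArea", function(x) standardGeneric("truthArea"))

#' @rdname accessors
#' @export
setGeneric("truthMask", function(x) standardGeneric("truthMask"))

#' @rdname accessors
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))

#' @rdname textureMap
#' @export
setGeneric("textureMap", function(x, textureRadiusPx = 5L)
    standardGeneric("textureMap"))

#' @rdname segmentWound
#' @export
setGeneric("segmentWound", function(x, params = segmentationParams())
    standardGeneric("segmentWound"))

#' @rdname subtractMigratedCells
#' @export
setGeneric("subtractMigratedCells",
    function(mask, image, params = mask@params)
        standardGeneric("subtractMigratedCells"))

#' @rdname outlineWound
#' @export
setGeneric("outlineWound", function(mask) standardGeneric("outlineWound"))

#' @rdname applyManualOverride
#' @export
setGeneric("applyManualOverride",
    function(mask, editMask, mode = c("add", "remove"))
        standardGeneric("applyManualOverride"))

#' @rdname measureCenterWidth
#' @export
setGeneric("measureCenterWidth",
    function(mask, pixelSizeUm = NULL) standardGeneric("measureCenterWidth"))

#' @rdname generateScene
#' @export
setGeneric("generateScene",
    function(spec, wellId = "W1", replicateId = "R1", fovIndex = 1L,
             timepointH = 0) standardGeneric("generateScene"))
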