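#' @rdname accessors
#' @export
setMethod("imagePixels", "CalibratedImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("pixelSize", "CalibratedImage", function(x) x@pixelSizeUm)

#' @rdname accessors
#' @export
setMethod("pixelSize", "WoundMask", function(x) x@pixelSizeUm)

.frameIdDf <- function(x) {
    data.frame(well_id = x@wellId, replicate_id = x@replicateId,
               fov_index = x@fovIndex, timepoint_h = x@timepointH,
               stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @export
setMethod("frameId", "CalibratedImage", .frameIdDf)

#' @rdname accessors
#' @export
setMethod("frameId", "WoundMask", .frameIdDf)

#' @rdname accessors
#' @export
setMethod("woundArea", "WoundMask", function(x, units = c("px", "um2")) {
    units <- match.arg(units)
    if (units == "px") x@areaPx else x@areaUm2
})

#' @rdname accessors
#' @export
setMethod("isClosed", "WoundMask", function(x) x@closed)

#' @rdname accessors
#' @export
setMethod("nIslands", "WoundMask", function(x) x@nIslandsSubtracted)

#' @rdname accessors
#' @export
setMethod("woundMask", "WoundMask", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("manifestTable", "ExperimentManifest", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("truthArea", "SyntheticScene", function(x) x@truthAreaPx)

#' @rdname accessors
#' @export
setMethod("truthMask", "SyntheticScene", function(x) x@truthWoundMask)

#' @rdname accessors
#' @export
setMethod("sceneImage", "SyntheticScene", function(x) x@image)

setMethod("show", "CalibratedImage", function(object) {
    cat("CalibratedImage:", nrow(object@pixels), "x", ncol(object@pixels),
        "px,", object@pixelSizeUm, "um/px\n")
    cat("  well", object@wellId, "replicate", object@replicateId,
        "fov", object@fovIndex, "t =", object@timepointH, "h,",
        object@magnificationLabel, "\n")
})

setMethod("show", "ExperimentManifest", function(object) {
    tab <- object@table
    cat("ExperimentManifest:", nrow(tab), "frames |",
        length(unique(tab$well_id)), "well(s),",
        length(unique(paste(tab$well_id, tab$replicate_id))), "replicate(s),",
        length(unique(tab$timepoint_h)), "timepoint(s)\n")
})

setMethod("show", "SegmentationParams", function(object) {
    cat("SegmentationParams: textureRadiusPx =", object@textureRadiusPx,
        "| threshold =", object@thresholdMethod,
        if (object@thresholdMethod == "fixed")
            paste0("(", object@fixedThreshold, ")") else "",
        "\n  closingRadiusPx =", object@closingRadiusPx,
        "| minIslandAreaPx =", object@minIslandAreaPx,
        "| minWoundFraction =", object@minWoundFraction,
        "\n  scratchAxis =", object@scratchAxis,
        "| bandMarginPx =", object@bandMarginPx, "\n")
})

setMethod("show", "WoundMask", function(object) {
    cat("WoundMask (", nrow(object@mask), "x", ncol(object@mask), "px )",
        if (object@closed) "[closed]" else "", "\n")
    cat("  area:", object@areaPx, "px =", object@areaUm2, "um^2 |",
        object@nIslandsSubtracted, "island(s) subtracted (",
        object@islandAreaPx, "px )\n")
    cat("  well", object@wellId, "replicate", object@replicateId,
        "fov", object@fovIndex, "t =", object@timepointH, "h\n")
})

setMethod("show", "CoveragePlan", function(object) {
    cat("CoveragePlan: scratch", object@scratchLengthUm, "um, fov extent",
        object@fovExtentUm, "um\n")
    cat("  frames tiled:", object@nTiled, "| included:", object@nIncluded,
        if (object@dropEnds) "(both end frames dropped)" else "", "\n")
    cat(sprintf("  coverage: %.1f%% of scratched length — target (>= 76%%) %s\n",
        100 * object@coverageFraction,
        if (object@meetsTarget) "met" else "NOT met"))
})

setMethod("show", "SyntheticSceneSpec", function(object) {
    cat("SyntheticSceneSpec:", object@heightPx, "x", object@widthPx,
        "px, scratch width", object@scratchWidthPx, "px @ col",
        object@scratchCenterColPx, "\n")
    cat("  roughness", object@edgeRoughnessAmpPx, "px / wavelength",
        object@edgeRoughnessWavelengthPx, "px | contrast",
        object@cellTextureContrast, "| noise", object@noiseSigma,
        "| islands:", nrow(object@islands), "| seed", object@seed, "\n")
})

setMethod("show", "SyntheticScene", function(object) {
    cat("SyntheticScene: truth wound area", object@truthAreaPx, "px,",
        nrow(object@spec@islands), "island(s)\n")
    show(object@image)
})
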