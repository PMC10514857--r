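#' Segment the cell-free wound region of one frame
#'
#' Texture-based wound segmentation. The pipeline: (1) local-SD texture map
#' ([textureMap()]); (2) binarization of low-texture pixels at an Otsu (or
#' fixed) threshold on the texture map; (3) morphological closing;
#' (4) 8-connected component labeling; (5) selection of low-texture
#' components that span at least 80\% of the frame along the scratch axis
#' and lie within the dominant scratch band plus \code{bandMarginPx};
#' (6) edge restoration: the windowed-SD score of a wound pixel is inflated
#' whenever its window overlaps the monolayer, which erodes the raw
#' low-texture region by one window radius on every side, so the final
#' region is rebuilt by dilating the near-floor texture core by the window
#' radius (exact boundary recovery on ideal edges); (7) the frame is
#' reported closed when the candidate is smaller than
#' \code{minWoundFraction} of the frame (or when the texture histogram has
#' no genuinely smooth class); (8) internal holes are filled and
#' migrated-cell islands at least \code{minIslandAreaPx} large are
#' subtracted via [subtractMigratedCells()] (smaller holes count as debris
#' and stay filled).
#'
#' A frame with no detectable wound is a valid "closed" result (the
#' assay's terminal state), not an error.
#'
#' @param x a [CalibratedImage-class] or [SyntheticScene-class].
#' @param params a [SegmentationParams-class].
#' @return A [WoundMask-class] satisfying \code{areaPx == sum(mask)} and
#'   \code{areaUm2 == areaPx * pixelSizeUm^2}.
#' @examples
#' scene <- generateScene(syntheticSceneSpec(heightPx = 192, widthPx = 256,
#'     scratchCenterColPx = 128, scratchWidthPx = 80, edgeRoughnessAmpPx = 0,
#'     noiseSigma = 0, seed = 1))
#' wm <- segmentWound(scene)
#' woundArea(wm) == truthArea(scene)
#' @seealso [textureMap()], [subtractMigratedCells()], [measureCenterWidth()]
#' @name segmentWound
NULL

#' @rdname segmentWound
#' @export
setMethod("segmentWound", "SyntheticScene", function(x, params = segmentationParams()) {
    segmentWound(x@image, params)
})

#' @rdname segmentWound
#' @export
setMethod("segmentWound", "CalibratedImage", function(x, params = segmentationParams()) {
    validObject(params)
    horiz <- params@scratchAxis == "horizontal"
    px <- if (horiz) t(x@pixels) else x@pixels
    r <- params@textureRadiusPx
    tex <- textureMap(px, r)
    thr <- if (params@thresholdMethod == "fixed") params@fixedThreshold
           else .otsuThreshold(tex)
    prov <- c(sprintf("texture: local SD, radius %d px", r),
              sprintf("threshold (%s): %.6g", params@thresholdMethod, thr))

    closed <- function(note) {
        m <- matrix(FALSE, nrow(x@pixels), ncol(x@pixels))
        .woundMask(m, x, params, closed = TRUE,
                   provenance = c(prov, note))
    }

    low <- tex < thr
    if (params@thresholdMethod == "otsu" && any(low) && any(!low) &&
        stats::median(tex[low]) > 0.5 * stats::median(tex[!low])) {
        # Otsu misses smooth classes occupying few pixels (narrow or nearly
        # closed wounds): its "low" class is then just the lower tail of the
        # monolayer texture mode. Retry at half the global median score; on
        # a genuinely confluent frame that keeps only scattered tail pixels,
        # which the span/band selection below rejects.
        thr <- 0.5 * stats::median(tex)
        low <- tex < thr
        prov <- c(prov, sprintf("threshold retry (half-median): %.6g", thr))
        if (any(low) && any(!low) &&
            stats::median(tex[low]) > 0.5 * stats::median(tex[!low]))
            return(closed("closed: no smooth texture class"))
    }
    if (!any(low)) return(closed("closed: no low-texture pixels"))

    if (params@closingRadiusPx > 0L)
        low <- .closeDisc(low, params@closingRadiusPx)
    lab <- .label8(low)

    # components spanning >= 80% of the frame along the scratch axis
    idx <- which(lab > 0L)
    lb <- lab[idx]
    rr <- ((idx - 1L) %% nrow(lab)) + 1L
    cc <- ((idx - 1L) %/% nrow(lab)) + 1L
    rmin <- tapply(rr, lb, min); rmax <- tapply(rr, lb, max)
    span <- (rmax - rmin + 1L) / nrow(lab)
    sizes <- tapply(rep(1L, length(lb)), lb, sum)
    spanning <- as.integer(names(span))[span >= 0.8]
    if (!length(spanning)) return(closed("closed: no spanning component"))

    dominant <- spanning[which.max(sizes[as.character(spanning)])]
    cmin <- tapply(cc, lb, min); cmax <- tapply(cc, lb, max)
    bandLo <- cmin[as.character(dominant)] - params@bandMarginPx
    bandHi <- cmax[as.character(dominant)] + params@bandMarginPx
    keep <- spanning[cmin[as.character(spanning)] >= bandLo &
                     cmax[as.character(spanning)] <= bandHi]
    coarse <- matrix(lab %in% keep, nrow(lab), ncol(lab))
    prov <- c(prov, sprintf("band: cols %d..%d (+/- %d px margin)",
                            as.integer(cmin[as.character(dominant)]),
                            as.integer(cmax[as.character(dominant)]),
                            params@bandMarginPx))

    # edge restoration: dilate the near-floor core by the window radius
    plateau <- if (any(tex >= thr)) stats::median(tex[tex >= thr]) else max(tex)
    floorv <- stats::median(tex[coarse])
    tCore <- max(1.15 * floorv, 1e-4 * plateau)
    core <- (tex <= tCore) & .dilateBox(coarse, r)
    if (!any(core)) return(closed("closed: empty texture core"))
    refined <- .dilateBox(core, r)
    if (params@closingRadiusPx > 0L)
        refined <- .closeDisc(refined, params@closingRadiusPx)

    if (sum(refined) < params@minWoundFraction * length(px))
        return(closed(sprintf("closed: candidate below minWoundFraction (%g)",
                              params@minWoundFraction)))

    foot <- .fillHoles(refined)
    filled <- sum(foot) - sum(refined)
    prov <- c(prov, sprintf("filled %d interior hole px", filled))

    isl <- .islandSubtract(foot, tex, r, params@minIslandAreaPx)
    prov <- c(prov, sprintf("subtracted %d migrated-cell island(s), %d px",
                            isl$n, isl$areaRemoved))
    maskOut <- if (horiz) t(isl$mask) else isl$mask
    .woundMask(maskOut, x, params, nIslands = isl$n,
               islandArea = isl$areaRemoved, closed = FALSE,
               provenance = prov)
})

# Otsu threshold on an arbitrary non-negative score matrix
.otsuThreshold <- function(tex) {
    mx <- max(tex)
    if (mx <= 0) return(0)
    EBImage::otsu(EBImage::Image(tex / mx), range = c(0, 1), levels = 256L) * mx
}

# Remove migrated-cell islands >= minArea inside a wound footprint.
# An island is a textured region the smooth-core coverage cannot reach:
# within the footprint, the near-floor texture core is dilated by the
# window radius (the same edge-restoration rule used for the outer wound
# boundary); enclosed regions left uncovered are holes. Holes smaller
# than minArea are debris and stay filled; larger holes are counted and
# subtracted. Under additive noise, stochastic inclusion of transition
# pixels shifts the restored boundary slightly outward and shrinks holes by
# the same amount, so detected islands are re-inflated by 1 px then
# (calibrated on the synthetic scene suite; no compensation is applied in
# the noiseless regime, where boundary recovery is exact).
.islandSubtract <- function(foot, tex, r, minArea) {
    if (!any(foot))
        return(list(mask = foot, n = 0L, areaRemoved = 0L))
    floorv <- stats::median(tex[foot])
    plateau <- if (any(!foot)) stats::median(tex[!foot]) else max(tex)
    tCore <- max(1.15 * floorv, 1e-4 * plateau)
    core <- (tex <= tCore) & foot
    covered <- .dilateBox(core, r) & foot
    holes <- foot & !covered
    if (!any(holes))
        return(list(mask = foot, n = 0L, areaRemoved = 0L))
    lab <- .label8(holes)
    sizes <- .labelSizes(lab)
    keep <- which(sizes >= minArea)
    if (!length(keep))
        return(list(mask = foot, n = 0L, areaRemoved = 0L))
    islands <- matrix(lab %in% keep, nrow(lab), ncol(lab))
    noisy <- floorv > 0.01 * plateau
    if (noisy) islands <- .dilateDisc(islands, 1L)
    removed <- islands & foot
    list(mask = foot & !removed, n = length(keep),
         areaRemoved = as.integer(sum(removed)))
}

#' Subtract migrated-cell islands from a wound mask
#'
#' Within the wound region, connected textured components (cells that
#' migrated into the scratch) with area at least
#' \code{params@minIslandAreaPx} are removed from the mask; smaller
#' textured patches are treated as debris and left in place. Islands are
#' found as the enclosed regions that the smooth texture core, dilated by
#' the texture-window radius, cannot cover — the same boundary rule used
#' for the outer wound edge, so island and wound boundaries are located
#' consistently. Output area is never larger than input area.
#'
#' @param mask a [WoundMask-class].
#' @param image the matching [CalibratedImage-class] (same shape).
#' @param params a [SegmentationParams-class]; defaults to the parameters
#'   stored in \code{mask}.
#' @return An updated [WoundMask-class] with islands removed and
#'   \code{nIslandsSubtracted} / \code{islandAreaPx} incremented.
#' @seealso [segmentWound()]
#' @name subtractMigratedCells
NULL

#' @rdname subtractMigratedCells
#' @export
setMethod("subtractMigratedCells", signature("WoundMask", "CalibratedImage"),
    function(mask, image, params = mask@params) {
        if (!identical(dim(mask@mask), dim(image@pixels)))
            stop("mask and image shapes differ: ",
                 paste(dim(mask@mask), collapse = "x"), " vs ",
                 paste(dim(image@pixels), collapse = "x"))
        horiz <- params@scratchAxis == "horizontal"
        m <- if (horiz) t(mask@mask) else mask@mask
        px <- if (horiz) t(image@pixels) else image@pixels
        tex <- textureMap(px, params@textureRadiusPx)
        isl <- .islandSubtract(m, tex, params@textureRadiusPx,
                               params@minIslandAreaPx)
        maskOut <- if (horiz) t(isl$mask) else isl$mask
        .woundMask(maskOut, image, params,
                   nIslands = mask@nIslandsSubtracted + isl$n,
                   islandArea = mask@islandAreaPx + isl$areaRemoved,
                   closed = mask@closed,
                   provenance = c(mask@provenance,
                       sprintf("subtracted %d migrated-cell island(s), %d px",
                               isl$n, isl$areaRemoved)))
    })

#' Trace the boundary contours of a wound mask
#'
#' Returns the closed boundary polylines of the wound region: one outer
#' contour per connected wound component and one inner contour per
#' enclosed hole (e.g. a subtracted migrated-cell island), suitable for
#' overlay rendering. An empty mask yields an empty contour list.
#'
#' @param mask a [WoundMask-class].
#' @return A list with elements \code{outer} and \code{inner}, each a list
#'   of two-column coordinate matrices, with attribute \code{areaPx} equal
#'   to the enclosed wound pixel count.
#' @seealso [segmentWound()]
#' @name outlineWound
NULL

#' @rdname outlineWound
#' @export
setMethod("outlineWound", "WoundMask", function(mask) {
    m <- mask@mask
    if (!any(m)) return(list())
    outer <- EBImage::ocontour(.label8(m))
    holes <- .fillHoles(m) & !m
    inner <- if (any(holes)) EBImage::ocontour(.label8(holes)) else list()
    out <- list(outer = outer, inner = inner)
    attr(out, "areaPx") <- mask@areaPx
    out
})

#' Apply a manual mask edit
#'
#' Applies a user-drawn correction of the leading edge: in \code{"add"}
#' mode the edit is unioned with the wound mask, in \code{"remove"} mode
#' it is subtracted. Areas are recomputed and the edit is recorded in the
#' mask's provenance log.
#'
#' @param mask a [WoundMask-class].
#' @param editMask logical (or 0/1) matrix of the same shape.
#' @param mode \code{"add"} or \code{"remove"}.
#' @return The edited [WoundMask-class].
#' @name applyManualOverride
NULL

#' @rdname applyManualOverride
#' @export
setMethod("applyManualOverride", "WoundMask",
    function(mask, editMask, mode = c("add", "remove")) {
        mode <- match.arg(mode)
        editMask <- editMask > 0
        if (!identical(dim(editMask), dim(mask@mask)))
            stop("edit mask shape differs from wound mask: ",
                 paste(dim(editMask), collapse = "x"), " vs ",
                 paste(dim(mask@mask), collapse = "x"))
        m <- if (mode == "add") mask@mask | editMask else mask@mask & !editMask
        new("WoundMask", mask = m, areaPx = as.integer(sum(m)),
            areaUm2 = as.integer(sum(m)) * mask@pixelSizeUm^2,
            nIslandsSubtracted = mask@nIslandsSubtracted,
            islandAreaPx = mask@islandAreaPx,
            closed = sum(m) == 0L, params = mask@params,
            pixelSizeUm = mask@pixelSizeUm, wellId = mask@wellId,
            replicateId = mask@replicateId, fovIndex = mask@fovIndex,
            timepointH = mask@timepointH,
            provenance = c(mask@provenance,
                sprintf("manual override (%s): %d px edit", mode,
                        sum(editMask))))
    })
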