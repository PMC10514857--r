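#' Center-line wound width
#'
#' Width of the scratch measured along the single pixel line through the
#' frame center perpendicular to the scratch axis, wall to wall: the span
#' from the first to the last wound pixel on that line times the pixel
#' size. Subtracted migrated-cell islands inside the span do not shorten
#' it. Returns 0 when the center line crosses no wound pixels.
#'
#' @param mask a [WoundMask-class].
#' @param pixelSizeUm calibration override; defaults to the mask's own.
#' @return Width in micrometres (numeric scalar >= 0).
#' @examples
#' scene <- generateScene(syntheticSceneSpec(heightPx = 192, widthPx = 256,
#'     scratchCenterColPx = 128, scratchWidthPx = 80, edgeRoughnessAmpPx = 0,
#'     noiseSigma = 0, seed = 1))
#' measureCenterWidth(segmentWound(scene))   # 80 px * 1.6 um
#' @name measureCenterWidth
NULL

#' @rdname measureCenterWidth
#' @export
setMethod("measureCenterWidth", "WoundMask",
    function(mask, pixelSizeUm = NULL) {
        ps <- if (is.null(pixelSizeUm)) mask@pixelSizeUm else pixelSizeUm
        m <- if (mask@params@scratchAxis == "horizontal") t(mask@mask)
             else mask@mask
        center <- (nrow(m) + 1L) %/% 2L
        hit <- which(m[center, ])
        if (!length(hit)) return(0)
        (max(hit) - min(hit) + 1L) * ps
    })

#' Measure one segmented frame
#'
#' Collects the per-field-of-view quantities into a one-row data.frame:
#' identity, pixel and physical wound area, center-line width and the
#' closed flag.
#'
#' @param mask a [WoundMask-class].
#' @return data.frame with columns \code{well_id}, \code{replicate_id},
#'   \code{fov_index}, \code{timepoint_h}, \code{area_px}, \code{area_um2},
#'   \code{width_center_um}, \code{closed_flag},
#'   \code{n_islands_subtracted}.
#' @export
measureFov <- function(mask) {
    stopifnot(is(mask, "WoundMask"))
    cbind(frameId(mask),
          data.frame(area_px = mask@areaPx, area_um2 = mask@areaUm2,
                     width_center_um = measureCenterWidth(mask),
                     closed_flag = mask@closed,
                     n_islands_subtracted = mask@nIslandsSubtracted))
}

#' Total scratch area of one replicate at one timepoint
#'
#' Combines the wound areas of all fields of view of one technical
#' replicate into the replicate's total scratch area — the aggregation
#' that makes closure rates robust against per-field variability. All
#' rows must share (well, replicate, timepoint) and carry distinct
#' \code{fov_index} values; when \code{baselineFovs} is supplied the set
#' of fields must match the replicate's 0 h set exactly.
#'
#' @param fovMeasurements data.frame as produced by [measureFov()] (one
#'   row per field of view).
#' @param baselineFovs optional integer vector of the fov indices present
#'   at 0 h for this replicate.
#' @return One-row data.frame with \code{well_id}, \code{replicate_id},
#'   \code{timepoint_h}, \code{n_fovs}, \code{included_fovs}
#'   (comma-separated), \code{total_area_px}, \code{total_area_um2}.
#' @examples
#' fov <- data.frame(well_id = "W1", replicate_id = "R1", fov_index = 1:5,
#'     timepoint_h = 0, area_px = c(12000, 9000, 11000, 8000, 10000),
#'     area_um2 = 0)
#' totalReplicateArea(fov)$total_area_px   # 50000
#' @export
totalReplicateArea <- function(fovMeasurements, baselineFovs = NULL) {
    x <- fovMeasurements
    req <- c("well_id", "replicate_id", "fov_index", "timepoint_h", "area_px")
    miss <- setdiff(req, names(x))
    if (length(miss))
        stop("fov measurements lack column(s): ", paste(miss, collapse = ", "))
    if (nrow(x) == 0L) stop("no field-of-view measurements supplied")
    ident <- unique(x[, c("well_id", "replicate_id", "timepoint_h")])
    if (nrow(ident) != 1L)
        stop("all measurements must share one (well, replicate, timepoint); got ",
             nrow(ident), " distinct identities")
    if (anyDuplicated(x$fov_index))
        stop("duplicate fov_index values: ",
             paste(x$fov_index[duplicated(x$fov_index)], collapse = ", "))
    if (!is.null(baselineFovs) &&
        !setequal(as.integer(x$fov_index), as.integer(baselineFovs)))
        stop(sprintf(
            "fov set {%s} of replicate %s/%s at t=%g h differs from its 0 h set {%s}",
            paste(sort(x$fov_index), collapse = ","),
            ident$well_id, ident$replicate_id, ident$timepoint_h,
            paste(sort(baselineFovs), collapse = ",")))
    um2 <- if ("area_um2" %in% names(x)) sum(x$area_um2) else NA_real_
    data.frame(well_id = ident$well_id, replicate_id = ident$replicate_id,
               timepoint_h = ident$timepoint_h, n_fovs = nrow(x),
               included_fovs = paste(sort(x$fov_index), collapse = ","),
               total_area_px = sum(as.numeric(x$area_px)),
               total_area_um2 = um2, stringsAsFactors = FALSE)
}

#' Percent of the wound remaining open
#'
#' \code{100 * area_t / area_0}: the scratch area at time t divided by the
#' initial (0 h) scratch area of the same replicate. Values above 100
#' (wound widening, e.g. cell retraction) are allowed but flagged with a
#' warning rather than clamped, since clamping would hide protocol
#' failures. A replicate already closed at 0 h has no defined baseline and
#' is an error.
#'
#' @param areaT total scratch area at time t (same units as \code{area0}).
#' @param area0 total scratch area at 0 h (> 0).
#' @return Percent open (numeric scalar >= 0).
#' @examples
#' percentOpen(30000, 50000)   # 60
#' @export
percentOpen <- function(areaT, area0) {
    if (!is.finite(area0) || area0 <= 0)
        stop("undefined baseline: replicate scratch area at 0 h must be > 0 ",
             "(a wound closed at 0 h is a protocol failure)")
    if (!is.finite(areaT) || areaT < 0)
        stop("'areaT' must be a non-negative number")
    p <- 100 * areaT / area0
    if (p > 100)
        warning(sprintf("percent open %.1f exceeds 100: wound widened", p))
    p
}

#' Mean and SD of percent-open across technical replicates
#'
#' Arithmetic mean and sample (n-1) standard deviation of the
#' percent-open values of the technical replicates at one timepoint, as
#' plotted in closure-kinetics summaries (mean +/- SD). With a single
#' replicate the SD is reported as 0 with a warning.
#'
#' @param percentOpenValues numeric vector, one value per replicate.
#' @return list with \code{mean}, \code{sd}, \code{n}.
#' @examples
#' summarizeReplicates(c(50, 60, 70))   # mean 60, sd 10
#' @export
summarizeReplicates <- function(percentOpenValues) {
    x <- percentOpenValues
    if (!length(x)) stop("no replicate values supplied")
    if (any(!is.finite(x))) stop("replicate values must be finite")
    if (length(x) == 1L) {
        warning("only one replicate: SD reported as 0")
        return(list(mean = as.numeric(x), sd = 0, n = 1L))
    }
    list(mean = mean(x), sd = stats::sd(x), n = length(x))
}

#' Plan field-of-view coverage of a scratch
#'
#' How many frames of extent \code{fovExtentUm} are needed to tile a
#' scratch of length \code{scratchLengthUm}, and what fraction of the
#' scratched length remains covered after dropping the two end frames
#' (which contain the blunt, inconsistent scratch ends and are omitted
#' from analysis). The plan reports whether the kept frames cover at
#' least 76 percent of the scratched length, the threshold for robust
#' closure quantification. In a standard 24-well plate the scratch runs
#' the full well diameter (15.6 mm), and a 4x field spanning 2.4 mm gives
#' 7 tiled frames, 5 kept, covering 77 percent.
#'
#' @param scratchLengthUm scratch length in micrometres (> 0); defaults to
#'   the nominal 24-well diameter, 15600.
#' @param fovExtentUm frame extent along the scratch axis in micrometres
#'   (> 0 and smaller than the scratch length).
#' @param dropEnds drop the two blunt-end frames (default TRUE).
#' @return A [CoveragePlan-class].
#' @examples
#' planCoverage(15600, 2400)   # 7 tiled, 5 included, 76.9% covered
#' @export
planCoverage <- function(scratchLengthUm = 15600, fovExtentUm,
                         dropEnds = TRUE) {
    if (!is.finite(scratchLengthUm) || scratchLengthUm <= 0 ||
        !is.finite(fovExtentUm) || fovExtentUm <= 0)
        stop("'scratchLengthUm' and 'fovExtentUm' must be positive numbers")
    if (fovExtentUm >= scratchLengthUm)
        stop("'fovExtentUm' must be smaller than 'scratchLengthUm'")
    nTiled <- as.integer(ceiling(scratchLengthUm / fovExtentUm))
    nIncluded <- if (dropEnds) nTiled - 2L else nTiled
    if (nIncluded < 1L)
        stop("dropping both end frames leaves no frame; scratch too short ",
             "relative to the field of view")
    coverage <- min(1, nIncluded * fovExtentUm / scratchLengthUm)
    new("CoveragePlan", scratchLengthUm = as.numeric(scratchLengthUm),
        fovExtentUm = as.numeric(fovExtentUm), nTiled = nTiled,
        nIncluded = nIncluded, dropEnds = isTRUE(dropEnds),
        coverageFraction = coverage, meetsTarget = coverage >= 0.76)
}

#' Seeding density from cell count and growth area
#'
#' Cells per square centimetre for a given cell number and culture-vessel
#' growth area, reported as whole cells (fractional part dropped). For a
#' 24-well plate well (1.9 cm^2), 10,000 cells give 5263 cells/cm^2 (the
#' recommended density for primary dermal fibroblasts) and 60,000 cells
#' give 31,578 cells/cm^2 (the recommended density for HEKa
#' keratinocytes).
#'
#' @param cells number of cells seeded (> 0).
#' @param growthAreaCm2 vessel growth area in cm^2 (> 0).
#' @return Integer cells per cm^2.
#' @examples
#' seedingDensity(10000, 1.9)   # 5263
#' seedingDensity(60000, 1.9)   # 31578
#' @export
seedingDensity <- function(cells, growthAreaCm2) {
    if (!is.finite(cells) || cells <= 0 ||
        !is.finite(growthAreaCm2) || growthAreaCm2 <= 0)
        stop("'cells' and 'growthAreaCm2' must be positive numbers")
    as.integer(floor(cells / growthAreaCm2))
}
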