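#' Quantify a scratch-assay experiment end to end
#'
#' Orchestrates the full analysis: load and validate the manifest, segment
#' every frame, measure per-field areas and center-line widths, aggregate
#' fields of view into per-replicate total scratch areas, compute
#' percent-wound-remaining-open against each replicate's 0 h baseline,
#' and summarize replicates as mean +/- sample SD per well and timepoint.
#' Writes three CSVs (\code{fov_measurements.csv},
#' \code{replicate_measurements.csv}, \code{summary.csv}) and a plain-text
#' run log echoing all effective parameters. A frame whose segmentation
#' fails is logged and skipped — the affected replicate timepoint is
#' dropped — without aborting the run. The run is deterministic: identical
#' inputs and configuration produce byte-identical outputs.
#'
#' @param manifest path to a manifest CSV or an
#'   [ExperimentManifest-class].
#' @param outDir output directory (created if needed).
#' @param params a [SegmentationParams-class].
#' @param defaultPixelSizeUm calibration for manifest rows with blank
#'   \code{pixel_size_um} (only used when \code{manifest} is a path).
#' @param dropEnds drop each replicate's lowest- and highest-index field
#'   of view before aggregation (for experiments that imaged the blunt
#'   scratch ends; default FALSE, assuming the manifest lists only the
#'   fields to analyze).
#' @param emitOverlays write per-frame QC PNGs (wound contour over the
#'   source frame, plus the binary mask).
#' @return Invisibly, a list with the three result data.frames
#'   (\code{fov}, \code{replicates}, \code{summary}), the \code{failures}
#'   character vector and the output file \code{paths}.
#' @seealso [segmentWound()], [totalReplicateArea()], [percentOpen()]
#' @export
runQuantify <- function(manifest, outDir, params = segmentationParams(),
                        defaultPixelSizeUm = NULL, dropEnds = FALSE,
                        emitOverlays = FALSE) {
    if (is.character(manifest))
        manifest <- loadManifest(manifest, defaultPixelSizeUm)
    stopifnot(is(manifest, "ExperimentManifest"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    tab <- manifest@table
    failures <- character()
    fovRows <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
        res <- tryCatch({
            img <- loadImage(manifest, i)
            wm <- segmentWound(img, params)
            if (emitOverlays) .writeOverlays(img, wm, outDir)
            measureFov(wm)
        }, error = function(e) {
            sprintf("frame %s/%s fov %d t=%g h (%s): %s",
                    tab$well_id[i], tab$replicate_id[i], tab$fov_index[i],
                    tab$timepoint_h[i], tab$file_path[i],
                    conditionMessage(e))
        })
        if (is.character(res)) failures <- c(failures, res)
        else fovRows[[i]] <- res
    }
    fov <- do.call(rbind, fovRows)
    if (is.null(fov) || nrow(fov) == 0L)
        stop("no frame could be processed; first failure: ", failures[1L])

    if (dropEnds) {
        repKey <- paste(fov$well_id, fov$replicate_id)
        keep <- rep(TRUE, nrow(fov))
        for (rk in unique(repKey)) {
            sel <- repKey == rk
            rng <- range(fov$fov_index[sel])
            keep[sel & fov$fov_index %in% rng] <- FALSE
        }
        fov <- fov[keep, , drop = FALSE]
    }

    # aggregate fields of view; a replicate timepoint with missing frames
    # (failed or dropped) is excluded and noted in the run log
    repRows <- list(); q <- 0L
    repKey <- paste(fov$well_id, fov$replicate_id, sep = "|")
    for (rk in unique(repKey)) {
        sub <- fov[repKey == rk, , drop = FALSE]
        fov0 <- sort(sub$fov_index[sub$timepoint_h == 0])
        if (!length(fov0)) {
            failures <- c(failures, sprintf(
                "replicate %s: no usable 0 h frames; replicate skipped",
                gsub("\\|", "/", rk)))
            next
        }
        for (t in sort(unique(sub$timepoint_h))) {
            st <- sub[sub$timepoint_h == t, , drop = FALSE]
            tot <- tryCatch(totalReplicateArea(st, baselineFovs = fov0),
                            error = function(e) conditionMessage(e))
            if (is.character(tot)) {
                failures <- c(failures, sprintf(
                    "replicate %s at t=%g h excluded: %s",
                    gsub("\\|", "/", rk), t, tot))
                next
            }
            q <- q + 1L
            repRows[[q]] <- tot
        }
    }
    reps <- do.call(rbind, repRows)
    if (is.null(reps)) stop("no replicate could be aggregated")

    reps$percent_open <- NA_real_
    reps$widened_flag <- FALSE
    repKey2 <- paste(reps$well_id, reps$replicate_id, sep = "|")
    for (rk in unique(repKey2)) {
        sel <- repKey2 == rk
        base <- reps$total_area_px[sel & reps$timepoint_h == 0]
        if (!length(base) || base <= 0) {
            failures <- c(failures, sprintf(
                "replicate %s has no positive 0 h total area; percent open undefined",
                gsub("\\|", "/", rk)))
            next
        }
        p <- withCallingHandlers(
            vapply(reps$total_area_px[sel], percentOpen, 0, area0 = base),
            warning = function(w) invokeRestart("muffleWarning"))
        reps$percent_open[sel] <- p
        reps$widened_flag[sel] <- p > 100
    }

    sumRows <- list(); q <- 0L
    ok <- !is.na(reps$percent_open)
    wellKey <- paste(reps$well_id, reps$timepoint_h, sep = "|")
    for (wk in unique(wellKey[ok])) {
        sel <- ok & wellKey == wk
        s <- suppressWarnings(summarizeReplicates(reps$percent_open[sel]))
        q <- q + 1L
        sumRows[[q]] <- data.frame(
            well_id = reps$well_id[sel][1L],
            timepoint_h = reps$timepoint_h[sel][1L],
            mean_percent_open = s$mean, sd_percent_open = s$sd, n = s$n,
            stringsAsFactors = FALSE)
    }
    summary <- do.call(rbind, sumRows)
    summary <- summary[order(summary$well_id, summary$timepoint_h), ,
                       drop = FALSE]

    paths <- list(fov = file.path(outDir, "fov_measurements.csv"),
                  replicates = file.path(outDir, "replicate_measurements.csv"),
                  summary = file.path(outDir, "summary.csv"),
                  log = file.path(outDir, "run_log.txt"))
    utils::write.csv(fov, paths$fov, row.names = FALSE)
    utils::write.csv(reps, paths$replicates, row.names = FALSE)
    utils::write.csv(summary, paths$summary, row.names = FALSE)
    writeLines(c(
        "scratchquant run log",
        sprintf("frames_in_manifest=%d", nrow(tab)),
        sprintf("frames_measured=%d", nrow(fov)),
        sprintf("texture_radius_px=%d", params@textureRadiusPx),
        sprintf("threshold_method=%s", params@thresholdMethod),
        sprintf("fixed_threshold=%s", params@fixedThreshold),
        sprintf("closing_radius_px=%d", params@closingRadiusPx),
        sprintf("min_wound_fraction=%g", params@minWoundFraction),
        sprintf("min_island_area_px=%d", params@minIslandAreaPx),
        sprintf("scratch_axis=%s", params@scratchAxis),
        sprintf("band_margin_px=%d", params@bandMarginPx),
        sprintf("drop_ends=%s", dropEnds),
        sprintf("emit_overlays=%s", emitOverlays),
        if (length(failures)) paste0("failure=", failures) else
            "failures=none"),
        paths$log)
    invisible(list(fov = fov, replicates = reps, summary = summary,
                   failures = failures, paths = paths))
}

# per-frame QC images: contours over the source frame + binary mask
.writeOverlays <- function(img, wm, outDir) {
    stem <- sprintf("%s_%s_F%d_t%04.1fh", img@wellId, img@replicateId,
                    img@fovIndex, img@timepointH)
    g <- img@pixels / max(img@pixels, 1)
    m <- wm@mask
    boundary <- m & !.erodeBox(m, 1L)
    rgb <- array(c(g, g, g), dim = c(dim(g), 3L))
    rgb[, , 1L][boundary] <- 1
    rgb[, , 2L][boundary] <- 0
    rgb[, , 3L][boundary] <- 0
    png::writePNG(rgb, file.path(outDir, paste0(stem, "_overlay.png")))
    png::writePNG(m * 1.0, file.path(outDir, paste0(stem, "_mask.png")))
    invisible(NULL)
}

#' Generate a synthetic dataset from the command-line surface
#'
#' Thin wrapper over [generateTimeCourse()] that prints the manifest path,
#' for scripted use.
#'
#' @param outDir output directory.
#' @param spec baseline [SyntheticSceneSpec-class].
#' @param schedule named width-scale schedule (see
#'   [generateTimeCourse()]).
#' @param nFovs,nReplicates layout of the simulated experiment.
#' @param seed master seed.
#' @return Invisibly, the [generateTimeCourse()] result list.
#' @export
runSimulate <- function(outDir, spec = syntheticSceneSpec(),
                        schedule = c("0" = 1, "12" = 0.5), nFovs = 5L,
                        nReplicates = 3L, seed = 1L) {
    out <- generateTimeCourse(spec, schedule, nFovs = nFovs,
                              nReplicates = nReplicates, dir = outDir,
                              seed = seed)
    message("manifest: ", out$manifest)
    invisible(out)
}

#' Print a field-of-view coverage plan
#'
#' Thin wrapper over [planCoverage()] that prints the plan and whether the
#' 76 percent coverage target is met.
#'
#' @param scratchLengthUm,fovExtentUm,dropEnds see [planCoverage()].
#' @return Invisibly, the [CoveragePlan-class].
#' @export
runPlan <- function(scratchLengthUm = 15600, fovExtentUm,
                    dropEnds = TRUE) {
    plan <- planCoverage(scratchLengthUm, fovExtentUm, dropEnds)
    show(plan)
    invisible(plan)
}
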