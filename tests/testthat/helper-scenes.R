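# small, fast scene factories used across tests

# compact scene (256 x 192) for unit tests; defaults mirror the package's
# reference family scaled down (CNR 4, roughness ~ frame/75)
smallSpec <- function(widthPx = 80, roughness = 4, noise = 7.5,
                      islands = data.frame(row = numeric(0),
                                           col = numeric(0),
                                           radius = numeric(0)),
                      seed = 1L, ...) {
    syntheticSceneSpec(heightPx = 192L, widthPx = 256L,
        scratchCenterColPx = 128, scratchWidthPx = widthPx,
        edgeRoughnessAmpPx = roughness, edgeRoughnessWavelengthPx = 48,
        noiseSigma = noise, islands = islands, seed = seed, ...)
}

smallParams <- function(...) {
    args <- utils::modifyList(list(minIslandAreaPx = 100L,
                                   bandMarginPx = 25L), list(...))
    do.call(segmentationParams, args)
}

# write a minimal valid manifest + TIFF frames into `dir`; returns the
# manifest path. layout: one well, `nRep` replicates x `nFov` fovs x `tps`.
writeTinyExperiment <- function(dir, nRep = 1L, nFov = 3L, tps = c(0, 12)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rows <- list(); k <- 0L
    for (r in seq_len(nRep)) for (f in seq_len(nFov)) for (t in tps) {
        sc <- generateScene(smallSpec(seed = 100L * r + 10L * f + t),
                            wellId = "W1", replicateId = paste0("R", r),
                            fovIndex = f, timepointH = t)
        fn <- sprintf("r%d_f%d_t%d.tif", r, f, t)
        writeCalibratedImage(sceneImage(sc), file.path(dir, fn))
        k <- k + 1L
        rows[[k]] <- data.frame(file_path = fn, well_id = "W1",
            replicate_id = paste0("R", r), fov_index = f, timepoint_h = t,
            pixel_size_um = 1.6)
    }
    path <- file.path(dir, "manifest.csv")
    write.csv(do.call(rbind, rows), path, row.names = FALSE)
    path
}

# brute-force windowed standard deviation with edge-mirrored padding:
# the independent oracle for textureMap
bruteLocalSd <- function(m, r) {
    n <- nrow(m); p <- ncol(m)
    mirror <- function(i, k) { i[i < 1] <- 1 - i[i < 1]; i[i > k] <- 2 * k + 1 - i[i > k]; i }
    out <- matrix(0, n, p)
    for (i in seq_len(n)) for (j in seq_len(p)) {
        ri <- mirror((i - r):(i + r), n)
        ci <- mirror((j - r):(j + r), p)
        w <- m[ri, ci]
        out[i, j] <- sqrt(max(mean(w^2) - mean(w)^2, 0))
    }
    out
}
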