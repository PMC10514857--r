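#' Load and validate an experiment manifest
#'
#' Reads the CSV that maps image files to their place in the experiment:
#' required columns \code{file_path}, \code{well_id}, \code{replicate_id},
#' \code{fov_index}, \code{timepoint_h}, plus \code{pixel_size_um} per row
#' or as a global default. Validation enforces that (well, replicate, fov,
#' timepoint) tuples are unique and that every replicate present at a
#' later timepoint also has 0 h frames with the same set of fields of
#' view, since all closure metrics normalize by the 0 h area. Rows are
#' returned sorted by (well, replicate, timepoint, fov); validation is
#' idempotent and independent of input row order.
#'
#' @param path manifest CSV path.
#' @param defaultPixelSizeUm calibration applied to rows with a blank
#'   \code{pixel_size_um}.
#' @return An [ExperimentManifest-class].
#' @seealso [loadImage()], [runQuantify()]
#' @export
loadManifest <- function(path, defaultPixelSizeUm = NULL) {
    if (!file.exists(path)) stop("manifest file not found: ", path)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    req <- c("file_path", "well_id", "replicate_id", "fov_index",
             "timepoint_h")
    miss <- setdiff(req, names(tab))
    if (length(miss))
        stop("manifest is missing required column(s): ",
             paste(miss, collapse = ", "))
    if (nrow(tab) == 0L)
        stop("manifest contains no rows")
    if (!"pixel_size_um" %in% names(tab))
        tab$pixel_size_um <- NA_real_
    tab$pixel_size_um <- as.numeric(tab$pixel_size_um)
    if (!is.null(defaultPixelSizeUm))
        tab$pixel_size_um[is.na(tab$pixel_size_um)] <- defaultPixelSizeUm
    if (anyNA(tab$pixel_size_um))
        stop("pixel_size_um is blank for ", sum(is.na(tab$pixel_size_um)),
             " row(s) and no default was supplied")
    if (any(tab$pixel_size_um <= 0))
        stop("pixel_size_um must be > 0 for every row")
    tab$fov_index <- as.integer(tab$fov_index)
    tab$timepoint_h <- as.numeric(tab$timepoint_h)
    if (anyNA(tab$fov_index) || any(tab$fov_index < 1L))
        stop("fov_index must be an integer >= 1 for every row")
    if (anyNA(tab$timepoint_h) || any(tab$timepoint_h < 0))
        stop("timepoint_h must be a number >= 0 for every row")

    key <- paste(tab$well_id, tab$replicate_id, tab$fov_index,
                 tab$timepoint_h, sep = "|")
    if (anyDuplicated(key)) {
        dup <- unique(key[duplicated(key)])
        stop("duplicate (well, replicate, fov, timepoint) tuple(s): ",
             paste(gsub("\\|", ", ", dup), collapse = "; "))
    }
    repKey <- paste(tab$well_id, tab$replicate_id, sep = "|")
    for (rk in unique(repKey)) {
        sub <- tab[repKey == rk, ]
        fov0 <- sort(sub$fov_index[sub$timepoint_h == 0])
        if (!length(fov0))
            stop("replicate ", gsub("\\|", "/", rk),
                 " has no 0 h frames; every replicate needs a 0 h baseline")
        for (t in unique(sub$timepoint_h)) {
            fovT <- sort(sub$fov_index[sub$timepoint_h == t])
            if (!identical(fovT, fov0))
                stop("replicate ", gsub("\\|", "/", rk), " at t = ", t,
                     " h has fov set {", paste(fovT, collapse = ","),
                     "} but its 0 h set is {", paste(fov0, collapse = ","),
                     "}")
        }
    }
    tab <- tab[order(tab$well_id, tab$replicate_id, tab$timepoint_h,
                     tab$fov_index), , drop = FALSE]
    rownames(tab) <- NULL
    new("ExperimentManifest", table = tab,
        dir = dirname(normalizePath(path)))
}

#' Load one frame of the manifest as a CalibratedImage
#'
#' Reads the image file of one manifest row (16/8-bit grayscale TIFF or
#' PNG) with intensities preserved exactly as stored — no rescaling or
#' normalization happens at load time. Multi-channel input is converted to
#' luminance (Rec. 709 weights) with a warning. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param manifest an [ExperimentManifest-class] (or a one-row data.frame
#'   with the manifest columns plus an optional \code{dir} attribute).
#' @param row row number of the frame to load.
#' @return A [CalibratedImage-class].
#' @seealso [loadManifest()], [writeCalibratedImage()]
#' @export
loadImage <- function(manifest, row = 1L) {
    if (is(manifest, "ExperimentManifest")) {
        r <- manifest@table[row, , drop = FALSE]
        base <- manifest@dir
    } else {
        r <- as.data.frame(manifest)[row, , drop = FALSE]
        base <- attr(manifest, "dir")
        if (is.null(base)) base <- "."
    }
    path <- r$file_path
    if (!grepl("^(/|[A-Za-z]:)", path)) path <- file.path(base, path)
    if (!file.exists(path)) stop("image file not found: ", path)
    px <- .readRaster(path)
    if (length(dim(px)) == 3L) {
        nc <- dim(px)[3L]
        warning("multi-channel image converted to luminance: ", path)
        px <- if (nc >= 3L)
            0.2126 * px[, , 1L] + 0.7152 * px[, , 2L] + 0.0722 * px[, , 3L]
        else px[, , 1L]
    }
    if (any(dim(px) == 0L)) stop("zero-area image: ", path)
    calibratedImage(px, r$pixel_size_um, r$well_id, r$replicate_id,
                    r$fov_index, r$timepoint_h,
                    magnificationLabel = "unspecified")
}

.readRaster <- function(path) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
        tryCatch(tiff::readTIFF(path, as.is = TRUE),
                 error = function(e) stop("failed to read TIFF '", path,
                                          "': ", conditionMessage(e)))
    } else if (ext == "png") {
        depth <- .pngBitDepth(path)
        a <- tryCatch(png::readPNG(path),
                      error = function(e) stop("failed to read PNG '", path,
                                               "': ", conditionMessage(e)))
        round(a * (2^depth - 1))
    } else {
        stop("unsupported image format '", ext, "' for ", path,
             " (TIFF or PNG expected)")
    }
}

# bit depth from the PNG IHDR chunk (byte 25 of the file)
.pngBitDepth <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- readBin(con, "raw", n = 25L)
    if (length(hdr) < 25L) stop("failed to read PNG '", path,
                                "': file truncated")
    as.integer(hdr[25L])
}

#' Write a CalibratedImage as a 16-bit grayscale TIFF
#'
#' Intensities are rounded to integers and stored losslessly for values in
#' 0..65535: writing and reloading with [loadImage()] round-trips the
#' integer intensities exactly.
#'
#' @param image a [CalibratedImage-class].
#' @param path output TIFF path.
#' @return Invisibly, \code{path}.
#' @export
writeCalibratedImage <- function(image, path) {
    stopifnot(is(image, "CalibratedImage"))
    v <- round(image@pixels)
    if (any(v < 0) || any(v > 65535))
        stop("intensities outside the 16-bit range 0..65535")
    tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L)
    invisible(path)
}
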